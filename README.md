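# fibrilcohesion

Collagen fibrils are held together laterally by a balance of weak
intermolecular forces whose strengths depend strongly on how much water sits
between the tropocollagen (TC) molecules. Tendon-like Type I fibrils are
relatively dry (1.6 g H2O per g dry collagen) and tightly packed; cartilage
Type II fibrils are far wetter (2.39 g/g) and looser. `fibrilcohesion`
implements a mesoscale model that decomposes the cohesive energy per TC
molecule into five hydration-modulated mechanisms and quantifies why the
hydrated Type II fibril is substantially weaker — useful to anyone
parameterizing coarse-grained models of collagen mechanics or studying
hydration-driven softening of cartilage.

## The model

For each mechanism the cohesive energy is (number of interactions) x
(energy per interaction), with explicit accessibility and shared-contact
divisors. Per TC molecule:

* **Direct hydrogen bonds.** Water competes with neighbouring molecules for
  the N ≈ 5,017 polar sites; the water-occupied fraction follows a Hill
  curve θ(C) = Cⁿ/(K_d ⁿ + Cⁿ) with K_d fitted from the Type I reference
  (392 direct bonds at 1.6 g/g, K_d = 0.136). Direct bonds number
  (1 − θ)N; the per-bond energy is 2.64 kcal/mol (Type I) or 1.58 kcal/mol
  (highly hydrated limit, Type II).
* **Water-mediated bridges.** One bridge per Gly-X-Y triplet. Single-water
  bridges carry 0.46 kcal/mol; in the expanded Type II lattice they become
  double-water bridges whose donor–acceptor path grows from 4.92 Å to
  7.72 Å, attenuating the energy by (4.92/7.72)³ ≈ 0.26 (dipolar 1/r³
  decay).
* **Van der Waals.** Contacts among surface-accessible side-chain atoms are
  counted statistically from element frequencies (P_X−Y = 2 f_X f_Y) and
  scored with Lennard-Jones well depths under Lorentz–Berthelot mixing;
  hydration swells all contact distances by the gap ratio (1.40 for
  Type II), attenuating the dispersion energy.
* **Hydrophobic association.** Each buried side-chain CH2/CH3 group gains
  ~0.057 kcal/mol per displaced water molecule (1.1 kcal/mol at the
  fully hydrated reference of 19.2 waters per residue), totalled as
  n_CHx · E_CHx / (2·2) for accessibility and sharing.
* **Salt bridges.** A charged residue (Asp/Glu/Lys/Arg; fraction P) pairs
  if at least one of the n facing residues across the gap is charged:
  P_coul = 1 − (1 − P)ⁿ, with n = 9 (Type I) or 7 (Type II). The per-pair
  energy 3.0 kcal/mol is screened by the Maxwell Garnett effective
  dielectric of the protein–water composite (ε = 21.2 → 26.9 between the
  two hydration states).

The lattice geometry itself is derived from hydration: lateral swelling at
conserved axial length gives spacing a ∝ √(1/ρ_c + C/ρ_w), reproducing the
19.1 Å Type II lattice from the 16.52 Å Type I reference.

## Worked example

```r
library(fibrilcohesion)

fit1 <- cohesion(collagen_scenario("typeI"))
fit2 <- cohesion(collagen_scenario("typeII"))
summary(fit2)
```

```
Cohesion decomposition summary - typeII
  Composition : 3648 residues, 1216 triplets, 551 charged (15.1%), 4152 CHx groups
  Hydration   : 2.39 g/g (70.5% wt, phi_w 76.3%)
  Geometry    : lattice 19.11 A, gap 9.11 A, swelling 1.397
  Dielectric  : eps 27.0 (reference 21.1)
  H-bonds     : Kd 0.136, 269 direct bonds x 1.58 kcal/mol
  Salt bridges: pairing 68.2%, 188 bridges x 2.35 kcal/mol
Cohesion decomposition: typeII (total 2206 kcal/mol per TC)
  hbond           425 kcal/mol  (19%)
  water_bridge     72 kcal/mol  ( 3%)
  vdw             125 kcal/mol  ( 6%)
  hydrophobic    1142 kcal/mol  (52%)
  coulomb         442 kcal/mol  (20%)
```

The Type II fibril totals ~2,206 kcal/mol per molecule versus ~3,046 for
Type I — a 27.6% reduction:

```r
round(100 * compare_cohesion(fit1, fit2)$reduction, 1)
#> [1] 27.6
```

Hydrophobic association dominates the wet fibril (52% of cohesion) while
the dry fibril is dominated by direct hydrogen bonds (34%). A hydration
sweep is available via `predict(fit1, c_gg = seq(1, 3, 0.1))`, synthetic
collagen-like chains via `generate_chain()`, and composition input from
FASTA (`read_fasta_chains()`) or TSV count tables
(`read_composition_tsv()`; synthetic per-type tables ship in
`inst/extdata/`).

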