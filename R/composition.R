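# Residue-level chemistry tables and composition statistics.
#
# All per-tropocollagen (TC) statistics downstream energy mechanisms consume
# are derived here: residue counts, side-chain atom composition and element
# frequencies, charged-residue tallies, and CH2/CH3 group counts.

# Side-chain elemental formulas, obtained by subtracting the repeating
# backbone unit C2H4NO2 (the -NH-CHa-CO- peptide unit plus its hydrogens as
# present in the free amino acid) from the full amino-acid formula. Glycine
# is left with a single side-chain hydrogen under this convention.
# Rows "O" (4-hydroxyproline) and "J" (5-hydroxylysine) are optional alphabet
# extensions for hydroxylated chains.
SIDECHAIN_FORMULAS <- local({
  m <- rbind(
    A = c(1, 3, 0, 0, 0),
    R = c(4, 10, 3, 0, 0),
    N = c(2, 4, 1, 1, 0),
    D = c(2, 3, 0, 2, 0),
    C = c(1, 3, 0, 0, 1),
    E = c(3, 5, 0, 2, 0),
    Q = c(3, 6, 1, 1, 0),
    G = c(0, 1, 0, 0, 0),
    H = c(4, 5, 2, 0, 0),
    I = c(4, 9, 0, 0, 0),
    L = c(4, 9, 0, 0, 0),
    K = c(4, 10, 1, 0, 0),
    M = c(3, 7, 0, 0, 1),
    F = c(7, 7, 0, 0, 0),
    P = c(3, 5, 0, 0, 0),
    S = c(1, 3, 0, 1, 0),
    T = c(2, 5, 0, 1, 0),
    W = c(9, 8, 1, 0, 0),
    Y = c(7, 7, 0, 1, 0),
    V = c(3, 7, 0, 0, 0),
    O = c(3, 5, 0, 1, 0),
    J = c(4, 10, 1, 1, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  m
})

# Full amino-acid formulas (free amino acid), used only to assert atom
# conservation: backbone C2H4NO2 + side chain = full formula.
BACKBONE_FORMULA <- c(C = 2, H = 4, N = 1, O = 2, S = 0)

#' @keywords internal
AA_ALPHABET <- rownames(SIDECHAIN_FORMULAS)

# CH2/CH3 groups per side chain. Only purely aliphatic stalk groups are
# counted as hydrophobic contributors; single-hydrogen CH groups and
# methyl(ene) groups attached directly to polar moieties (Ser, Thr, Cys,
# Tyr, Asn, Gln, Asp, Glu, His) contribute negligible burial stabilization
# and are excluded. Hydroxyproline keeps two ring methylenes (the
# hydroxyl-bearing carbon is a CH), hydroxylysine three.
CHX_GROUPS <- c(
  A = 1, R = 3, N = 0, D = 0, C = 0, E = 0, Q = 0, G = 0, H = 0, I = 3,
  L = 3, K = 4, M = 3, F = 1, P = 3, S = 0, T = 0, W = 1, Y = 0, V = 2,
  O = 2, J = 3
)

# The four principal charged residues at physiological pH.
CHARGED_RESIDUES <- c("D", "E", "K", "R")

# Side-chain extension from the backbone C-alpha to the charged terminal
# atom (Angstrom), projected geometry from standard bond lengths.
SIDECHAIN_REACH_A <- c(R = 6.3, K = 6.2, D = 3.6, E = 4.8)

# round-half-up for interaction counts (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Construct a collagen chain sequence
#'
#' A chain is an ordered vector of one-letter residue codes together with a
#' stoichiometric multiplicity: a homotrimeric molecule (e.g. type II
#' collagen, alpha1 x3) can be given as one chain with `multiplicity = 3`,
#' a heterotrimer (type I, alpha1 x2 + alpha2) as two chains with
#' multiplicities 2 and 1.
#'
#' @param residues character vector of one-letter codes, or a single string.
#'   Lowercase is accepted and upcased. Codes `O` (hydroxyproline) and `J`
#'   (hydroxylysine) are accepted as alphabet extensions.
#' @param id text label for the chain.
#' @param multiplicity number of copies of this chain per molecule.
#' @return an object of class `chain_sequence`.
#' @examples
#' chain_sequence("GPAGPA", id = "toy")
#' @export
chain_sequence <- function(residues, id = "chain", multiplicity = 1L) {
  if (length(residues) == 1L && nchar(residues[1]) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(as.character(residues))
  if (length(residues) < 3L) {
    stop("chain '", id, "': need at least 3 residues, got ", length(residues))
  }
  bad <- which(!residues %in% AA_ALPHABET)
  if (length(bad)) {
    stop("chain '", id, "': illegal residue character '", residues[bad[1]],
         "' at position ", bad[1])
  }
  if (multiplicity < 1L) stop("multiplicity must be >= 1")
  structure(
    list(id = as.character(id), residues = residues,
         multiplicity = as.integer(multiplicity)),
    class = "chain_sequence"
  )
}

#' @export
print.chain_sequence <- function(x, ...) {
  cat(sprintf("<chain_sequence> %s: %d residues x%d\n",
              x$id, length(x$residues), x$multiplicity))
  invisible(x)
}

#' Fraction of triplet positions occupied by glycine
#'
#' Collagen chains are built from Gly-X-Y triplets; this reports the fraction
#' of first-in-triplet positions (0-based positions 0, 3, 6, ...) holding
#' glycine, a quick diagnostic of collagen-likeness.
#'
#' @param chain a [chain_sequence()].
#' @return a fraction in `[0, 1]`.
#' @export
triplet_fraction <- function(chain) {
  stopifnot(inherits(chain, "chain_sequence"))
  idx <- seq(1L, length(chain$residues), by = 3L)
  mean(chain$residues[idx] == "G")
}

#' Read collagen chains from a FASTA file
#'
#' Thin wrapper over [seqinr::read.fasta()] that validates the residue
#' alphabet and preserves record order. Each record becomes one
#' [chain_sequence()] with multiplicity 1 (set multiplicities afterwards for
#' homotrimers).
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @return list of [chain_sequence()] objects, in file order.
#' @export
read_fasta_chains <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                       forceDNAtolower = FALSE),
    error = function(e) stop("cannot parse FASTA '", path, "': ",
                             conditionMessage(e))
  )
  if (!length(recs)) stop("FASTA file '", path, "' contains no records")
  lapply(seq_along(recs), function(i) {
    chain_sequence(as.character(recs[[i]]), id = names(recs)[i])
  })
}

#' Read a residue-composition table (TSV)
#'
#' Alternative entry point to FASTA input: a two-column tab-separated table
#' with columns `residue` and `count_per_TC`, giving counts summed over the
#' three chains of one tropocollagen molecule.
#'
#' @param path path to the TSV file.
#' @return a [residue_counts()] object.
#' @export
read_composition_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "count_per_TC")
  if (!all(need %in% names(df))) {
    stop("composition table must have columns: ", paste(need, collapse = ", "))
  }
  counts <- as.integer(df$count_per_TC)
  names(counts) <- toupper(df$residue)
  residue_counts(counts)
}

#' Per-molecule residue counts
#'
#' @param counts named integer vector, residue code -> count per TC molecule.
#' @return object of class `residue_counts` with fields `counts`,
#'   `n_residues` and `n_triplets` (= `n_residues / 3`, rounded half up;
#'   collagen sequences are expected to be triplet multiples).
#' @export
residue_counts <- function(counts) {
  if (!length(counts)) stop("empty residue counts")
  bad <- setdiff(names(counts), AA_ALPHABET)
  if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("negative residue counts")
  counts <- counts[counts > 0]
  n <- sum(counts)
  structure(
    list(counts = counts, n_residues = as.integer(n),
         n_triplets = as.integer(round_half_up(n / 3))),
    class = "residue_counts"
  )
}

#' @export
print.residue_counts <- function(x, ...) {
  cat(sprintf("<residue_counts> %d residues, %d triplets, %d residue types\n",
              x$n_residues, x$n_triplets, length(x$counts)))
  invisible(x)
}

#' Profile a tropocollagen molecule from its chains
#'
#' Sums residue counts over all chains, each weighted by its multiplicity.
#' A TC molecule is three alpha-chains; give either three chains, or fewer
#' chains whose multiplicities sum to three.
#'
#' @param chains list of [chain_sequence()] objects (or a single chain).
#' @return a [residue_counts()] object.
#' @export
profile_tc <- function(chains) {
  if (inherits(chains, "chain_sequence")) chains <- list(chains)
  if (!length(chains)) stop("profile_tc(): no chains given")
  tab <- integer(length(AA_ALPHABET))
  names(tab) <- AA_ALPHABET
  for (ch in chains) {
    stopifnot(inherits(ch, "chain_sequence"))
    t1 <- table(factor(ch$residues, levels = AA_ALPHABET))
    tab <- tab + as.integer(t1) * ch$multiplicity
  }
  residue_counts(tab)
}

#' Side-chain elemental formula of a residue
#'
#' Subtracting the backbone unit C2H4NO2 from the full amino-acid formula
#' leaves the side chain; arginine (C6H14N4O2) gives C4H10N3, glycine a
#' single hydrogen.
#'
#' @param residue one-letter code.
#' @return named integer vector over elements C, H, N, O, S.
#' @examples
#' sidechain_formula("R")  # C4 H10 N3
#' @export
sidechain_formula <- function(residue) {
  residue <- toupper(residue)
  if (!residue %in% AA_ALPHABET) stop("unknown residue code: ", residue)
  f <- SIDECHAIN_FORMULAS[residue, ]
  storage.mode(f) <- "integer"
  f
}

#' Side-chain atom composition of a molecule
#'
#' Sums side-chain elemental formulas over all residues and normalizes to
#' element frequencies; these frequencies drive the van der Waals pair
#' statistics.
#'
#' @param rc a [residue_counts()] object.
#' @return object of class `atom_composition` with fields `atoms` (named
#'   counts over C, H, N, O, S), `total` and `frequencies`.
#' @export
atom_composition <- function(rc) {
  stopifnot(inherits(rc, "residue_counts"))
  m <- SIDECHAIN_FORMULAS[names(rc$counts), , drop = FALSE]
  atoms <- colSums(m * rc$counts)
  total <- sum(atoms)
  structure(
    list(atoms = atoms, total = total,
         frequencies = if (total > 0) atoms / total else atoms),
    class = "atom_composition"
  )
}

#' @export
print.atom_composition <- function(x, ...) {
  cat(sprintf("<atom_composition> %d side-chain atoms\n", x$total))
  print(round(x$frequencies, 4))
  invisible(x)
}

#' Charged-residue statistics
#'
#' Counts the four principal charged residues (Asp, Glu, Lys, Arg) per TC
#' molecule; histidine is excluded (low abundance in collagen).
#'
#' @param rc a [residue_counts()] object.
#' @return list with `n_charged`, `charged_fraction` and the per-residue
#'   breakdown `by_residue`.
#' @export
charge_stats <- function(rc) {
  stopifnot(inherits(rc, "residue_counts"))
  by <- rc$counts[intersect(CHARGED_RESIDUES, names(rc$counts))]
  n <- sum(by)
  list(n_charged = as.integer(n),
       charged_fraction = n / rc$n_residues,
       by_residue = by)
}

#' Hydrophobic CH2/CH3 group statistics
#'
#' Counts side-chain CH2/CH3 groups per TC molecule using the embedded
#' per-residue group table (`CHX_GROUPS`); alpha-CH groups are never counted.
#'
#' @param rc a [residue_counts()] object.
#' @return list with `n_chx_groups` (total CH2 + CH3 groups) and
#'   `n_hydrophobic_residues` (residues carrying at least one group).
#' @export
chx_stats <- function(rc) {
  stopifnot(inherits(rc, "residue_counts"))
  g <- CHX_GROUPS[names(rc$counts)]
  list(n_chx_groups = as.integer(sum(g * rc$counts)),
       n_hydrophobic_residues = as.integer(sum(rc$counts[g > 0])))
}
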