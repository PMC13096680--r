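# The fitted cohesion model: one call runs composition -> geometry ->
# five mechanisms -> assembled decomposition for a scenario.

#' Fit the cohesion decomposition for a fibril scenario
#'
#' Runs the full mesoscale pipeline for one fibril type: composition
#' statistics from the scenario profile, hydration-derived lattice geometry
#' and effective dielectric, then the five energy mechanisms (direct
#' hydrogen bonds, water-mediated bridges, van der Waals, hydrophobic,
#' coulombic), assembled into a [cohesion_decomposition()].
#'
#' @param scenario a [collagen_scenario()].
#' @return object of class `cohesion` with elements `scenario`,
#'   `hydration`, `geometry`, `dielectric`, `stats` (composition
#'   intermediates), `details` (per-mechanism intermediates) and
#'   `decomposition`.
#' @examples
#' fit <- cohesion(collagen_scenario("typeI"))
#' print(fit)
#' coef(fit)
#' @export
cohesion <- function(scenario = collagen_scenario("typeI")) {
  stopifnot(inherits(scenario, "collagen_scenario"))
  sc <- scenario
  rc <- sc$profile

  # hydration & lattice geometry
  h <- hydration_state(sc$c_gg, sc$rho_water, sc$rho_collagen)
  h_ref <- hydration_state(sc$ref_c_gg, sc$rho_water, sc$rho_collagen)
  lattice <- lattice_spacing(sc$ref_lattice_A, h_ref, h)
  geom <- fibril_geometry(lattice, sc$core_diameter_A)
  geom_ref <- fibril_geometry(sc$ref_lattice_A, sc$core_diameter_A)
  swell <- swelling_factor(geom, geom_ref)

  # effective dielectric at this and at the reference hydration
  eps_eff <- maxwell_garnett(sc$eps_protein, sc$eps_water, h$phi_w)
  eps_ref <- maxwell_garnett(sc$eps_protein, sc$eps_water, h_ref$phi_w)

  # hydrogen bonds: Hill model fitted at the reference state
  hill <- fit_kd(sc$hbond_c_ref, sc$hbond_direct_ref, sc$hbond_n_total,
                 sc$hbond_n_hill)
  n_direct <- direct_bond_count(sc$c_gg, hill)
  hbond <- hbond_component(n_direct, sc$hbond_e_per_bond)

  # water bridges
  bgeom <- bridge_geometry(sc$bridge_leg_A, sc$bridge_da_single_A,
                           sc$bridge_ow_ow_A, sc$bridge_decay_exponent)
  benerg <- bridge_energetics(sc$bridge_e_single, bgeom, sc$bridge_sharing)
  n_bridges <- bridge_count(rc)
  bridge <- bridge_component(n_bridges, sc$bridge_type, benerg)

  # van der Waals
  ac <- atom_composition(rc)
  n_acc <- accessible_atom_count(ac, sc$vdw_accessibility)
  pt <- vdw_pair_table(ac, n_acc, sc$vdw_lj)
  # compression below the reference does not strengthen dispersion cohesion
  # beyond contact (side chains reorient), so swelling is floored at 1
  vdw_computed <- vdw_component(pt, swelling = max(swell, 1))
  pin <- if (isTRUE(sc$use_computed_vdw)) NULL else sc$vdw_pinned_total
  vdw <- if (is.null(pin)) {
    vdw_computed
  } else {
    energy_component("vdw", vdw_computed$n_interactions,
                     vdw_computed$e_per_interaction,
                     divisors = vdw_computed$divisors,
                     total_kcal_mol = pin,
                     detail = c(vdw_computed$detail,
                                list(pinned = TRUE,
                                     note = "calibration reference total")))
  }

  # hydrophobic
  hscale <- hydrophobic_scale(sc$hydroph_e_per_group_ref, sc$hydroph_waters_ref,
                              sc$hydroph_accessibility_divisor,
                              sc$hydroph_sharing_divisor)
  chx <- chx_stats(rc)
  e_group <- per_group_energy(sc$hydroph_waters, hscale)
  hydroph <- hydrophobic_component(chx$n_chx_groups, e_group, hscale)

  # coulomb
  chg <- charge_stats(rc)
  p_pair <- pairing_probability(chg$charged_fraction, sc$coulomb_n_window)
  n_salt <- salt_bridge_count(p_pair, chg$n_charged)
  e_pair <- scaled_bridge_energy(sc$coulomb_e_ref, eps_ref, eps_eff)
  coul <- coulomb_component(n_salt, e_pair)

  decomp <- assemble(list(hbond, bridge, vdw, hydroph, coul), label = sc$label)

  structure(
    list(
      scenario = sc,
      hydration = h,
      geometry = geom,
      swelling = swell,
      dielectric = list(eps_effective = eps_eff, eps_reference = eps_ref),
      stats = list(atom_composition = ac, charge = chg, chx = chx,
                   accessible_atoms = n_acc),
      details = list(hill = hill, n_direct_bonds = n_direct,
                     bridge_energetics = benerg,
                     vdw_pair_table = pt, vdw_computed = vdw_computed,
                     pairing_probability = p_pair,
                     salt_bridges = n_salt, e_salt_pair = e_pair),
      decomposition = decomp
    ),
    class = "cohesion"
  )
}

#' @export
print.cohesion <- function(x, ...) {
  cat(sprintf("Collagen fibril cohesion model - %s\n", x$scenario$label))
  cat(sprintf("  hydration %.3g g/g | lattice %.2f A | eps_eff %.1f\n",
              x$hydration$c_gg, x$geometry$lattice_A,
              x$dielectric$eps_effective))
  print(x$decomposition)
  invisible(x)
}

#' @export
summary.cohesion <- function(object, ...) {
  structure(list(fit = object), class = "summary.cohesion")
}

#' @export
print.summary.cohesion <- function(x, ...) {
  f <- x$fit
  sc <- f$scenario
  cat(sprintf("Cohesion decomposition summary - %s\n", sc$label))
  cat(sprintf("  Composition : %d residues, %d triplets, %d charged (%.1f%%), %d CHx groups\n",
              sc$profile$n_residues, sc$profile$n_triplets,
              f$stats$charge$n_charged, 100 * f$stats$charge$charged_fraction,
              f$stats$chx$n_chx_groups))
  cat(sprintf("  Hydration   : %.3g g/g (%.1f%% wt, phi_w %.1f%%)\n",
              f$hydration$c_gg, 100 * f$hydration$w_frac,
              100 * f$hydration$phi_w))
  cat(sprintf("  Geometry    : lattice %.2f A, gap %.2f A, swelling %.3f\n",
              f$geometry$lattice_A, f$geometry$radial_gap_A, f$swelling))
  cat(sprintf("  Dielectric  : eps %.1f (reference %.1f)\n",
              f$dielectric$eps_effective, f$dielectric$eps_reference))
  cat(sprintf("  H-bonds     : Kd %.3f, %d direct bonds x %.2f kcal/mol\n",
              f$details$hill$kd, f$details$n_direct_bonds,
              sc$hbond_e_per_bond))
  cat(sprintf("  Salt bridges: pairing %.1f%%, %.0f bridges x %.2f kcal/mol\n",
              100 * f$details$pairing_probability,
              round_half_up(f$details$salt_bridges), f$details$e_salt_pair))
  print(f$decomposition)
  invisible(x)
}

#' Component energies of a fitted cohesion model
#'
#' @param object a [cohesion()] fit.
#' @param ... unused.
#' @return named numeric vector: the five mechanism totals and `total`
#'   (kcal/mol per TC molecule, unrounded).
#' @export
coef.cohesion <- function(object, ...) {
  d <- object$decomposition
  totals <- vapply(d$components, function(x) x$total_kcal_mol, numeric(1))
  c(totals, total = d$total_kcal_mol)
}

#' Hydration sweep of the cohesion decomposition
#'
#' Re-evaluates the model over a grid of hydration levels. Mechanism rules
#' that are per-type constants in the headline scenarios are replaced by
#' hydration-continuous surrogates, so the sweep is exploratory rather than
#' exact at the two study points: the per-bond hydrogen-bond energy is
#' interpolated in weight fraction, the bridge type switches from single to
#' double once the lattice expansion exceeds half a water-water spacing,
#' displaced waters per residue follow the linear reference anchoring, the
#' accessibility window shrinks linearly with the radial gap, and the van
#' der Waals total follows the pinned reference attenuated by the swelling
#' factor.
#'
#' @param object a [cohesion()] fit.
#' @param c_gg numeric vector of hydration levels (g/g).
#' @param ... unused.
#' @return data.frame with one row per hydration level: lattice, dielectric
#'   and the component/total energies.
#' @export
predict.cohesion <- function(object, c_gg = seq(1.0, 3.0, by = 0.1), ...) {
  sc <- object$scenario
  rows <- lapply(c_gg, function(ci) {
    h <- hydration_state(ci, sc$rho_water, sc$rho_collagen)
    h_ref <- hydration_state(sc$ref_c_gg, sc$rho_water, sc$rho_collagen)
    lattice <- lattice_spacing(sc$ref_lattice_A, h_ref, h)
    geom <- fibril_geometry(lattice, sc$core_diameter_A)
    swell <- swelling_factor(geom, fibril_geometry(sc$ref_lattice_A,
                                                   sc$core_diameter_A))
    eps <- maxwell_garnett(sc$eps_protein, sc$eps_water, h$phi_w)
    eps_ref <- object$dielectric$eps_reference

    hill <- object$details$hill
    nb <- direct_bond_count(ci, hill)
    e_b <- hbond_energy_interpolated(ci)
    hb <- nb * e_b

    benerg <- object$details$bridge_energetics
    delta <- lattice - sc$ref_lattice_A
    type <- if (delta >= benerg$geometry$ow_ow_A / 2) "double" else "single"
    wb <- bridge_component(bridge_count(sc$profile), type, benerg)$total_kcal_mol

    vdw_ref <- if (!is.null(sc$vdw_pinned_total) && !isTRUE(sc$use_computed_vdw)) {
      # pinned total quoted at the scenario's own swelling; rescale to s = 1
      sc$vdw_pinned_total / lj_swelling_attenuation(object$swelling)
    } else {
      object$details$vdw_computed$total_kcal_mol /
        lj_swelling_attenuation(object$swelling)
    }
    vdw <- vdw_ref * lj_swelling_attenuation(max(swell, 1))

    hscale <- hydrophobic_scale(sc$hydroph_e_per_group_ref,
                                sc$hydroph_waters_ref,
                                sc$hydroph_accessibility_divisor,
                                sc$hydroph_sharing_divisor)
    waters <- waters_per_residue(h, sc$profile)
    hyd <- hydrophobic_component(object$stats$chx$n_chx_groups,
                                 per_group_energy(max(waters, 0), hscale),
                                 hscale)$total_kcal_mol

    # window scales with the reference windows at the two anchor gaps
    gap <- geom$radial_gap_A
    n_win <- max(1L, round_half_up(9 + (7 - 9) * (gap - 6.52) / (9.1 - 6.52)))
    p_pair <- pairing_probability(object$stats$charge$charged_fraction, n_win)
    ns <- salt_bridge_count(p_pair, object$stats$charge$n_charged)
    cl <- ns * scaled_bridge_energy(sc$coulomb_e_ref, eps_ref, eps)

    data.frame(c_gg = ci, lattice_A = lattice, swelling = swell,
               eps_effective = eps, hbond = hb, water_bridge = wb, vdw = vdw,
               hydrophobic = hyd, coulomb = cl,
               total = hb + wb + vdw + hyd + cl)
  })
  do.call(rbind, rows)
}

#' Bar plot of the cohesion decomposition
#'
#' @param x a [cohesion()] fit (optionally compare against a second fit).
#' @param y optional second fit to plot side by side.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.cohesion <- function(x, y = NULL, ...) {
  t1 <- coef(x)[MECHANISMS]
  if (is.null(y)) {
    graphics::barplot(t1, ylab = "kcal/mol per TC",
                      main = sprintf("Cohesive energy - %s", x$scenario$label),
                      ...)
  } else {
    m <- rbind(t1, coef(y)[MECHANISMS])
    graphics::barplot(m, beside = TRUE, ylab = "kcal/mol per TC",
                      legend.text = c(x$scenario$label, y$scenario$label),
                      main = "Cohesive energy components", ...)
  }
  invisible(x)
}

#' Compare two fitted cohesion models
#'
#' @param fit1,fit2 [cohesion()] fits (reference first).
#' @return the [compare_decompositions()] record.
#' @export
compare_cohesion <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "cohesion"), inherits(fit2, "cohesion"))
  compare_decompositions(fit1$decomposition, fit2$decomposition)
}
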