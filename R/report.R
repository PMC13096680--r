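# Energy components, the assembled cohesion decomposition, cross-type
# comparison, coarse-grained reference cross-check and report serialization.

MECHANISMS <- c("hbond", "water_bridge", "vdw", "hydrophobic", "coulomb")

#' One mechanism's energy component
#'
#' @param mechanism one of `"hbond"`, `"water_bridge"`, `"vdw"`,
#'   `"hydrophobic"`, `"coulomb"`.
#' @param n_interactions interaction count (may be fractional when an
#'   unrounded intermediate is carried through, e.g. salt bridges).
#' @param e_per_interaction energy per interaction (kcal/mol).
#' @param divisors named vector of accessibility/sharing divisors applied to
#'   the product.
#' @param total_kcal_mol override for the total; by default
#'   `n * e / prod(divisors)`.
#' @param detail free-form list of mechanism-specific intermediates.
#' @return object of class `energy_component`.
#' @export
energy_component <- function(mechanism, n_interactions, e_per_interaction,
                             divisors = numeric(0), total_kcal_mol = NULL,
                             detail = list()) {
  mechanism <- match.arg(mechanism, MECHANISMS)
  if (n_interactions < 0 || e_per_interaction < 0) {
    stop("counts and energies must be non-negative")
  }
  if (length(divisors) && any(divisors < 1)) stop("divisors must be >= 1")
  total <- n_interactions * e_per_interaction / prod(divisors)
  if (!is.null(total_kcal_mol)) {
    detail$computed_total_kcal_mol <- total
    total <- total_kcal_mol
  }
  structure(
    list(mechanism = mechanism,
         n_interactions = n_interactions,
         e_per_interaction = e_per_interaction,
         divisors = divisors,
         total_kcal_mol = total,
         detail = detail),
    class = "energy_component"
  )
}

#' @export
print.energy_component <- function(x, ...) {
  cat(sprintf("<energy_component> %-12s n = %-8.6g e = %-7.4g -> %.1f kcal/mol\n",
              x$mechanism, x$n_interactions, x$e_per_interaction,
              x$total_kcal_mol))
  invisible(x)
}

#' Assemble the five components into a cohesion decomposition
#'
#' @param components list of five [energy_component()] objects, one per
#'   mechanism (any order).
#' @param label fibril label, e.g. `"typeI"`.
#' @return object of class `cohesion_decomposition` with the unrounded
#'   component totals, the grand total, exact fractional shares and their
#'   rounded display percentages.
#' @export
assemble <- function(components, label = "fibril") {
  mechs <- vapply(components, function(x) x$mechanism, character(1))
  if (length(components) != length(MECHANISMS) || !setequal(mechs, MECHANISMS)) {
    stop("need exactly one component per mechanism: ",
         paste(MECHANISMS, collapse = ", "))
  }
  components <- components[match(MECHANISMS, mechs)]
  names(components) <- MECHANISMS
  totals <- vapply(components, function(x) x$total_kcal_mol, numeric(1))
  total <- sum(totals)
  if (total <= 0) stop("degenerate decomposition: total energy is zero")
  structure(
    list(label = label, components = components,
         total_kcal_mol = total,
         fractions = totals / total,
         percent_display = round(100 * totals / total)),
    class = "cohesion_decomposition"
  )
}

#' @export
print.cohesion_decomposition <- function(x, ...) {
  cat(sprintf("Cohesion decomposition: %s (total %.0f kcal/mol per TC)\n",
              x$label, x$total_kcal_mol))
  for (m in MECHANISMS) {
    cmp <- x$components[[m]]
    cat(sprintf("  %-12s %6.0f kcal/mol  (%2d%%)\n",
                m, cmp$total_kcal_mol, x$percent_display[[m]]))
  }
  invisible(x)
}

#' Compare two cohesion decompositions
#'
#' @param d1,d2 [assemble()]d decompositions (reference first).
#' @return list with per-mechanism and total absolute/relative differences
#'   and the overall `reduction` `(T1 - T2)/T1`.
#' @export
compare_decompositions <- function(d1, d2) {
  stopifnot(inherits(d1, "cohesion_decomposition"),
            inherits(d2, "cohesion_decomposition"))
  t1 <- vapply(d1$components, function(x) x$total_kcal_mol, numeric(1))
  t2 <- vapply(d2$components, function(x) x$total_kcal_mol, numeric(1))
  list(labels = c(d1$label, d2$label),
       delta_kcal_mol = t1 - t2,
       relative_delta = (t1 - t2) / t1,
       total_delta_kcal_mol = d1$total_kcal_mol - d2$total_kcal_mol,
       reduction = (d1$total_kcal_mol - d2$total_kcal_mol) / d1$total_kcal_mol)
}

#' Coarse-grained bead-spring reference energy
#'
#' Total lateral cohesion implied by a hexagonally packed bead-spring model
#' of the TC molecule: `epsilon * n_beads * coordination * f_gap / 2`, where
#' the factor 2 removes pair double counting and `f_gap` discounts beads in
#' the D-period gap regions. With epsilon = 6.72 kcal/mol, 218 beads,
#' coordination 6 and the calibrated `f_gap = 0.89` this gives
#' ~3,911 kcal/mol, the energy scale against which the decomposition total
#' is checked.
#'
#' @param epsilon_kcal bead pair-potential well depth (kcal/mol).
#' @param n_beads beads per molecule.
#' @param coordination lateral neighbours per bead in the hexagonal lattice.
#' @param f_gap gap-region discount factor (calibrated, not derived).
#' @return energy in kcal/mol.
#' @export
buehler_reference <- function(epsilon_kcal = 6.72, n_beads = 218L,
                              coordination = 6L, f_gap = 0.89) {
  stopifnot(epsilon_kcal >= 0, n_beads >= 0, coordination >= 0,
            f_gap >= 0, f_gap <= 1)
  epsilon_kcal * n_beads * coordination * f_gap / 2
}

#' Serialize a cohesion decomposition
#'
#' Deterministic report: mechanisms in fixed order, unrounded totals plus
#' display integers; no timestamps. JSON reports round-trip through
#' [read_cohesion_report()].
#'
#' @param d a [cohesion_decomposition()].
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_cohesion_report <- function(d, path, format = c("json", "tsv")) {
  stopifnot(inherits(d, "cohesion_decomposition"))
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      package = "fibrilcohesion",
      version = as.character(utils::packageVersion("fibrilcohesion")),
      label = d$label,
      total_kcal_mol = d$total_kcal_mol,
      total_display = round(d$total_kcal_mol),
      components = lapply(d$components, function(cmp) {
        list(mechanism = cmp$mechanism,
             n_interactions = cmp$n_interactions,
             e_per_interaction = cmp$e_per_interaction,
             divisors = as.list(cmp$divisors),
             total_kcal_mol = cmp$total_kcal_mol,
             total_display = round(cmp$total_kcal_mol))
      }),
      fractions = as.list(d$fractions),
      percent_display = as.list(d$percent_display)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    totals <- vapply(d$components, function(x) x$total_kcal_mol, numeric(1))
    df <- data.frame(
      mechanism = c(MECHANISMS, "total"),
      kcal_mol = round(c(totals, d$total_kcal_mol), 1),
      display = round(c(totals, d$total_kcal_mol)),
      percent = c(d$percent_display, 100)
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON cohesion report
#'
#' @param path a JSON file written by [write_cohesion_report()].
#' @return a [cohesion_decomposition()].
#' @export
read_cohesion_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  comps <- lapply(obj$components, function(cmp) {
    energy_component(cmp$mechanism, cmp$n_interactions, cmp$e_per_interaction,
                     divisors = unlist(cmp$divisors),
                     total_kcal_mol = cmp$total_kcal_mol)
  })
  assemble(comps, label = obj$label)
}
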