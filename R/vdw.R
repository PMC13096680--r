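# Dispersion (van der Waals) cohesion from side-chain atom statistics.
#
# No coordinates are used: contacts are counted statistically from element
# frequencies among surface-accessible side-chain atoms, and each contact is
# scored with a Lennard-Jones pair energy at the equilibrium separation,
# attenuated when hydration swells the intermolecular gap.

#' Default Lennard-Jones parameter table
#'
#' Representative force-field atom classes for side-chain atoms in collagen:
#' aliphatic sp3 carbon (CT2-like), carbonyl/carboxyl oxygen, amide nitrogen
#' (NH1-like), aliphatic hydrogen (HA2-like) and thioether sulfur. `sigma_A`
#' is the zero-crossing distance (Angstrom), `epsilon_kcal` the well depth.
#' Values are embedded class representatives and can be overridden via a
#' table of the same shape.
#'
#' @return data.frame with columns `element`, `class`, `sigma_A`,
#'   `epsilon_kcal`.
#' @export
lj_default_params <- function() {
  rmin_half <- c(C = 2.010, H = 1.340, N = 1.850, O = 1.700, S = 2.000)
  eps <- c(C = 0.056, H = 0.034, N = 0.200, O = 0.120, S = 0.450)
  cls <- c(C = "CT2-like", H = "HA2-like", N = "NH1-like",
           O = "carbonyl/carboxyl", S = "thioether")
  data.frame(
    element = names(eps),
    class = cls[names(eps)],
    sigma_A = 2 * rmin_half[names(eps)] / 2^(1 / 6),
    epsilon_kcal = eps,
    row.names = names(eps),
    stringsAsFactors = FALSE
  )
}

#' Number of surface-accessible side-chain atoms
#'
#' By the symmetry of the triple helix about half of the side chains face
#' outward toward neighbouring molecules; only their atoms can form
#' intermolecular contacts.
#'
#' @param ac an [atom_composition()].
#' @param accessibility fraction of side-chain atoms accessible, default 0.5.
#' @return integer atom count.
#' @export
accessible_atom_count <- function(ac, accessibility = 0.5) {
  stopifnot(inherits(ac, "atom_composition"))
  if (accessibility <= 0 || accessibility > 1) {
    stop("accessibility must lie in (0, 1]")
  }
  as.integer(round_half_up(ac$total * accessibility))
}

#' Pairwise contact probability from element frequencies
#'
#' Cross pairs occur with probability `2 * fX * fY`, self pairs with `fX^2`,
#' so probabilities over all unordered element pairs sum to one.
#'
#' @param f_x,f_y element frequencies.
#' @param same logical: is this a self pair (X == Y)?
#' @return probability.
#' @export
pair_probability <- function(f_x, f_y, same = FALSE) {
  if (f_x < 0 || f_x > 1 || f_y < 0 || f_y > 1) stop("frequencies must lie in [0, 1]")
  if (same) f_x * f_y else 2 * f_x * f_y
}

#' Lorentz-Berthelot mixing rules
#'
#' Arithmetic mean of sigma, geometric mean of epsilon.
#'
#' @param sigma_i,sigma_j zero-crossing distances (Angstrom).
#' @param eps_i,eps_j well depths (kcal/mol).
#' @return list with `sigma_A` and `epsilon_kcal`.
#' @export
mix_lj <- function(sigma_i, eps_i, sigma_j, eps_j) {
  list(sigma_A = (sigma_i + sigma_j) / 2,
       epsilon_kcal = sqrt(eps_i * eps_j))
}

#' Lennard-Jones 12-6 pair energy
#'
#' `4 eps [ (sigma/r)^12 - (sigma/r)^6 ]`; minimum `-eps` at
#' `r = 2^(1/6) sigma`.
#'
#' @param r separation (Angstrom).
#' @param sigma_A zero-crossing distance (Angstrom).
#' @param epsilon_kcal well depth (kcal/mol).
#' @return energy (kcal/mol; negative in the attractive well).
#' @export
lj_energy <- function(r, sigma_A, epsilon_kcal) {
  if (any(r <= 0)) stop("r must be positive")
  sr6 <- (sigma_A / r)^6
  4 * epsilon_kcal * (sr6^2 - sr6)
}

# relative magnitude of the LJ energy at r = s * r_min (equals 1 at s = 1);
# identical for every pair, so swelling is a pure geometric attenuation
lj_swelling_attenuation <- function(s) {
  if (any(s < 1)) stop("swelling factor must be >= 1")
  x6 <- (1 / (s * 2^(1 / 6)))^6
  abs(4 * (x6^2 - x6))
}

#' Statistical van der Waals pair table
#'
#' Distributes `n_total` accessible atoms over all unordered element pairs
#' by contact probability, and attaches Lorentz-Berthelot mixed LJ
#' parameters per pair.
#'
#' @param ac an [atom_composition()].
#' @param n_total total accessible atoms (see [accessible_atom_count()]).
#' @param lj LJ parameter table, by default [lj_default_params()].
#' @return data.frame of class `vdw_pair_table` with one row per unordered
#'   element pair: probability, count, mixed sigma/epsilon.
#' @export
vdw_pair_table <- function(ac, n_total, lj = lj_default_params()) {
  stopifnot(inherits(ac, "atom_composition"))
  els <- rownames(lj)
  f <- ac$frequencies[els]
  f[is.na(f)] <- 0
  names(f) <- els
  pairs <- utils::combn(seq_along(els), 2)
  rows <- data.frame(
    x = c(els, els[pairs[1, ]]),
    y = c(els, els[pairs[2, ]]),
    stringsAsFactors = FALSE
  )
  rows$same <- rows$x == rows$y
  rows$probability <- mapply(function(x, y, s) pair_probability(f[[x]], f[[y]], s),
                             rows$x, rows$y, rows$same)
  rows$count <- round_half_up(rows$probability * n_total)
  mixed <- mapply(function(x, y) {
    m <- mix_lj(lj[x, "sigma_A"], lj[x, "epsilon_kcal"],
                lj[y, "sigma_A"], lj[y, "epsilon_kcal"])
    c(m$sigma_A, m$epsilon_kcal)
  }, rows$x, rows$y)
  rows$sigma_A <- mixed[1, ]
  rows$epsilon_kcal <- mixed[2, ]
  rows$pair <- paste(rows$x, rows$y, sep = "-")
  attr(rows, "n_total") <- n_total
  class(rows) <- c("vdw_pair_table", "data.frame")
  rows
}

#' Van der Waals energy component
#'
#' Each counted contact contributes the magnitude of its LJ well
#' (`epsilon_ij`, contact at the equilibrium separation); under a swelling
#' factor s > 1 every pair distance becomes `s * r_min` and the energy is
#' attenuated by the same geometric factor for all pairs. The grand total is
#' halved for shared contacts.
#'
#' @param pt a [vdw_pair_table()].
#' @param swelling hydration-induced swelling factor (>= 1).
#' @param sharing_factor double-counting correction, default 2.
#' @return an [energy_component()] for mechanism `"vdw"`.
#' @export
vdw_component <- function(pt, swelling = 1, sharing_factor = 2) {
  stopifnot(inherits(pt, "vdw_pair_table"))
  att <- lj_swelling_attenuation(swelling)
  subtotal <- sum(pt$count * pt$epsilon_kcal * att)
  n <- sum(pt$count)
  energy_component("vdw",
                   n_interactions = n,
                   e_per_interaction = if (n > 0) subtotal / n else 0,
                   divisors = c(sharing = sharing_factor),
                   detail = list(swelling = swelling, attenuation = att))
}
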