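# Shared test fixtures, built in code.

toy_chain <- function(n_triplets = 2, x = "P", y = "A", id = "toy") {
  chain_sequence(paste(rep(c("G", x, y), n_triplets), collapse = ""), id = id)
}

type1_profile <- function() fixture_profiles()$typeI
type2_profile <- function() fixture_profiles()$typeII

# full amino-acid formulas of the free amino acids (independent reference
# for atom-conservation checks), elements C,H,N,O,S
FULL_AA_FORMULAS <- rbind(
  A = c(3, 7, 1, 2, 0),  R = c(6, 14, 4, 2, 0), N = c(4, 8, 2, 3, 0),
  D = c(4, 7, 1, 4, 0),  C = c(3, 7, 1, 2, 1),  E = c(5, 9, 1, 4, 0),
  Q = c(5, 10, 2, 3, 0), G = c(2, 5, 1, 2, 0),  H = c(6, 9, 3, 2, 0),
  I = c(6, 13, 1, 2, 0), L = c(6, 13, 1, 2, 0), K = c(6, 14, 2, 2, 0),
  M = c(5, 11, 1, 2, 1), F = c(9, 11, 1, 2, 0), P = c(5, 9, 1, 2, 0),
  S = c(3, 7, 1, 3, 0),  T = c(4, 9, 1, 3, 0),  W = c(11, 12, 2, 2, 0),
  Y = c(9, 11, 1, 3, 0), V = c(5, 11, 1, 2, 0),
  O = c(5, 9, 1, 3, 0),  J = c(6, 14, 2, 3, 0)
)
colnames(FULL_AA_FORMULAS) <- c("C", "H", "N", "O", "S")
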