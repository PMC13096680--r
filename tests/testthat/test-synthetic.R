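test_that("degenerate recipe generates the exact repeat", {
  r <- sequence_recipe(2, x_freq = c(P = 1), y_freq = c(A = 1))
  ch <- generate_chain(r)
  expect_equal(paste(ch$residues, collapse = ""), "GPAGPA")
  expect_equal(triplet_fraction(ch), 1)
})

test_that("generation is reproducible and seed-sensitive", {
  rc <- type1_profile()
  r1 <- recipe_from_profile(rc, n_triplets = 200, seed = 11)
  expect_identical(generate_chain(r1)$residues, generate_chain(r1)$residues)
  r2 <- recipe_from_profile(rc, n_triplets = 200, seed = 12)
  expect_false(identical(generate_chain(r1)$residues,
                         generate_chain(r2)$residues))
  # caller RNG state is untouched
  set.seed(99)
  before <- .Random.seed
  invisible(generate_chain(r1))
  expect_identical(.Random.seed, before)
})

test_that("empirical X/Y frequencies converge to the recipe", {
  rc <- type1_profile()
  r <- recipe_from_profile(rc, n_triplets = 5000, seed = 3)
  ch <- generate_chain(r)
  xy <- ch$residues[-seq(1, length(ch$residues), by = 3)]
  emp <- table(factor(xy, levels = names(r$x_freq))) / length(xy)
  expect_lt(max(abs(as.numeric(emp) - as.numeric(r$x_freq))), 0.01)
})

test_that("composition recovered from a generated chain matches the recipe", {
  rc <- type1_profile()
  r <- recipe_from_profile(rc, n_triplets = 1078, seed = 5)
  ch <- generate_chain(r)
  prof <- profile_tc(chain_sequence(paste(ch$residues, collapse = ""),
                                    multiplicity = 3))
  expect_equal(prof$n_residues, 3 * 3 * 1078)
  # charged fraction within 1 point of the fixture's 16.1%
  implied <- charge_stats(rc)$charged_fraction
  got <- charge_stats(prof)$charged_fraction
  expect_lt(abs(got - implied), 0.01)
  # atom frequencies within 2 points
  fa <- atom_composition(prof)$frequencies
  fb <- atom_composition(rc)$frequencies
  expect_lt(max(abs(fa - fb)), 0.02)
})

test_that("recipes validate their frequency tables", {
  expect_error(sequence_recipe(5, x_freq = c(P = 0.6, A = 0.5)), "sum to 1")
  expect_error(sequence_recipe(5, x_freq = c(Z = 1)), "valid residue")
  expect_error(sequence_recipe(0, x_freq = c(P = 1)))
})

test_that("scenarios bundle the study conditions with override support", {
  s1 <- collagen_scenario("typeI")
  expect_equal(s1$c_gg, 1.6)
  expect_equal(s1$bridge_type, "single")
  expect_equal(s1$coulomb_n_window, 9L)
  expect_equal(s1$hbond_e_per_bond, 2.64)
  s2 <- collagen_scenario("typeII")
  expect_equal(s2$c_gg, 2.39)
  expect_equal(s2$bridge_type, "double")
  expect_equal(s2$coulomb_n_window, 7L)
  expect_equal(s2$vdw_pinned_total, 125)
  s3 <- collagen_scenario("typeI", c_gg = 2.0)
  expect_equal(s3$c_gg, 2.0)
  expect_error(collagen_scenario("typeI", nope = 1), "unknown scenario")
})

test_that("scenarios load from YAML with overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("fibril_type: typeII", "c_gg: 2.5", "coulomb_e_ref: 2.8"), path)
  sc <- scenario_from_yaml(path)
  expect_equal(sc$label, "typeII")
  expect_equal(sc$c_gg, 2.5)
  expect_equal(sc$coulomb_e_ref, 2.8)
})

test_that("FASTA written chains read back identically", {
  r <- sequence_recipe(50, x_freq = c(P = 0.7, K = 0.3),
                       y_freq = c(A = 0.5, E = 0.5), seed = 8)
  ch <- generate_chain(r, id = "syn1")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_chains(ch, path)
  back <- read_fasta_chains(path)
  expect_equal(back[[1]]$residues, ch$residues)
  expect_equal(back[[1]]$id, "syn1")
})
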