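test_that("FASTA chains are parsed, validated and order-preserving", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "GPA", ">b", "gpagpa", ">c", "GPKGDA"), path)
  chains <- read_fasta_chains(path)
  expect_length(chains, 3)
  expect_equal(vapply(chains, function(x) x$id, character(1)), c("a", "b", "c"))
  expect_equal(chains[[1]]$residues, c("G", "P", "A"))
  # lowercase upcased
  expect_equal(chains[[2]]$residues, c("G", "P", "A", "G", "P", "A"))

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "GBA"), bad)
  expect_error(read_fasta_chains(bad), "position 2")

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_fasta_chains(empty))
})

test_that("profile_tc sums chains with multiplicity and counts triplets", {
  ch <- toy_chain(2)  # GPAGPA
  rc <- profile_tc(list(chain_sequence("GPAGPA", multiplicity = 3)))
  expect_equal(rc$n_residues, 18L)
  expect_equal(rc$n_triplets, 6L)
  expect_equal(unname(rc$counts[c("G", "P", "A")]), c(6L, 6L, 6L))
  expect_error(profile_tc(list()), "no chains")

  # additivity: profile of concatenated chain lists = sum of profiles
  c1 <- toy_chain(3, "P", "A")
  c2 <- toy_chain(5, "K", "E")
  both <- profile_tc(list(c1, c2))
  a <- profile_tc(c1)$counts
  b <- profile_tc(c2)$counts
  merged <- tapply(c(a, b), names(c(a, b)), sum)
  expect_equal(both$counts[sort(names(both$counts))],
               merged[sort(names(merged))],
               ignore_attr = TRUE)
})

test_that("type fixtures reproduce every published composition anchor", {
  rc1 <- type1_profile()
  expect_equal(rc1$n_residues, 3233L)
  expect_equal(rc1$n_triplets, 1078L)
  expect_equal(unname(rc1$counts["R"]), 165L)
  cs1 <- charge_stats(rc1)
  expect_equal(cs1$n_charged, 522L)
  expect_equal(cs1$charged_fraction, 522 / 3233, tolerance = 1e-12)
  ac1 <- atom_composition(rc1)
  expect_equal(unname(ac1$frequencies["C"]), 0.2922, tolerance = 1e-3)
  expect_lt(abs(ac1$frequencies[["C"]] - 0.2922), 2e-4)
  expect_lt(abs(ac1$frequencies[["O"]] - 0.0395), 2e-4)
  expect_equal(chx_stats(rc1)$n_chx_groups, 3073L)

  rc2 <- type2_profile()
  expect_equal(rc2$n_residues, 3648L)
  expect_equal(rc2$n_triplets, 1216L)
  expect_equal(charge_stats(rc2)$n_charged, 551L)
  expect_equal(charge_stats(rc2)$charged_fraction, 0.151, tolerance = 1e-3)
  chx2 <- chx_stats(rc2)
  expect_equal(chx2$n_chx_groups, 4152L)
  expect_equal(chx2$n_hydrophobic_residues, 1683L)
})

test_that("side-chain formulas conserve atoms against the backbone unit", {
  backbone <- c(C = 2, H = 4, N = 1, O = 2, S = 0)
  for (aa in rownames(FULL_AA_FORMULAS)) {
    expect_equal(sidechain_formula(aa) + backbone,
                 FULL_AA_FORMULAS[aa, ],
                 ignore_attr = TRUE,
                 label = paste("residue", aa))
  }
  expect_equal(unname(sidechain_formula("R")), c(4L, 10L, 3L, 0L, 0L))  # C4H10N3
  expect_equal(unname(sidechain_formula("G")), c(0L, 1L, 0L, 0L, 0L))  # one H
  expect_equal(unname(sidechain_formula("A")), c(1L, 3L, 0L, 0L, 0L))  # C1H3
  expect_error(sidechain_formula("B"), "unknown residue")
})

test_that("atom composition matches the arginine worked example", {
  rc <- residue_counts(c(R = 165L))
  ac <- atom_composition(rc)
  expect_equal(unname(ac$atoms[c("C", "H", "N")]), c(660, 1650, 495))
  expect_equal(sum(ac$frequencies), 1, tolerance = 1e-12)

  # all-Gly chain: only hydrogens
  acg <- atom_composition(residue_counts(c(G = 30L)))
  expect_equal(unname(acg$frequencies["H"]), 1)
})

test_that("frequencies always sum to one across random compositions", {
  set.seed(42)
  aas <- rownames(FULL_AA_FORMULAS)[1:20]
  for (i in 1:20) {
    counts <- rpois(20, lambda = 30)
    names(counts) <- aas
    counts["G"] <- counts["G"] + 10L
    ac <- atom_composition(residue_counts(counts))
    expect_equal(sum(ac$frequencies), 1, tolerance = 1e-12)
    expect_true(all(ac$atoms >= 0))
  }
})

test_that("charge and CHx statistics behave on toy inputs", {
  neutral <- profile_tc(toy_chain(4, "P", "S"))
  expect_equal(charge_stats(neutral)$n_charged, 0L)
  expect_equal(charge_stats(neutral)$charged_fraction, 0)

  ala <- residue_counts(c(A = 1L))
  expect_equal(chx_stats(ala)$n_chx_groups, 1L)
  expect_equal(chx_stats(ala)$n_hydrophobic_residues, 1L)

  gly <- residue_counts(c(G = 9L))
  expect_equal(chx_stats(gly)$n_chx_groups, 0L)
  expect_equal(chx_stats(gly)$n_hydrophobic_residues, 0L)

  # every CHx-bearing residue carries at least one group
  rc <- type2_profile()
  s <- chx_stats(rc)
  expect_gte(s$n_chx_groups, s$n_hydrophobic_residues)
})

test_that("triplet fraction and validation work", {
  expect_equal(triplet_fraction(toy_chain(5)), 1)
  mixed <- chain_sequence("GPAAPA")
  expect_equal(triplet_fraction(mixed), 0.5)
  expect_error(chain_sequence("GP"), "at least 3")
  expect_error(chain_sequence("GPB"), "position 3")
})

test_that("composition TSV round-trips through the reader", {
  rc <- type1_profile()
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(residue = names(rc$counts), count_per_TC = rc$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  rc2 <- read_composition_tsv(path)
  expect_equal(rc2$counts[sort(names(rc2$counts))],
               rc$counts[sort(names(rc$counts))])
  expect_equal(rc2$n_triplets, rc$n_triplets)
})
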