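make_components <- function(totals = c(hbond = 1035, water_bridge = 248,
                                       vdw = 414, hydrophobic = 726,
                                       coulomb = 622)) {
  lapply(names(totals), function(m) {
    energy_component(m, n_interactions = totals[[m]], e_per_interaction = 1)
  })
}

test_that("energy components keep the n x e / divisors invariant", {
  cmp <- energy_component("hbond", 392, 2.64)
  expect_equal(cmp$total_kcal_mol, 392 * 2.64)
  cmp2 <- energy_component("hydrophobic", 4152, 1.1, divisors = c(2, 2))
  expect_lt(abs(cmp2$total_kcal_mol - 4152 * 1.1 / 4), 0.5)
  expect_error(energy_component("nope", 1, 1))
  expect_error(energy_component("hbond", -1, 1))
})

test_that("assembly computes totals, shares and display percents", {
  d <- assemble(make_components(), label = "typeI")
  expect_equal(d$total_kcal_mol, 3045)
  expect_equal(sum(d$fractions), 1, tolerance = 1e-9)
  expect_equal(unname(d$percent_display),
               c(34, 8, 14, 24, 20))
  expect_lte(abs(sum(d$percent_display) - 100), 1)
  # order independence
  d2 <- assemble(rev(make_components()), label = "typeI")
  expect_equal(coef_like <- vapply(d2$components, `[[`, 1, "total_kcal_mol"),
               vapply(d$components, `[[`, 1, "total_kcal_mol"))
  # duplicate / missing mechanism and degenerate input
  expect_error(assemble(make_components()[c(1, 1, 2, 3, 4)]), "one component")
  zero <- lapply(c("hbond", "water_bridge", "vdw", "hydrophobic", "coulomb"),
                 function(m) energy_component(m, 0, 0))
  expect_error(assemble(zero), "degenerate")
})

test_that("comparison record is antisymmetric and matches printed deltas", {
  d1 <- assemble(make_components(), "typeI")
  d2 <- assemble(make_components(c(hbond = 426, water_bridge = 72, vdw = 125,
                                   hydrophobic = 1142, coulomb = 443)),
                 "typeII")
  cmpr <- compare_decompositions(d1, d2)
  expect_equal(unname(cmpr$delta_kcal_mol["hbond"]), 1035 - 426)
  expect_equal(cmpr$reduction, (3045 - 2208) / 3045)
  rev_cmp <- compare_decompositions(d2, d1)
  expect_equal(unname(rev_cmp$delta_kcal_mol), -unname(cmpr$delta_kcal_mol))
  same <- compare_decompositions(d1, d1)
  expect_true(all(same$delta_kcal_mol == 0))
  expect_equal(same$reduction, 0)
})

test_that("the bead-spring reference energy matches its closed form", {
  expect_equal(buehler_reference(6.72, 218, 6, 0.89), 3911, tolerance = 2e-4)
  expect_equal(buehler_reference(f_gap = 0), 0)
  expect_equal(buehler_reference(n_beads = 436), 2 * buehler_reference())
})

test_that("reports serialize deterministically and round-trip", {
  d <- assemble(make_components(), "typeI")
  j1 <- withr::local_tempfile(fileext = ".json")
  j2 <- withr::local_tempfile(fileext = ".json")
  write_cohesion_report(d, j1)
  write_cohesion_report(d, j2)
  expect_identical(readLines(j1), readLines(j2))  # byte-identical
  d2 <- read_cohesion_report(j1)
  expect_equal(d2$total_kcal_mol, d$total_kcal_mol)
  expect_equal(d2$fractions, d$fractions, tolerance = 1e-12)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_cohesion_report(d, tsv, format = "tsv")
  tab <- utils::read.delim(tsv)
  expect_equal(nrow(tab), 6)  # 5 mechanisms + total
  expect_equal(tab$mechanism[6], "total")
})
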