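test_that("event tallies count onsets and company correctly", {
  rec <- data.frame(
    animal_id = "p1",
    objp_onset_kind = c("initiate", "join", "initiate", "none", "none"),
    objp_company = c("alone", "together", "alone", "alone", "none"))
  tl <- tally_events(rec)
  expect_equal(tl$n_initiate, 2L)
  expect_equal(tl$n_join, 1L)
  expect_equal(tl$n_alone, 3L)
  expect_equal(tl$n_together, 1L)
  none <- tally_events(data.frame(animal_id = "p2",
                                  objp_onset_kind = "none",
                                  objp_company = "none"))
  expect_equal(unlist(none[, -1]), c(n_initiate = 0, n_join = 0,
                                     n_alone = 0, n_together = 0))
})

test_that("proportion classification matches the exact binomial CI", {
  expect_equal(as.character(classify_proportion(20, 20)), "high")
  expect_equal(as.character(classify_proportion(10, 20)), "mixed")
  expect_equal(as.character(classify_proportion(18, 20)), "high")
  ci <- attr(classify_proportion(18, 20), "ci")
  expect_equal(ci, binom.test(18, 20, conf.level = 0.9)$conf.int[1:2])
  expect_gt(ci[1], 0.717 - 1e-3); expect_lt(ci[2], 0.982 + 1e-3)
  m <- classify_proportion(0, 0)
  expect_equal(as.character(m), "mixed")
  expect_true(attr(m, "no_events"))
  expect_error(classify_proportion(5, 4), "exceed")
  # mirror symmetry: classify(x, n) is the reflection of classify(n - x, n)
  flip <- c(high = "low", mixed = "mixed", low = "high")
  for (n in c(5, 12, 40)) for (x in 0:n)
    expect_equal(unname(flip[as.character(classify_proportion(x, n))]),
                 as.character(classify_proportion(n - x, n)))
  # Wilson and Wald variants agree at comfortable sample sizes
  expect_equal(as.character(classify_proportion(45, 50, method = "wilson")), "high")
  expect_equal(as.character(classify_proportion(5, 50, method = "wald")), "low")
})

test_that("cross-tabulation counts classified animals by both axes", {
  ty <- data.frame(
    ij_class = factor(c("initiator", "mixed", "joiner", "joiner"),
                      c("initiator", "mixed", "joiner")),
    ss_class = factor(c("solitary", "mixed", "social", "social"),
                      c("solitary", "mixed", "social")))
  tab <- crosstab_players(ty)
  expect_equal(sum(tab), 4L)
  expect_equal(tab["joiner", "social"], 2L)
  one <- crosstab_players(ty[1, , drop = FALSE])
  expect_equal(sum(one), 1L)
  expect_equal(one["initiator", "solitary"], 1L)
})

test_that("tau-b on the reference player-type table reproduces its statistics", {
  kt <- kendall_tau_b(TABLE2)
  expect_equal(round(abs(kt$tau), 3), 0.614)
  expect_equal(round(kt$ase, 3), 0.069)
  expect_equal(kt$C, 718)
  expect_equal(kt$D, 42)
  expect_equal(kt$n0, 1770)
  expect_equal(kt$n1, 718)
  expect_equal(kt$n2, 619)
  expect_equal(kt$tau, 676 / sqrt(1052 * 1151))
  expect_lt(kt$p, 0.05)
})

test_that("tau-b has the expected invariances and reference values", {
  expect_equal(kendall_tau_b(diag(c(10, 10, 10)))$tau, 1)
  expect_equal(kendall_tau_b(matrix(5, 2, 2))$tau, 0)
  set.seed(2)
  for (i in 1:20) {
    tab <- matrix(rpois(9, 4), 3)
    if (sum(tab) < 2) next
    kt <- kendall_tau_b(tab)
    expect_equal(kendall_tau_b(t(tab))$tau, kt$tau)        # transpose
    expect_equal(kendall_tau_b(tab[, 3:1])$tau, -kt$tau)   # reversed columns
    # point estimate agrees with cor() on the expanded unit records
    rows <- rep(rep(1:3, 3), as.vector(tab))
    cols <- rep(rep(1:3, each = 3), as.vector(tab))
    if (var(rows) > 0 && var(cols) > 0)
      expect_equal(kt$tau, suppressWarnings(cor(rows, cols, method = "kendall")))
  }
})

test_that("Fisher r x c p-values are exact, degenerate-safe, and reproducible", {
  expect_equal(fisher_exact_rxc(matrix(c(5, 0, 0, 5), 2)), 2 / 252)
  expect_equal(fisher_exact_rxc(matrix(c(3, 4, 0, 0), 2, byrow = TRUE)), 1)
  set.seed(4)
  mc_tab <- matrix(rpois(9, 6), 3)
  p1 <- fisher_exact_rxc(mc_tab, n_mc = 2000, seed = 99)
  p2 <- fisher_exact_rxc(mc_tab, n_mc = 2000, seed = 99)
  expect_identical(p1, p2)
  expect_error(fisher_exact_rxc(matrix(0, 2, 2)), "empty")
})

test_that("strong planted player types are recovered from generated data", {
  ds <- generate_dataset(preset_strong_types(seed = 1))
  tal <- do.call(rbind, lapply(split(ds$records, ds$records$animal_id),
                               tally_events))
  tal <- classify_players(tal)
  tr <- ds$truth[match(tal$animal_id, ds$truth$animal_id), ]
  expect_gte(min(tal$n_initiate + tal$n_join), 20)
  expect_gte(mean(as.character(tal$ij_class) == tr$ij_class), 0.9)
  # tallies equal the planted event labels counted directly
  one <- ds$records[ds$records$animal_id == tal$animal_id[1], ]
  expect_equal(tal$n_initiate[1], sum(one$objp_onset_kind == "initiate"))
  expect_equal(tal$n_alone[1], sum(one$objp_company == "alone"))
})
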