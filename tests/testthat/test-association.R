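test_that("survey validation restricts categorical levels", {
  bad <- transition_zone_survey()
  bad$haplotype[1] <- "HT3"
  expect_error(validate_survey(bad), "HT3")
  expect_error(summarize_association(transition_zone_survey(), "colour"),
               "unknown stratum")
})

test_that("transition-zone fixture reproduces the printed mismatch counts", {
  tz <- transition_zone_survey()
  by_period <- summarize_association(tz, strata = "period")
  expect_equal(by_period$period, c("2000/2001", "2008", "2014"))
  expect_equal(by_period$n_double_typed, c(29, 31, 4))
  expect_equal(by_period$n_double_ht1, c(9, 4, 1))
  # HT2 association percentages as printed: 69%, 87.1%, 75%
  expect_equal(percent_round(100 * (by_period$n_double_typed -
                 by_period$n_double_ht1) / by_period$n_double_typed),
               c(69.0, 87.1, 75.0))

  pooled <- summarize_association(tz, strata = character(0))
  expect_equal(pooled$n_double_ht1, 14)
  expect_equal(pooled$n_double_typed, 64)
  expect_equal(pooled$pct_double_ht1, 21.9)
  # singly infected: 197 of 198 carry HT1
  expect_equal(pooled$n_single_typed, 198)
  expect_equal(pooled$n_single_ht2, 1)
})

test_that("outside-zone fixture reproduces the printed association", {
  out <- summarize_association(outside_zone_survey(), strata = "period")
  expect_equal(out$n_double_typed, c(66, 200, 10))
  expect_equal(out$n_double_ht1, c(3, 1, 0))
  pooled <- summarize_association(outside_zone_survey(), character(0))
  expect_equal(pooled$n_double_ht1 / pooled$n_double_typed, 4 / 276)
  # 4/276 = 1.449% (prints as 1.4 at one decimal, half-up)
  expect_equal(pooled$pct_double_ht1, 1.4)
})

test_that("empty strata yield zero counts and undefined percentages", {
  tz <- transition_zone_survey()
  s <- summarize_association(tz[tz$infection == "single", ], character(0))
  expect_equal(s$n_double, 0)
  expect_true(is.na(s$pct_double_ht1))
})

test_that("summaries are order-invariant and additive over disjoint strata", {
  all <- paper_survey_fixtures()
  set.seed(5)
  shuffled <- all[sample(nrow(all)), ]
  expect_equal(summarize_association(shuffled, c("zone", "period")),
               summarize_association(all, c("zone", "period")))
  by_zone <- summarize_association(all, "zone")
  pooled <- summarize_association(all, character(0))
  cnt <- c("n", "n_double", "n_double_typed", "n_double_ht1",
           "n_single", "n_single_typed", "n_single_ht2")
  expect_equal(colSums(by_zone[cnt]), unlist(pooled[cnt]),
               ignore_attr = TRUE)
})

test_that("Fisher exact test matches enumeration and flags associations", {
  expect_equal(fisher_exact(matrix(5, 2, 2))$p_value, 1)

  # transition vs outside doubly infected, 2000/2001
  tab <- matrix(c(9, 3, 20, 63), nrow = 2)
  ft <- fisher_exact(tab)
  expect_lt(ft$p_value, 0.001)
  expect_equal(ft$p_value, oracle_fisher_p(tab), tolerance = 1e-10)
  expect_gt(ft$odds_ratio, 1)

  # two-table support, enumerated by hand: p = 286/1001
  tab2 <- matrix(c(1, 0, 3, 10), nrow = 2)
  expect_equal(fisher_exact(tab2)$p_value, 286 / 1001, tolerance = 1e-12)

  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), nrow = 2)), "margin")
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), nrow = 2)), "integer")
})

test_that("host-plant contrast reproduces the printed percentages", {
  hp <- host_plant_contrast(transition_zone_survey())
  expect_equal(hp$summary$host_plant, c("Lonicera", "Prunus"))
  expect_equal(hp$summary$n_double_typed, c(47, 17))
  expect_equal(hp$summary$n_double_ht1, c(12, 2))
  expect_equal(hp$summary$pct_double_ht1, c(25.5, 11.8))
  expect_true(hp$p_value > 0 && hp$p_value <= 1)

  # identical proportions give p = 1
  eq <- transition_zone_survey()
  eq <- eq[eq$infection == "double", ]
  eq$haplotype <- rep_len(c("HT1", "HT2"), nrow(eq))
  eq$host_plant <- rep_len(c("Lonicera", "Lonicera", "Prunus", "Prunus"),
                           nrow(eq))
  expect_equal(host_plant_contrast(eq)$p_value, 1)
})

test_that("survey tables round-trip through TSV", {
  tz <- transition_zone_survey()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_survey(tz, path)
  back <- read_survey(path)
  expect_equal(back, tz, ignore_attr = TRUE)
})
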