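test_that("survey generation is deterministic given the seed", {
  d <- survey_design(seq(0, 200, by = 20), n_per_site = 25)
  a <- generate_survey(d, seed = 99)
  b <- generate_survey(d, seed = 99)
  expect_identical(a, b)
  c2 <- generate_survey(d, seed = 100)
  expect_false(identical(a, c2))
  expect_equal(attr(a, "seed"), 99L)
  # the global RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_survey(d, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("degenerate site frequencies are honoured exactly", {
  d <- survey_design(c(0, 100), n_per_site = c(50, 0),
                     freq_double = c(1, 1))
  sv <- generate_survey(d, seed = 2)
  expect_equal(nrow(sv), 50)
  expect_true(all(sv$infection == "double"))
  expect_equal(nrow(attr(sv, "design")), 2)  # n = 0 site kept in metadata
})

test_that("sampling is binomial around the design frequency", {
  d <- survey_design(0, n_per_site = 100, freq_double = 0.5,
                     p_mismatch = 0.2)
  counts <- vapply(1:200, function(s) {
    sum(generate_survey(d, seed = s)$infection == "double")
  }, numeric(1))
  expect_gt(mean(counts), 45)
  expect_lt(mean(counts), 55)
})

test_that("generated frequencies converge to the design (law of large numbers)", {
  d <- survey_design(c(0, 50, 100), n_per_site = 20000,
                     freq_double = c(0.1, 0.5, 0.9),
                     p_mismatch = 0.2, p_leak = 0.01)
  sv <- generate_survey(d, seed = 7)
  for (i in 1:3) {
    g <- sv[sv$population == sprintf("s%02d", i), ]
    p <- d$freq_double[i]
    se <- sqrt(p * (1 - p) / d$n[i])
    expect_lt(abs(mean(g$infection == "double") - p), 3 * se)
  }
  dbl <- sv[sv$infection == "double" & sv$zone == "transition", ]
  expect_equal(mean(dbl$haplotype == "HT1"), 0.2, tolerance = 0.05)
})

test_that("generated surveys flow into the association and wave modules", {
  d <- survey_design(seq(0, 300, by = 15), n_per_site = 200, sigma = 25)
  sv <- generate_survey(d, seed = 13)
  s <- summarize_association(sv, strata = "zone")
  expect_true(all(c("fixed", "transition") %in% s$zone))
  # mismatch elevated in the transition zone relative to fixed populations
  expect_gt(s$pct_double_ht1[s$zone == "transition"],
            s$pct_double_ht1[s$zone == "fixed"])

  # per-site frequencies feed the wave module; width near the analytic value
  freq <- vapply(split(sv, sv$population),
                 function(g) mean(g$infection == "double"), numeric(1))
  pos <- d$position[match(names(freq), d$site)]
  o <- order(pos)
  w <- transition_zone_width(pos[o], freq[o])
  expect_lt(abs(w - 3 * 25 / sqrt(0.98)) / (3 * 25 / sqrt(0.98)), 0.15)
})

test_that("survey round-trip recovers generating frequencies within binomial bounds", {
  n <- 500
  p <- 0.3
  d <- survey_design(0, n_per_site = n, freq_double = p, p_mismatch = 0.2)
  sv <- generate_survey(d, seed = 21)
  phat <- mean(sv$infection == "double")
  half <- 1.96 * sqrt(p * (1 - p) / n)
  expect_lt(abs(phat - p), half)
})

test_that("fixture amplicons are reproducible and distinct across seeds", {
  expect_identical(as.character(generate_fixture_amplicons(seed = 5)),
                   as.character(generate_fixture_amplicons(seed = 5)))
  expect_false(identical(as.character(generate_fixture_amplicons(seed = 5)),
                         as.character(generate_fixture_amplicons(seed = 6))))
  # every seed yields the diagnostic digest profiles
  for (s in 1:5) {
    fx <- generate_fixture_amplicons(seed = s)
    expect_equal(rflp_type(fx)$call, c("HT1", "HT2"))
  }
})

test_that("paper-count fixtures agree with their printed row totals", {
  tz <- transition_zone_survey()
  expect_equal(nrow(tz), 64 + 198)
  out <- outside_zone_survey()
  expect_equal(nrow(out), 276)
  expect_equal(nrow(paper_survey_fixtures()), 64 + 198 + 276)
})
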