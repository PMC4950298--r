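test_that("parameter validation enforces ranges and scenarios are expressible", {
  expect_error(model_params(l_ci = 1.2), "l_ci")
  expect_error(model_params(mu = -0.1), "mu")
  expect_error(model_params(f_a = 0), "f_a")

  pat <- scenario_params("paternal")
  expect_equal(pat$tau, 0.3)
  expect_equal(pat$beta, 0)
  her <- scenario_params("heritable")
  expect_equal(c(her$tau, her$alpha, her$beta), c(0, 1, 0.015))
  som <- scenario_params("somatic")
  expect_equal(c(som$tau, som$alpha, som$beta), c(0, 0, 0.3))
  for (p in list(pat, her, som)) {
    expect_equal(p$l_ci, 0.98)
    expect_equal(p$mu, 0)
    expect_equal(c(p$f_a, p$f_b), c(1, 1))
  }
})

test_that("cytotype states are validated and normalized", {
  st <- cytotype_state(a1 = 0.99, b2 = 0.01)
  expect_s3_class(st, "cyto_state")
  expect_equal(sum(unclass(st)), 1)
  expect_error(cytotype_state(a1 = 0.5), "sum to 1")
  expect_error(cytotype_state(a1 = 1.5, b2 = -0.5), "non-negative")
})

test_that("mating table encodes CI, maternal inheritance and paternal rescue", {
  row_of <- function(tab, m, f) tab[tab$mother == m & tab$father == f, ]

  # strict maternal inheritance without paternal transmission
  p0 <- model_params(l_ci = 0.98, mu = 0, tau = 0)
  r <- row_of(build_mating_table(p0), "a1", "b2")
  expect_equal(r$weight, 1 * (1 - 0.98))
  expect_equal(c(r$off_a1, r$off_a2, r$off_b1, r$off_b2), c(1, 0, 0, 0))

  # paternal transmission keeps the maternal haplotype
  pp <- model_params(l_ci = 0.98, mu = 0, tau = 0.3)
  r <- row_of(build_mating_table(pp), "a1", "b2")
  expect_equal(r$weight, 0.02)
  expect_equal(c(r$off_b1, r$off_a1), c(0.3, 0.7))
  expect_equal(c(r$off_b2, r$off_a2), c(0, 0))

  # rescue cross: doubly infected mother, maternal haplotype, leakage
  pm <- model_params(l_ci = 0.98, mu = 0.05, f_b = 2)
  r <- row_of(build_mating_table(pm), "b2", "a1")
  expect_equal(r$weight, 2)
  expect_equal(c(r$off_b2, r$off_a2), c(0.95, 0.05))

  # every offspring distribution is a distribution; weights follow mothers
  tab <- build_mating_table(model_params(l_ci = 0.7, mu = 0.1, f_a = 0.9,
                                         f_b = 1.3, tau = 0.2))
  expect_equal(rowSums(tab[, c("off_a1", "off_a2", "off_b1", "off_b2")]),
               rep(1, 16), ignore_attr = TRUE)
  a_mother_b_father <- with(tab, grepl("^a", mother) & grepl("^b", father))
  expect_equal(unique(tab$weight[a_mother_b_father]), 0.9 * 0.3)
})

test_that("one-generation step matches the reduced recursion and enumeration", {
  # neutral dynamics: any state is a fixed point
  st <- cytotype_state(0.3, 0.2, 0.4, 0.1)
  neutral <- model_params(l_ci = 0)
  expect_equal(unclass(step_cytotypes(st, neutral)), unclass(st),
               tolerance = 1e-14)

  # hand-evaluated reduced recursion p' = p / (1 - l p (1 - p))
  p <- model_params(l_ci = 0.98)
  st <- cytotype_state(a1 = 0.5, b2 = 0.5)
  nxt <- step_cytotypes(st, p)
  expect_equal(nxt[["b1"]] + nxt[["b2"]], 0.5 / (1 - 0.98 * 0.25),
               tolerance = 1e-12)
  expect_equal(classic_ci_recursion(0.5, 0.98), 0.5 / (1 - 0.98 * 0.25),
               tolerance = 1e-12)
  # cross-check the full state against the enumeration oracle
  expect_equal(unclass(nxt), oracle_step(c(0.5, 0, 0, 0.5), 0.98, 0, 1, 1, 0),
               tolerance = 1e-14, ignore_attr = TRUE)

  # somatic acquisition leaves heritable state unchanged, shows in overlay
  som <- model_params(beta = 0.3, alpha = 0)
  pure <- cytotype_state(a1 = 1)
  expect_equal(unclass(step_cytotypes(pure, som)), unclass(pure),
               tolerance = 1e-14)
  o <- observed_frequencies(pure, som)
  expect_equal(o[["b1"]], 0.3)
  expect_equal(sum(o), 1)

  # degenerate all-incompatible input
  broken <- model_params(l_ci = 1, f_b = 1)
  half <- cytotype_state(a1 = 0.5, b2 = 0.5)
  # A mothers x B fathers all die, but B mothers still reproduce: fine
  expect_silent(step_cytotypes(half, broken))
})

test_that("classic recursion has absorbing boundaries and finite invasion time", {
  expect_equal(classic_ci_recursion(0, 0.98), 0)
  expect_equal(classic_ci_recursion(1, 0.98, mu = 0), 1)
  # brute-force iteration from 1% exceeds 99% in finitely many generations
  p <- 0.01
  gens <- 0L
  while (p <= 0.99 && gens < 10000L) {
    p <- classic_ci_recursion(p, 0.98)
    gens <- gens + 1L
  }
  expect_lt(gens, 10000L)
  expect_gt(p, 0.99)
  expect_equal(gens, 108L)  # frozen from the brute-force loop above
})

test_that("heritable frequencies are conserved across random steps", {
  set.seed(42)
  for (i in 1:200) {
    prm <- model_params(l_ci = runif(1), mu = runif(1, 0, 0.3),
                        f_a = runif(1, 0.5, 2), f_b = runif(1, 0.5, 2),
                        tau = runif(1, 0, 0.5), alpha = runif(1),
                        beta = runif(1, 0, 0.5))
    nxt <- step_cytotypes(random_state(), prm)
    expect_equal(sum(unclass(nxt)), 1, tolerance = 1e-12)
    expect_equal(sum(observed_frequencies(nxt, prm)), 1, tolerance = 1e-12)
  }
})

test_that("haplotype-aggregated step equals the classic recursion", {
  set.seed(7)
  for (i in 1:1000) {
    l <- runif(1); mu <- runif(1, 0, 0.5)
    fa <- runif(1, 0.5, 2); fb <- runif(1, 0.5, 2)
    st <- random_state()
    prm <- model_params(l_ci = l, mu = mu, f_a = fa, f_b = fb)
    nxt <- step_cytotypes(st, prm)
    p0 <- st[["b1"]] + st[["b2"]]
    expect_equal(nxt[["b1"]] + nxt[["b2"]],
                 classic_ci_recursion(p0, l, mu, fb / fa),
                 tolerance = 1e-12)
  }
})

test_that("haplotype frequency is neutral without CI or transmission asymmetry", {
  set.seed(11)
  prm <- model_params(l_ci = 0, mu = 0.1, f_a = 1.2, f_b = 1.2)
  st <- random_state()
  ht1 <- st[["a1"]] + st[["b1"]]
  for (g in 1:25) {
    st <- step_cytotypes(st, prm)
    expect_equal(st[["a1"]] + st[["b1"]], ht1, tolerance = 1e-12)
  }
})

test_that("invasion is monotone and complete under perfect transmission", {
  for (p0 in c(0.001, 0.05, 0.4)) {
    st <- cytotype_state(a1 = 1 - p0, b2 = p0)
    prm <- model_params(l_ci = 0.6)
    p_prev <- p0
    for (g in 1:2000) {
      st <- step_cytotypes(st, prm)
      p_now <- st[["b1"]] + st[["b2"]]
      expect_gte(p_now, p_prev - 1e-15)
      p_prev <- p_now
    }
    expect_gt(p_prev, 1 - 1e-6)
  }
})
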