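ctl_fast <- ht_control(restarts = 3, warn = FALSE)

test_that("g_squared matches direct evaluation and handles zero cells", {
  expect_equal(g_squared(c(10, 20, 30), c(10, 20, 30)), 0)
  expect_equal(g_squared(c(30, 20), c(25, 25)),
               2 * (30 * log(30 / 25) + 20 * log(20 / 25)),
               tolerance = 1e-12)
  expect_equal(round(g_squared(c(30, 20), c(25, 25)), 4), 2.0136)
  expect_equal(g_squared(c(0, 50), c(10, 40)), 2 * 50 * log(50 / 40))
  expect_warning(res <- g_squared(c(5, 5), c(0, 10)), "infinite")
  expect_identical(res, Inf)
})

test_that("a saturated fit to model-generated expected counts recovers the parameters", {
  # interior theta chosen so all expected counts are integers at these totals
  theta <- c(dP = .5, b = .2, g = .5, dA = .1)
  e <- expected_frequencies(category_probabilities(theta, 6), 300, 100)
  d <- one_cond_data(e[1:3], e[4:6])
  fit <- ht_fit(saturated_spec(d), d, ctl_fast)
  expect_lte(fit$g_squared, 1e-8)
  est <- fit$estimates[c("dP_c1", "b_c1", "g_c1", "dA_c1")]
  expect_equal(unname(est), unname(theta), tolerance = 1e-6)
})

test_that("the saturated single-condition fit matches independent oracles", {
  d <- one_cond_data(c(60, 20, 20), c(10, 30, 60))
  fit <- ht_fit(saturated_spec(d), d, ctl_fast)
  expect_equal(fit$g_squared, 0, tolerance = 1e-8)

  # algebraic inversion of the tree equations
  inv <- oracle_invert_saturated(c(60, 20, 20), c(10, 30, 60), 6)
  expect_equal(unname(fit$estimates[c("dP_c1", "b_c1", "g_c1", "dA_c1")]),
               unname(inv), tolerance = 1e-5)

  # exhaustive 0.005-step grid search cannot beat the fit
  grid_min <- oracle_grid_g2(c(60, 20, 20), c(10, 30, 60), 6, step = 0.005)
  expect_lte(fit$g_squared, grid_min + 1e-3)
})

test_that("fitted G-squared never exceeds the grid-search minimum on random instances", {
  set.seed(42)
  for (rep in 1:3) {
    cp <- drop(stats::rmultinom(1, 150, c(.5, .3, .2)))
    ca <- drop(stats::rmultinom(1, 200, c(.2, .3, .5)))
    d <- one_cond_data(cp, ca)
    fit <- ht_fit(saturated_spec(d), d, ctl_fast)
    grid_min <- oracle_grid_g2(cp, ca, 6, step = 0.005)
    expect_lte(fit$g_squared, grid_min + 1e-3)
  }
})

test_that("the EM log-likelihood is non-decreasing on fixtures and random instances", {
  for (name in fixture_names()) {
    fx <- lineup_fixture(name)
    m <- lineup2ht:::compile_model(fx$comparison, fx$data)
    run <- lineup2ht:::em_fit(m, lineup2ht:::heuristic_start(m), trace = TRUE)
    expect_true(all(diff(run$trace) >= -1e-10), info = name)
  }
  set.seed(7)
  d_template <- one_cond_data(c(1, 1, 1), c(1, 1, 1))
  sat <- saturated_spec(d_template)
  m0 <- NULL
  for (i in 1:100) {
    cp <- drop(stats::rmultinom(1, 60, c(runif(1), runif(1), runif(1) + .1)))
    ca <- drop(stats::rmultinom(1, 60, c(runif(1), runif(1), runif(1) + .1)))
    d <- one_cond_data(cp + 1, ca + 1)  # keep trees non-empty
    m <- lineup2ht:::compile_model(sat, d)
    st <- runif(4, 0.05, 0.95)
    run <- lineup2ht:::em_fit(m, st, trace = TRUE, max_iter = 2000)
    expect_true(all(diff(run$trace) >= -1e-10))
  }
})

test_that("EM and the logit-space quasi-Newton optimizer agree on every fixture", {
  for (name in fixture_names()) {
    fx <- lineup_fixture(name)
    fit <- ht_fit(fx$comparison, fx$data, ht_control(restarts = 3, warn = FALSE))
    expect_lt(fit$diagnostics$crosscheck_agreement, 1e-4, label = name)
  }
})

test_that("standard errors match a finite-difference Hessian oracle at interior estimates", {
  d <- one_cond_data(c(60, 20, 20), c(10, 30, 60))
  spec <- saturated_spec(d)
  fit <- ht_fit(spec, d, ctl_fast)
  expect_true(all(!fit$boundary))
  m <- lineup2ht:::compile_model(spec, d)
  H <- oracle_hessian(function(x) -lineup2ht:::loglik_compiled(m, x),
                      fit$estimates)
  se_oracle <- sqrt(diag(solve(H)))
  expect_equal(unname(fit$standard_errors), unname(se_oracle), tolerance = 1e-4)
})

test_that("parameters fixed by the specification carry no standard error", {
  fx <- lineup_fixture("smith2014")
  one_ht <- fix_parameters(fx$comparison, c(dA = 0))
  fit <- ht_fit(one_ht, fx$data, ctl_fast)
  expect_false("dA" %in% names(fit$estimates))
  expect_false("dA" %in% names(standard_errors(fit)))
  expect_identical(length(standard_errors(fit)), 5L)
})

test_that("boundary estimates are flagged but still carry standard errors", {
  fx <- lineup_fixture("smith2014")
  fit <- ht_fit(fx$comparison, fx$data, ctl_fast)
  expect_true(fit$boundary[["dA"]])
  expect_true(is.finite(fit$standard_errors[["dA"]]))
  expect_false(fit$boundary[["g_clear"]])
})

test_that("local identifiability is diagnosed from the probability Jacobian rank", {
  d <- one_cond_data(c(60, 20, 20), c(10, 30, 60))
  chk <- identifiability_check(saturated_spec(d), d,
                               c(dP_c1 = .4, b_c1 = .1, g_c1 = .5, dA_c1 = .3))
  expect_identical(chk$rank, 4L)
  expect_true(chk$identifiable)

  # only culprit-absent data, dA fixed: dP cannot be told apart from anything,
  # and b and g trade off against each other in the two remaining categories
  d2 <- ht_data("c1", 6, 0, 0, 0, 10, 30, 60)
  spec2 <- ht_spec("c1", bind = list(dP = "c1.dP", b = "c1.b", g = "c1.g"),
                   fix = c(c1.dA = 0))
  chk2 <- identifiability_check(spec2, d2, c(dP = .4, b = .2, g = .5))
  expect_lt(chk2$rank, chk2$n_free)
  expect_false(chk2$identifiable)

  memon <- lineup_fixture("memon2003")
  fit <- ht_fit(memon$comparison, memon$data, ctl_fast)
  chk3 <- identifiability_check(memon$comparison, memon$data, fit$estimates)
  expect_identical(chk3$rank, 6L)
  expect_true(chk3$identifiable)
})

test_that("nested-model dominance holds across the fixture restriction sets", {
  for (name in c("memon2003", "karageorge_zajac")) {
    fx <- lineup_fixture(name)
    general <- ht_fit(fx$comparison, fx$data, ctl_fast)
    for (par in names(fx$restrictions)) {
      restricted <- ht_fit(fx$restrictions[[par]], fx$data, ctl_fast)
      expect_gte(restricted$g_squared, general$g_squared - 1e-6)
    }
  }
})

test_that("invalid comparisons are refused", {
  fx <- lineup_fixture("wilcock_bull")
  fit <- ht_fit(fx$comparison, fx$data, ctl_fast)
  expect_error(compare_fits(fit, fit), "not nested \\(Δdf=0\\)")

  other <- lineup_fixture("karageorge_zajac")
  fit2 <- ht_fit(other$comparison, other$data, ctl_fast)
  expect_error(compare_fits(fit2, fit), "identical data")

  # same data, non-nested pair: restrict different parameters
  r1 <- ht_fit(fx$restrictions$dA, fx$data, ctl_fast)
  r2 <- ht_fit(fx$restrictions$g, fx$data, ctl_fast)
  expect_error(compare_fits(r1, r2), "not nested")
})
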