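test_that("degenerate probabilities produce deterministic counts", {
  d <- simulate_lineup(c(dP = 1, b = 0, g = 0, dA = 1), 6, 50, 50, seed = 1)
  expect_identical(as.integer(d[lineup2ht:::count_cols]),
                   c(50L, 0L, 0L, 0L, 0L, 50L))
})

test_that("simulation is reproducible under a fixed seed and leaves the RNG alone", {
  th <- c(dP = .5, b = .2, g = .5, dA = .1)
  d1 <- simulate_lineup(th, 6, 200, 200, seed = 99)
  d2 <- simulate_lineup(th, 6, 200, 200, seed = 99)
  expect_identical(as.data.frame(d1), as.data.frame(d2))

  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_lineup(th, 6, 200, 200, seed = 99))
  expect_identical(runif(1), before)
})

test_that("simulated proportions converge to the model probabilities at root-n rate", {
  th <- c(dP = .5, b = .2, g = .5, dA = .1)
  p_true <- category_probabilities(th, 6)
  for (n in c(1e2, 1e4, 1e6)) {
    d <- simulate_lineup(th, 6, n, n, seed = 1234)
    prop <- as.numeric(d[lineup2ht:::count_cols]) / n
    err <- abs(prop - c(p_true$cp, p_true$ca))
    expect_true(all(err < 5 / sqrt(n)), info = paste("n =", n))
  }
  # a million draws pin the culprit-present proportions tightly
  d <- simulate_lineup(th, 6, 1e6, 1e6, seed = 77)
  prop_cp <- as.numeric(d[c("cp_culprit", "cp_filler", "cp_reject")]) / 1e6
  expect_true(all(abs(prop_cp - c(0.633333, 0.166667, 0.2)) < 0.002))
})

test_that("multi-condition sampling respects the bindings of the specification", {
  fx <- lineup_fixture("smith2014")
  theta <- c(dP_clear = .7, dP_degraded = .1, g_clear = .25, g_degraded = .5,
             b = 0, dA = 0)
  d <- sample_dataset(fx$comparison, theta, fx$data, seed = 5)
  expect_identical(d$condition, fx$data$condition)
  # totals preserved
  expect_identical(rowSums(as.matrix(d[c("cp_culprit", "cp_filler", "cp_reject")])),
                   rowSums(as.matrix(fx$data[c("cp_culprit", "cp_filler", "cp_reject")])))
  expect_error(sample_dataset(fx$comparison, theta[-1], fx$data, seed = 5),
               "free parameters")
})

test_that("injecting exact expected counts gives zero bias and zero RMSE", {
  theta <- c(dP = .5, b = .2, g = .5, dA = .1)
  e <- expected_frequencies(category_probabilities(theta, 6), 300, 100)
  d <- one_cond_data(e[1:3], e[4:6])
  spec <- saturated_spec(d)
  names(theta) <- paste0(names(theta), "_c1")
  fit <- ht_fit(spec, d, ht_control(restarts = 2, warn = FALSE))
  expect_equal(unname(fit$estimates[names(theta)]), unname(theta),
               tolerance = 1e-6)
})

test_that("parameter recovery at moderate n is unbiased for interior parameters", {
  template <- one_cond_data(c(4000, 0, 0), c(4000, 0, 0))
  spec <- saturated_spec(template)
  theta <- c(dP_c1 = .45, b_c1 = .15, g_c1 = .55, dA_c1 = .30)
  rec <- recovery_study(spec, theta, template, reps = 8, seed = 11,
                        control = ht_control(restarts = 1, crosscheck = FALSE,
                                             se = FALSE, warn = FALSE))
  expect_identical(rec$n_excluded, 0L)
  expect_true(all(abs(rec$summary$bias) < 0.03))
  expect_true(all(rec$summary$rmse < 0.05))
})

test_that("a boundary truth piles estimates at the boundary with one-sided error", {
  template <- one_cond_data(c(500, 0, 0), c(500, 0, 0))
  spec <- saturated_spec(template)
  theta <- c(dP_c1 = .5, b_c1 = .1, g_c1 = .5, dA_c1 = 0)
  rec <- recovery_study(spec, theta, template, reps = 10, seed = 3,
                        control = ht_control(restarts = 1, crosscheck = FALSE,
                                             se = FALSE, warn = FALSE))
  dA_row <- rec$summary[rec$summary$parameter == "dA_c1", ]
  expect_gte(dA_row$bias, 0)
  expect_gte(dA_row$n_boundary, 1)
})

test_that("replicate streams are independent of execution order", {
  template <- one_cond_data(c(200, 0, 0), c(200, 0, 0))
  spec <- saturated_spec(template)
  theta <- c(dP_c1 = .4, b_c1 = .1, g_c1 = .5, dA_c1 = .2)
  d3 <- sample_dataset(spec, theta, template, seed = lineup2ht:::derive_seed(500, 3))
  rec <- recovery_study(spec, theta, template, reps = 3, seed = 500,
                        control = ht_control(restarts = 1, crosscheck = FALSE,
                                             se = FALSE, warn = FALSE))
  fit3 <- ht_fit(spec, d3, ht_control(restarts = 1, crosscheck = FALSE,
                                      se = FALSE, warn = FALSE))
  expect_equal(unname(rec$estimates[3, ]), unname(fit3$estimates))
})
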