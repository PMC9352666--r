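#' JSON report of a fitted model
#'
#' Serializes a fit at full precision: estimates, standard errors, boundary
#' flags, observed and expected tables, fit statistics and restart
#' diagnostics.
#'
#' @param fit an [ht_fit] object.
#' @param path optional file path; when supplied the JSON is written there.
#' @return The report list, invisibly when written to file.
#' @export
fit_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "ht_fit"))
  rep <- list(
    model = fit$spec$description,
    estimates = as.list(fit$estimates),
    standard_errors = as.list(fit$standard_errors),
    boundary = as.list(fit$boundary),
    observed = as.data.frame(fit$observed[c("condition", "lineup_size", count_cols)]),
    expected = cbind(condition = rownames(fit$expected), fit$expected),
    g_squared = fit$g_squared,
    df = fit$df,
    p_value = fit$p_value,
    log_likelihood = fit$log_likelihood,
    converged = fit$converged,
    n_restarts_agreeing = fit$n_restarts_agreeing,
    diagnostics = fit$diagnostics[c("restart_g_squared", "em_iterations",
                                    "g_squared_em", "g_squared_optim",
                                    "crosscheck_agreement", "notes")],
    seed = fit$control$seed,
    restarts = fit$control$restarts)
  if (is.null(path)) return(rep)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(rep)
}

#' Reproduce the eight bundled reanalyses
#'
#' Fits the comparison-standard model of every bundled fixture, runs every
#' published nested likelihood-ratio test, and lays the recomputed values
#' side by side with the published ones.
#'
#' @param fixtures fixture names (default: all eight).
#' @param control fitting controls.
#' @param tol_g2,tol_est,tol_se pass/fail tolerances for G-squared (and
#'   delta G-squared), parameter estimates and standard errors.
#' @return A list of class `ht_reproduction` with data frames `fits`
#'   (G-squared, df, p per fixture), `tests` (delta G-squared per published
#'   restriction) and `estimates` (published 2-dp estimates and SEs vs
#'   refitted values).
#' @export
reproduce_analyses <- function(fixtures = fixture_names(),
                               control = ht_control(),
                               tol_g2 = 0.05, tol_est = 0.01, tol_se = 0.02) {
  fits <- NULL; tests <- NULL; ests <- NULL
  for (name in fixtures) {
    fx <- lineup_fixture(name)
    fit <- ht_fit(fx$comparison, fx$data, control)
    fits <- rbind(fits, data.frame(
      fixture = name,
      g_squared = fit$g_squared, df = fit$df, p_value = fit$p_value,
      published_g_squared = fx$published$g_squared,
      published_df = fx$published$df,
      pass = abs(fit$g_squared - fx$published$g_squared) <= tol_g2 &
        fit$df == fx$published$df))
    for (par in names(fx$restrictions)) {
      rfit <- ht_fit(fx$restrictions[[par]], fx$data, control)
      cmp <- compare_fits(rfit, fit)
      tests <- rbind(tests, data.frame(
        fixture = name, parameter = par,
        delta_g_squared = cmp$delta_g_squared,
        delta_df = cmp$delta_df, p_value = cmp$p_value,
        published_delta_g_squared = unname(fx$published$delta_g_squared[par]),
        pass = abs(cmp$delta_g_squared - fx$published$delta_g_squared[par]) <= tol_g2))
    }
    pub <- fx$published$estimates
    ests <- rbind(ests, data.frame(
      fixture = name, parameter = names(pub),
      estimate = unname(fit$estimates[names(pub)]),
      published = unname(pub),
      se = unname(fit$standard_errors[names(pub)]),
      published_se = unname(fx$published$ses[names(pub)]),
      pass = abs(fit$estimates[names(pub)] - pub) <= tol_est &
        abs(fit$standard_errors[names(pub)] - fx$published$ses[names(pub)]) <= tol_se,
      row.names = NULL))
  }
  structure(list(fits = fits, tests = tests, estimates = ests),
            class = "ht_reproduction")
}

#' @export
print.ht_reproduction <- function(x, digits = 2, ...) {
  fmt <- function(d) {
    if ("p_value" %in% names(d)) d$p_value <- round(d$p_value, 3)
    num <- vapply(d, is.numeric, logical(1)) & names(d) != "p_value"
    d[num] <- lapply(d[num], round, digits)
    d
  }
  cat("Goodness of fit of the comparison-standard models\n")
  print(fmt(x$fits), row.names = FALSE)
  cat("\nNested likelihood-ratio tests\n")
  print(fmt(x$tests), row.names = FALSE)
  cat("\nParameter estimates (published values printed to 2 dp)\n")
  print(fmt(x$estimates), row.names = FALSE)
  invisible(x)
}
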