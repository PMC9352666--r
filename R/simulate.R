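derive_seed <- function(seed, r) as.integer((seed + 104729 * r) %% 2147483629L)

#' Simulate lineup frequencies for one condition
#'
#' Draws the culprit-present and culprit-absent response counts from
#' multinomial distributions with the model's category probabilities.
#'
#' @param theta named parameter vector `c(dP, b, g, dA)`.
#' @param lineup_size lineup size (integer `>= 2`).
#' @param n_cp,n_ca tree totals.
#' @param condition condition label of the returned data.
#' @param seed optional integer seed (the caller's random-number state is
#'   preserved).
#' @return An [ht_data] object with one row.
#' @export
simulate_lineup <- function(theta, lineup_size, n_cp, n_ca,
                            condition = "sim", seed = NULL) {
  p <- category_probabilities(theta, lineup_size)
  counts <- with_seed(seed, {
    cp <- drop(stats::rmultinom(1, n_cp, p$cp))
    ca <- drop(stats::rmultinom(1, n_ca, p$ca))
    c(cp, ca)
  })
  ht_data(condition, lineup_size,
          counts[1], counts[2], counts[3], counts[4], counts[5], counts[6])
}

#' Simulate a multi-condition dataset under a model specification
#'
#' @param spec an [ht_spec].
#' @param theta named numeric vector of values for the free parameters of
#'   `spec`.
#' @param template an [ht_data] object supplying the conditions, lineup
#'   sizes and tree totals to simulate at.
#' @param seed optional integer seed.
#' @return An [ht_data] object shaped like `template`.
#' @export
sample_dataset <- function(spec, theta, template, seed = NULL) {
  check_spec_data(spec, template)
  if (!setequal(names(theta), names(spec$bind)))
    stop("theta must name exactly the free parameters of spec", call. = FALSE)
  sb <- slot_bindings(spec)
  slot_value <- function(cond, par) {
    bnd <- sb[[paste(cond, par, sep = ".")]]
    if (!is.null(bnd$free)) unname(theta[[bnd$free]]) else bnd$value
  }
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(template)), function(i) {
      cond <- template$condition[i]
      th <- vapply(ht_parameters, slot_value, numeric(1), cond = cond)
      p <- category_probabilities(th, template$lineup_size[i])
      n_cp <- sum(template$cp_culprit[i], template$cp_filler[i], template$cp_reject[i])
      n_ca <- sum(template$ca_suspect[i], template$ca_filler[i], template$ca_reject[i])
      c(drop(stats::rmultinom(1, n_cp, p$cp)), drop(stats::rmultinom(1, n_ca, p$ca)))
    })
    cnt <- do.call(rbind, rows)
    ht_data(template$condition, template$lineup_size,
            cnt[, 1], cnt[, 2], cnt[, 3], cnt[, 4], cnt[, 5], cnt[, 6])
  })
}

#' Parameter-recovery study
#'
#' Repeatedly simulates data at a known parameter vector and refits the
#' generating specification, summarizing bias and root-mean-square error per
#' free parameter.  Replicates use seeds derived from `seed` and the
#' replicate index, so results do not depend on execution order.  Replicates
#' whose fit does not converge are excluded (and counted); replicates with
#' boundary estimates are retained and counted.
#'
#' @param spec the generating (and fitted) [ht_spec].
#' @param theta_true named numeric vector of true free-parameter values.
#' @param template an [ht_data] object giving conditions, lineup sizes and
#'   tree totals.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param control fitting controls for the replicate fits.
#' @return A list with `summary` (data frame: truth, mean estimate, bias,
#'   rmse, n_boundary per free parameter), the raw `estimates` matrix and
#'   `n_excluded`.
#' @export
recovery_study <- function(spec, theta_true, template, reps = 20,
                           seed = 20220804,
                           control = ht_control(restarts = 2, warn = FALSE)) {
  free <- names(spec$bind)
  theta_true <- theta_true[free]
  est <- matrix(NA_real_, reps, length(free), dimnames = list(NULL, free))
  boundary <- matrix(FALSE, reps, length(free), dimnames = list(NULL, free))
  ok <- logical(reps)
  for (r in seq_len(reps)) {
    dat <- sample_dataset(spec, theta_true, template, seed = derive_seed(seed, r))
    fit <- ht_fit(spec, dat, control)
    ok[r] <- fit$converged
    if (fit$converged) {
      est[r, ] <- fit$estimates[free]
      boundary[r, ] <- fit$boundary[free]
    }
  }
  kept <- est[ok, , drop = FALSE]
  summary <- data.frame(
    parameter = free,
    truth = unname(theta_true),
    mean_estimate = colMeans(kept),
    bias = colMeans(kept) - unname(theta_true),
    rmse = sqrt(colMeans((kept - rep(theta_true, each = nrow(kept)))^2)),
    n_boundary = colSums(boundary[ok, , drop = FALSE]),
    row.names = NULL)
  list(summary = summary, estimates = est, n_excluded = sum(!ok))
}

#' Empirical error rate of the nested likelihood-ratio test
#'
#' Simulates data under the restricted model (so the restriction holds),
#' fits both models to every replicate, and reports the proportion of
#' delta-G-squared tests rejecting at `alpha` — the empirical type-I error
#' rate of the test.
#'
#' @param general,restricted nested [ht_spec] objects (restricted generates).
#' @param theta_true named values of the restricted model's free parameters.
#' @param template an [ht_data] object giving conditions, lineup sizes and
#'   tree totals.
#' @param reps number of replicates.
#' @param alpha nominal significance level.
#' @param seed integer seed.
#' @param control fitting controls for the replicate fits.
#' @return A list with `rejection_rate`, the vector of `p_values` and the
#'   vector of `delta_g_squared` statistics.
#' @export
lrt_error_rate <- function(general, restricted, theta_true, template,
                           reps = 2000, alpha = 0.05, seed = 20220804,
                           control = ht_control(restarts = 0, crosscheck = FALSE,
                                                se = FALSE, warn = FALSE)) {
  if (!is_nested(restricted, general))
    stop("restricted specification is not nested in the general one", call. = FALSE)
  pvals <- numeric(reps)
  dg2 <- numeric(reps)
  for (r in seq_len(reps)) {
    dat <- sample_dataset(restricted, theta_true, template,
                          seed = derive_seed(seed, r))
    fg <- ht_fit(general, dat, control)
    fr <- ht_fit(restricted, dat, control)
    cmp <- compare_fits(fr, fg)
    pvals[r] <- cmp$p_value
    dg2[r] <- cmp$delta_g_squared
  }
  list(rejection_rate = mean(pvals < alpha), p_values = pvals,
       delta_g_squared = dg2)
}
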