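#' Nested likelihood-ratio model comparison
#'
#' Tests an equality or fixing restriction by the difference in G-squared
#' between a restricted model and the more general model it is nested in,
#' referred to the upper tail of the chi-squared distribution with
#' `df_restricted - df_general` degrees of freedom.
#'
#' @param restricted,general [ht_fit] objects fitted to identical data;
#'   `restricted$spec` must be structurally nested in `general$spec`
#'   (see [is_nested()]).
#' @return An object of class `ht_comparison` with `delta_g_squared`,
#'   `delta_df` and `p_value`.
#' @examples
#' fx <- lineup_fixture("wilcock_bull")
#' ctl <- ht_control(restarts = 4)
#' general <- ht_fit(fx$comparison, fx$data, ctl)
#' restricted <- ht_fit(fx$restrictions$dA, fx$data, ctl)
#' compare_fits(restricted, general)
#' @export
compare_fits <- function(restricted, general) {
  stopifnot(inherits(restricted, "ht_fit"), inherits(general, "ht_fit"))
  same_data <- isTRUE(all.equal(
    as.data.frame(restricted$observed[c("condition", "lineup_size", count_cols)]),
    as.data.frame(general$observed[c("condition", "lineup_size", count_cols)]),
    check.attributes = FALSE))
  if (!same_data)
    stop("the two fits are not based on identical data", call. = FALSE)
  if (!is_nested(restricted$spec, general$spec))
    stop("restricted specification is not nested in the general one",
         call. = FALSE)
  delta_df <- restricted$df - general$df
  if (delta_df <= 0)
    stop(sprintf("not nested (Δdf=%d): the restricted model must have fewer free parameters",
                 delta_df), call. = FALSE)
  delta <- restricted$g_squared - general$g_squared
  if (delta < 0) {
    if (delta < -1e-6)
      warning(sprintf(
        "restricted model fits better than the general model (delta G-squared = %.3g); check convergence",
        delta), call. = FALSE)
    delta <- 0
  }
  structure(
    list(delta_g_squared = delta,
         delta_df = delta_df,
         p_value = stats::pchisq(delta, delta_df, lower.tail = FALSE),
         restricted = restricted$spec$description,
         general = general$spec$description),
    class = "ht_comparison")
}

#' @export
print.ht_comparison <- function(x, ...) {
  cat("Nested likelihood-ratio test\n")
  if (nzchar(x$general))    cat("  general:    ", x$general, "\n", sep = "")
  if (nzchar(x$restricted)) cat("  restricted: ", x$restricted, "\n", sep = "")
  cat(sprintf("  delta G-squared(%d) = %.2f, p = %.3f\n",
              x$delta_df, x$delta_g_squared, x$p_value))
  invisible(x)
}
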