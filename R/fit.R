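# Model compilation: flatten spec + data into the path representation used
# by the EM loop.  Global categories are numbered condition-major, 6 per
# condition.  Fixed slots are folded into the path constants so that the
# free-parameter exponent matrices S (successes) and F (failures) only carry
# free parameters.
compile_model <- function(spec, data) {
  check_spec_data(spec, data)
  data <- data[match(spec$conditions, data$condition), , drop = FALSE]
  free <- names(spec$bind)
  nfree <- length(free)
  sb <- slot_bindings(spec)
  ncond <- nrow(data)

  S <- NULL; F_ <- NULL; const <- NULL; cat_g <- NULL
  for (i in seq_len(ncond)) {
    tp <- tree_paths(data$lineup_size[i])
    np <- length(tp$const)
    Si <- matrix(0, np, nfree, dimnames = list(NULL, free))
    Fi <- matrix(0, np, nfree, dimnames = list(NULL, free))
    ci <- tp$const
    for (p in ht_parameters) {
      bnd <- sb[[paste(data$condition[i], p, sep = ".")]]
      if (!is.null(bnd$free)) {
        Si[, bnd$free] <- Si[, bnd$free] + tp$S[, p]
        Fi[, bnd$free] <- Fi[, bnd$free] + tp$F[, p]
      } else {
        v <- bnd$value
        # 0^0 := 1
        ci <- ci * ifelse(tp$S[, p] == 0, 1, v^tp$S[, p]) *
          ifelse(tp$F[, p] == 0, 1, (1 - v)^tp$F[, p])
      }
    }
    S <- rbind(S, Si); F_ <- rbind(F_, Fi)
    const <- c(const, ci)
    cat_g <- c(cat_g, tp$category + 6L * (i - 1L))
  }
  ncat <- 6L * ncond
  A <- matrix(0, ncat, length(const))
  A[cbind(cat_g, seq_along(const))] <- 1

  O <- as.vector(t(as.matrix(data[count_cols])))
  tree_of_cat <- rep(rep(1:2, each = 3L), ncond) + 2L * rep(seq_len(ncond) - 1L, each = 6L)
  tree_tot <- tapply(O, tree_of_cat, sum)
  Ncat <- as.numeric(tree_tot[tree_of_cat])

  # saturated log-likelihood kernel (for G2)
  pos <- O > 0
  ll_sat <- sum(O[pos] * log(O[pos] / Ncat[pos]))

  list(spec = spec, data = data, free = free, nfree = nfree,
       S = S, F = F_, const = const, A = A, O = O, Ncat = Ncat,
       pos = pos, ll_sat = ll_sat, ncond = ncond)
}

cat_probs_compiled <- function(m, theta) {
  p_path <- m$const * exp(m$S %*% log(theta) + m$F %*% log1p(-theta))
  drop(m$A %*% p_path)
}

loglik_compiled <- function(m, theta) {
  p <- cat_probs_compiled(m, theta)
  if (any(p[m$pos] <= 0)) return(-Inf)
  sum(m$O[m$pos] * log(p[m$pos]))
}

g2_from_loglik <- function(m, ll) 2 * (m$ll_sat - ll)

# EM per the conditional-expectation scheme for multinomial processing
# trees: the E-step distributes each observed category count over its paths
# in proportion to path probabilities; the M-step sets each free parameter
# to expected successes over expected trials across all branches sharing it.
em_fit <- function(m, start, tol = 1e-10, max_iter = 1e5, trace = FALSE) {
  theta <- pmin(pmax(start, 1e-9), 1 - 1e-9)
  tS <- t(m$S); tF <- t(m$F); tA <- t(m$A)
  ll_old <- -Inf
  ll_trace <- if (trace) numeric(0) else NULL
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p_path <- m$const * exp(m$S %*% log(theta) + m$F %*% log1p(-theta))
    p_cat <- drop(m$A %*% p_path)
    ll <- if (any(p_cat[m$pos] <= 0)) -Inf else sum(m$O[m$pos] * log(p_cat[m$pos]))
    if (trace) ll_trace <- c(ll_trace, ll)
    if (is.finite(ll) && is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    if (!is.finite(ll) && !is.finite(ll_old)) break  # cannot recover from zero-probability start
    ll_old <- ll
    if (iter >= max_iter) break
    r_cat <- ifelse(p_cat > 0, m$O / p_cat, 0)
    mexp <- drop(p_path) * drop(tA %*% r_cat)
    succ <- drop(tS %*% mexp)
    trials <- succ + drop(tF %*% mexp)
    theta_new <- ifelse(trials > 0, succ / trials, theta)
    theta <- pmin(pmax(theta_new, 1e-12), 1 - 1e-12)
  }
  names(theta) <- m$free
  list(theta = theta, loglik = ll_old, iterations = iter,
       converged = converged, trace = ll_trace)
}

heuristic_start <- function(m) {
  # one start informed by the typical magnitude of each process: detection
  # around .5, biased selection and absence detection small, guessing mid
  defaults <- c(dP = 0.5, b = 0.1, g = 0.5, dA = 0.1)
  vapply(m$free, function(nm) {
    slots <- m$spec$bind[[nm]]
    pars <- sub("^.*\\.", "", slots)
    mean(defaults[pars])
  }, numeric(1))
}

#' Fitting controls
#'
#' @param restarts number of uniform-random starting vectors in addition to
#'   one heuristic start; the best (lowest G-squared) solution is reported.
#' @param seed integer seed for the random starts (restored afterwards; the
#'   user's random-number state is untouched).
#' @param tol convergence tolerance on the log-likelihood improvement per
#'   EM iteration.
#' @param max_iter maximum EM iterations per start.
#' @param crosscheck also minimize G-squared by quasi-Newton optimization on
#'   logit-transformed parameters and record the agreement?
#' @param se compute standard errors from the observed Fisher information?
#' @param strict_df use the reconstructed-tree degrees-of-freedom correction
#'   (see [independent_category_count()])?
#' @param warn emit warnings for non-convergence and restart disagreement?
#' @return A list of class `ht_control`.
#' @export
ht_control <- function(restarts = 10, seed = 20220804, tol = 1e-10,
                       max_iter = 1e5, crosscheck = TRUE, se = TRUE,
                       strict_df = FALSE, warn = TRUE) {
  structure(list(restarts = restarts, seed = seed, tol = tol,
                 max_iter = max_iter, crosscheck = crosscheck, se = se,
                 strict_df = strict_df, warn = warn),
            class = "ht_control")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

#' Fit the 2-HT eyewitness identification model
#'
#' Maximum-likelihood estimation of a multi-condition model specification by
#' the expectation-maximization algorithm for multinomial processing tree
#' models, with multiple restarts and a quasi-Newton cross-check on
#' logit-transformed parameters.  Goodness of fit is summarized by the
#' log-likelihood-ratio statistic G-squared with an upper-tail chi-squared
#' p-value at `degrees_of_freedom(spec, data)`.
#'
#' @param spec an [ht_spec].
#' @param data an [ht_data] object over the same conditions.
#' @param control fitting controls, see [ht_control()].
#' @return An object of class `ht_fit` with components `estimates`,
#'   `standard_errors`, `boundary`, `expected`, `observed`, `g_squared`,
#'   `df`, `p_value`, `log_likelihood`, `converged`, `n_restarts_agreeing`
#'   and `diagnostics`.
#' @examples
#' fx <- lineup_fixture("wilcock_bull")
#' fit <- ht_fit(fx$comparison, fx$data, ht_control(restarts = 4))
#' fit
#' @export
ht_fit <- function(spec, data, control = ht_control()) {
  m <- compile_model(spec, data)
  if (m$nfree == 0L)
    stop("specification has no free parameters", call. = FALSE)

  starts <- with_seed(control$seed, {
    s <- replicate(control$restarts, stats::runif(m$nfree, 0.05, 0.95),
                   simplify = FALSE)
    c(list(heuristic_start(m)), s)
  })
  runs <- lapply(starts, function(st)
    em_fit(m, st, tol = control$tol, max_iter = control$max_iter))
  g2s <- vapply(runs, function(r) g2_from_loglik(m, r$loglik), numeric(1))
  best_i <- which(g2s <= min(g2s) + 1e-9)[1]  # first-found wins ties
  best <- runs[[best_i]]
  g2 <- g2s[best_i]

  n_agree <- sum(abs(g2s - g2) <= 1e-3)
  if (control$warn && n_agree < length(runs))
    warning(sprintf(
      "restarts disagree in G-squared by more than 1e-3 (%d of %d agree): possible multimodality",
      n_agree, length(runs)), call. = FALSE)
  if (control$warn && !best$converged)
    warning("EM did not converge within max_iter iterations", call. = FALSE)

  diagnostics <- list(
    restart_g_squared = g2s,
    em_iterations = best$iterations,
    g_squared_em = g2,
    g_squared_optim = NA_real_,
    crosscheck_agreement = NA_real_,
    notes = character(0))

  if (any(!is.finite(g2s)))
    diagnostics$notes <- c(diagnostics$notes,
                           "some restarts ended with observed counts in zero-probability categories")

  theta <- best$theta
  log_likelihood <- best$loglik
  if (control$crosscheck) {
    opt <- optim_crosscheck(m, best$theta)
    diagnostics$g_squared_optim <- opt$g2
    diagnostics$crosscheck_agreement <- abs(opt$g2 - g2)
    if (opt$g2 < g2) {
      # the quasi-Newton refinement sharpens the EM solution; keep the
      # better optimum
      theta <- pmin(pmax(opt$theta, 1e-12), 1 - 1e-12)
      names(theta) <- m$free
      g2 <- opt$g2
      log_likelihood <- loglik_compiled(m, theta)
      diagnostics$notes <- c(diagnostics$notes, "quasi-Newton refinement adopted")
    }
  }
  boundary <- theta < 1e-4 | theta > 1 - 1e-4
  se <- rep(NA_real_, m$nfree)
  names(se) <- m$free
  if (control$se) {
    se_out <- observed_information_se(m, theta)
    se <- se_out$se
    if (se_out$singular) {
      diagnostics$notes <- c(diagnostics$notes,
                             "observed information matrix is singular: standard errors undefined (model may not be identified)")
      if (control$warn)
        warning("observed information matrix is singular; standard errors undefined",
                call. = FALSE)
    }
  }

  df <- degrees_of_freedom(spec, data, strict = control$strict_df)
  p_value <- if (df > 0) stats::pchisq(g2, df, lower.tail = FALSE) else NA_real_

  expected <- expected_table(m, theta)
  structure(
    list(estimates = theta,
         standard_errors = se,
         boundary = boundary,
         observed = m$data,
         expected = expected,
         g_squared = g2,
         df = df,
         p_value = p_value,
         log_likelihood = log_likelihood,
         converged = best$converged,
         n_restarts_agreeing = n_agree,
         diagnostics = diagnostics,
         spec = spec,
         control = control),
    class = "ht_fit")
}

optim_crosscheck <- function(m, theta_start) {
  eta0 <- stats::qlogis(pmin(pmax(theta_start, 1e-7), 1 - 1e-7))
  fn <- function(eta) {
    ll <- loglik_compiled(m, stats::plogis(eta))
    if (!is.finite(ll)) return(1e12)
    g2_from_loglik(m, ll)
  }
  o <- stats::optim(eta0, fn, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-14))
  list(g2 = o$value, theta = stats::plogis(o$par))
}

# Standard errors: square roots of the diagonal of the inverse observed
# Fisher information of the product-multinomial log-likelihood kernel,
# evaluated at the estimates.  Boundary estimates are perturbed inward by
# 1e-3 so that the finite-difference Hessian stays inside the unit cube.
observed_information_se <- function(m, theta) {
  th <- pmin(pmax(theta, 1e-3), 1 - 1e-3)
  nll <- function(x) -loglik_compiled(m, pmin(pmax(x, 1e-9), 1 - 1e-9))
  H <- stats::optimHess(th, nll, control = list(ndeps = rep(1e-5, length(th))))
  se <- rep(NA_real_, length(theta))
  names(se) <- names(theta)
  singular <- FALSE
  inv <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(inv) || any(!is.finite(diag(inv))) || any(diag(inv) < 0)) {
    singular <- TRUE
  } else {
    se[] <- sqrt(diag(inv))
  }
  list(se = se, singular = singular)
}

expected_table <- function(m, theta) {
  p <- cat_probs_compiled(m, theta)
  E <- matrix(p * m$Ncat, ncol = 6L, byrow = TRUE,
              dimnames = list(m$data$condition, count_cols))
  as.data.frame(E)
}

#' Log-likelihood-ratio goodness-of-fit statistic G-squared
#'
#' `G2 = 2 * sum(O * log(O / E))` over all categories; categories with a
#' zero observed count contribute nothing.  A positive observed count facing
#' a zero expected count yields `Inf` (the model cannot fit), with a warning.
#'
#' @param observed,expected numeric vectors of matching length; expected
#'   counts from a model with the same totals.
#' @return The statistic (non-negative; additive over conditions).
#' @export
g_squared <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected must have the same length", call. = FALSE)
  if (any(observed < 0) || any(expected < 0))
    stop("counts must be non-negative", call. = FALSE)
  pos <- observed > 0
  if (any(expected[pos] == 0)) {
    warning("observed count in a zero-expectation category: G-squared is infinite",
            call. = FALSE)
    return(Inf)
  }
  2 * sum(observed[pos] * log(observed[pos] / expected[pos]))
}

#' Standard errors of a fitted model
#'
#' @param fit an [ht_fit] object.
#' @return Named numeric vector of standard errors (free parameters only;
#'   fixed constants have no sampling variance), with a logical `boundary`
#'   attribute flagging estimates within 1e-4 of 0 or 1.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "ht_fit"))
  structure(fit$standard_errors, boundary = fit$boundary)
}

#' Local identifiability diagnostic
#'
#' Computes the numerical Jacobian of all independent category probabilities
#' with respect to the free parameters and compares its rank with the number
#' of free parameters.  Rank deficiency means the data cannot distinguish
#' some parameter combinations near `theta` ("not locally identifiable").
#'
#' @param spec an [ht_spec].
#' @param data an [ht_data] object over the same conditions.
#' @param theta named numeric vector of free-parameter values at which to
#'   evaluate the Jacobian; boundary values are perturbed inward by 1e-3.
#' @return A list with `rank`, `n_free`, `identifiable` and the Jacobian's
#'   singular values.
#' @export
identifiability_check <- function(spec, data, theta) {
  m <- compile_model(spec, data)
  if (is.null(names(theta))) names(theta) <- m$free
  theta <- pmin(pmax(theta[m$free], 1e-3), 1 - 1e-3)
  # independent categories: drop the last category of each tree, and all
  # categories of trees without observations
  keep <- rep(c(TRUE, TRUE, FALSE), 2L * m$ncond) & m$Ncat > 0
  h <- 1e-5
  J <- vapply(seq_len(m$nfree), function(j) {
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    (cat_probs_compiled(m, up)[keep] - cat_probs_compiled(m, dn)[keep]) / (2 * h)
  }, numeric(sum(keep)))
  sv <- svd(J, nu = 0, nv = 0)$d
  rank <- sum(sv > max(dim(J)) * .Machine$double.eps * max(sv, 0))
  list(rank = rank, n_free = m$nfree, identifiable = rank == m$nfree,
       singular_values = sv)
}

#' @export
print.ht_fit <- function(x, ...) {
  cat("2-HT eyewitness identification model fit\n")
  if (nzchar(x$spec$description))
    cat("  model: ", x$spec$description, "\n", sep = "")
  p_str <- if (is.na(x$p_value)) "(saturated)" else sprintf("p = %.3f", x$p_value)
  cat(sprintf("  G-squared(%d) = %.2f, %s\n", x$df, x$g_squared, p_str))
  est <- sprintf("%.2f", x$estimates)
  se <- ifelse(is.na(x$standard_errors), "  NA",
               sprintf("(%.2f)", x$standard_errors))
  flag <- ifelse(x$boundary, " [boundary]", "")
  cat("  estimates:\n")
  for (i in seq_along(x$estimates))
    cat(sprintf("    %-14s %s %s%s\n", names(x$estimates)[i], est[i], se[i], flag[i]))
  if (!x$converged) cat("  WARNING: EM did not converge\n")
  cat(sprintf("  restarts agreeing on G-squared: %d of %d",
              x$n_restarts_agreeing, length(x$diagnostics$restart_g_squared)))
  if (is.finite(x$diagnostics$crosscheck_agreement))
    cat(sprintf("; EM/quasi-Newton agreement: %.2e",
                x$diagnostics$crosscheck_agreement))
  cat("\n")
  invisible(x)
}
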