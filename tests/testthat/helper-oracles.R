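# Independent oracles used by the tests.  These are deliberately written as
# direct transcriptions of the tree equations / definitions, separate from
# the package's path-table machinery.

# Closed-form category probabilities, read directly off the two trees.
oracle_probs <- function(dP, b, g, dA, k) {
  list(cp = c(dP + (1 - dP) * b + (1 - dP) * (1 - b) * g / k,
              (1 - dP) * (1 - b) * g * (k - 1) / k,
              (1 - dP) * (1 - b) * (1 - g)),
       ca = c((1 - dA) * b + (1 - dA) * (1 - b) * g / k,
              (1 - dA) * (1 - b) * g * (k - 1) / k,
              dA + (1 - dA) * (1 - b) * (1 - g)))
}

# G-squared of a single condition at given parameters (direct evaluation).
oracle_g2_condition <- function(theta, k, cp, ca) {
  p <- oracle_probs(theta[1], theta[2], theta[3], theta[4], k)
  O <- c(cp, ca)
  E <- c(sum(cp) * p$cp, sum(ca) * p$ca)
  pos <- O > 0
  if (any(E[pos] <= 0)) return(Inf)
  2 * sum(O[pos] * log(O[pos] / E[pos]))
}

# Minimum G-squared over the full (dP, b, g, dA) grid with the given step,
# for a single condition.  Uses the separability of G-squared into a
# culprit-present part (dP, b, g) and a culprit-absent part (dA, b, g):
# for every (b, g) pair the minimum over dP and over dA can be profiled
# independently, which makes the complete grid tractable.
oracle_grid_g2 <- function(cp, ca, k, step = 0.005) {
  grid <- seq(0, 1, by = step)
  n_cp <- sum(cp); n_ca <- sum(ca)
  term <- function(O, E) if (O > 0) 2 * O * log(O / pmax(E, 1e-300)) else 0
  best <- Inf
  d_outer <- outer(grid, grid, function(b, dP) (1 - dP) * (1 - b))  # b x dP (same for dA)
  bias_cp <- outer(grid, grid, function(b, dP) dP + (1 - dP) * b)
  bias_ca <- outer(grid, grid, function(b, dA) (1 - dA) * b)
  dA_add <- matrix(grid, length(grid), length(grid), byrow = TRUE)     # dA term
  for (g in grid) {
    # culprit-present: categories as functions of (b, dP)
    p1 <- bias_cp + d_outer * g / k
    p2 <- d_outer * g * (k - 1) / k
    p3 <- d_outer * (1 - g)
    g2_cp <- term(cp[1], n_cp * p1) + term(cp[2], n_cp * p2) + term(cp[3], n_cp * p3)
    prof_cp <- apply(g2_cp, 1, min)   # min over dP, per b
    # culprit-absent: categories as functions of (b, dA)
    q1 <- bias_ca + d_outer * g / k
    q2 <- d_outer * g * (k - 1) / k
    q3 <- dA_add + d_outer * (1 - g)
    g2_ca <- term(ca[1], n_ca * q1) + term(ca[2], n_ca * q2) + term(ca[3], n_ca * q3)
    prof_ca <- apply(g2_ca, 1, min)   # min over dA, per b
    best <- min(best, min(prof_cp + prof_ca))
  }
  best
}

# Algebraic inversion of the saturated single-condition model: solves the
# six tree equations for (dP, b, g, dA) from the observed proportions.
# Valid for interior solutions; an independent route to the saturated MLE.
oracle_invert_saturated <- function(cp, ca, k) {
  pc <- cp / sum(cp); qa <- ca / sum(ca)
  # culprit-present: filler = u*g*(k-1)/k, reject = u*(1-g) with u = (1-dP)(1-b)
  g <- (pc[2] * k / (k - 1)) / (pc[2] * k / (k - 1) + pc[3])
  u <- pc[3] / (1 - g)
  # culprit-absent: filler = v*g*(k-1)/k with v = (1-dA)(1-b)
  v <- qa[2] * k / (g * (k - 1))
  # suspect = (1-dA)*b + v*g/k and (1-dA) = v/(1-b)  =>  b/(1-b) = s/v
  s <- qa[1] - v * g / k
  b <- (s / v) / (1 + s / v)
  dP <- 1 - u / (1 - b)
  dA <- 1 - v / (1 - b)
  c(dP = unname(dP), b = unname(b), g = unname(g), dA = unname(dA))
}

# Richardson-extrapolated central-difference Hessian of f at x.
oracle_hessian <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  hess_step <- function(hh) {
    Hs <- matrix(0, n, n)
    for (i in 1:n) for (j in i:n) {
      ei <- ej <- rep(0, n); ei[i] <- hh; ej[j] <- hh
      Hs[i, j] <- Hs[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hh^2)
    }
    Hs
  }
  (4 * hess_step(h) - hess_step(2 * h)) / 3
}

# Small synthetic single-condition dataset helper; tolerates counts that
# are integral up to floating-point noise (e.g. exact expected frequencies).
one_cond_data <- function(cp, ca, k = 6, label = "c1") {
  snap <- function(x) {
    r <- round(x)
    stopifnot(all(abs(x - r) < 1e-6))
    r
  }
  cp <- snap(cp); ca <- snap(ca)
  ht_data(label, k, cp[1], cp[2], cp[3], ca[1], ca[2], ca[3])
}
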