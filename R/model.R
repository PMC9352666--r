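#' @keywords internal
"_PACKAGE"

ht_parameters <- c("dP", "b", "g", "dA")

# Root-to-leaf paths of the two processing trees for one condition.
#
# Categories are numbered 1..6: culprit-present culprit/filler/reject,
# then culprit-absent suspect/filler/reject.  Each path records the
# category it terminates in, a structural constant (the 1/k guessing
# weights), and 0/1 exponents on the success (theta) and failure
# (1 - theta) of each of the four parameters.
tree_paths <- function(lineup_size) {
  k <- lineup_size
  S <- matrix(0L, 10, 4, dimnames = list(NULL, ht_parameters))
  F_ <- matrix(0L, 10, 4, dimnames = list(NULL, ht_parameters))
  cat_ <- integer(10)
  const <- numeric(10)
  set_path <- function(i, category, weight, succ, fail) {
    cat_[i] <<- category; const[i] <<- weight
    S[i, succ] <<- 1L; F_[i, fail] <<- 1L
  }
  # culprit-present tree
  set_path(1L, 1L, 1,           "dP", character())
  set_path(2L, 1L, 1,           "b",  "dP")
  set_path(3L, 1L, 1 / k,       "g",  c("dP", "b"))
  set_path(4L, 2L, (k - 1) / k, "g",  c("dP", "b"))
  set_path(5L, 3L, 1,           character(), c("dP", "b", "g"))
  # culprit-absent tree
  set_path(6L, 6L, 1,           "dA", character())
  set_path(7L, 4L, 1,           "b",  "dA")
  set_path(8L, 4L, 1 / k,       "g",  c("dA", "b"))
  set_path(9L, 5L, (k - 1) / k, "g",  c("dA", "b"))
  set_path(10L, 6L, 1,          character(), c("dA", "b", "g"))
  list(category = cat_, const = const, S = S, F = F_)
}

check_theta <- function(theta) {
  theta <- unlist(theta)
  if (length(theta) != 4L)
    stop("theta must supply the four parameters dP, b, g, dA", call. = FALSE)
  if (is.null(names(theta)) || !all(nzchar(names(theta)))) {
    names(theta) <- ht_parameters
  } else {
    if (!setequal(names(theta), ht_parameters))
      stop("theta names must be dP, b, g, dA", call. = FALSE)
    theta <- theta[ht_parameters]
  }
  if (any(is.na(theta)) || any(theta < 0) || any(theta > 1))
    stop("all parameters must lie in [0, 1]", call. = FALSE)
  theta
}

#' Category probabilities of the 2-HT eyewitness identification model
#'
#' Maps the four latent-process probabilities onto the six observable
#' response categories of a lineup of a given size by summing branch
#' products over all root-to-leaf paths of the two processing trees.
#'
#' @param theta numeric vector of the four parameters, named `dP`
#'   (culprit-presence detection), `b` (biased suspect selection), `g`
#'   (guessing-based selection) and `dA` (culprit-absence detection); all in
#'   `[0, 1]`.
#' @param lineup_size number of persons in the lineup (integer `>= 2`).
#' @return A list with components `cp` (culprit-present tree: `culprit`,
#'   `filler`, `reject`) and `ca` (culprit-absent tree: `suspect`, `filler`,
#'   `reject`); each triple sums to 1.
#' @examples
#' category_probabilities(c(dP = .5, b = .2, g = .5, dA = .1), lineup_size = 6)
#' @export
category_probabilities <- function(theta, lineup_size) {
  theta <- check_theta(theta)
  if (length(lineup_size) != 1L || is.na(lineup_size) || lineup_size < 2 ||
      lineup_size != round(lineup_size))
    stop("lineup_size must be a single integer >= 2", call. = FALSE)
  tp <- tree_paths(lineup_size)
  # 0^0 := 1 for the exponent products
  pow <- function(base, ex) ifelse(ex == 0L, 1, base^ex)
  p_path <- tp$const *
    apply(pow(rep(theta, each = 10), tp$S), 1L, prod) *
    apply(pow(rep(1 - theta, each = 10), tp$F), 1L, prod)
  p <- vapply(1:6, function(j) sum(p_path[tp$category == j]), numeric(1))
  list(cp = c(culprit = p[1], filler = p[2], reject = p[3]),
       ca = c(suspect = p[4], filler = p[5], reject = p[6]))
}

#' Expected response frequencies
#'
#' Scales the model's category probabilities by the two tree totals.
#'
#' @param probs category probabilities as returned by
#'   [category_probabilities()].
#' @param n_cp,n_ca non-negative totals of the culprit-present and
#'   culprit-absent trees.
#' @return Named numeric vector of the six expected counts
#'   (`cp_culprit`, ..., `ca_reject`).
#' @export
expected_frequencies <- function(probs, n_cp, n_ca) {
  if (n_cp < 0 || n_ca < 0)
    stop("tree totals must be non-negative", call. = FALSE)
  e <- c(n_cp * probs$cp, n_ca * probs$ca)
  names(e) <- count_cols
  e
}
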