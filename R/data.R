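#' Lineup frequency data
#'
#' Constructs a set of per-condition lineup frequency tables.  Each condition
#' contributes two multinomial trees: the culprit-present tree (culprit
#' identifications, filler identifications, lineup rejections) and the
#' culprit-absent tree (innocent-suspect identifications, filler
#' identifications, lineup rejections).
#'
#' @param condition character vector of condition labels (unique).
#' @param lineup_size integer vector (recycled) of lineup sizes, `>= 2`.
#' @param cp_culprit,cp_filler,cp_reject non-negative integer counts for the
#'   culprit-present tree.
#' @param ca_suspect,ca_filler,ca_reject non-negative integer counts for the
#'   culprit-absent tree.
#' @param reconstructed_ca logical (recycled): was the innocent-suspect count
#'   reconstructed by splitting total false identifications rather than
#'   observed for a designated innocent suspect?  Only consulted by the
#'   `strict_df` degrees-of-freedom variant.
#' @return A data frame of class `ht_data`, one row per condition.
#' @examples
#' ht_data("control", 6, cp_culprit = 36, cp_filler = 8, cp_reject = 9,
#'         ca_suspect = 25, ca_filler = 13, ca_reject = 16)
#' @export
ht_data <- function(condition, lineup_size,
                    cp_culprit, cp_filler, cp_reject,
                    ca_suspect, ca_filler, ca_reject,
                    reconstructed_ca = FALSE) {
  condition <- as.character(condition)
  if (anyDuplicated(condition))
    stop("condition labels must be unique", call. = FALSE)
  n <- length(condition)
  d <- data.frame(
    condition = condition,
    lineup_size = rep_len(as.integer(lineup_size), n),
    cp_culprit = rep_len(cp_culprit, n),
    cp_filler = rep_len(cp_filler, n),
    cp_reject = rep_len(cp_reject, n),
    ca_suspect = rep_len(ca_suspect, n),
    ca_filler = rep_len(ca_filler, n),
    ca_reject = rep_len(ca_reject, n),
    reconstructed_ca = rep_len(as.logical(reconstructed_ca), n),
    stringsAsFactors = FALSE
  )
  validate_ht_data(d)
  class(d) <- c("ht_data", "data.frame")
  d
}

count_cols <- c("cp_culprit", "cp_filler", "cp_reject",
                "ca_suspect", "ca_filler", "ca_reject")

validate_ht_data <- function(d) {
  cnt <- as.matrix(d[count_cols])
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("all six counts must be non-negative integers", call. = FALSE)
  if (any(is.na(d$lineup_size)) || any(d$lineup_size < 2))
    stop("lineup_size must be an integer >= 2", call. = FALSE)
  tot <- rowSums(cnt)
  if (any(tot == 0))
    stop("each condition needs at least one non-empty tree", call. = FALSE)
  invisible(d)
}

#' Read lineup frequency data from a delimited text file
#'
#' Expects a comma-separated file with the header
#' `condition,lineup_size,cp_culprit,cp_filler,cp_reject,ca_suspect,ca_filler,ca_reject`
#' and one row per condition.  An optional `reconstructed_ca` column (0/1 or
#' TRUE/FALSE) is honoured.
#'
#' @param path file path.
#' @return An [ht_data] object.
#' @export
read_lineup_data <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("condition", "lineup_size", count_cols)
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop(sprintf("malformed lineup data file '%s': missing column(s) %s",
                 path, paste(sQuote(missing), collapse = ", ")), call. = FALSE)
  rec <- if ("reconstructed_ca" %in% names(raw)) as.logical(raw$reconstructed_ca) else FALSE
  ht_data(raw$condition, raw$lineup_size,
          raw$cp_culprit, raw$cp_filler, raw$cp_reject,
          raw$ca_suspect, raw$ca_filler, raw$ca_reject,
          reconstructed_ca = rec)
}

#' Write lineup frequency data to a delimited text file
#'
#' @param data an [ht_data] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_lineup_data <- function(data, path) {
  stopifnot(inherits(data, "ht_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.ht_data <- function(x, ...) {
  cat(sprintf("Lineup frequency data: %d condition(s)\n", nrow(x)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
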