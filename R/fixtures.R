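#' Split total false identifications into suspect and filler counts
#'
#' For culprit-absent lineups without a designated innocent suspect, the
#' innocent-suspect count is reconstructed by the standard convention of
#' dividing the total number of false identifications by the lineup size
#' (rounding half up); the remainder is attributed to the fillers.  This
#' assumes a fair lineup in which the notional innocent suspect is selected
#' with the same probability as each filler.
#'
#' @param total_false total number of false identifications (suspect plus
#'   fillers) in the culprit-absent lineups.
#' @param lineup_size number of persons in the lineup.
#' @return Named integer vector `c(suspect = ..., filler = ...)`.
#' @examples
#' split_false_identifications(107, 6)  # c(suspect = 18, filler = 89)
#' @export
split_false_identifications <- function(total_false, lineup_size) {
  if (any(total_false < 0) || any(lineup_size < 2))
    stop("total_false must be >= 0 and lineup_size >= 2", call. = FALSE)
  suspect <- floor(total_false / lineup_size + 0.5)  # round half up
  c(suspect = as.integer(suspect), filler = as.integer(total_false - suspect))
}

#' Equal per-condition cell sizes
#'
#' Divides a total sample size evenly across conditions, as used when a
#' source reports only group totals and assignment to conditions was
#' balanced.
#'
#' @param total_n total number of participants.
#' @param n_conditions number of equally sized conditions.
#' @return The integer per-condition cell size.
#' @export
equal_cell_counts <- function(total_n, n_conditions) {
  if (total_n < 0 || n_conditions < 1)
    stop("total_n must be >= 0 and n_conditions >= 1", call. = FALSE)
  if (total_n %% n_conditions != 0)
    stop(sprintf("total_n = %d is not divisible by %d conditions: supply explicit per-cell counts",
                 total_n, n_conditions), call. = FALSE)
  as.integer(total_n / n_conditions)
}

# ---- fixture registry ------------------------------------------------------
#
# Frequencies are stored as literal integers exactly as printed in the
# source publications (or as reconstructed there from printed proportions);
# no runtime re-derivation.  `published` holds the reference statistics and
# 2-dp parameter estimates/SEs that the fitted models are compared against.

fixture_registry <- function() {
  reg <- list()

  # Memon, Hope & Bull (2003, Br J Psychol 94, Table 1): exposure duration
  # (long/short) x age group; equal cell sizes 84/4 and 80/4; innocent-suspect
  # counts reconstructed by the 1/6 split.
  conds <- c("younger_long", "younger_short", "older_long", "older_short")
  reg$memon2003 <- list(
    name = "memon2003",
    provenance = "Memon, Hope & Bull (2003), Table 1; frequencies reconstructed with equal cell sizes and the innocent-suspect split rule",
    data = ht_data(conds, 6,
                   cp_culprit = c(20, 6, 17, 7),
                   cp_filler  = c(1, 9, 2, 9),
                   cp_reject  = c(0, 6, 1, 4),
                   ca_suspect = c(2, 3, 2, 3),
                   ca_filler  = c(7, 16, 8, 13),
                   ca_reject  = c(12, 2, 10, 4),
                   reconstructed_ca = TRUE),
    comparison = ht_spec(conds, bind = list(
      dP_long  = c("younger_long.dP", "older_long.dP"),
      dP_short = c("younger_short.dP", "older_short.dP"),
      g_long   = c("younger_long.g", "older_long.g"),
      g_short  = c("younger_short.g", "older_short.g"),
      b        = paste0(conds, ".b"),
      dA       = paste0(conds, ".dA")),
      description = "exposure-duration comparison standard (dP, g per exposure; b, dA shared)"),
    tested = list(dP = c("dP_long", "dP_short"), g = c("g_long", "g_short")),
    published = list(
      g_squared = 8.19, df = 10, p = 0.610,
      delta_g_squared = c(dP = 34.33, g = 10.24),
      estimates = c(b = .02, g_long = .48, g_short = .78, dA = .00),
      ses       = c(b = .04, g_long = .09, g_short = .06, dA = .12)))

  # Smith (2014-style viewing-conditions experiment, Exp. 1, Table 1):
  # clear vs degraded video; innocent-suspect counts reconstructed.
  conds <- c("clear", "degraded")
  reg$smith2014 <- list(
    name = "smith2014",
    provenance = "Smith, Experiment 1, Table 1; innocent-suspect counts reconstructed with the split rule",
    data = ht_data(conds, 6,
                   cp_culprit = c(79, 17),
                   cp_filler  = c(9, 35),
                   cp_reject  = c(20, 47),
                   ca_suspect = c(9, 18),
                   ca_filler  = c(43, 89),
                   ca_reject  = c(153, 96),
                   reconstructed_ca = TRUE),
    comparison = ht_spec(conds, bind = list(
      dP_clear = "clear.dP", dP_degraded = "degraded.dP",
      g_clear = "clear.g", g_degraded = "degraded.g",
      b = paste0(conds, ".b"), dA = paste0(conds, ".dA")),
      description = "viewing-conditions comparison standard (dP, g per condition; b, dA shared)"),
    tested = list(dP = c("dP_clear", "dP_degraded"), g = c("g_clear", "g_degraded")),
    published = list(
      g_squared = 1.81, df = 2, p = 0.405,
      delta_g_squared = c(dP = 74.73, g = 32.02),
      estimates = c(b = .00, g_clear = .26, g_degraded = .51, dA = .00),
      ses       = c(b = .01, g_clear = .04, g_degraded = .05, dA = .12)))

  # Wetmore et al. (2015, Table 2): lineup fairness x retention delay;
  # designated innocent suspects (two, aggregated).
  conds <- c("immediate_fair", "immediate_unfair", "delayed_fair", "delayed_unfair")
  reg$wetmore <- list(
    name = "wetmore",
    provenance = "Wetmore et al., Table 2; lineup arms only, frequencies reconstructed from printed proportions, the two innocent suspects aggregated",
    data = ht_data(conds, 6,
                   cp_culprit = c(41, 57, 59, 54),
                   cp_filler  = c(6, 2, 13, 4),
                   cp_reject  = c(13, 11, 14, 14),
                   ca_suspect = c(31, 56, 22, 48),
                   ca_filler  = c(74, 37, 59, 31),
                   ca_reject  = c(54, 58, 38, 39),
                   reconstructed_ca = FALSE),
    comparison = ht_spec(conds, bind = list(
      dP_fair   = c("immediate_fair.dP", "delayed_fair.dP"),
      dP_unfair = c("immediate_unfair.dP", "delayed_unfair.dP"),
      b_fair    = c("immediate_fair.b", "delayed_fair.b"),
      b_unfair  = c("immediate_unfair.b", "delayed_unfair.b"),
      g_fair    = c("immediate_fair.g", "delayed_fair.g"),
      g_unfair  = c("immediate_unfair.g", "delayed_unfair.g"),
      dA        = paste0(conds, ".dA")),
      description = "lineup-fairness comparison standard (dP, b, g per fairness; dA shared)"),
    tested = list(b = c("b_fair", "b_unfair"),
                  g = c("g_fair", "g_unfair"),
                  dP = c("dP_fair", "dP_unfair")),
    published = list(
      g_squared = 14.10, df = 9, p = 0.119,
      delta_g_squared = c(b = 31.84, g = 15.42, dP = 0.19),
      estimates = c(dP_fair = .61, g_fair = .61, dA = .00,
                    dP_unfair = .64, g_unfair = .42),
      ses       = c(dP_fair = .05, g_fair = .05, dA = .07,
                    dP_unfair = .06, g_unfair = .05)))

  # Colloff et al. (2016, Table 2): distinctive-feature treatment (three fair
  # variants vs unfair); designated innocent suspects.
  conds <- c("block", "pixelation", "replication", "unfair")
  fair <- c("block", "pixelation", "replication")
  reg$colloff <- list(
    name = "colloff",
    provenance = "Colloff, Wade & Strange, Table 2 (rounded to integers); designated innocent suspects",
    data = ht_data(conds, 6,
                   cp_culprit = c(323, 320, 347, 629),
                   cp_filler  = c(390, 411, 382, 206),
                   cp_reject  = c(414, 414, 396, 275),
                   ca_suspect = c(101, 102, 105, 364),
                   ca_filler  = c(503, 512, 523, 219),
                   ca_reject  = c(534, 510, 513, 434),
                   reconstructed_ca = FALSE),
    comparison = ht_spec(conds, bind = list(
      dP_fair = paste0(fair, ".dP"), dP_unfair = "unfair.dP",
      b_fair = paste0(fair, ".b"), b_unfair = "unfair.b",
      g_fair = paste0(fair, ".g"), g_unfair = "unfair.g",
      dA = paste0(conds, ".dA")),
      description = "distinctive-feature comparison standard (dP, b, g shared across fair variants; dA shared)"),
    tested = list(b = c("b_fair", "b_unfair"),
                  g = c("g_fair", "g_unfair"),
                  dP = c("dP_fair", "dP_unfair")),
    published = list(
      g_squared = 12.92, df = 9, p = 0.166,
      delta_g_squared = c(b = 418.89, g = 48.99, dP = 8.37),
      estimates = c(dP_fair = .22, g_fair = .55, dA = .02,
                    dP_unfair = .32, g_unfair = .43),
      ses       = c(dP_fair = .01, g_fair = .01, dA = .02,
                    dP_unfair = .03, g_unfair = .02)))

  # Malpass & Devine (1981, Table 1): one-sided vs two-sided pre-lineup
  # instructions, five-person live lineup; innocent-suspect counts
  # reconstructed by the 1/5 split.
  conds <- c("one_sided", "two_sided")
  reg$malpass_devine <- list(
    name = "malpass_devine",
    provenance = "Malpass & Devine, Table 1; five-person lineup, frequencies reconstructed from printed proportions with the split rule",
    data = ht_data(conds, 5,
                   cp_culprit = c(21, 19),
                   cp_filler  = c(7, 0),
                   cp_reject  = c(0, 4),
                   ca_suspect = c(3, 2),
                   ca_filler  = c(14, 7),
                   ca_reject  = c(5, 18),
                   reconstructed_ca = TRUE),
    comparison = ht_spec(conds, bind = list(
      dP_one_sided = "one_sided.dP", dP_two_sided = "two_sided.dP",
      g_one_sided = "one_sided.g", g_two_sided = "two_sided.g",
      b = paste0(conds, ".b"), dA = paste0(conds, ".dA")),
      description = "pre-lineup-instruction comparison standard (dP, g per instruction; b, dA shared)"),
    tested = list(g = c("g_one_sided", "g_two_sided"),
                  dP = c("dP_one_sided", "dP_two_sided")),
    published = list(
      g_squared = 3.35, df = 2, p = 0.187,
      delta_g_squared = c(g = 20.95, dP = 0.88),
      estimates = c(dP_one_sided = .68, b = .01, dA = .21, dP_two_sided = .81),
      ses       = c(dP_one_sided = .11, b = .06, dA = .30, dP_two_sided = .09)))

  # Lampinen et al. (Exp. 1, Table 1): one-sided vs two two-sided instruction
  # variants; equal assignment assumed; innocent-suspect counts reconstructed.
  conds <- c("one_sided", "standard_two_sided", "detailed_two_sided")
  reg$lampinen <- list(
    name = "lampinen",
    provenance = "Lampinen et al., Experiment 1, Table 1; frequencies reconstructed from printed proportions assuming equal assignment, with the split rule",
    data = ht_data(conds, 6,
                   cp_culprit = c(68, 60, 56),
                   cp_filler  = c(88, 85, 76),
                   cp_reject  = c(10, 22, 32),
                   ca_suspect = c(25, 19, 20),
                   ca_filler  = c(126, 97, 100),
                   ca_reject  = c(15, 50, 46),
                   reconstructed_ca = TRUE),
    comparison = ht_spec(conds, bind = list(
      dP_one_sided = "one_sided.dP",
      dP_two_sided = c("standard_two_sided.dP", "detailed_two_sided.dP"),
      g_one_sided = "one_sided.g",
      g_two_sided = c("standard_two_sided.g", "detailed_two_sided.g"),
      b = paste0(conds, ".b"), dA = paste0(conds, ".dA")),
      description = "pre-lineup-instruction comparison standard (two-sided variants combined; b, dA shared)"),
    tested = list(g = c("g_one_sided", "g_two_sided"),
                  dP = c("dP_one_sided", "dP_two_sided")),
    published = list(
      g_squared = 4.86, df = 6, p = 0.562,
      delta_g_squared = c(g = 36.39, dP = 0.69),
      estimates = c(dP_one_sided = .30, b = .00, dA = .04, dP_two_sided = .26),
      ses       = c(dP_one_sided = .05, b = .02, dA = .03, dP_two_sided = .03)))

  # Karageorge & Zajac (2011, Table 1): wildcard vs control with children;
  # designated innocent suspect; choosing the wildcard silhouette counts as a
  # lineup rejection.
  conds <- c("wildcard", "control")
  reg$karageorge_zajac <- list(
    name = "karageorge_zajac",
    provenance = "Karageorge & Zajac, Table 1, collapsed over delay and age; wildcard choices scored as lineup rejections",
    data = ht_data(conds, 6,
                   cp_culprit = c(31, 36),
                   cp_filler  = c(10, 8),
                   cp_reject  = c(7, 9),
                   ca_suspect = c(2, 25),
                   ca_filler  = c(6, 13),
                   ca_reject  = c(41, 16),
                   reconstructed_ca = FALSE),
    comparison = ht_spec(conds, bind = list(
      dP_wildcard = "wildcard.dP", dP_control = "control.dP",
      g_wildcard = "wildcard.g", g_control = "control.g",
      dA_wildcard = "wildcard.dA", dA_control = "control.dA",
      b = paste0(conds, ".b")),
      description = "wildcard comparison standard (dP, g, dA per condition; b shared)"),
    tested = list(dA = c("dA_wildcard", "dA_control"),
                  dP = c("dP_wildcard", "dP_control"),
                  g = c("g_wildcard", "g_control")),
    published = list(
      g_squared = 3.58, df = 1, p = 0.059,
      delta_g_squared = c(dA = 29.79, dP = 0.21, g = 1.44),
      estimates = c(dP_wildcard = .37, b = .37, g_wildcard = .67,
                    dP_control = .45, g_control = .51),
      ses       = c(dP_wildcard = .15, b = .09, g_wildcard = .10,
                    dP_control = .14, g_control = .11)))

  # Wilcock & Bull (Exp. 2, Table 3): culprit-absent practice lineup vs
  # control with older adults; innocent-suspect counts reconstructed.
  conds <- c("practice", "control")
  reg$wilcock_bull <- list(
    name = "wilcock_bull",
    provenance = "Wilcock & Bull, Experiment 2, Table 3; innocent-suspect counts reconstructed with the split rule",
    data = ht_data(conds, 6,
                   cp_culprit = c(24, 20),
                   cp_filler  = c(21, 20),
                   cp_reject  = c(5, 10),
                   ca_suspect = c(2, 7),
                   ca_filler  = c(12, 36),
                   ca_reject  = c(36, 7),
                   reconstructed_ca = TRUE),
    comparison = ht_spec(conds, bind = list(
      dP_practice = "practice.dP", dP_control = "control.dP",
      g_practice = "practice.g", g_control = "control.g",
      dA_practice = "practice.dA", dA_control = "control.dA",
      b = paste0(conds, ".b")),
      description = "practice-lineup comparison standard (dP, g, dA per condition; b shared)"),
    tested = list(dA = c("dA_practice", "dA_control"),
                  dP = c("dP_practice", "dP_control"),
                  g = c("g_practice", "g_control")),
    published = list(
      g_squared = 2.92, df = 1, p = 0.087,
      delta_g_squared = c(dA = 23.42, dP = 0.58, g = 0.18),
      estimates = c(dP_practice = .40, b = .00, g_practice = .83,
                    dP_control = .31, g_control = .80),
      ses       = c(dP_practice = .09, b = .05, g_practice = .07,
                    dP_control = .09, g_control = .06)))

  reg
}

#' Names of the bundled study fixtures
#' @return Character vector of registry names accepted by [lineup_fixture()].
#' @export
fixture_names <- function() names(fixture_registry())

#' Load a bundled study fixture
#'
#' Each fixture packages one published lineup experiment: the per-condition
#' frequency tables, the comparison-standard model specification, and one
#' restricted (nested) specification per reported likelihood-ratio test,
#' together with the published goodness-of-fit statistics, test statistics
#' and 2-dp parameter estimates for side-by-side comparison.
#'
#' @param name one of [fixture_names()].
#' @return A list of class `ht_fixture` with components `name`, `data`,
#'   `comparison`, `restrictions` (named by the parameter whose equality is
#'   tested), `published` and `provenance`.
#' @examples
#' fx <- lineup_fixture("karageorge_zajac")
#' fx$data
#' @export
lineup_fixture <- function(name) {
  reg <- fixture_registry()
  if (length(name) != 1L || !name %in% names(reg))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(names(reg), collapse = ", "), call. = FALSE)
  fx <- reg[[name]]
  fx$restrictions <- lapply(stats::setNames(names(fx$tested), names(fx$tested)),
                            function(par)
    merge_parameters(fx$comparison, fx$tested[[par]], new_name = par,
                     description = sprintf("%s restricted: %s equal",
                                           fx$name,
                                           paste(fx$tested[[par]], collapse = " = "))))
  class(fx) <- "ht_fixture"
  fx
}

#' @export
print.ht_fixture <- function(x, ...) {
  cat(sprintf("Fixture '%s'\n  %s\n", x$name, x$provenance))
  cat(sprintf("  %d condition(s), lineup size %s; restrictions: %s\n",
              nrow(x$data), paste(unique(x$data$lineup_size), collapse = "/"),
              paste(names(x$restrictions), collapse = ", ")))
  invisible(x)
}

#' Export a fixture to the standard delimited data and JSON spec formats
#'
#' @param name one of [fixture_names()].
#' @param dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
export_fixture <- function(name, dir) {
  fx <- lineup_fixture(name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, paste0(name, "_data.csv"))
  write_lineup_data(fx$data, files)
  f <- file.path(dir, paste0(name, "_comparison.json"))
  write_spec(fx$comparison, f)
  files <- c(files, f)
  for (par in names(fx$restrictions)) {
    f <- file.path(dir, paste0(name, "_restricted_", par, ".json"))
    write_spec(fx$restrictions[[par]], f)
    files <- c(files, f)
  }
  invisible(files)
}
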