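#' Model specification: parameter bindings across conditions
#'
#' A model specification binds every parameter slot — one of `dP`, `b`, `g`,
#' `dA` for each condition — either to a named free parameter (slots sharing
#' a name are constrained to be equal) or to a fixed constant.  Equality and
#' fixing restrictions are how hypotheses about the latent processes are
#' expressed and tested.
#'
#' Slots are written `"<condition>.<parameter>"`, e.g. `"control.dA"`.
#'
#' @param conditions character vector of condition labels, in display order.
#' @param bind named list: free-parameter name -> character vector of slots
#'   bound to it.
#' @param fix named numeric: slot -> constant in `[0, 1]`.
#' @param description free-text description of the hypothesis.
#' @return An object of class `ht_spec`.
#' @examples
#' ht_spec(c("fair", "unfair"),
#'         bind = list(dP = c("fair.dP", "unfair.dP"),
#'                     g = c("fair.g", "unfair.g"),
#'                     b_fair = "fair.b", b_unfair = "unfair.b"),
#'         fix = c(fair.dA = 0, unfair.dA = 0))
#' @export
ht_spec <- function(conditions, bind = list(), fix = NULL, description = "") {
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions))
    stop("condition labels must be unique", call. = FALSE)
  slots <- as.vector(outer(conditions, ht_parameters, paste, sep = "."))
  bound <- unlist(bind, use.names = FALSE)
  fixed <- names(fix)
  all_bound <- c(bound, fixed)
  if (anyDuplicated(all_bound))
    stop("slot(s) bound more than once: ",
         paste(unique(all_bound[duplicated(all_bound)]), collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(all_bound, slots)
  if (length(unknown))
    stop("unknown slot(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  unbound <- setdiff(slots, all_bound)
  if (length(unbound))
    stop("unbound slot(s): ", paste(unbound, collapse = ", "), call. = FALSE)
  if (length(fix) && (any(fix < 0) || any(fix > 1)))
    stop("fixed constants must lie in [0, 1]", call. = FALSE)
  if (length(bind) && (is.null(names(bind)) || !all(nzchar(names(bind)))))
    stop("every free parameter must be named", call. = FALSE)
  structure(
    list(conditions = conditions,
         bind = lapply(bind, as.character),
         fix = fix,
         description = description),
    class = "ht_spec")
}

#' Saturated specification
#'
#' One free parameter per slot: as many free parameters as independent data
#' categories, hence zero degrees of freedom.
#'
#' @param data an [ht_data] object (or character vector of condition labels).
#' @param sep separator between parameter and condition in the generated
#'   free-parameter names.
#' @return An `ht_spec`.
#' @export
saturated_spec <- function(data, sep = "_") {
  conditions <- if (inherits(data, "ht_data")) data$condition else as.character(data)
  bind <- list()
  for (cond in conditions)
    for (par in ht_parameters)
      bind[[paste(par, cond, sep = sep)]] <- paste(cond, par, sep = ".")
  ht_spec(conditions, bind, description = "saturated (per-condition) model")
}

# slot -> binding lookup: list with entries list(free = name) or list(value = x)
slot_bindings <- function(spec) {
  out <- list()
  for (nm in names(spec$bind))
    for (slot in spec$bind[[nm]]) out[[slot]] <- list(free = nm)
  for (slot in names(spec$fix)) out[[slot]] <- list(value = unname(spec$fix[[slot]]))
  out
}

#' Derive a nested specification by merging free parameters
#'
#' Replaces the named free parameters by a single shared parameter — the
#' equality restriction used in nested likelihood-ratio tests.
#'
#' @param spec an [ht_spec].
#' @param pars character vector (length >= 2) of free-parameter names to merge.
#' @param new_name name of the merged parameter (default: first of `pars`).
#' @param description optional description of the restricted model.
#' @return The restricted `ht_spec`.
#' @export
merge_parameters <- function(spec, pars, new_name = pars[1], description = NULL) {
  stopifnot(inherits(spec, "ht_spec"))
  if (length(pars) < 2 || !all(pars %in% names(spec$bind)))
    stop("pars must name at least two free parameters of the specification",
         call. = FALSE)
  bind <- spec$bind
  merged <- unlist(bind[pars], use.names = FALSE)
  bind[pars] <- NULL
  if (new_name %in% names(bind))
    stop("new_name collides with an existing free parameter", call. = FALSE)
  bind[[new_name]] <- merged
  ht_spec(spec$conditions, bind, spec$fix,
          description %||%
            sprintf("%s [restriction: %s equal]",
                    spec$description, paste(pars, collapse = " = ")))
}

#' Derive a nested specification by fixing free parameters
#'
#' Pins free parameters to constants, e.g. `dA = 0` turns the
#' two-high-threshold model into its one-high-threshold variant.
#'
#' @param spec an [ht_spec].
#' @param values named numeric: free-parameter name -> constant in `[0, 1]`.
#' @param description optional description of the restricted model.
#' @return The restricted `ht_spec`.
#' @export
fix_parameters <- function(spec, values, description = NULL) {
  stopifnot(inherits(spec, "ht_spec"))
  if (!all(names(values) %in% names(spec$bind)))
    stop("values must name free parameters of the specification", call. = FALSE)
  bind <- spec$bind
  fix <- spec$fix
  for (nm in names(values)) {
    add <- rep(unname(values[[nm]]), length(bind[[nm]]))
    names(add) <- bind[[nm]]
    fix <- c(fix, add)
    bind[[nm]] <- NULL
  }
  ht_spec(spec$conditions, bind, fix,
          description %||%
            sprintf("%s [restriction: %s fixed]",
                    spec$description, paste(names(values), collapse = ", ")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of free parameters of a specification
#' @param spec an [ht_spec].
#' @return Integer count of distinct free parameters.
#' @export
free_parameter_count <- function(spec) {
  stopifnot(inherits(spec, "ht_spec"))
  length(spec$bind)
}

#' Number of independent data categories
#'
#' Each multinomial tree with a positive total contributes its number of
#' categories minus one (two, for the three-category lineup trees).  With
#' `strict = TRUE`, culprit-absent trees whose innocent-suspect count was
#' reconstructed from the total false identifications contribute one fewer
#' category, reflecting that their suspect and filler cells carry a single
#' independent observation.
#'
#' @param data an [ht_data] object.
#' @param strict apply the reconstructed-tree correction?
#' @return Integer count.
#' @export
independent_category_count <- function(data, strict = FALSE) {
  stopifnot(inherits(data, "ht_data"))
  cp_tot <- rowSums(as.matrix(data[c("cp_culprit", "cp_filler", "cp_reject")]))
  ca_tot <- rowSums(as.matrix(data[c("ca_suspect", "ca_filler", "ca_reject")]))
  n <- sum(2L * (cp_tot > 0)) + sum(2L * (ca_tot > 0))
  if (strict)
    n <- n - sum(data$reconstructed_ca & ca_tot > 0)
  as.integer(n)
}

#' Degrees of freedom of a model
#'
#' Independent data categories minus free parameters; zero for the saturated
#' model.
#'
#' @param spec an [ht_spec].
#' @param data an [ht_data] object over the same conditions.
#' @param strict see [independent_category_count()].
#' @return Integer degrees of freedom.
#' @export
degrees_of_freedom <- function(spec, data, strict = FALSE) {
  check_spec_data(spec, data)
  independent_category_count(data, strict = strict) - free_parameter_count(spec)
}

check_spec_data <- function(spec, data) {
  stopifnot(inherits(spec, "ht_spec"), inherits(data, "ht_data"))
  if (!setequal(spec$conditions, data$condition))
    stop("specification and data refer to different conditions", call. = FALSE)
  invisible(TRUE)
}

#' Structural nesting test for two specifications
#'
#' `restricted` is nested in `general` when its bindings can be obtained from
#' those of `general` by merging free parameters and/or fixing them to
#' constants: every free parameter of the general model must map, slot for
#' slot, onto a single binding of the restricted model, and slots fixed in
#' the general model must be fixed to the same constants in the restricted
#' model.
#'
#' @param restricted,general [ht_spec] objects over the same conditions.
#' @return `TRUE` or `FALSE`.
#' @export
is_nested <- function(restricted, general) {
  stopifnot(inherits(restricted, "ht_spec"), inherits(general, "ht_spec"))
  if (!setequal(restricted$conditions, general$conditions)) return(FALSE)
  sb_r <- slot_bindings(restricted)
  sb_g <- slot_bindings(general)
  # fixed-in-general slots stay identically fixed
  for (slot in names(general$fix)) {
    br <- sb_r[[slot]]
    if (is.null(br$value) || br$value != general$fix[[slot]]) return(FALSE)
  }
  # each general free parameter maps onto exactly one restricted binding
  for (nm in names(general$bind)) {
    images <- lapply(general$bind[[nm]], function(slot) sb_r[[slot]])
    if (length(unique(vapply(images, binding_key, character(1)))) != 1L)
      return(FALSE)
  }
  TRUE
}

binding_key <- function(b) {
  if (!is.null(b$free)) paste0("free:", b$free)
  else paste0("fixed:", format(b$value, digits = 17))
}

#' @export
print.ht_spec <- function(x, ...) {
  cat("2-HT model specification")
  if (nzchar(x$description)) cat(": ", x$description, sep = "")
  cat("\n  conditions: ", paste(x$conditions, collapse = ", "), "\n", sep = "")
  cat(sprintf("  free parameters (%d):\n", length(x$bind)))
  for (nm in names(x$bind))
    cat(sprintf("    %-12s <- %s\n", nm, paste(x$bind[[nm]], collapse = ", ")))
  if (length(x$fix)) {
    cat("  fixed:\n")
    for (nm in names(x$fix))
      cat(sprintf("    %-12s = %g\n", nm, x$fix[[nm]]))
  }
  invisible(x)
}

#' Write a model specification to JSON
#' @param spec an [ht_spec].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "ht_spec"))
  obj <- list(conditions = spec$conditions,
              free_parameters = names(spec$bind),
              bind = spec$bind,
              fix = as.list(spec$fix),
              description = spec$description)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model specification from JSON
#' @param path file path to a JSON file produced by [write_spec()] (keys
#'   `conditions`, `bind`, `fix`, optionally `description`).
#' @return An `ht_spec`.
#' @export
read_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("conditions", "bind"))
    if (is.null(obj[[key]]))
      stop(sprintf("malformed model-spec file '%s': missing key '%s'", path, key),
           call. = FALSE)
  fix <- unlist(obj$fix)
  ht_spec(obj$conditions, as.list(obj$bind), fix, obj$description %||% "")
}
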