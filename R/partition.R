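#' Specify a grouped k-fold partition
#'
#' @param k Number of folds (>= 2).
#' @param level Grouping level: all patches of a unit at this level share a
#'   fold. "patient" prevents any same-patient leakage, "core" prevents
#'   same-core leakage only, "patch" is plain ungrouped k-fold.
#' @param seed Shuffle seed.
#' @return An object of class `fold_spec`.
#' @export
fold_spec <- function(k, level = c("patient", "core", "patch"), seed = 1L) {
  level <- match.arg(level)
  stopifnot(length(k) == 1, length(seed) == 1)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  structure(list(k = as.integer(k), level = level, seed = as.integer(seed)),
            class = "fold_spec")
}

#' Build a grouped k-fold assignment
#'
#' Units at the chosen level (patients, cores, or patches) are shuffled
#' deterministically by the fold specification's seed and dealt round-robin
#' into `k` folds,
#' so fold sizes differ by at most one unit: with `n = qk + r` units the
#' first `r` folds hold `q + 1` units, the rest `q`. Every patch inherits the
#' fold of its unit, so each patch is tested exactly once across the `k`
#' train/test splits. No class stratification is applied by default (plain
#' random shuffling); `stratify = TRUE` (patch level only) deals each class
#' separately.
#'
#' @param cohort A `patch_cohort`.
#' @param spec A [fold_spec()].
#' @param stratify Stratify patch-level folds by true class (off by default).
#' @return An object of class `fold_assignment`: list with `unit_to_fold`
#'   (named integer vector, folds 0-based), `patch_fold` (named by patch id),
#'   `level`, `k`, `seed`.
#' @export
make_folds <- function(cohort, spec, stratify = FALSE) {
  stopifnot(inherits(cohort, "patch_cohort"), inherits(spec, "fold_spec"))
  units <- switch(spec$level,
                  patient = cohort$patients$patient_id,
                  core = cohort$cores$core_id,
                  patch = cohort$patches$patch_id)
  n <- length(units)
  if (spec$k > n)
    stop(sprintf("k = %d exceeds the %d units at level '%s'",
                 spec$k, n, spec$level), call. = FALSE)
  set.seed(spec$seed)
  if (stratify && spec$level == "patch") {
    cls <- cohort$patches$true_class
    shuffled <- units[order(.severity(cls), sample.int(n))]
  } else {
    shuffled <- units[sample.int(n)]
  }
  unit_to_fold <- stats::setNames(rep_len(0:(spec$k - 1L), n), shuffled)
  unit_to_fold <- unit_to_fold[units] # original unit order, same mapping

  patch_unit <- switch(spec$level,
                       patient = cohort$patches$patient_id,
                       core = cohort$patches$core_id,
                       patch = cohort$patches$patch_id)
  patch_fold <- stats::setNames(as.integer(unit_to_fold[patch_unit]),
                                cohort$patches$patch_id)
  structure(list(unit_to_fold = unit_to_fold, patch_fold = patch_fold,
                 level = spec$level, k = spec$k, seed = spec$seed),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  sizes <- table(x$unit_to_fold)
  cat(sprintf("%d-fold assignment at %s level (%d units, seed %d)\n",
              x$k, x$level, length(x$unit_to_fold), x$seed))
  cat("Unit counts per fold:", paste(range(sizes), collapse = "-"), "\n")
  invisible(x)
}

#' Audit a fold assignment for group leakage
#'
#' Counts, per fold, the audit-level units (patients or cores) whose patches
#' appear both in that fold and in at least one other fold. A grouped
#' assignment at or above the audit level is clean (all zeros); patch-level
#' assignments typically leak nearly every multi-patch unit.
#'
#' @param assignment A `fold_assignment`.
#' @param cohort The `patch_cohort` it was built from.
#' @param audit_level "patient" or "core".
#' @return Object of class `leakage_report`: data frame (`fold`,
#'   `leaked_units`) with attributes `total_leaked` (units spanning more than
#'   one fold) and `audit_level`.
#' @export
audit_leakage <- function(assignment, cohort, audit_level = c("patient", "core")) {
  stopifnot(inherits(assignment, "fold_assignment"),
            inherits(cohort, "patch_cohort"))
  audit_level <- match.arg(audit_level)
  unit <- switch(audit_level,
                 patient = cohort$patches$patient_id,
                 core = cohort$patches$core_id)
  fold <- assignment$patch_fold[cohort$patches$patch_id]
  spans <- tapply(fold, unit, function(f) length(unique(f)))
  leaked <- names(spans)[spans > 1]
  k <- assignment$k
  if (length(leaked)) {
    sel <- unit %in% leaked
    pres <- unique(data.frame(unit = unit[sel], fold = fold[sel]))
    per_fold <- as.integer(table(factor(pres$fold, levels = 0:(k - 1L))))
  } else {
    per_fold <- integer(k)
  }
  structure(data.frame(fold = 0:(k - 1L), leaked_units = per_fold),
            total_leaked = length(leaked),
            audit_level = audit_level,
            class = c("leakage_report", "data.frame"))
}

#' @export
print.leakage_report <- function(x, ...) {
  cat(sprintf("Leakage audit at %s level: %d unit(s) span more than one fold\n",
              attr(x, "audit_level"), attr(x, "total_leaked")))
  print.data.frame(x)
  invisible(x)
}
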