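#' Write a full report bundle for a comparison study
#'
#' Emits the study's tables as CSV — `cv_metrics.csv` (per scheme and task:
#' mean (SD) accuracy/sensitivity/specificity), one `mcnemar_<task>.csv` per
#' task (lower-triangular p-value matrix, values below 0.001 formatted
#' `<.001`), optionally `agreement.csv` (the cross-expert kappa matrix) —
#' plus `manifest.json` (package/R versions, classifier, excluded-patch
#' counts, seeds and config when supplied) and a plain-text `summary.txt`.
#' All inputs are validated before anything is written, and no timestamps
#' are embedded, so re-running with identical inputs reproduces the bundle
#' byte for byte.
#'
#' @param comparison A `cv_comparison`.
#' @param dir Output directory (created if needed).
#' @param agreement Optional `agreement_matrix`.
#' @param manifest Optional named list merged into the JSON manifest
#'   (e.g. the `sim_config` and seeds used).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(comparison, dir, agreement = NULL, manifest = list()) {
  if (!inherits(comparison, "cv_comparison"))
    stop("comparison must be a cv_comparison object", call. = FALSE)
  if (is.null(comparison$metrics) || nrow(comparison$metrics) == 0 ||
      length(comparison$predictions) == 0)
    stop("empty comparison: nothing to report", call. = FALSE)
  if (!is.null(agreement) && !inherits(agreement, "agreement_matrix"))
    stop("agreement must be an agreement_matrix", call. = FALSE)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  f <- file.path(dir, "cv_metrics.csv")
  utils::write.csv(comparison$metrics, f, row.names = FALSE)
  files <- c(files, f)

  for (tk in comparison$tasks) {
    f <- file.path(dir, sprintf("mcnemar_%s.csv", tk))
    utils::write.csv(as.data.frame(format_p_matrix(comparison$mcnemar[[tk]]$p)),
                     f, row.names = TRUE)
    files <- c(files, f)
  }

  if (!is.null(agreement)) {
    f <- file.path(dir, "agreement.csv")
    df <- data.frame(trainer = rownames(agreement),
                     round(unclass(agreement), 4), check.names = FALSE)
    utils::write.csv(df, f, row.names = FALSE)
    files <- c(files, f)
  }

  excl <- vapply(comparison$predictions, function(p)
    as.integer(attr(p, "n_excluded")), integer(1))
  man <- c(list(package = "patchcv",
                package_version = as.character(utils::packageVersion("patchcv")),
                r_version = R.version.string,
                classifier = comparison$classifier,
                tasks = comparison$tasks,
                methods = names(comparison$predictions),
                n_excluded_patches = as.list(excl)),
           manifest)
  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)

  f <- file.path(dir, "summary.txt")
  txt <- c(utils::capture.output(print(comparison)),
           if (!is.null(agreement)) c("", utils::capture.output(print(agreement))))
  writeLines(txt, f)
  files <- c(files, f)

  invisible(files)
}
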