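#' Write a cohort to disk
#'
#' Writes `patches.csv` (patch_id, core_id, patient_id, true_class, feature
#' columns) and `config.json`; with `write_images = TRUE` (image-mode cohorts
#' only, requires the \pkg{png} package) one `<patch_id>.png` per patch.
#'
#' @param cohort A `patch_cohort`.
#' @param dir Output directory (created if needed).
#' @param write_images Also write per-patch PNGs.
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir, write_images = FALSE) {
  stopifnot(inherits(cohort, "patch_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$patches, file.path(dir, "patches.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (write_images) {
    if (is.null(cohort$images))
      stop("cohort has no images (image_mode was off)", call. = FALSE)
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNGs requires the 'png' package", call. = FALSE)
    for (pid in names(cohort$images))
      png::writePNG(cohort$images[[pid]], file.path(dir, paste0(pid, ".png")))
  }
  invisible(dir)
}

#' Read a patch label/prediction table from CSV
#'
#' Accepts externally supplied tables with at least `patch_id` plus a label
#' column (`pred`, `consensus`, `label`, or `true_class` — the first found is
#' used). Empty fields become `NA` (missing).
#'
#' @param path CSV path.
#' @return Data frame with `patch_id` and `pred` columns (plus `fold` if
#'   present in the file).
#' @export
read_prediction_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!"patch_id" %in% names(df))
    stop("CSV must contain a patch_id column", call. = FALSE)
  lab_col <- intersect(c("pred", "consensus", "label", "true_class"), names(df))
  if (!length(lab_col))
    stop("CSV must contain a label column (pred/consensus/label/true_class)",
         call. = FALSE)
  out <- data.frame(patch_id = as.character(df$patch_id),
                    pred = as.character(df[[lab_col[1]]]),
                    stringsAsFactors = FALSE)
  .assert_classes(out$pred, "CSV labels")
  if ("fold" %in% names(df)) out$fold <- as.integer(df$fold)
  out
}

#' Write an annotation matrix to CSV
#'
#' One row per patch, one column per annotator; missing labels are written
#' as empty fields.
#'
#' @param annotations An `annotation_matrix`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_matrix"))
  df <- data.frame(patch_id = rownames(annotations$labels),
                   annotations$labels, stringsAsFactors = FALSE,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an annotation matrix from CSV
#'
#' Inverse of [write_annotations()]: `patch_id` column plus one column per
#' annotator, empty fields meaning missing.
#'
#' @param path CSV path.
#' @return An `annotation_matrix`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  if (!"patch_id" %in% names(df))
    stop("CSV must contain a patch_id column", call. = FALSE)
  ids <- setdiff(names(df), "patch_id")
  lab <- as.matrix(df[, ids, drop = FALSE])
  storage.mode(lab) <- "character"
  rownames(lab) <- df$patch_id
  .assert_classes(as.vector(lab), "annotation labels")
  structure(list(labels = lab, annotators = ids, profiles = NULL),
            class = "annotation_matrix")
}

#' Write a fold assignment to CSV
#'
#' Two files: `<stem>_units.csv` (unit_id, level, fold) and
#' `<stem>_patches.csv` (patch_id, fold).
#'
#' @param assignment A `fold_assignment`.
#' @param stem Path stem (without extension).
#' @return Invisibly, the two paths.
#' @export
write_folds <- function(assignment, stem) {
  stopifnot(inherits(assignment, "fold_assignment"))
  p1 <- paste0(stem, "_units.csv")
  p2 <- paste0(stem, "_patches.csv")
  utils::write.csv(data.frame(unit_id = names(assignment$unit_to_fold),
                              level = assignment$level,
                              fold = as.integer(assignment$unit_to_fold)),
                   p1, row.names = FALSE)
  utils::write.csv(data.frame(patch_id = names(assignment$patch_fold),
                              fold = as.integer(assignment$patch_fold)),
                   p2, row.names = FALSE)
  invisible(c(p1, p2))
}
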