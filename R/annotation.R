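#' Define an annotator profile
#'
#' An annotator is characterised by a 4x4 row-stochastic confusion matrix
#' (row = true class, column = assigned class) and a core coverage fraction:
#' the annotator labels all patches of a covered core and none of an
#' uncovered one, emulating pathologists who graded only a subset of the
#' cores.
#'
#' @param id Annotator identifier.
#' @param confusion 4x4 row-stochastic matrix over `gleason_classes()`.
#' @param coverage Fraction of cores annotated, in `[0, 1]`.
#' @return An object of class `annotator_profile`.
#' @seealso [make_confusion()], [default_annotator_profiles()]
#' @export
annotator_profile <- function(id, confusion, coverage = 1) {
  stopifnot(length(id) == 1, length(coverage) == 1)
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(4, 4)) || any(confusion < 0) ||
      any(abs(rowSums(confusion) - 1) > 1e-12))
    stop("confusion must be a 4x4 row-stochastic matrix", call. = FALSE)
  if (coverage < 0 || coverage > 1)
    stop("coverage must be in [0, 1]", call. = FALSE)
  dimnames(confusion) <- list(.CLASSES, .CLASSES)
  structure(list(id = as.character(id), confusion = confusion,
                 coverage = as.numeric(coverage)),
            class = "annotator_profile")
}

#' Build a tri-diagonal grading confusion matrix
#'
#' Constructs a row-stochastic confusion matrix for an annotator with overall
#' per-class accuracy `accuracy` whose errors go to the adjacent grade.
#' `bias` controls the systematic direction: positive values over-grade
#' (errors shift toward more severe classes), negative under-grade. At the
#' severity boundaries (benign cannot be under-called, grade 5 not
#' over-called) the unavailable error mass folds back onto the diagonal.
#' Systematic threshold differences of exactly this kind are the dominant
#' source of interobserver variability in Gleason grading.
#'
#' @param accuracy Diagonal probability before boundary fold-back, in (0, 1].
#' @param bias Grade-shift tendency in `[-1, 1]`; 0 splits errors evenly.
#' @return 4x4 row-stochastic matrix.
#' @export
#' @examples
#' make_confusion(0.8, bias = 0.5) # tends to over-grade
make_confusion <- function(accuracy, bias = 0) {
  stopifnot(accuracy > 0, accuracy <= 1, bias >= -1, bias <= 1)
  C <- matrix(0, 4, 4, dimnames = list(.CLASSES, .CLASSES))
  for (t in 1:4) {
    up <- if (t < 4) (1 - accuracy) * (1 + bias) / 2 else 0
    down <- if (t > 1) (1 - accuracy) * (1 - bias) / 2 else 0
    C[t, t] <- 1 - up - down
    if (t < 4) C[t, t + 1] <- up
    if (t > 1) C[t, t - 1] <- down
  }
  C
}

#' Default panel of six simulated annotators
#'
#' Six heterogeneous profiles emulating a panel of pathologists: accuracies
#' between 0.55 and 0.80 with distinct systematic grading tendencies
#' (under- and over-callers), four annotators covering all cores and two
#' partial annotators covering fractions 191/333 and 92/333 of the cores.
#'
#' @return List of six [annotator_profile()] objects.
#' @export
default_annotator_profiles <- function() {
  list(
    annotator_profile("path1", make_confusion(0.55, -0.6)),
    annotator_profile("path2", make_confusion(0.70, +0.3)),
    annotator_profile("path3", make_confusion(0.80, 0.0)),
    annotator_profile("path4", make_confusion(0.78, +0.1)),
    annotator_profile("path5", make_confusion(0.75, -0.2), coverage = 191 / 333),
    annotator_profile("path6", make_confusion(0.65, +0.4), coverage = 92 / 333)
  )
}

#' Simulate multi-annotator patch labels
#'
#' For each annotator, a deterministic (seed-derived) subset of
#' `round(coverage * n_cores)` cores is selected; every patch of a covered
#' core receives a label drawn from the confusion-matrix row of the patch's
#' true class, independently across patches. Patches of uncovered cores are
#' missing (`NA`) for that annotator — coverage is decided per core, never
#' per patch.
#'
#' @param cohort A `patch_cohort`.
#' @param profiles List of [annotator_profile()] objects (at least one).
#' @param seed Root seed for coverage selection and label draws.
#' @return An object of class `annotation_matrix`: a list with `labels`
#'   (character matrix patches x annotators, `NA` = missing, rownames =
#'   patch ids) and `annotators` (ids).
#' @export
simulate_annotations <- function(cohort, profiles = default_annotator_profiles(),
                                 seed = 1L) {
  stopifnot(inherits(cohort, "patch_cohort"))
  if (length(profiles) < 1) stop("need at least one profile", call. = FALSE)
  ok <- vapply(profiles, inherits, logical(1), "annotator_profile")
  if (!all(ok)) stop("profiles must be annotator_profile objects", call. = FALSE)

  ids <- vapply(profiles, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate annotator ids", call. = FALSE)
  patches <- cohort$patches
  core_ids <- cohort$cores$core_id
  n_cores <- length(core_ids)
  labels <- matrix(NA_character_, nrow(patches), length(profiles),
                   dimnames = list(patches$patch_id, ids))

  for (a in seq_along(profiles)) {
    prof <- profiles[[a]]
    n_cov <- round(prof$coverage * n_cores)
    if (n_cov == 0) next
    set.seed(.child_seed(seed, paste0("coverage:", prof$id)))
    covered <- core_ids[sample.int(n_cores)][seq_len(n_cov)]
    for (cid in covered) {
      rows <- which(patches$core_id == cid)
      set.seed(.child_seed(seed, paste0("labels:", prof$id, ":", cid)))
      sev <- .severity(patches$true_class[rows])
      for (t in 1:4) {
        rt <- rows[sev == t]
        if (length(rt))
          labels[rt, a] <- sample(.CLASSES, length(rt), replace = TRUE,
                                  prob = prof$confusion[t, ])
      }
    }
  }
  structure(list(labels = labels, annotators = ids, profiles = profiles),
            class = "annotation_matrix")
}

#' @export
print.annotation_matrix <- function(x, ...) {
  n_lab <- colSums(!is.na(x$labels))
  cat(sprintf("Annotation matrix: %d patches x %d annotators\n",
              nrow(x$labels), ncol(x$labels)))
  cat("Labeled patches per annotator:\n")
  print(n_lab)
  invisible(x)
}

#' Majority-vote consensus labels
#'
#' Aggregates an annotation matrix into one consensus label per patch: the
#' modal label among non-missing votes. Ties are resolved by `tie_rule`
#' ("severe", the default, picks the most severe tied class — a
#' clinically conservative choice; "lenient" the least severe; "random" a
#' seed-determined draw among the tied classes). Patches with fewer than
#' `min_votes` non-missing votes are flagged undefined (`NA` consensus).
#'
#' @param annotations An `annotation_matrix`.
#' @param tie_rule One of "severe", "lenient", "random".
#' @param min_votes Minimum non-missing votes for a defined consensus.
#' @param seed Seed used only by `tie_rule = "random"`.
#' @return Data frame with `patch_id`, `consensus` (`NA` when undefined),
#'   `n_votes`, `undefined`.
#' @export
majority_vote <- function(annotations, tie_rule = c("severe", "lenient", "random"),
                          min_votes = 1L, seed = 1L) {
  stopifnot(inherits(annotations, "annotation_matrix"))
  tie_rule <- match.arg(tie_rule)
  lab <- annotations$labels
  counts <- vapply(.CLASSES, function(cl) rowSums(lab == cl, na.rm = TRUE),
                   numeric(nrow(lab)))
  if (nrow(lab) == 1L) counts <- matrix(counts, 1L, 4L)
  n_votes <- as.integer(rowSums(counts))
  if (tie_rule == "random") set.seed(seed)
  idx <- switch(tie_rule,
                severe = max.col(counts, ties.method = "last"),
                lenient = max.col(counts, ties.method = "first"),
                random = max.col(counts, ties.method = "random"))
  consensus <- .CLASSES[idx]
  undefined <- n_votes < max(1L, min_votes)
  consensus[undefined] <- NA_character_
  data.frame(patch_id = rownames(lab), consensus = consensus,
             n_votes = n_votes, undefined = undefined,
             stringsAsFactors = FALSE)
}

#' Pairwise inter-annotator agreement
#'
#' Quadratic-weighted Cohen kappa between every pair of annotators, computed
#' on the patches both members of the pair labeled. Cells for pairs with no
#' common patches are `NA`.
#'
#' @param annotations An `annotation_matrix`.
#' @return Symmetric numeric matrix (diagonal 1) of kappa values.
#' @export
pairwise_annotator_agreement <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_matrix"))
  lab <- annotations$labels
  ids <- annotations$annotators
  K <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(K) <- 1
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    common <- !is.na(lab[, i]) & !is.na(lab[, j])
    if (!any(common)) next
    k <- weighted_kappa(lab[common, i], lab[common, j])$kappa
    K[i, j] <- K[j, i] <- k
  }
  K
}
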