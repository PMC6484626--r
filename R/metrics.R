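#' Define a binary evaluation task
#'
#' The two clinical binarizations of the 4-class labels: `"detection"`
#' (benign vs cancer; positive = any of G3/G4/G5; every patch included) and
#' `"grading"` (low- vs high-grade among cancer patches; positive =
#' high-grade G4/G5, negative = G3; patches whose *true* label is benign are
#' excluded). Under grading, a *predicted* benign on a true-cancer patch
#' counts as negative (low-grade): this is the only binary-consistent way to
#' keep every non-benign-truth patch in the task, and it is the package-wide
#' convention — reported in output headers.
#'
#' @param name `"detection"` or `"grading"`.
#' @return An object of class `task_spec` with fields `name`, `positive`,
#'   `excluded`.
#' @export
task_spec <- function(name = c("detection", "grading")) {
  name <- match.arg(name)
  if (name == "detection") {
    structure(list(name = name, positive = c("G3", "G4", "G5"),
                   excluded = character(0)), class = "task_spec")
  } else {
    structure(list(name = name, positive = c("G4", "G5"),
                   excluded = "benign"), class = "task_spec")
  }
}

#' Binarize labels and predictions for a task
#'
#' @param truth,pred Character vectors of 4-class labels, aligned by patch.
#' @param task A [task_spec()] or task name.
#' @return Data frame with logical `truth`, `pred` and the `include` mask
#'   (FALSE for patches excluded by the task definition).
#' @export
binarize <- function(truth, pred, task = task_spec("detection")) {
  if (is.character(task)) task <- task_spec(task)
  stopifnot(inherits(task, "task_spec"), length(truth) == length(pred))
  .assert_classes(truth, "truth")
  .assert_classes(pred, "predictions")
  data.frame(truth = truth %in% task$positive,
             pred = pred %in% task$positive,
             include = !(truth %in% task$excluded))
}

#' Per-fold accuracy, sensitivity and specificity
#'
#' Computes the binary confusion per fold and reports accuracy
#' `(TP+TN)/n`, sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)` as
#' percentages, aggregated as mean (SD) across folds (SD with the `n-1`
#' denominator). A fold in which a rate's denominator is zero (e.g. a small
#' test fold without positives) contributes no value to that rate's mean/SD;
#' this skip policy is recorded in the output. Pooled counts over all folds
#' are returned alongside.
#'
#' @param truth,pred Logical vectors (included patches only), aligned.
#' @param fold Integer fold index per patch.
#' @return An object of class `metrics_summary`.
#' @export
fold_metrics <- function(truth, pred, fold) {
  stopifnot(length(truth) == length(pred), length(truth) == length(fold))
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  folds <- sort(unique(fold))
  per <- data.frame(fold = folds, n = NA_integer_,
                    tp = NA_integer_, fn = NA_integer_,
                    tn = NA_integer_, fp = NA_integer_,
                    accuracy = NA_real_, sensitivity = NA_real_,
                    specificity = NA_real_)
  for (i in seq_along(folds)) {
    s <- fold == folds[i]
    tp <- sum(truth[s] & pred[s]); fn <- sum(truth[s] & !pred[s])
    tn <- sum(!truth[s] & !pred[s]); fp <- sum(!truth[s] & pred[s])
    per$n[i] <- sum(s); per$tp[i] <- tp; per$fn[i] <- fn
    per$tn[i] <- tn; per$fp[i] <- fp
    per$accuracy[i] <- 100 * (tp + tn) / sum(s)
    per$sensitivity[i] <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    per$specificity[i] <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  }
  msd <- function(x) c(mean = mean(x, na.rm = TRUE),
                       sd = if (sum(!is.na(x)) > 1) stats::sd(x, na.rm = TRUE) else 0)
  structure(list(
    per_fold = per,
    accuracy = msd(per$accuracy),
    sensitivity = msd(per$sensitivity),
    specificity = msd(per$specificity),
    pooled = c(tp = sum(per$tp), fn = sum(per$fn),
               tn = sum(per$tn), fp = sum(per$fp))
  ), class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, digits = 1, ...) {
  f <- function(v) sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
                           v["mean"], v["sd"])
  cat(sprintf("Across %d folds, mean (SD), %%:\n", nrow(x$per_fold)))
  cat("  Accuracy:   ", f(x$accuracy), "\n")
  cat("  Sensitivity:", f(x$sensitivity), "\n")
  cat("  Specificity:", f(x$specificity), "\n")
  invisible(x)
}

#' Quadratic-weighted Cohen kappa
#'
#' Chance-corrected agreement between two ordinal label vectors over the
#' severity-ordered classes, with disagreement weights
#' `w_ij = (i - j)^2 / (C - 1)^2` so that a benign-vs-G5 disagreement is
#' penalised far more than G4-vs-G5:
#' \deqn{\kappa = 1 - \frac{\sum_{ij} w_{ij} O_{ij}}{\sum_{ij} w_{ij} E_{ij}},}
#' where `O` is the observed joint proportion table and
#' `E_ij = row_i * col_j` its independence expectation. Pairs where either
#' side is missing (`NA`) are dropped before tabulation.
#'
#' @param labels_a,labels_b Character vectors over `classes`.
#' @param classes Ordered class set (defaults to `gleason_classes()`).
#' @return Object of class `kappa_result`: `kappa`, `observed_disagreement`,
#'   `expected_disagreement`, `n` (usable pairs), `C`, `weights`.
#' @export
weighted_kappa <- function(labels_a, labels_b, classes = gleason_classes()) {
  stopifnot(length(labels_a) == length(labels_b))
  keep <- !is.na(labels_a) & !is.na(labels_b)
  a <- labels_a[keep]; b <- labels_b[keep]
  n <- length(a)
  if (n == 0) stop("no usable (non-missing) label pairs", call. = FALSE)
  bad <- !(a %in% classes) | !(b %in% classes)
  if (any(bad)) stop("labels outside the declared class set", call. = FALSE)

  C <- length(classes)
  O <- table(factor(a, classes), factor(b, classes)) / n
  idx <- seq_len(C)
  w <- outer(idx, idx, function(i, j) (i - j)^2) / (C - 1)^2
  E <- outer(rowSums(O), colSums(O))
  obs <- sum(w * O)
  expd <- sum(w * E)
  if (expd == 0) {
    if (obs > 0)
      stop("degenerate marginals: zero expected disagreement with nonzero observed",
           call. = FALSE)
    kappa <- 1 # identical constant vectors: perfect agreement
  } else {
    kappa <- 1 - obs / expd
  }
  structure(list(kappa = kappa, observed_disagreement = obs,
                 expected_disagreement = expd, n = n, C = C, weights = w),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Quadratic-weighted kappa: %.4f (%s agreement), n = %d pairs\n",
              x$kappa, interpret_kappa(x$kappa), x$n))
  invisible(x)
}

#' Verbal interpretation band of a kappa value
#'
#' Maps kappa to the conventional agreement bands: nonpositive values are
#' "accidental"; 0.1-0.2 "slight"; 0.21-0.4 "fair"; 0.41-0.6 "moderate";
#' 0.61-0.8 "substantial"; 0.81-1.0 "near-perfect". The convention leaves
#' (0, 0.1) unnamed; such values are labeled "below slight".
#'
#' @param kappa Scalar in `[-1, 1]`.
#' @return Band label (character).
#' @export
interpret_kappa <- function(kappa) {
  stopifnot(length(kappa) == 1, is.finite(kappa))
  if (kappa < -1 - 1e-9 || kappa > 1 + 1e-9)
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  if (kappa <= 0) "accidental"
  else if (kappa < 0.1) "below slight"
  else if (kappa <= 0.2) "slight"
  else if (kappa <= 0.4) "fair"
  else if (kappa <= 0.6) "moderate"
  else if (kappa <= 0.8) "substantial"
  else "near-perfect"
}
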