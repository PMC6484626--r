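#' Run one grouped cross-validation experiment
#'
#' For each of the `k` folds, fits the classifier on all included patches
#' outside the fold and predicts the held-out patches, so the union of
#' held-out predictions covers every included patch exactly once. Patches
#' with undefined truth (`NA`, e.g. an undefined majority-vote consensus)
#' are excluded up front from both training and testing; the count is
#' recorded on the result. A training split missing one of the classes
#' present in the truth is an error naming the fold.
#'
#' @param cohort A `patch_cohort`.
#' @param truth Named character vector of true classes over the cohort's
#'   patch ids (`NA` = excluded), or a [majority_vote()] data frame.
#' @param spec A [fold_spec()] or a prebuilt `fold_assignment`.
#' @param classifier `"knn"` or `"nearest_centroid"`.
#' @param k_neighbors Neighbourhood size for `"knn"`.
#' @return Object of class `prediction_table`: data frame (`patch_id`,
#'   `fold`, `pred`, `truth`) with attributes `level`, `k`, `classifier`,
#'   `n_excluded`.
#' @export
run_cv_experiment <- function(cohort, truth, spec,
                              classifier = c("knn", "nearest_centroid"),
                              k_neighbors = 1L) {
  stopifnot(inherits(cohort, "patch_cohort"))
  classifier <- match.arg(classifier)
  truth <- .coerce_truth(truth, cohort)
  assignment <- if (inherits(spec, "fold_assignment")) spec
                else make_folds(cohort, spec)

  ids <- cohort$patches$patch_id
  fold <- assignment$patch_fold[ids]
  include <- !is.na(truth[ids])
  if (!any(include)) stop("no patches with defined truth", call. = FALSE)
  X <- cohort_features(cohort)
  y <- truth[ids]
  present <- unique(y[include])

  pred <- rep(NA_character_, length(ids))
  for (f in sort(unique(fold))) {
    tr <- include & fold != f
    te <- include & fold == f
    if (!any(te)) next
    miss <- setdiff(present, unique(y[tr]))
    if (length(miss))
      stop(sprintf("training split for fold %d is missing class(es): %s",
                   f, paste(miss, collapse = ", ")), call. = FALSE)
    model <- fit_patch_classifier(X[tr, , drop = FALSE], y[tr],
                                  kind = classifier, k_neighbors = k_neighbors)
    pred[te] <- predict(model, X[te, , drop = FALSE])
  }
  out <- data.frame(patch_id = ids[include], fold = fold[include],
                    pred = pred[include], truth = y[include],
                    stringsAsFactors = FALSE)
  structure(out, level = assignment$level, k = assignment$k,
            classifier = classifier, n_excluded = sum(!include),
            class = c("prediction_table", "data.frame"))
}

#' @keywords internal
.coerce_truth <- function(truth, cohort) {
  if (is.data.frame(truth)) {
    if (!all(c("patch_id", "consensus") %in% names(truth)))
      stop("truth data frame needs patch_id and consensus columns", call. = FALSE)
    truth <- stats::setNames(truth$consensus, truth$patch_id)
  }
  if (is.null(names(truth)))
    stop("truth must be named by patch id", call. = FALSE)
  miss <- setdiff(cohort$patches$patch_id, names(truth))
  if (length(miss))
    stop(sprintf("truth missing for %d cohort patches", length(miss)),
         call. = FALSE)
  .assert_classes(truth, "truth")
  truth
}

#' Compare cross-validation schemes on one cohort
#'
#' Runs every fold specification on the same cohort and truth, computes
#' per-scheme mean (SD) accuracy/sensitivity/specificity for the requested
#' tasks, and tests every pair of schemes with the McNemar test on their
#' per-patch correctness (all schemes share one patch universe, so the
#' pairing is exact).
#'
#' @param cohort A `patch_cohort`.
#' @param truth Truth as in [run_cv_experiment()].
#' @param specs Named list of at least two [fold_spec()]s; names label the
#'   schemes in all outputs.
#' @param classifier,k_neighbors Passed to [run_cv_experiment()].
#' @param tasks Character vector of task names.
#' @param mcnemar_variant Passed to [mcnemar_test()].
#' @return Object of class `cv_comparison`: list with `metrics` (long data
#'   frame: method, task, mean/SD of the three rates), `mcnemar` (per task: a
#'   lower-triangular p-value matrix and the discordance tables),
#'   `predictions` (per-scheme `prediction_table`s), `tasks`.
#' @export
compare_cv_methods <- function(cohort, truth, specs,
                               classifier = c("knn", "nearest_centroid"),
                               k_neighbors = 1L,
                               tasks = c("detection", "grading"),
                               mcnemar_variant = "auto") {
  classifier <- match.arg(classifier)
  if (length(specs) < 2) stop("need at least two fold specs", call. = FALSE)
  if (is.null(names(specs)) || any(names(specs) == ""))
    names(specs) <- vapply(specs, function(s)
      sprintf("%d-fold leave-%s-out", s$k, paste0(s$level, "s")), character(1))
  truth <- .coerce_truth(truth, cohort)

  preds <- lapply(specs, function(s)
    run_cv_experiment(cohort, truth, s, classifier, k_neighbors))

  metrics <- do.call(rbind, lapply(names(preds), function(m) {
    do.call(rbind, lapply(tasks, function(tk) {
      bz <- binarize(preds[[m]]$truth, preds[[m]]$pred, tk)
      ms <- fold_metrics(bz$truth[bz$include], bz$pred[bz$include],
                         preds[[m]]$fold[bz$include])
      data.frame(method = m, task = tk,
                 accuracy_mean = ms$accuracy["mean"], accuracy_sd = ms$accuracy["sd"],
                 sensitivity_mean = ms$sensitivity["mean"],
                 sensitivity_sd = ms$sensitivity["sd"],
                 specificity_mean = ms$specificity["mean"],
                 specificity_sd = ms$specificity["sd"],
                 row.names = NULL)
    }))
  }))

  nm <- names(preds)
  mcnemar <- lapply(tasks, function(tk) {
    P <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
    tabs <- list()
    for (i in seq_along(nm)) for (j in seq_len(i - 1L)) {
      tab <- build_discordance(preds[[i]], preds[[j]],
                               truth, tk, methods = c(nm[i], nm[j]))
      P[i, j] <- mcnemar_test(tab, mcnemar_variant)$p_value
      tabs[[paste(nm[i], "vs", nm[j])]] <- tab
    }
    list(p = P, tables = tabs)
  })
  names(mcnemar) <- tasks

  structure(list(metrics = metrics, mcnemar = mcnemar,
                 predictions = preds, tasks = tasks, classifier = classifier),
            class = "cv_comparison")
}

#' @export
print.cv_comparison <- function(x, ...) {
  cat(sprintf("Cross-validation comparison (%s classifier)\n", x$classifier))
  cat("\nPer-scheme metrics, mean (SD) % across folds:\n")
  m <- x$metrics
  for (r in seq_len(nrow(m))) {
    cat(sprintf("  %-28s %-10s acc %5.1f (%4.1f)  sens %5.1f (%4.1f)  spec %5.1f (%4.1f)\n",
                m$method[r], m$task[r],
                m$accuracy_mean[r], m$accuracy_sd[r],
                m$sensitivity_mean[r], m$sensitivity_sd[r],
                m$specificity_mean[r], m$specificity_sd[r]))
  }
  tk <- x$tasks[1]
  cat(sprintf("\nPairwise McNemar p-values (%s task, lower triangle):\n", tk))
  print(format_p_matrix(x$mcnemar[[tk]]$p), quote = FALSE)
  invisible(x)
}

#' Format a p-value matrix with the conventional "<.001" display
#' @param p Numeric matrix of p-values.
#' @return Character matrix.
#' @export
format_p_matrix <- function(p) {
  out <- ifelse(is.na(p), "NA",
                ifelse(p < 0.001, "<.001", sprintf("%.3f", p)))
  dimnames(out) <- dimnames(p)
  out
}

#' Cross-expert training study
#'
#' Reproduces the single-expert-vs-majority training design: under one
#' patient-level fold assignment, the classifier is trained once per
#' annotator (on the patches that annotator labeled, outside the held-out
#' fold) and once on the majority-vote consensus, and each trained model's
#' pooled held-out predictions are scored by quadratic-weighted kappa
#' against the labels of every annotator on the held-out patches that
#' annotator labeled. Patches with undefined consensus are excluded from
#' the whole study so all rows share one patch universe. The `overall`
#' column pools the (prediction, evaluator-label) pairs across evaluators
#' before computing kappa (`overall = "pooled"`, default) or averages the
#' per-evaluator cells (`overall = "mean"`); the rule used is recorded on
#' the result.
#'
#' @param cohort A `patch_cohort`.
#' @param annotations An `annotation_matrix` over the cohort.
#' @param spec A patient-level [fold_spec()] (other levels are an error:
#'   the design evaluates generalisation to held-out patients).
#' @param classifier,k_neighbors Passed to [fit_patch_classifier()].
#' @param tie_rule,min_votes Passed to [majority_vote()].
#' @param overall `"pooled"` or `"mean"`.
#' @return Object of class `agreement_matrix`: numeric matrix with one row
#'   per training-label source (each annotator + `"majority"`) and one
#'   column per evaluating annotator + `"overall"`.
#' @export
cross_expert_experiment <- function(cohort, annotations, spec,
                                    classifier = c("knn", "nearest_centroid"),
                                    k_neighbors = 1L,
                                    tie_rule = "severe", min_votes = 1L,
                                    overall = c("pooled", "mean")) {
  stopifnot(inherits(cohort, "patch_cohort"),
            inherits(annotations, "annotation_matrix"))
  classifier <- match.arg(classifier)
  overall <- match.arg(overall)
  if (inherits(spec, "fold_spec") && spec$level != "patient")
    stop("cross-expert experiment requires patient-level folds", call. = FALSE)
  assignment <- if (inherits(spec, "fold_assignment")) spec
                else make_folds(cohort, spec)
  if (assignment$level != "patient")
    stop("cross-expert experiment requires patient-level folds", call. = FALSE)

  cons <- majority_vote(annotations, tie_rule = tie_rule, min_votes = min_votes)
  universe <- cons$patch_id[!cons$undefined]
  if (!length(universe)) stop("no patches with defined consensus", call. = FALSE)
  X <- cohort_features(cohort)[universe, , drop = FALSE]
  fold <- assignment$patch_fold[universe]
  lab <- annotations$labels[universe, , drop = FALSE]
  ids <- annotations$annotators

  trainers <- c(ids, "majority")
  train_labels <- c(lapply(seq_along(ids), function(a) lab[, a]),
                    list(stats::setNames(cons$consensus[!cons$undefined], universe)))
  names(train_labels) <- trainers

  keep <- vapply(train_labels, function(v) sum(!is.na(v)) > 0, logical(1))
  if (!all(keep)) {
    warning(sprintf("dropping trainer(s) with no labeled patches: %s",
                    paste(trainers[!keep], collapse = ", ")))
    trainers <- trainers[keep]
    train_labels <- train_labels[keep]
  }

  K <- matrix(NA_real_, length(trainers), length(ids) + 1L,
              dimnames = list(trainers, c(ids, "overall")))
  for (t in seq_along(trainers)) {
    yl <- train_labels[[t]]
    pred <- rep(NA_character_, length(universe))
    for (f in sort(unique(fold))) {
      tr <- which(!is.na(yl) & fold != f)
      te <- which(fold == f)
      if (!length(te)) next
      if (!length(tr))
        stop(sprintf("trainer %s has no training patches outside fold %d",
                     trainers[t], f), call. = FALSE)
      model <- fit_patch_classifier(X[tr, , drop = FALSE], yl[tr],
                                    kind = classifier, k_neighbors = k_neighbors)
      pred[te] <- predict(model, X[te, , drop = FALSE])
    }
    pooled_pred <- character(0); pooled_lab <- character(0)
    for (e in seq_along(ids)) {
      common <- !is.na(lab[, e])
      if (any(common))
        K[t, e] <- weighted_kappa(pred[common], lab[common, e])$kappa
      pooled_pred <- c(pooled_pred, pred[common])
      pooled_lab <- c(pooled_lab, lab[common, e])
    }
    K[t, "overall"] <- if (overall == "pooled")
      weighted_kappa(pooled_pred, pooled_lab)$kappa
    else mean(K[t, seq_along(ids)], na.rm = TRUE)
  }
  structure(K, overall_rule = overall, classifier = classifier,
            n_universe = length(universe),
            class = c("agreement_matrix", "matrix"))
}

#' @export
print.agreement_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Cross-expert agreement (quadratic-weighted kappa), %s classifier\n",
              attr(x, "classifier")))
  cat(sprintf("Rows: training label source; columns: evaluating annotator; overall = %s\n",
              attr(x, "overall_rule")))
  print(round(unclass(x), digits))
  invisible(x)
}
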