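#' Run the complete evaluation study
#'
#' One-call orchestration of the package's two demonstrations, with every
#' sub-seed derived from the single root seed by the package's stable
#' hashing convention:
#'
#' 1. **Leakage study** (on `leakage_config`, by default the pinned
#'    high-patient-effect scenario): simulate the cohort and the six-
#'    annotator panel, take the majority-vote consensus as ground truth, run
#'    the four cross-validation schemes (20-fold leave-patients-out,
#'    leave-cores-out, leave-patches-out, and 2-fold leave-patches-out) with
#'    the leakage-sensitive kNN classifier, and compare all pairs with the
#'    McNemar test.
#' 2. **Cross-expert study** (on `cross_config`, by default the pinned
#'    informative-feature scenario): train per single annotator and on the
#'    majority vote under patient-level folds, and tabulate
#'    quadratic-weighted kappa against every annotator.
#'
#' @param seed Root seed; all simulation and fold seeds derive from it.
#' @param leakage_config `sim_config` for the CV-scheme comparison.
#' @param cross_config `sim_config` for the cross-expert study, or `NULL`
#'   to skip it.
#' @param k Fold count for the 20-fold analogues.
#' @param classifier,k_neighbors Classifier used throughout.
#' @param tasks Tasks evaluated in the comparison.
#' @return List of class `patchcv_study` with elements `comparison`
#'   (a `cv_comparison`), `agreement` (an `agreement_matrix` or `NULL`),
#'   `consensus` (majority-vote table of the leakage cohort), and `seed`.
#' @export
run_full_study <- function(seed = 20190442,
                           leakage_config = default_scenario(seed = seed),
                           cross_config = cross_expert_scenario(
                             seed = .child_seed(seed, "cross-cohort")),
                           k = 20,
                           classifier = "knn", k_neighbors = 1L,
                           tasks = c("detection", "grading")) {
  coh <- simulate_cohort(leakage_config)
  ann <- simulate_annotations(coh, seed = .child_seed(seed, "annotations"))
  cons <- majority_vote(ann)
  truth <- stats::setNames(cons$consensus, cons$patch_id)

  specs <- list(
    fold_spec(k, "patient", seed = .child_seed(seed, "folds:patient")),
    fold_spec(k, "core", seed = .child_seed(seed, "folds:core")),
    fold_spec(k, "patch", seed = .child_seed(seed, "folds:patch")),
    fold_spec(2, "patch", seed = .child_seed(seed, "folds:patch2")))
  names(specs) <- c(sprintf("%d-fold leave-patients-out", k),
                    sprintf("%d-fold leave-cores-out", k),
                    sprintf("%d-fold leave-patches-out", k),
                    "2-fold leave-patches-out")
  comparison <- compare_cv_methods(coh, truth, specs, classifier,
                                   k_neighbors, tasks)

  agreement <- NULL
  if (!is.null(cross_config)) {
    coh_x <- simulate_cohort(cross_config)
    ann_x <- simulate_annotations(coh_x,
                                  seed = .child_seed(seed, "cross-annotations"))
    agreement <- cross_expert_experiment(
      coh_x, ann_x,
      fold_spec(k, "patient", seed = .child_seed(seed, "cross-folds")),
      classifier = classifier, k_neighbors = k_neighbors)
  }
  structure(list(comparison = comparison, agreement = agreement,
                 consensus = cons, seed = seed),
            class = "patchcv_study")
}

#' @export
print.patchcv_study <- function(x, ...) {
  cat(sprintf("patchcv study (root seed %d)\n\n", x$seed))
  print(x$comparison)
  if (!is.null(x$agreement)) {
    cat("\n")
    print(x$agreement)
  }
  invisible(x)
}
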