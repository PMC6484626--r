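# Shared small cohort for the experiment-driver contracts.
exp_cohort <- function() {
  simulate_cohort(sim_config(n_patients = 40, cores_per_patient = 2,
                             patches_per_core = 10, delta = 2,
                             sigma_p = 0.3, sigma_c = 0.2, sigma_e = 0.4,
                             seed = 88))
}

test_that("every included patch is predicted exactly once per experiment", {
  coh <- exp_cohort()
  truth <- true_labels(coh)
  truth[1:7] <- NA # undefined-consensus analogue
  preds <- run_cv_experiment(coh, truth, fold_spec(8, "patient", seed = 4),
                             "nearest_centroid")
  expect_identical(sort(preds$patch_id), sort(names(truth)[!is.na(truth)]))
  expect_identical(anyDuplicated(preds$patch_id), 0L)
  expect_identical(attr(preds, "n_excluded"), 7L)
  expect_false(anyNA(preds$pred))
})

test_that("a training split missing a class errors with the fold named", {
  coh <- simulate_cohort(sim_config(n_patients = 4, cores_per_patient = 1,
                                    patches_per_core = 4,
                                    class_prevalence = c(0.5, 0.5, 0, 0),
                                    sigma_p = 0, sigma_c = 0, sigma_e = 0.1,
                                    seed = 12))
  truth <- true_labels(coh)
  # make one class appear only inside one patient: that fold's complement
  # would still have it, so instead concentrate it by hand
  truth[coh$patches$patient_id != "P0001"] <- "G3"
  truth[coh$patches$patient_id == "P0001"] <- "G5"
  expect_error(
    run_cv_experiment(coh, truth, fold_spec(4, "patient", seed = 1),
                      "nearest_centroid"),
    "missing class")
})

test_that("zero-noise cohort yields 100% accuracy in every fold and scheme", {
  coh <- clean_cohort()
  truth <- true_labels(coh)
  for (lvl in c("patient", "core", "patch")) {
    p <- run_cv_experiment(coh, truth, fold_spec(4, lvl, seed = 6),
                           "nearest_centroid")
    b <- binarize(p$truth, p$pred, "detection")
    ms <- fold_metrics(b$truth, b$pred, p$fold)
    expect_true(all(ms$per_fold$accuracy == 100))
  }
})

test_that("identical fold specs give identical predictions and p = 1 everywhere", {
  coh <- exp_cohort()
  specs <- list(a = fold_spec(5, "patient", seed = 9),
                b = fold_spec(5, "patient", seed = 9))
  cmp <- compare_cv_methods(coh, true_labels(coh), specs,
                            "nearest_centroid", tasks = "detection")
  expect_identical(cmp$predictions$a$pred, cmp$predictions$b$pred)
  expect_equal(cmp$mcnemar$detection$p["b", "a"], 1)
})

test_that("the comparison pipeline is deterministic end to end", {
  coh <- exp_cohort()
  specs <- list(patient = fold_spec(5, "patient", seed = 2),
                patch = fold_spec(5, "patch", seed = 3))
  run <- function() compare_cv_methods(coh, true_labels(coh), specs,
                                       "knn", 1, tasks = "detection")
  expect_identical(run()$metrics, run()$metrics)

  d1 <- tempfile(); d2 <- tempfile()
  write_report(run(), d1)
  write_report(run(), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("the report bundle has the expected tables and is validated upfront", {
  coh <- exp_cohort()
  specs <- list(m1 = fold_spec(4, "patient", seed = 2),
                m2 = fold_spec(4, "core", seed = 2),
                m3 = fold_spec(4, "patch", seed = 2))
  cmp <- compare_cv_methods(coh, true_labels(coh), specs, "nearest_centroid")
  d <- tempfile()
  files <- write_report(cmp, d, manifest = list(root_seed = 1L))
  expect_true(all(file.exists(files)))
  # k methods -> k(k-1)/2 populated p-value cells
  p <- as.matrix(utils::read.csv(file.path(d, "mcnemar_detection.csv"),
                                 row.names = 1))
  expect_identical(sum(!is.na(p)), 3L)
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_identical(man$root_seed, 1L)

  # invalid input errors before any file is written
  d_bad <- tempfile()
  expect_error(write_report(list(), d_bad), "cv_comparison")
  expect_false(dir.exists(d_bad))
})

test_that("cross-expert experiment enforces patient-level folds and row/col shape", {
  coh <- exp_cohort()
  profs <- list(annotator_profile("a1", make_confusion(0.8, 0)),
                annotator_profile("a2", make_confusion(0.7, 0.3)),
                annotator_profile("a3", make_confusion(0.75, -0.2), coverage = 0.6))
  ann <- simulate_annotations(coh, profs, seed = 3)
  expect_error(
    cross_expert_experiment(coh, ann, fold_spec(4, "patch", seed = 1)),
    "patient-level")
  K <- cross_expert_experiment(coh, ann, fold_spec(4, "patient", seed = 1),
                               classifier = "nearest_centroid")
  expect_identical(rownames(K), c("a1", "a2", "a3", "majority"))
  expect_identical(colnames(K), c("a1", "a2", "a3", "overall"))
  expect_true(all(K >= -1 & K <= 1))
  # identical noiseless annotators: all rows identical, all cells equal
  perfect <- list(annotator_profile("p1", diag(4)),
                  annotator_profile("p2", diag(4)))
  annp <- simulate_annotations(coh, perfect, seed = 4)
  Kp <- cross_expert_experiment(coh, annp, fold_spec(4, "patient", seed = 1),
                                classifier = "nearest_centroid")
  expect_lt(max(Kp) - min(Kp), 1e-12)
})

test_that("simulated annotator confusions are recovered empirically", {
  coh <- simulate_cohort(sim_config(n_patients = 100, cores_per_patient = 1,
                                    patches_per_core = 30, seed = 19))
  C <- make_confusion(0.7, 0.4)
  ann <- simulate_annotations(coh, list(annotator_profile("a", C)), seed = 23)
  truth <- coh$patches$true_class
  for (t in 1:4) for (j in 1:4) {
    sel <- truth == gleason_classes()[t]
    n_t <- sum(sel)
    emp <- mean(ann$labels[sel, 1] == gleason_classes()[j])
    tol <- 4 * sqrt(max(C[t, j] * (1 - C[t, j]), 1e-4) / n_t)
    expect_lt(abs(emp - C[t, j]), tol + 1e-9)
  }
})

test_that("patch-vs-patient accuracy gap grows with the patient effect", {
  gaps <- sapply(c(0, 0.5, 1, 2), function(sp) {
    coh <- simulate_cohort(sim_config(n_patients = 100, cores_per_patient = 2,
                                      patches_per_core = 25, delta = 1,
                                      sigma_p = sp, sigma_c = 0.5, sigma_e = 1,
                                      seed = 55))
    truth <- true_labels(coh)
    acc <- function(lvl) {
      p <- run_cv_experiment(coh, truth, fold_spec(10, lvl, seed = 5), "knn", 1)
      b <- binarize(p$truth, p$pred, "detection")
      100 * mean(b$truth == b$pred)
    }
    acc("patch") - acc("patient")
  })
  # weak monotonicity with 1-percentage-point sampling tolerance
  expect_true(all(diff(gaps) >= -1))
  expect_gt(gaps[4], gaps[1])
})
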