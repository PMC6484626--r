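test_that("profile construction rejects invalid confusion matrices", {
  expect_error(annotator_profile("x", matrix(1, 4, 4)), "row-stochastic")
  expect_error(annotator_profile("x", diag(4), coverage = 1.2), "coverage")
  expect_true(all(abs(rowSums(make_confusion(0.7, 0.5)) - 1) < 1e-12))
  expect_true(all(make_confusion(0.6, -1) >= 0))
})

test_that("noiseless full-coverage annotator reproduces truth; zero coverage all missing", {
  coh <- clean_cohort(n_patients = 10)
  profs <- list(annotator_profile("perfect", diag(4), coverage = 1),
                annotator_profile("absent", diag(4), coverage = 0))
  ann <- simulate_annotations(coh, profs, seed = 2)
  expect_identical(unname(ann$labels[, "perfect"]), coh$patches$true_class)
  expect_true(all(is.na(ann$labels[, "absent"])))
})

test_that("coverage realizes exactly round(coverage * n_cores) cores", {
  coh <- simulate_cohort(sim_config(n_patients = 40, cores_per_patient = 2,
                                    patches_per_core = 3, seed = 6))
  for (cov in c(191 / 333, 92 / 333, 0.5)) {
    ann <- simulate_annotations(
      coh, list(annotator_profile("a", diag(4), coverage = cov)), seed = 3)
    covered <- unique(coh$patches$core_id[!is.na(ann$labels[, 1])])
    expect_identical(length(covered), as.integer(round(cov * nrow(coh$cores))))
    # missingness is decided per core, not per patch
    per_core <- tapply(is.na(ann$labels[, 1]), coh$patches$core_id,
                       function(x) length(unique(x)))
    expect_true(all(per_core == 1))
  }
})

test_that("confusion rates reproduce the generating matrix (binomial oracle)", {
  # 10 000 G3 patches, P(G4 | G3) = 0.3
  coh <- simulate_cohort(sim_config(n_patients = 200, cores_per_patient = 1,
                                    patches_per_core = 50,
                                    class_prevalence = c(0, 1, 0, 0),
                                    sigma_p = 0, sigma_c = 0, sigma_e = 0,
                                    seed = 14))
  C <- diag(4) * 0.7
  C[2, 3] <- 0.3; C[1, 1] <- 1; C[3, 4] <- 0.3; C[4, 3] <- 0.3
  ann <- simulate_annotations(coh, list(annotator_profile("a", C)), seed = 5)
  n <- nrow(coh$patches)
  frac <- mean(ann$labels[, 1] == "G4")
  expect_lt(abs(frac - 0.3), 4 * sqrt(0.3 * 0.7 / n))
})

test_that("majority vote follows modal label, severity tie-break, undefined flag", {
  lab <- rbind(
    p1 = c("G3", "G3", "G4"),
    p2 = c("G3", "G4", NA),
    p3 = c(NA, NA, NA),
    p4 = c("benign", "G5", NA))
  colnames(lab) <- c("a", "b", "c")
  mv <- majority_vote(manual_annotations(lab))
  expect_identical(mv$consensus, c("G3", "G4", NA, "G5"))
  expect_identical(mv$undefined, c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(mv$n_votes, c(3L, 2L, 0L, 2L))
  # lenient rule flips the ties
  mv2 <- majority_vote(manual_annotations(lab), tie_rule = "lenient")
  expect_identical(mv2$consensus[c(2, 4)], c("G3", "benign"))
  # min_votes flags sparse patches
  mv3 <- majority_vote(manual_annotations(lab), min_votes = 3)
  expect_identical(mv3$undefined, c(FALSE, TRUE, TRUE, TRUE))
})

test_that("majority-vote error is non-increasing in annotator count", {
  coh <- simulate_cohort(sim_config(n_patients = 150, cores_per_patient = 1,
                                    patches_per_core = 20, seed = 31))
  C <- make_confusion(0.7, 0)
  err <- sapply(c(1, 3, 5), function(m) {
    profs <- lapply(seq_len(m), function(i)
      annotator_profile(paste0("a", i), C))
    mv <- majority_vote(simulate_annotations(coh, profs, seed = 17))
    mean(mv$consensus != coh$patches$true_class)
  })
  expect_true(all(diff(err) <= 0.01)) # small simulation tolerance
  expect_lt(err[3], err[1])
})

test_that("pairwise agreement: self is 1, independent raters near 0, oracle match", {
  # two independent uniform-random annotators over 10 000 patches
  set.seed(404)
  n <- 10000
  lab <- cbind(a = sample(gleason_classes(), n, TRUE),
               b = sample(gleason_classes(), n, TRUE))
  rownames(lab) <- paste0("p", 1:n)
  K <- pairwise_annotator_agreement(manual_annotations(lab))
  expect_identical(diag(K), c(a = 1, b = 1))
  expect_lt(abs(K["a", "b"]), 0.05)
  expect_identical(K["a", "b"], K["b", "a"])

  # constructed 12-patch, 3-annotator table vs the brute-force oracle
  lab3 <- cbind(
    x = c("benign", "G3", "G3", "G4", "G5", "benign", "G3", "G4", "G4", "G5", "benign", "G3"),
    y = c("benign", "G3", "G4", "G4", "G4", "G3", "G3", "G5", "G4", "G5", "benign", "benign"),
    z = c("G3", "G3", "G3", "G5", "G5", "benign", "G4", "G4", "G3", "G5", "benign", "G3"))
  rownames(lab3) <- paste0("p", 1:12)
  K3 <- pairwise_annotator_agreement(manual_annotations(lab3))
  for (i in 1:3) for (j in 1:3) if (i != j)
    expect_equal(K3[i, j],
                 oracle_qwk(lab3[, i], lab3[, j]), tolerance = 1e-12)
})
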