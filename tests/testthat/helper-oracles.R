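# Independent oracles and small fixtures used across test files.

# Brute-force quadratic-weighted kappa: builds the C x C contingency table
# and evaluates the definition by direct double summation, sharing no code
# with weighted_kappa().
oracle_qwk <- function(a, b, classes = gleason_classes()) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  C <- length(classes)
  O <- matrix(0, C, C)
  for (p in seq_len(n)) {
    i <- which(classes == a[p]); j <- which(classes == b[p])
    O[i, j] <- O[i, j] + 1 / n
  }
  row_m <- rowSums(O); col_m <- colSums(O)
  num <- 0; den <- 0
  for (i in seq_len(C)) for (j in seq_len(C)) {
    w <- (i - j)^2 / (C - 1)^2
    num <- num + w * O[i, j]
    den <- den + w * row_m[i] * col_m[j]
  }
  1 - num / den
}

# Unweighted Cohen kappa by direct computation (for the 2-class collapse
# property).
oracle_cohen <- function(a, b, classes) {
  n <- length(a)
  po <- mean(a == b)
  pe <- 0
  for (cl in classes) pe <- pe + mean(a == cl) * mean(b == cl)
  (po - pe) / (1 - pe)
}

# A tiny noise-free cohort: classes perfectly separable in feature space.
clean_cohort <- function(n_patients = 12, patches_per_core = 6, seed = 5) {
  simulate_cohort(sim_config(
    n_patients = n_patients, cores_per_patient = 2,
    patches_per_core = patches_per_core,
    class_prevalence = c(0.25, 0.25, 0.25, 0.25),
    feature_dim = 4, delta = 2,
    sigma_p = 0, sigma_c = 0, sigma_e = 0, seed = seed))
}

true_labels <- function(cohort) {
  stats::setNames(cohort$patches$true_class, cohort$patches$patch_id)
}

# Annotation matrix built directly from a patch x annotator label matrix,
# bypassing the simulator (for hand-constructed vote tables).
manual_annotations <- function(lab) {
  structure(list(labels = lab, annotators = colnames(lab), profiles = NULL),
            class = "annotation_matrix")
}
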