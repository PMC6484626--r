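test_that("task binarization follows the clinical definitions", {
  # true G3 predicted G4 is concordant under detection (both cancer)
  b <- binarize("G3", "G4", "detection")
  expect_true(b$truth & b$pred & b$include)
  # benign truth is excluded from grading; benign prediction counts negative
  tr <- c("benign", "benign", "benign", "G3", "G3", "G4", "G4", "G5", "G3", "G5")
  pr <- c("G3", "benign", "G4", "benign", "G4", "G4", "G3", "G5", "G3", "benign")
  g <- binarize(tr, pr, "grading")
  expect_identical(sum(g$include), 7L)
  expect_false(g$pred[4])  # benign prediction -> low-grade (negative)
  expect_error(binarize("G2", "G3", "detection"), "unknown class")
})

test_that("fold metrics reproduce hand-computed rates and the pooling identity", {
  # single fold with TP=8 FN=2 TN=9 FP=1: acc 85, sens 80, spec 90
  truth <- c(rep(TRUE, 10), rep(FALSE, 10))
  pred <- c(rep(TRUE, 8), rep(FALSE, 2), rep(FALSE, 9), TRUE)
  ms <- fold_metrics(truth, pred, rep(0L, 20))
  expect_equal(unname(ms$accuracy["mean"]), 85)
  expect_equal(unname(ms$sensitivity["mean"]), 80)
  expect_equal(unname(ms$specificity["mean"]), 90)

  # perfect predictions: 100/100/100 with SD 0
  mp <- fold_metrics(truth, truth, rep(0:1, 10))
  for (r in c("accuracy", "sensitivity", "specificity"))
    expect_equal(unname(mp[[r]]), c(100, 0))

  # pooled confusion equals the sum of per-fold confusions (additivity),
  # and accuracy = prevalence * sens + (1 - prevalence) * spec on pooled counts
  set.seed(33)
  n <- 400L
  tr <- sample(c(TRUE, FALSE), n, TRUE)
  pr <- ifelse(runif(n) < 0.7, tr, !tr)
  fold <- sample(0:19, n, TRUE)
  ms2 <- fold_metrics(tr, pr, fold)
  expect_identical(sum(ms2$pooled), n)
  expect_identical(unname(ms2$pooled["tp"]), sum(tr & pr))
  pooled_acc <- 100 * (ms2$pooled["tp"] + ms2$pooled["tn"]) / n
  prev <- mean(tr)
  sens_p <- 100 * ms2$pooled["tp"] / (ms2$pooled["tp"] + ms2$pooled["fn"])
  spec_p <- 100 * ms2$pooled["tn"] / (ms2$pooled["tn"] + ms2$pooled["fp"])
  expect_equal(unname(pooled_acc), unname(prev * sens_p + (1 - prev) * spec_p))
  expect_error(fold_metrics(logical(0), logical(0), integer(0)), "empty")
})

test_that("folds lacking a rate's denominator are skipped, not propagated", {
  truth <- c(TRUE, TRUE, FALSE, FALSE) # fold 1 has no positives
  pred <- c(TRUE, FALSE, FALSE, TRUE)
  fold <- c(0L, 0L, 1L, 1L)
  ms <- fold_metrics(truth, pred, fold)
  expect_true(is.na(ms$per_fold$sensitivity[2]))
  expect_equal(unname(ms$sensitivity["mean"]), 50) # from fold 0 only
})

test_that("weighted kappa matches its definition on trivial cases", {
  a <- c("benign", "G3", "G4", "G5", "G3")
  expect_equal(weighted_kappa(a, a)$kappa, 1)
  # observed equals expected independence table -> kappa = 0
  g <- expand.grid(a = gleason_classes(), b = gleason_classes(),
                   stringsAsFactors = FALSE)
  expect_equal(weighted_kappa(g$a, g$b)$kappa, 0)
  # constant identical vectors are perfect agreement
  expect_equal(weighted_kappa(rep("G3", 5), rep("G3", 5))$kappa, 1)
  # two constant but disagreeing raters: observed equals expected -> 0
  expect_equal(weighted_kappa(rep("G3", 5), rep("G4", 5))$kappa, 0)
  expect_error(weighted_kappa(NA_character_, "G3"), "usable")
  # missing pairs dropped before tabulation
  expect_equal(weighted_kappa(c(a, NA), c(a, "G3"))$kappa, 1)
})

test_that("weighted kappa equals the brute-force oracle on random pairs", {
  set.seed(501)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    a <- sample(gleason_classes(), n, TRUE)
    b <- ifelse(runif(n) < 0.6, a, sample(gleason_classes(), n, TRUE))
    k <- weighted_kappa(a, b)
    expect_equal(k$kappa, oracle_qwk(a, b), tolerance = 1e-12)
    # symmetry is exact
    expect_identical(k$kappa, weighted_kappa(b, a)$kappa)
  }
})

test_that("weighted kappa matches an independent established implementation", {
  set.seed(77)
  n <- 200
  a <- sample(gleason_classes(), n, TRUE)
  b <- ifelse(runif(n) < 0.5, a, sample(gleason_classes(), n, TRUE))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = match(a, gleason_classes()),
                              b = match(b, gleason_classes())),
                   f, row.names = FALSE)
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import csv; from sklearn.metrics import cohen_kappa_score\n",
    "rows=list(csv.DictReader(open('", f, "')))\n",
    "a=[int(r['a']) for r in rows]; b=[int(r['b']) for r in rows]\n",
    "print(repr(cohen_kappa_score(a,b,labels=[1,2,3,4],weights='quadratic')))"))),
    stdout = TRUE, stderr = FALSE))
  expect_equal(weighted_kappa(a, b)$kappa, as.numeric(out[1]),
               tolerance = 1e-10)
})

test_that("for two classes quadratic weights collapse to unweighted Cohen kappa", {
  set.seed(92)
  cl2 <- c("G3", "G4")
  a <- sample(cl2, 80, TRUE)
  b <- ifelse(runif(80) < 0.7, a, sample(cl2, 80, TRUE))
  expect_equal(weighted_kappa(a, b, classes = cl2)$kappa,
               oracle_cohen(a, b, cl2), tolerance = 1e-12)
})

test_that("kappa is invariant to order-preserving relabeling with equal spacing", {
  set.seed(15)
  a <- sample(gleason_classes(), 60, TRUE)
  b <- sample(gleason_classes(), 60, TRUE)
  relab <- c(benign = "s1", G3 = "s2", G4 = "s3", G5 = "s4")
  expect_equal(weighted_kappa(a, b)$kappa,
               weighted_kappa(unname(relab[a]), unname(relab[b]),
                              classes = unname(relab))$kappa,
               tolerance = 1e-15)
})

test_that("kappa interpretation bands match the conventional scale", {
  expect_identical(interpret_kappa(0.60), "moderate")
  expect_identical(interpret_kappa(-0.2), "accidental")
  expect_identical(interpret_kappa(1.0), "near-perfect")
  expect_identical(interpret_kappa(0.41), "moderate")
  expect_identical(interpret_kappa(0.15), "slight")
  expect_identical(interpret_kappa(0.05), "below slight")
  expect_identical(interpret_kappa(0.75), "substantial")
  expect_identical(interpret_kappa(0.3), "fair")
  expect_error(interpret_kappa(1.5), "lie in")
})
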