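#' Pair two prediction tables into a McNemar discordance table
#'
#' Both methods must have predicted exactly the same patch set, each patch
#' once (the paired design requires every patch tested exactly once per
#' method). After binarizing against the common truth under the task,
#' per-patch correctness is tallied into the 2x2 table: `n11` both correct,
#' `n10` only method 1 correct (b), `n01` only method 2 correct (c), `n00`
#' neither.
#'
#' @param preds_m1,preds_m2 `prediction_table` objects or data frames with
#'   `patch_id` and `pred` columns.
#' @param truth Named character vector of true classes (names = patch ids).
#' @param task A [task_spec()] or task name.
#' @param methods Optional length-2 character vector of method labels.
#' @return Object of class `discordance_table`.
#' @export
build_discordance <- function(preds_m1, preds_m2, truth,
                              task = task_spec("detection"),
                              methods = c("method1", "method2")) {
  if (is.character(task)) task <- task_spec(task)
  p1 <- as.data.frame(preds_m1)[, c("patch_id", "pred")]
  p2 <- as.data.frame(preds_m2)[, c("patch_id", "pred")]
  if (anyDuplicated(p1$patch_id) || anyDuplicated(p2$patch_id))
    stop("duplicate patch_id in a prediction table", call. = FALSE)
  if (!setequal(p1$patch_id, p2$patch_id))
    stop("prediction tables cover different patch sets", call. = FALSE)
  p2 <- p2[match(p1$patch_id, p2$patch_id), ]
  tr <- truth[p1$patch_id]
  if (anyNA(tr)) stop("truth missing for some predicted patches", call. = FALSE)

  b1 <- binarize(tr, p1$pred, task)
  b2 <- binarize(tr, p2$pred, task)
  inc <- b1$include
  c1 <- b1$truth[inc] == b1$pred[inc]
  c2 <- b2$truth[inc] == b2$pred[inc]
  structure(list(n11 = sum(c1 & c2), n10 = sum(c1 & !c2),
                 n01 = sum(!c1 & c2), n00 = sum(!c1 & !c2),
                 methods = methods, task = task$name),
            class = "discordance_table")
}

#' @export
print.discordance_table <- function(x, ...) {
  cat(sprintf("Discordance table (%s task): %s vs %s\n",
              x$task, x$methods[1], x$methods[2]))
  m <- matrix(c(x$n11, x$n01, x$n10, x$n00), 2, 2,
              dimnames = list(paste(x$methods[1], c("correct", "incorrect")),
                              paste(x$methods[2], c("correct", "incorrect"))))
  print(m)
  invisible(x)
}

#' McNemar test of equal marginal correctness
#'
#' Tests the null that the two paired methods are equally likely to be the
#' only correct one on a patch, using just the discordant counts
#' `b = n10`, `c = n01`. The exact variant computes the two-sided binomial
#' p-value `min(1, 2 * min(P(X <= b), P(X >= b)))` with
#' `X ~ Binomial(b + c, 1/2)` (doubling convention); the asymptotic variant
#' uses the continuity-corrected chi-square statistic
#' `max(|b - c| - 1, 0)^2 / (b + c)` with 1 df; the correction is clamped at
#' zero so that perfectly balanced discordance (`b = c`) gives `p = 1`,
#' matching the exact test, rather than overshooting. `variant = "auto"`
#' uses the exact test when `b + c < 25` and the chi-square otherwise. When
#' `b = c = 0` the test is undefined and `p = 1` is returned by convention.
#'
#' @param table A `discordance_table`, or a list/vector with `n10` and `n01`.
#' @param variant `"auto"`, `"exact"`, or `"chisq"`.
#' @param alpha Significance threshold for the reported flag (default the
#'   conventional strict 0.001).
#' @return Object of class `mcnemar_result`: `b`, `c`, `statistic` (`NA` for
#'   the exact variant), `p_value`, `variant` actually used, `significant`.
#' @export
mcnemar_test <- function(table, variant = c("auto", "exact", "chisq"),
                         alpha = 0.001) {
  variant <- match.arg(variant)
  b <- table[["n10"]]; cc <- table[["n01"]]
  if (is.null(b) || is.null(cc)) stop("need n10 and n01 counts", call. = FALSE)
  if (b < 0 || cc < 0) stop("negative discordant counts", call. = FALSE)
  m <- b + cc
  if (m == 0) {
    res <- list(b = b, c = cc, statistic = NA_real_, p_value = 1,
                variant = "degenerate")
  } else if (variant == "exact" || (variant == "auto" && m < 25)) {
    tail_low <- stats::pbinom(b, m, 0.5)
    tail_high <- stats::pbinom(b - 1, m, 0.5, lower.tail = FALSE)
    res <- list(b = b, c = cc, statistic = NA_real_,
                p_value = min(1, 2 * min(tail_low, tail_high)),
                variant = "exact")
  } else {
    stat <- max(abs(b - cc) - 1, 0)^2 / m
    res <- list(b = b, c = cc, statistic = stat,
                p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                variant = "chisq")
  }
  res$significant <- res$p_value < alpha
  res$alpha <- alpha
  class(res) <- "mcnemar_result"
  res
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar test (%s): b = %d, c = %d, p = %s%s\n",
              x$variant, x$b, x$c, format.pval(x$p_value, digits = 3),
              if (x$significant) sprintf(" (significant at P < %g)", x$alpha) else ""))
  if (!is.na(x$statistic))
    cat(sprintf("  chi-square statistic (continuity-corrected): %.4f, df = 1\n",
                x$statistic))
  invisible(x)
}
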