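#' Ordered Gleason class labels
#'
#' The four patch classes used throughout the package, ordered by clinical
#' severity: benign, Gleason grade 3 (low-grade cancer), grade 4 and grade 5
#' (high-grade cancer). The position of a class in this vector is its
#' severity rank; ordinal statistics (quadratic-weighted kappa) and
#' severity-based tie-breaking rely on this order.
#'
#' @return Character vector of length 4.
#' @export
#' @examples
#' gleason_classes()
gleason_classes <- function() c("benign", "G3", "G4", "G5")

.CLASSES <- c("benign", "G3", "G4", "G5")

#' @keywords internal
.severity <- function(labels) match(labels, .CLASSES)

#' Derive a child RNG seed from a root seed and a string key.
#'
#' Stable 31-adic polynomial hash modulo 2^31 - 1, so every simulated unit
#' (patient, core, annotator) owns its own reproducible random stream:
#' extending a cohort does not reshuffle draws for existing units.
#' @keywords internal
.child_seed <- function(root, key) {
  h <- as.double(root) %% 2147483647
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' @keywords internal
.assert_classes <- function(x, what = "labels") {
  bad <- !is.na(x) & !(x %in% .CLASSES)
  if (any(bad)) {
    stop(sprintf("unknown class value(s) in %s: %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Squared Euclidean distances between the rows of two matrices.
#' @keywords internal
.dist2 <- function(A, B) {
  d2 <- matrix(rowSums(A^2), nrow(A), nrow(B)) +
    matrix(rowSums(B^2), nrow(A), nrow(B), byrow = TRUE) -
    2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}
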