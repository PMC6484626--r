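#' Fit a reference patch classifier
#'
#' Two deliberately simple, fully deterministic classifiers with a uniform
#' fit/predict contract serve as stand-ins for a real model under the
#' evaluation protocols. `"nearest_centroid"` stores the per-class mean
#' feature vector and generalises across patients (centroids average out
#' patient effects); `"knn"` memorises the training set and is maximally
#' leakage-sensitive — with `k_neighbors = 1` a same-patient neighbour in the
#' training fold is typically the nearest point, which is exactly the
#' mechanism that inflates ungrouped cross-validation. Any model exposing
#' this contract (`fit` on a feature matrix + labels, `predict` on new
#' features returning class labels) can be plugged into the experiment
#' drivers.
#'
#' @param features Numeric matrix or data frame, one row per training patch.
#' @param labels Character vector of classes from `gleason_classes()`.
#' @param kind `"nearest_centroid"` or `"knn"`.
#' @param k_neighbors Neighbourhood size for `"knn"`.
#' @return An object of class `patch_model`.
#' @seealso [predict.patch_model()]
#' @export
fit_patch_classifier <- function(features, labels,
                                 kind = c("nearest_centroid", "knn"),
                                 k_neighbors = 1L) {
  kind <- match.arg(kind)
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (nrow(X) == 0) stop("no training rows", call. = FALSE)
  if (anyNA(X) || any(!is.finite(X)))
    stop("features contain NA/NaN/Inf", call. = FALSE)
  labels <- as.character(labels)
  .assert_classes(labels)
  if (anyNA(labels)) stop("labels contain NA", call. = FALSE)
  if (length(labels) != nrow(X))
    stop("labels length must match feature rows", call. = FALSE)

  classes <- .CLASSES[sort(unique(.severity(labels)))]
  model <- list(kind = kind, classes = classes, dim = ncol(X),
                fingerprint = sprintf("%dx%d:%.10e", nrow(X), ncol(X), sum(X)))
  if (kind == "nearest_centroid") {
    if (any(table(factor(labels, classes)) < 1))
      stop("a class has no training rows", call. = FALSE)
    model$centroids <- t(vapply(classes,
                                function(cl) colMeans(X[labels == cl, , drop = FALSE]),
                                numeric(ncol(X))))
  } else {
    k_neighbors <- as.integer(k_neighbors)
    if (k_neighbors < 1 || k_neighbors > nrow(X))
      stop("k_neighbors must be in [1, n]", call. = FALSE)
    model$train_x <- X
    model$train_y <- labels
    model$k_neighbors <- k_neighbors
  }
  class(model) <- "patch_model"
  model
}

#' Predict patch classes
#'
#' Nearest-centroid predicts the class whose centroid minimises Euclidean
#' distance; exact distance ties go to the more severe class. kNN takes the
#' majority vote among the `k_neighbors` nearest training points (neighbour
#' distance ties resolved toward the smallest training index); vote ties go
#' to the more severe class. Both rules are deterministic.
#'
#' @param object A `patch_model`.
#' @param newdata Numeric matrix/data frame of query features.
#' @param ... Unused.
#' @return Character vector of predicted classes.
#' @export
predict.patch_model <- function(object, newdata, ...) {
  Q <- as.matrix(newdata)
  storage.mode(Q) <- "double"
  if (ncol(Q) != object$dim)
    stop(sprintf("feature length %d does not match model dimension %d",
                 ncol(Q), object$dim), call. = FALSE)
  if (object$kind == "nearest_centroid") {
    D <- .dist2(Q, object$centroids)
    rmin <- do.call(pmin, as.data.frame(D))
    tie <- D <= rmin + 1e-9 * (1 + abs(rmin))
    # classes (columns) are in severity order; "last" = most severe tied
    return(object$classes[max.col(tie, ties.method = "last")])
  }
  k <- object$k_neighbors
  out <- character(nrow(Q))
  chunk <- 512L
  for (s in seq(1L, nrow(Q), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(Q))
    D <- .dist2(Q[s:e, , drop = FALSE], object$train_x)
    if (k == 1L) {
      # ties.method "first" = smallest training index on distance ties
      out[s:e] <- object$train_y[max.col(-D, ties.method = "first")]
    } else {
      for (r in seq_len(e - s + 1L)) {
        nb <- order(D[r, ])[seq_len(k)] # stable: smallest index on ties
        votes <- table(factor(object$train_y[nb], levels = object$classes))
        top <- which(votes == max(votes))
        out[s + r - 1L] <- object$classes[top[length(top)]] # most severe
      }
    }
  }
  out
}

#' @export
print.patch_model <- function(x, ...) {
  cat(sprintf("patch_model: %s (%d features, classes: %s)\n",
              x$kind, x$dim, paste(x$classes, collapse = ", ")))
  if (x$kind == "knn")
    cat(sprintf("  k = %d, %d training patches\n", x$k_neighbors, nrow(x$train_x)))
  cat("  training fingerprint:", x$fingerprint, "\n")
  invisible(x)
}
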