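#' Render a toy histology-like patch image
#'
#' Produces a small RGB raster whose morphology depends monotonically on the
#' Gleason class: benign tissue shows many large gland lumens, grade 3 fewer
#' and smaller, grade 4 few, grade 5 none, while nuclear density increases
#' with grade. Patient- and core-level mean shifts are added to the channel
#' intensities after rendering — a toy analogue of per-patient staining
#' variation, the mechanism by which patch-level cross-validation can leak
#' patient identity through color statistics alone.
#'
#' @param true_class One of `gleason_classes()`.
#' @param patient_shift,core_shift Length-3 numeric shifts added to the R, G,
#'   B channel means (values are clipped to `[0, 1]` afterwards; keep shifts
#'   within about ±0.25 so the shift survives clipping).
#' @param seed Integer seed; the raster is deterministic given all arguments.
#' @param size Image side length in pixels.
#' @return A `size x size x 3` numeric array in `[0, 1]`, with attribute
#'   `n_lumens` recording the number of gland lumens drawn.
#' @seealso [extract_features()]
#' @export
render_patch_image <- function(true_class,
                               patient_shift = c(0, 0, 0),
                               core_shift = c(0, 0, 0),
                               seed = 1L,
                               size = 64L) {
  .assert_classes(true_class, "true_class")
  if (length(true_class) != 1 || is.na(true_class))
    stop("true_class must be a single known class", call. = FALSE)
  stopifnot(length(patient_shift) == 3, length(core_shift) == 3)
  ci <- .severity(true_class)
  n_lumens <- c(7L, 4L, 2L, 0L)[ci]
  lumen_r <- c(8, 5.5, 3.5, 0)[ci]
  n_nuclei <- c(15L, 30L, 55L, 85L)[ci]

  set.seed(seed)
  stroma <- c(0.86, 0.70, 0.82) # eosin-pink background
  img <- array(0, dim = c(size, size, 3))
  for (ch in 1:3)
    img[, , ch] <- stroma[ch] + stats::rnorm(size * size, 0, 0.03)

  X <- matrix(seq_len(size), size, size)
  Y <- matrix(seq_len(size), size, size, byrow = TRUE)
  rim_col <- c(0.42, 0.28, 0.58)   # hematoxylin-purple epithelium
  lumen_col <- c(0.95, 0.93, 0.96) # open gland lumen

  if (n_lumens > 0) {
    for (i in seq_len(n_lumens)) {
      margin <- lumen_r + 3
      cx <- stats::runif(1, margin, size - margin)
      cy <- stats::runif(1, margin, size - margin)
      rx <- lumen_r * stats::runif(1, 0.75, 1.25)
      ry <- lumen_r * stats::runif(1, 0.75, 1.25)
      e <- ((X - cx) / rx)^2 + ((Y - cy) / ry)^2
      rim <- e <= 1.5
      lum <- e <= 1
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[rim] <- rim_col[ch]
        plane[lum] <- lumen_col[ch]
        img[, , ch] <- plane
      }
    }
  }
  # scattered nuclei: 2x2 dark dots, denser with grade
  nuc_col <- c(0.30, 0.18, 0.48)
  for (i in seq_len(n_nuclei)) {
    cx <- sample.int(size - 1L, 1)
    cy <- sample.int(size - 1L, 1)
    for (ch in 1:3) img[cx:(cx + 1L), cy:(cy + 1L), ch] <- nuc_col[ch]
  }

  for (ch in 1:3)
    img[, , ch] <- img[, , ch] + patient_shift[ch] + core_shift[ch]
  img[img < 0] <- 0
  img[img > 1] <- 1
  attr(img, "n_lumens") <- n_lumens
  img
}

#' Handcrafted features of a patch image
#'
#' Summarises an RGB raster by a fixed-length 7-vector: the three per-channel
#' means, three per-channel variances, and the edge density — the fraction of
#' interior pixels whose gray-level gradient magnitude exceeds 0.1. The
#' channel means carry the simulated patient/core staining shifts; the edge
#' density tracks glandular structure.
#'
#' @param image A numeric `h x w x 3` array.
#' @return Named numeric vector of length 7 (`r_mean`, `g_mean`, `b_mean`,
#'   `r_var`, `g_var`, `b_var`, `edge_density`).
#' @export
extract_features <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("image must be an h x w x 3 array", call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < 2 || w < 2 || h * w == 0) stop("empty image", call. = FALSE)

  means <- apply(image, 3, mean)
  vars <- apply(image, 3, function(m) stats::var(as.vector(m)))
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  gx <- gray[-1, , drop = FALSE] - gray[-h, , drop = FALSE]
  gy <- gray[, -1, drop = FALSE] - gray[, -w, drop = FALSE]
  mag <- sqrt(gx[, -w, drop = FALSE]^2 + gy[-h, , drop = FALSE]^2)
  edge <- mean(mag > 0.1)

  stats::setNames(c(means, as.numeric(vars), edge),
                  c("r_mean", "g_mean", "b_mean",
                    "r_var", "g_var", "b_var", "edge_density"))
}
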