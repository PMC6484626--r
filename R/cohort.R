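#' Configuration for a synthetic patch cohort
#'
#' Defines the hierarchical structure (patients contributing one or more
#' tissue cores, each core a grid of patches) and the feature-generating
#' model of a simulated cohort. Patch feature vectors follow
#' \deqn{x = \mu(\mathrm{class}) + u_{\mathrm{patient}} + v_{\mathrm{core}} + \varepsilon,}
#' where the class means are separated by `delta`, `u ~ N(0, sigma_p^2 I)` is
#' shared by all patches of a patient, `v ~ N(0, sigma_c^2 I)` by all patches
#' of a core, and `eps ~ N(0, sigma_e^2 I)` is patch noise. The patient and
#' core random effects are what make patch-level cross-validation leak:
#' a same-patient patch is closer in feature space than any other patient's.
#'
#' Defaults are the package's pinned study scenario, the single named
#' configuration under which the leakage and cross-expert demonstrations are
#' run and regression-tested.
#'
#' @param n_patients Number of patients.
#' @param cores_per_patient Either a single count, or a vector of candidate
#'   counts sampled uniformly per patient. The default `c(1, 2)` gives a
#'   50/50 mix of one- and two-core patients, so core-level and patient-level
#'   grouping genuinely differ (two cores of one patient can land in
#'   different core-level folds).
#' @param patches_per_core Patches tiled from each core.
#' @param class_prevalence Length-4 probability vector over
#'   `gleason_classes()`; must sum to 1.
#' @param feature_dim Feature vector length (ignored when `image_mode = TRUE`,
#'   where features come from [extract_features()] and have length 7).
#' @param delta Class-mean separation: class `c` (0-based) has mean
#'   `delta * e_(c mod feature_dim)`, so distinct classes on distinct axes are
#'   `delta * sqrt(2)` apart.
#' @param sigma_p,sigma_c,sigma_e Standard deviations of the patient, core
#'   and patch-level Gaussian effects (per coordinate).
#' @param image_mode If `TRUE`, render a toy histology image per patch and
#'   derive its features with [extract_features()]; patient/core effects act
#'   as stain-intensity shifts. Intended for small cohorts.
#' @param seed Root seed; every patient/core stream is derived from it by a
#'   stable hash, so identical configurations reproduce identical cohorts.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_patients = 200,
                       cores_per_patient = c(1, 2),
                       patches_per_core = 50,
                       class_prevalence = c(0.4, 0.3, 0.2, 0.1),
                       feature_dim = 8,
                       delta = 1,
                       sigma_p = 2,
                       sigma_c = 0.5,
                       sigma_e = 1,
                       image_mode = FALSE,
                       seed = 20190442) {
  stopifnot(length(n_patients) == 1, length(patches_per_core) == 1,
            length(feature_dim) == 1, length(seed) == 1)
  if (n_patients < 1 || patches_per_core < 1)
    stop("n_patients and patches_per_core must be >= 1", call. = FALSE)
  if (feature_dim < 1) stop("feature_dim must be >= 1", call. = FALSE)
  if (any(cores_per_patient < 1))
    stop("cores_per_patient values must be >= 1", call. = FALSE)
  if (length(class_prevalence) != 4 || any(class_prevalence < 0))
    stop("class_prevalence must be a nonnegative 4-vector", call. = FALSE)
  if (abs(sum(class_prevalence) - 1) > 1e-12)
    stop("class_prevalence must sum to 1 (within 1e-12)", call. = FALSE)
  if (sigma_p < 0 || sigma_c < 0 || sigma_e < 0)
    stop("sigma_p, sigma_c, sigma_e must be >= 0", call. = FALSE)
  structure(list(
    n_patients = as.integer(n_patients),
    cores_per_patient = as.integer(cores_per_patient),
    patches_per_core = as.integer(patches_per_core),
    class_prevalence = as.numeric(class_prevalence),
    feature_dim = as.integer(feature_dim),
    delta = as.numeric(delta),
    sigma_p = as.numeric(sigma_p),
    sigma_c = as.numeric(sigma_c),
    sigma_e = as.numeric(sigma_e),
    image_mode = isTRUE(image_mode),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' The pinned default study scenario
#'
#' Convenience wrapper around [sim_config()] returning the single named
#' configuration (200 patients with 1-2 cores, 50 patches per core,
#' prevalence 0.4/0.3/0.2/0.1, `delta = 1`, `sigma_p = 2`, `sigma_c = 0.5`,
#' `sigma_e = 1`, 8 features) under which the package's leakage and
#' cross-expert demonstrations are anchored. Any field can be overridden.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
default_scenario <- function(...) sim_config(...)

#' The pinned cross-expert study scenario
#'
#' Same cohort structure as [default_scenario()] but with the feature noise
#' scaled down (`sigma_p = 0.4`, `sigma_c = 0.2`, `sigma_e = 0.5`) so the
#' classifier carries real cross-patient signal. The leakage scenario
#' deliberately drowns the class separation in patient effects, which leaves
#' any classifier near chance on held-out patients — informative for
#' demonstrating leakage, but useless for studying how the choice of
#' training annotator propagates into agreement. The noise here is chosen so
#' the per-coordinate noise sd (`sqrt(sigma_p^2 + sigma_c^2 + sigma_e^2)
#' ~ 0.67`) puts pairwise class confusion, and hence classifier-vs-panel
#' quadratic-weighted kappa, in the moderate-agreement band typical of
#' published Gleason-grading classifiers.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
cross_expert_scenario <- function(...) {
  args <- list(...)
  defaults <- list(sigma_p = 0.4, sigma_c = 0.2, sigma_e = 0.5)
  do.call(sim_config, utils::modifyList(defaults, args))
}

#' Simulate a hierarchical patch cohort
#'
#' Draws a cohort of patients, cores and patches from the generative model in
#' [sim_config()]. Patch classes are i.i.d. from `class_prevalence`; feature
#' vectors add the class mean, patient effect, core effect and patch noise.
#' Identical configurations (including the seed) yield identical cohorts.
#'
#' @param config A [sim_config()].
#' @return An object of class `patch_cohort`: a list with data frames
#'   `patients` (`patient_id`), `cores` (`core_id`, `patient_id`) and
#'   `patches` (`patch_id`, `core_id`, `patient_id`, `true_class`, feature
#'   columns `f0..f{d-1}`), plus the `config`. When `image_mode` is set, an
#'   `images` list (one 64x64x3 array per patch) is attached.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 5, patches_per_core = 4))
#' head(coh$patches[, 1:4])
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be a sim_config object", call. = FALSE)
  root <- config$seed
  n <- config$n_patients
  patient_id <- sprintf("P%04d", seq_len(n))

  cpp <- config$cores_per_patient
  if (length(cpp) == 1L) {
    n_cores_i <- rep(cpp, n)
  } else {
    set.seed(.child_seed(root, "cores-per-patient"))
    n_cores_i <- sample(cpp, n, replace = TRUE)
  }

  d <- if (config$image_mode) 7L else config$feature_dim
  mu <- matrix(0, 4, config$feature_dim)
  for (c in 1:4) mu[c, ((c - 1L) %% config$feature_dim) + 1L] <- config$delta

  core_rows <- vector("list", n)
  patch_rows <- vector("list", n)
  images <- if (config$image_mode) list() else NULL
  core_counter <- 0L

  for (i in seq_len(n)) {
    pid <- patient_id[i]
    set.seed(.child_seed(root, paste0("patient:", pid)))
    u <- stats::rnorm(config$feature_dim, 0, config$sigma_p)

    cores_i <- sprintf("C%04d", core_counter + seq_len(n_cores_i[i]))
    core_counter <- core_counter + n_cores_i[i]
    core_rows[[i]] <- data.frame(core_id = cores_i, patient_id = pid,
                                 stringsAsFactors = FALSE)

    per_core <- vector("list", n_cores_i[i])
    for (j in seq_along(cores_i)) {
      cid <- cores_i[j]
      set.seed(.child_seed(root, paste0("core:", cid)))
      v <- stats::rnorm(config$feature_dim, 0, config$sigma_c)
      m <- config$patches_per_core
      cls <- sample(.CLASSES, m, replace = TRUE, prob = config$class_prevalence)
      pids <- sprintf("%s_p%03d", cid, seq_len(m))

      if (config$image_mode) {
        pshift <- pmax(pmin(u[1:3] * 0.05, 0.25), -0.25)
        cshift <- pmax(pmin(v[1:3] * 0.05, 0.25), -0.25)
        feats <- matrix(NA_real_, m, d)
        for (p in seq_len(m)) {
          img <- render_patch_image(cls[p], pshift, cshift,
                                    seed = .child_seed(root, paste0("img:", pids[p])))
          feats[p, ] <- extract_features(img)
          images[[pids[p]]] <- img
        }
      } else {
        eps <- matrix(stats::rnorm(m * d, 0, config$sigma_e), m, d)
        feats <- mu[.severity(cls), , drop = FALSE] +
          matrix(u, m, d, byrow = TRUE) +
          matrix(v, m, d, byrow = TRUE) + eps
      }
      df <- data.frame(patch_id = pids, core_id = cid, patient_id = pid,
                       true_class = cls, stringsAsFactors = FALSE)
      colnames(feats) <- paste0("f", seq_len(d) - 1L)
      per_core[[j]] <- cbind(df, as.data.frame(feats))
    }
    patch_rows[[i]] <- do.call(rbind, per_core)
  }

  cohort <- list(
    patients = data.frame(patient_id = patient_id, stringsAsFactors = FALSE),
    cores = do.call(rbind, core_rows),
    patches = do.call(rbind, patch_rows),
    config = config
  )
  rownames(cohort$cores) <- NULL
  rownames(cohort$patches) <- NULL
  if (config$image_mode) cohort$images <- images
  class(cohort) <- "patch_cohort"
  cohort
}

#' Extract the patch feature matrix of a cohort
#'
#' @param cohort A `patch_cohort`.
#' @return Numeric matrix (patches x features), rownames = patch ids.
#' @export
cohort_features <- function(cohort) {
  stopifnot(inherits(cohort, "patch_cohort"))
  fcols <- grep("^f[0-9]+$", names(cohort$patches), value = TRUE)
  m <- as.matrix(cohort$patches[, fcols, drop = FALSE])
  rownames(m) <- cohort$patches$patch_id
  m
}

#' @export
print.patch_cohort <- function(x, ...) {
  cat(sprintf("Synthetic patch cohort: %d patients, %d cores, %d patches\n",
              nrow(x$patients), nrow(x$cores), nrow(x$patches)))
  tab <- table(factor(x$patches$true_class, levels = .CLASSES))
  cat("Class counts:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("Features: %d-dimensional%s\n",
              ncol(cohort_features(x)),
              if (x$config$image_mode) " (image-derived)" else ""))
  invisible(x)
}

#' @export
summary.patch_cohort <- function(object, ...) {
  print(object)
  cpp <- table(table(object$patches$patient_id) /
                 object$config$patches_per_core)
  cat("Cores per patient:",
      paste(sprintf("%s core(s): %s patients", names(cpp), cpp), collapse = "; "),
      "\n")
  invisible(object)
}
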