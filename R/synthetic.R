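#' @title Synthetic lesion-phantom cohorts
#' @description Seeded two-class cohorts of 3D lesion phantoms standing in
#'   for the study's MRI data, which are not publicly deposited. Each phantom
#'   is an ellipsoidal lesion over a darker background; intra-lesion texture
#'   is a Gaussian random field (white noise smoothed per slice at a
#'   class-specific correlation length) passed through a class-specific
#'   monotone intensity transform that controls the skew of the intensity
#'   distribution, plus additive noise. Classes that differ in correlation
#'   length and distribution shape give genuine signal to GLCM, fractal and
#'   first-order features without modelling MRI physics; setting both class
#'   parameter sets equal defines a null cohort.
#' @name synthetic
NULL

#' Specification of a phantom cohort
#'
#' Defaults emulate the study cohort: 183 cases with 74 positives
#' (prevalence 74/183), lesions of 10 mm radius on a
#' 36 x 36 x 10 grid with 1.096 x 1.096 x 3 mm voxels (so planar resampling
#' to 0.548 mm is exercised downstream). The class texture parameters are
#' free knobs (the study reports no quantitative texture difference between
#' responders and non-responders); defaults give a clearly separable cohort.
#'
#' @param n_cases Number of cases.
#' @param prevalence_positive Fraction of positive (pCR) cases, in (0, 1);
#'   the label vector holds `round(n_cases * prevalence_positive)` positives.
#' @param grid_shape Length-3 integer voxel grid.
#' @param voxel_spacing_mm Length-3 positive voxel spacing.
#' @param lesion_radius_mm Ellipsoid radius in mm (per axis, capped by the
#'   grid so the mask stays interior).
#' @param texture_correlation_length_mm Named length-2 vector `c(neg=, pos=)`:
#'   Gaussian smoothing length of the intra-lesion random field per class.
#' @param intensity_shape Named length-2 vector `c(neg=, pos=)`: skewness
#'   control of the monotone transform `(exp(s*x)-1)/s` (0 = identity,
#'   larger = more right-skewed, heavier-tailed).
#' @param noise_sd Additive Gaussian noise SD in intensity units.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_cases = 183,
                         prevalence_positive = 74 / 183,
                         grid_shape = c(36L, 36L, 10L),
                         voxel_spacing_mm = c(1.096, 1.096, 3),
                         lesion_radius_mm = 10,
                         texture_correlation_length_mm = c(neg = 3.0, pos = 1.5),
                         intensity_shape = c(neg = 1.5, pos = 0),
                         noise_sd = 20,
                         seed = 1L) {
  if (!(prevalence_positive > 0 && prevalence_positive < 1))
    stop("`prevalence_positive` must lie strictly in (0, 1)", call. = FALSE)
  if (n_cases < 2) stop("`n_cases` must be at least 2", call. = FALSE)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            length(voxel_spacing_mm) == 3, all(voxel_spacing_mm > 0),
            lesion_radius_mm > 0, noise_sd >= 0)
  for (nm in c("neg", "pos")) {
    if (!nm %in% names(texture_correlation_length_mm) ||
        !nm %in% names(intensity_shape))
      stop("class parameters must be named 'neg' and 'pos'", call. = FALSE)
  }
  extent <- grid_shape * voxel_spacing_mm
  if (any(lesion_radius_mm > extent / 2 - voxel_spacing_mm))
    stop(sprintf(
      "lesion radius %.1f mm does not fit inside the %s mm grid",
      lesion_radius_mm, paste(round(extent, 1), collapse = " x ")), call. = FALSE)
  structure(
    list(n_cases = as.integer(n_cases),
         prevalence_positive = prevalence_positive,
         grid_shape = as.integer(grid_shape),
         voxel_spacing_mm = as.numeric(voxel_spacing_mm),
         lesion_radius_mm = lesion_radius_mm,
         texture_correlation_length_mm = texture_correlation_length_mm[c("neg", "pos")],
         intensity_shape = intensity_shape[c("neg", "pos")],
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# monotone skewing transform; s = 0 is the identity
skew_transform <- function(x, s) {
  if (abs(s) < 1e-12) x else (exp(s * x) - 1) / s
}

generate_phantom <- function(spec, class_label) {
  cls <- if (class_label == 1L) "pos" else "neg"
  d <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  corr <- spec$texture_correlation_length_mm[[cls]]
  shape <- spec$intensity_shape[[cls]]
  # ellipsoidal lesion mask at the grid centre
  centre <- d * sp / 2
  cx <- (seq_len(d[1]) - 0.5) * sp[1]
  cy <- (seq_len(d[2]) - 0.5) * sp[2]
  cz <- (seq_len(d[3]) - 0.5) * sp[3]
  r2 <- outer(outer(((cx - centre[1]) / spec$lesion_radius_mm)^2,
                    ((cy - centre[2]) / spec$lesion_radius_mm)^2, "+"),
              ((cz - centre[3]) / spec$lesion_radius_mm)^2, "+")
  mask <- r2 <= 1
  # planar-smoothed Gaussian random field
  field <- array(stats::rnorm(prod(d)), d)
  k <- gaussian_kernel_2d(c(corr / sp[1], corr / sp[2]))
  for (s in seq_len(d[3])) field[, , s] <- conv2d_replicate(field[, , s], k)
  field <- (field - mean(field)) / stats::sd(field)
  field <- skew_transform(field, shape)
  field <- (field - mean(field)) / stats::sd(field)
  ints <- array(120, d)                      # darker background
  ints[mask] <- 400 + 80 * field[mask]       # textured lesion
  ints <- ints + array(stats::rnorm(prod(d), sd = spec$noise_sd), d)
  volume_with_mask(ints, sp, mask)
}

#' Generate a seeded cohort of lesion phantoms
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `synthetic_cohort`: list with `cases` (list of
#'   [volume_with_mask()]), `labels` (integer, 1 = pCR) and the spec.
#'   Regenerating with the same spec reproduces identical voxel data.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    n_pos <- round(spec$n_cases * spec$prevalence_positive)
    labels <- sample(rep(c(1L, 0L), c(n_pos, spec$n_cases - n_pos)))
    cases <- lapply(labels, function(lb) generate_phantom(spec, lb))
  })
  structure(list(cases = cases, labels = labels, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cases (%d pCR), grid %s, seed %d\n",
              length(x$cases), sum(x$labels),
              paste(x$spec$grid_shape, collapse = "x"), x$spec$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk as NIfTI volumes plus labels
#'
#' Each case is written as `case_<i>_image.nii` / `case_<i>_mask.nii`;
#' labels go to `labels.csv` and the generating spec to `spec.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$cases)) {
    write_volume_nifti(cohort$cases[[i]],
                       file.path(dir, sprintf("case_%03d_image.nii", i)),
                       file.path(dir, sprintf("case_%03d_mask.nii", i)))
  }
  utils::write.csv(
    data.frame(case_id = sprintf("case_%03d", seq_along(cohort$cases)),
               pcr = cohort$labels),
    file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(cohort$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate a synthetic case-by-feature table directly
#'
#' Fast fixture for the selection and modelling stages: `n_informative`
#' columns carry a class mean shift of `effect_size` (standardised mean
#' difference, unit-variance noise); the rest are class-independent. An
#' optional block structure (consecutive blocks of `block_size` columns
#' sharing a latent factor with correlation `block_rho`) exercises the
#' Pearson pruning stage.
#'
#' @param n_cases,n_features Positive counts.
#' @param n_informative Number of informative columns (first columns;
#'   must not exceed `n_features`).
#' @param effect_size Standardised mean difference between classes.
#' @param prevalence Positive-class fraction in (0, 1).
#' @param seed Integer seed.
#' @param block_size,block_rho Optional equicorrelated block structure
#'   (default none).
#' @return A [feature_table()] with feature ids `f0001`, `f0002`, ...
#' @export
generate_feature_table <- function(n_cases, n_features, n_informative = 0,
                                   effect_size = 0, prevalence = 0.4,
                                   seed = 1L, block_size = 1, block_rho = 0) {
  if (n_cases < 2 || n_features < 1)
    stop("`n_cases` and `n_features` must be positive", call. = FALSE)
  if (n_informative > n_features)
    stop("`n_informative` cannot exceed `n_features`", call. = FALSE)
  if (!(prevalence > 0 && prevalence < 1))
    stop("`prevalence` must lie strictly in (0, 1)", call. = FALSE)
  withr::with_seed(seed, {
    n_pos <- round(n_cases * prevalence)
    labels <- sample(rep(c(1L, 0L), c(n_pos, n_cases - n_pos)))
    x <- matrix(stats::rnorm(n_cases * n_features), n_cases, n_features)
    if (block_size > 1 && block_rho > 0) {
      blocks <- split(seq_len(n_features),
                      ceiling(seq_len(n_features) / block_size))
      for (b in blocks) {
        z <- stats::rnorm(n_cases)
        x[, b] <- sqrt(block_rho) * z + sqrt(1 - block_rho) * x[, b]
      }
    }
    if (n_informative > 0)
      x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] +
        effect_size * labels
  })
  colnames(x) <- sprintf("f%04d", seq_len(n_features))
  feature_table(x, labels, case_ids = sprintf("case_%04d", seq_len(n_cases)))
}
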