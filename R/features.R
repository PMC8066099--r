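#' @title Radiomic feature families
#' @description First-order statistics computed on LoG-filtered images, and
#'   grey-level co-occurrence (GLCM), box-counting fractal and morphological
#'   features computed on intensity-based subpopulation masks. Feature values
#'   use population-moment conventions (variance with denominator n; Pearson
#'   kurtosis, so a normal distribution gives 3). Features on an empty or
#'   too-small subpopulation return `NA`, the missing sentinel.
#' @name features
NULL

first_order_names <- c(
  "mean", "variance", "sd", "skewness", "kurtosis", "energy", "entropy",
  "minimum", "maximum", "median", "p10", "p90", "iqr", "range", "mad",
  "rmad", "rms", "uniformity"
)
glcm_names <- c(
  "contrast", "correlation", "energy", "homogeneity", "entropy",
  "cluster_shade", "cluster_prominence"
)
fractal_names <- c("fd_mean", "fd_sd", "fd_max")
morphology_names <- c(
  "volume_mm3", "surface_mm2", "sphericity", "max_planar_diameter_mm",
  "n_components"
)

na_features <- function(names) stats::setNames(rep(NA_real_, length(names)), names)

#' First-order intensity statistics over an ROI
#'
#' @param img A numeric vector of ROI intensities, a 3D array, or a
#'   [volume_with_mask()].
#' @param mask Optional 3D logical mask (required when `img` is an array).
#' @param n_bins Number of fixed-width histogram bins for entropy and
#'   uniformity (default 64, over the observed ROI range).
#' @return Named numeric vector (see `first_order_names`); all `NA` when the
#'   mask is empty.
#' @export
first_order_features <- function(img, mask = NULL, n_bins = 64) {
  x <- if (inherits(img, "volume_with_mask")) roi_values(img)
       else if (is.array(img)) img[as.logical(mask)]
       else as.numeric(img)
  n <- length(x)
  if (n == 0L) return(na_features(first_order_names))
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  qs <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  rng <- range(x)
  if (rng[2] > rng[1]) {
    lev <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
    p <- tabulate(lev, n_bins) / n
    p <- p[p > 0]
  } else p <- 1
  core <- x[x >= qs[1] & x <= qs[4]]
  c(mean = mu, variance = m2, sd = sqrt(m2), skewness = skew, kurtosis = kurt,
    energy = sum(x^2), entropy = -sum(p * log2(p)),
    minimum = rng[1], maximum = rng[2], median = stats::median(x),
    p10 = qs[1], p90 = qs[4], iqr = qs[3] - qs[2], range = rng[2] - rng[1],
    mad = mean(abs(x - mu)), rmad = mean(abs(core - mean(core))),
    rms = sqrt(mean(x^2)), uniformity = sum(p^2))
}

# shift a matrix by (dr, dc), exposing NA at the vacated border
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA, nr, nc)
  sr <- max(1, 1 - dr):min(nr, nr - dr)
  sc <- max(1, 1 - dc):min(nc, nc - dc)
  out[sr, sc] <- m[sr + dr, sc + dc, drop = FALSE]
  out
}

glcm_offsets <- list(
  horizontal = c(0L, 1L), vertical = c(1L, 0L),
  diagonal = c(1L, 1L), antidiagonal = c(1L, -1L)
)

#' Grey-level co-occurrence matrix aggregated over axial slices
#'
#' Intensities at masked voxels are discretised to `n_bins` equal-width levels
#' (over `range_limits`, or the observed masked range if `NULL`); symmetric
#' co-occurrences are accumulated per slice over the requested planar
#' directions at the given pixel distance, summed across directions and
#' slices, and normalised to a probability matrix.
#'
#' @param img 3D numeric array (or [volume_with_mask()], whose ROI then serves
#'   as default mask).
#' @param mask 3D logical array selecting the voxel subpopulation.
#' @param n_bins Number of grey levels (default 32).
#' @param distance Pixel offset distance (default 1).
#' @param range_limits Length-2 discretisation range, e.g. `c(0, 1)` for
#'   IB-normalised images; `NULL` uses the masked value range.
#' @param directions Subset of `c("horizontal","vertical","diagonal","antidiagonal")`.
#' @return A symmetric `n_bins` x `n_bins` probability matrix, or `NULL` when
#'   no valid co-occurrence pair exists.
#' @export
glcm_matrix <- function(img, mask = NULL, n_bins = 32, distance = 1,
                        range_limits = NULL,
                        directions = names(glcm_offsets)) {
  if (inherits(img, "volume_with_mask")) {
    if (is.null(mask)) mask <- img$mask
    img <- img$intensities
  }
  mask <- array(as.logical(mask), dim = dim(img))
  if (sum(mask) < 2L) return(NULL)
  vals <- img[mask]
  rng <- if (is.null(range_limits)) range(vals) else as.numeric(range_limits)
  lev <- array(NA_integer_, dim = dim(img))
  lev[mask] <- if (rng[2] > rng[1])
    pmin(pmax(floor((vals - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, 1L), n_bins)
  else 1L
  counts <- matrix(0, n_bins, n_bins)
  offs <- glcm_offsets[match.arg(directions, names(glcm_offsets), several.ok = TRUE)]
  for (s in seq_len(dim(img)[3])) {
    ls <- lev[, , s]
    if (all(is.na(ls))) next
    for (off in offs) {
      nb <- shift_matrix(ls, off[1] * distance, off[2] * distance)
      ok <- !is.na(ls) & !is.na(nb)
      if (!any(ok)) next
      a <- ls[ok]; b <- nb[ok]
      counts <- counts + matrix(tabulate((a - 1L) * n_bins + b, n_bins * n_bins),
                                n_bins, n_bins, byrow = TRUE)
    }
  }
  counts <- counts + t(counts)   # symmetric accumulation
  tot <- sum(counts)
  if (tot == 0) return(NULL)
  counts / tot
}

#' Texture features from a GLCM probability matrix
#'
#' Computes contrast, correlation, angular second moment (energy),
#' homogeneity, entropy, cluster shade
#' \eqn{\sum_{ij}(i+j-\mu_i-\mu_j)^3 p(i,j)} and cluster prominence (its
#' fourth-power analogue). Cluster shade is the third co-occurrence moment
#' measuring asymmetry of the joint grey-level distribution; it is the most
#' important predictor in the study's final model.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector (see `glcm_names`); all `NA` when no valid
#'   pair exists.
#' @export
glcm_features <- function(img, mask = NULL, n_bins = 32, distance = 1,
                          range_limits = NULL,
                          directions = names(glcm_offsets)) {
  p <- glcm_matrix(img, mask, n_bins, distance, range_limits, directions)
  if (is.null(p)) return(na_features(glcm_names))
  glcm_stats(p)
}

#' Texture statistics from an explicit co-occurrence probability matrix
#'
#' @param p Square probability matrix summing to 1.
#' @return Named numeric vector (see `glcm_names`).
#' @export
glcm_stats <- function(p) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p), abs(sum(p) - 1) < 1e-8)
  nb <- nrow(p)
  i <- matrix(seq_len(nb), nb, nb)
  j <- t(i)
  pi_ <- rowSums(p); pj <- colSums(p)
  mui <- sum(seq_len(nb) * pi_); muj <- sum(seq_len(nb) * pj)
  si <- sqrt(sum((seq_len(nb) - mui)^2 * pi_))
  sj <- sqrt(sum((seq_len(nb) - muj)^2 * pj))
  corr <- if (si * sj > 1e-12) (sum(i * j * p) - mui * muj) / (si * sj) else 1
  pp <- p[p > 0]
  c(contrast = sum((i - j)^2 * p),
    correlation = corr,
    energy = sum(p^2),
    homogeneity = sum(p / (1 + abs(i - j))),
    entropy = -sum(pp * log2(pp)),
    cluster_shade = sum((i + j - mui - muj)^3 * p),
    cluster_prominence = sum((i + j - mui - muj)^4 * p))
}

#' Box-counting fractal dimension of a planar binary mask
#'
#' Counts occupied boxes N(eps) over dyadic box sizes anchored at the mask's
#' bounding box and returns the least-squares slope of log N(eps) versus
#' log(1/eps). A filled square tends to 2, a line to 1, an isolated pixel
#' gives 0.
#'
#' @param mask2d Logical matrix.
#' @return Dimension estimate in \[0, 2\], or `NA` for an empty mask.
#' @export
box_count_dimension <- function(mask2d) {
  idx <- which(mask2d, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NA_real_)
  r <- idx[, 1] - min(idx[, 1])
  c_ <- idx[, 2] - min(idx[, 2])
  maxdim <- max(max(r), max(c_)) + 1L
  k <- ceiling(log2(maxdim))
  if (k < 1L) return(0)
  sizes <- 2^(0:(k - 1L))
  n_boxes <- vapply(sizes, function(e) {
    length(unique(floor(r / e) * 2^30 + floor(c_ / e)))
  }, numeric(1))
  if (length(unique(n_boxes)) == 1L) return(0)
  unname(stats::coef(stats::lm(log(n_boxes) ~ log(1 / sizes)))[2])
}

#' Per-slice fractal dimensions of a subpopulation mask
#'
#' Box-counting dimension of each axial slice holding at least one masked
#' pixel; returns their mean, standard deviation and maximum (the study's
#' "maximum fractal dimension" is `fd_max`).
#'
#' @param mask 3D logical array (or a `volume_with_mask`, whose mask is used).
#' @return Named numeric vector (see `fractal_names`); all `NA` when every
#'   slice is empty.
#' @export
fractal_features <- function(mask) {
  if (inherits(mask, "volume_with_mask")) mask <- mask$mask
  dims <- apply(mask, 3, function(sl) box_count_dimension(sl))
  dims <- dims[!is.na(dims)]
  if (length(dims) == 0L) return(na_features(fractal_names))
  c(fd_mean = mean(dims),
    fd_sd = if (length(dims) > 1L) stats::sd(dims) else 0,
    fd_max = max(dims))
}

# 8-connected labelling of a planar mask (pixel adjacency graph components)
label_components_8 <- function(mask2d) {
  n <- sum(mask2d)
  out <- matrix(0L, nrow(mask2d), ncol(mask2d))
  if (n == 0L) return(out)
  ids <- matrix(0L, nrow(mask2d), ncol(mask2d))
  ids[mask2d] <- seq_len(n)
  edges <- integer(0)
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    nb <- shift_matrix(ids, o[1], o[2])
    ok <- mask2d & !is.na(nb) & nb > 0L
    if (any(ok)) edges <- c(edges, rbind(ids[ok], nb[ok]))
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  out[mask2d] <- as.integer(igraph::components(g)$membership)
  out
}

#' Morphological features of a subpopulation mask
#'
#' Volume (voxel count times voxel volume), a surface proxy (exposed voxel
#' faces times face area), a sphericity index
#' \eqn{\pi^{1/3}(6V)^{2/3}/A}, the maximum in-plane diameter (largest
#' pixel-centre distance within any single slice) and the total number of
#' 8-connected planar components.
#'
#' @param mask 3D logical array or `volume_with_mask`.
#' @param spacing_mm Length-3 voxel spacing in millimetres (taken from the
#'   volume when one is supplied).
#' @return Named numeric vector (see `morphology_names`); all `NA` when the
#'   mask is empty.
#' @export
morphology_features <- function(mask, spacing_mm = NULL) {
  if (inherits(mask, "volume_with_mask")) {
    spacing_mm <- mask$spacing_mm
    mask <- mask$mask
  }
  stopifnot(length(spacing_mm) == 3)
  nvox <- sum(mask)
  if (nvox == 0L) return(na_features(morphology_names))
  vol <- nvox * prod(spacing_mm)
  d <- dim(mask)
  face_area <- c(spacing_mm[2] * spacing_mm[3],  # faces normal to axis 1
                 spacing_mm[1] * spacing_mm[3],
                 spacing_mm[1] * spacing_mm[2])
  surf <- 0
  for (ax in 1:3) {
    for (sgn in c(-1L, 1L)) {
      nb <- array(FALSE, d)
      idx_src <- idx_dst <- lapply(d, seq_len)
      if (sgn == 1L) { idx_dst[[ax]] <- seq_len(d[ax] - 1L); idx_src[[ax]] <- 2:d[ax] }
      else { idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- seq_len(d[ax] - 1L) }
      if (d[ax] > 1L)
        nb[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
          mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
      surf <- surf + sum(mask & !nb) * face_area[ax]
    }
  }
  spher <- pi^(1 / 3) * (6 * vol)^(2 / 3) / surf
  maxdiam <- 0
  ncomp <- 0L
  for (s in seq_len(d[3])) {
    sl <- mask[, , s]
    if (!any(sl)) next
    ncomp <- ncomp + max(label_components_8(sl))
    pts <- which(sl, arr.ind = TRUE)
    xy <- cbind((pts[, 1] - 0.5) * spacing_mm[1], (pts[, 2] - 0.5) * spacing_mm[2])
    if (nrow(xy) > 3L) xy <- xy[grDevices::chull(xy), , drop = FALSE]
    if (nrow(xy) >= 2L) maxdiam <- max(maxdiam, max(stats::dist(xy)))
  }
  c(volume_mm3 = vol, surface_mm2 = surf, sphericity = spher,
    max_planar_diameter_mm = maxdiam, n_components = as.numeric(ncomp))
}

#' Configuration of the radiomic feature bank
#'
#' The bank follows the study's structural skeleton: first-order features on
#' every LoG scale, and GLCM/fractal/morphology features on every IB
#' threshold-pair subpopulation, so the census is
#' `length(sigmas) * 18 + n_pairs * 15` with the default families.
#'
#' @param sigmas LoG scale grid in mm (default [sigma_grid()], 13 scales).
#' @param ib_step_pct IB threshold level step in percent (default 10, giving
#'   55 pairs).
#' @param glcm_bins,glcm_distance GLCM discretisation levels and pixel
#'   distance (defaults 32 and 1).
#' @param fo_bins First-order histogram bins (default 64).
#' @param min_subpop_voxels Minimum subpopulation size for GLCM and fractal
#'   validity (default 8; smaller subpopulations yield the missing sentinel).
#' @return An object of class `bank_config`.
#' @export
bank_config <- function(sigmas = sigma_grid(), ib_step_pct = 10,
                        glcm_bins = 32, glcm_distance = 1, fo_bins = 64,
                        min_subpop_voxels = 8) {
  stopifnot(all(sigmas >= 0), glcm_bins >= 2, glcm_distance >= 1)
  structure(
    list(sigmas = as.numeric(sigmas),
         ib_step_pct = as.integer(ib_step_pct),
         ib_pairs = ib_threshold_pairs(ib_step_pct),
         glcm_bins = as.integer(glcm_bins),
         glcm_distance = as.integer(glcm_distance),
         fo_bins = as.integer(fo_bins),
         min_subpop_voxels = as.integer(min_subpop_voxels)),
    class = "bank_config"
  )
}

#' @export
print.bank_config <- function(x, ...) {
  cat(sprintf(
    "<bank_config> %d LoG scales x %d first-order + %d IB pairs x %d features = %d features\n",
    length(x$sigmas), length(first_order_names), nrow(x$ib_pairs),
    length(glcm_names) + length(fractal_names) + length(morphology_names),
    bank_census(x)))
  invisible(x)
}

#' Feature census implied by a bank configuration
#' @param config A [bank_config()].
#' @return Integer feature count.
#' @export
bank_census <- function(config) {
  length(config$sigmas) * length(first_order_names) +
    nrow(config$ib_pairs) *
      (length(glcm_names) + length(fractal_names) + length(morphology_names))
}

#' Extract the full radiomic feature bank for one case
#'
#' For each LoG scale the first-order family is computed on the filtered
#' image within the ROI; the volume is then IB-normalised and, for each
#' threshold pair, GLCM, fractal and morphological families are computed on
#' the subpopulation mask. Empty or too-small subpopulations propagate `NA`
#' without aborting.
#'
#' @param case A [volume_with_mask()], already resampled.
#' @param config A [bank_config()].
#' @return Named numeric vector of length [bank_census()]; names are
#'   structured feature identifiers (`filter:params:family:name`, see
#'   [parse_feature_ids()]).
#' @export
extract_bank <- function(case, config = bank_config()) {
  stopifnot(inherits(case, "volume_with_mask"), inherits(config, "bank_config"))
  out <- numeric(0)
  for (s in config$sigmas) {
    f <- log_filter(case, s)
    fo <- first_order_features(f$intensities[f$mask], n_bins = config$fo_bins)
    names(fo) <- sprintf("log:%.2f:first_order:%s", s, first_order_names)
    out <- c(out, fo)
  }
  nv <- ib_normalize(case)
  for (r in seq_len(nrow(config$ib_pairs))) {
    l <- config$ib_pairs$lower_pct[r]; u <- config$ib_pairs$upper_pct[r]
    sub <- subpopulation_mask(nv, l, u)
    nsub <- sum(sub)
    gl <- if (nsub >= config$min_subpop_voxels)
      glcm_features(nv$intensities, sub, n_bins = config$glcm_bins,
                    distance = config$glcm_distance, range_limits = c(0, 1))
    else na_features(glcm_names)
    fr <- if (nsub >= config$min_subpop_voxels) fractal_features(sub)
          else na_features(fractal_names)
    mo <- if (nsub >= 1L) morphology_features(sub, nv$spacing_mm)
          else na_features(morphology_names)
    names(gl) <- sprintf("ib:%d:%d:glcm:%s", l, u, glcm_names)
    names(fr) <- sprintf("ib:%d:%d:fractal:%s", l, u, fractal_names)
    names(mo) <- sprintf("ib:%d:%d:morphology:%s", l, u, morphology_names)
    out <- c(out, gl, fr, mo)
  }
  out
}

#' Parse structured feature identifiers back into their parts
#'
#' @param ids Character vector of feature identifiers as produced by
#'   [extract_bank()].
#' @return Data frame with columns `filter`, `sigma_mm`, `lower_pct`,
#'   `upper_pct`, `family`, `name`.
#' @export
parse_feature_ids <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  out <- data.frame(
    id = ids,
    filter = vapply(parts, `[`, "", 1L),
    sigma_mm = NA_real_, lower_pct = NA_integer_, upper_pct = NA_integer_,
    family = NA_character_, name = NA_character_,
    stringsAsFactors = FALSE
  )
  is_log <- out$filter == "log"
  is_ib <- out$filter == "ib"
  out$sigma_mm[is_log] <- as.numeric(vapply(parts[is_log], `[`, "", 2L))
  out$family[is_log] <- vapply(parts[is_log], `[`, "", 3L)
  out$name[is_log] <- vapply(parts[is_log], `[`, "", 4L)
  out$lower_pct[is_ib] <- as.integer(vapply(parts[is_ib], `[`, "", 2L))
  out$upper_pct[is_ib] <- as.integer(vapply(parts[is_ib], `[`, "", 3L))
  out$family[is_ib] <- vapply(parts[is_ib], `[`, "", 4L)
  out$name[is_ib] <- vapply(parts[is_ib], `[`, "", 5L)
  other <- !(is_log | is_ib)
  out$name[other] <- out$id[other]
  out$family[other] <- "synthetic"
  out
}
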