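## Texture feature engine.
##
## All features are computed in 2D on axial slices and then averaged across
## the usable slices of an ROI. Five families, 41 features in total:
## 12 histogram + 5 GLCM + 11 GLRL + 4 GLGM + 9 Laws.

.feature_families <- list(
  histogram = c("mean", "median", "sd", "variance", "skewness", "kurtosis",
                "energy", "entropy", "min", "max", "range", "iqr"),
  glcm = c("contrast", "correlation", "energy", "homogeneity", "entropy"),
  glrl = c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
           "SRLGE", "SRHGE", "LRLGE", "LRHGE"),
  glgm = c("MGR", "VGR", "skewness", "kurtosis"),
  laws = c("L3L3", "L3E3", "L3S3", "E3L3", "E3E3", "E3S3",
           "S3L3", "S3E3", "S3S3")
)

#' Canonical texture feature names
#'
#' Returns the `<family>.<name>` keys of the texture features, 41 in total
#' across the five families (12 histogram, 5 GLCM, 11 GLRL, 4 GLGM, 9 Laws).
#'
#' @param families Subset of `c("histogram","glcm","glrl","glgm","laws")`.
#' @return Character vector of feature keys, with a `families` attribute
#'   giving the per-family split.
#' @export
dect_feature_names <- function(families = names(.feature_families)) {
  families <- match.arg(families, names(.feature_families), several.ok = TRUE)
  out <- unlist(lapply(families, function(f)
    paste(f, .feature_families[[f]], sep = ".")), use.names = FALSE)
  attr(out, "families") <- vapply(.feature_families[families], length, 1L)
  out
}

#' Quantize intensities to discrete gray levels
#'
#' Linear binning of intensities into `n_levels` levels `0..n_levels-1`,
#' monotone in the input. By default the bin range is the min--max of the
#' (in-ROI) values themselves ("roi-min-max"); a fixed window can be given
#' instead, in which case out-of-window values are clamped to the extreme
#' levels. `NA`s (out-of-mask voxels) are preserved.
#'
#' @param x Numeric vector, matrix or array of intensities (HU).
#' @param n_levels Number of gray levels (>= 2); default 64.
#' @param range Optional fixed `c(lo, hi)` window; `NULL` uses the observed
#'   range. A constant input maps entirely to level 0.
#' @return Integer levels with the same shape as `x`.
#' @export
quantize <- function(x, n_levels = 64L, range = NULL) {
  if (!length(x) || all(is.na(x)))
    stop("ROI error: no values to quantize", call. = FALSE)
  if (n_levels < 2) stop("n_levels must be >= 2", call. = FALSE)
  if (is.null(range)) range <- base::range(x, na.rm = TRUE)
  if (length(range) != 2 || range[1] > range[2])
    stop("quantization range must be an ordered pair", call. = FALSE)
  lo <- range[1]; hi <- range[2]
  out <- x
  if (hi <= lo) {
    out[!is.na(x)] <- 0L
  } else {
    lv <- floor((x - lo) / (hi - lo) * n_levels)
    out <- pmax(0, pmin(n_levels - 1, lv))
  }
  storage.mode(out) <- "integer"
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

pop_skew_kurt <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(c(skewness = 0, kurtosis = 0))
  c(skewness = mean((x - m)^3) / m2^1.5,
    kurtosis = mean((x - m)^4) / m2^2)
}

#' First-order (histogram) features of ROI intensities
#'
#' Twelve first-order statistics on the raw, unquantized intensities: mean,
#' median, SD, variance, skewness, kurtosis, histogram energy, histogram
#' entropy (256 bins over the observed range, base-2), min, max, range and
#' interquartile range. Skewness and kurtosis use the population (biased)
#' moment definitions and kurtosis is non-excess; both are defined as 0 for
#' constant input. SD/variance use the usual n-1 denominator.
#'
#' @param x Numeric vector of in-ROI intensities.
#' @param n_bins Bins for the energy/entropy histogram.
#' @return Named numeric vector of the 12 features.
#' @export
histogram_features <- function(x, n_bins = 256L) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("ROI error: empty intensity sample", call. = FALSE)
  sk <- pop_skew_kurt(x)
  r <- range(x)
  if (r[2] > r[1]) {
    b <- pmin(n_bins, 1L + floor((x - r[1]) / (r[2] - r[1]) * n_bins))
    p <- tabulate(b, n_bins) / length(x)
  } else {
    p <- 1
  }
  p <- p[p > 0]
  s <- if (length(x) > 1) stats::sd(x) else 0
  c(mean = mean(x), median = stats::median(x), sd = s, variance = s^2,
    skewness = unname(sk["skewness"]), kurtosis = unname(sk["kurtosis"]),
    energy = sum(p^2), entropy = -sum(p * log2(p)),
    min = r[1], max = r[2], range = r[2] - r[1],
    iqr = unname(diff(stats::quantile(x, c(0.25, 0.75)))))
}

# The four 2D offsets used for both GLCM and GLRL: 0, 45, 90, 135 degrees
# in (d_row, d_col) matrix convention, 0 degrees running along a row.
# Matrices are symmetrized, so signs are immaterial.
.texture_offsets <- list(`0` = c(0L, 1L), `45` = c(1L, 1L),
                         `90` = c(1L, 0L), `135` = c(1L, -1L))

angle_offsets <- function(angles) {
  key <- as.character(angles)
  if (!all(key %in% names(.texture_offsets)))
    stop("angles must be a subset of 0, 45, 90, 135", call. = FALSE)
  .texture_offsets[key]
}

masked_levels <- function(levels, mask) {
  lv <- levels
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(levels)))
    lv[!mask] <- NA_integer_
  }
  lv
}

glcm_counts <- function(lv, dr, dc, n_levels) {
  nr <- nrow(lv); nc <- ncol(lv)
  ri <- seq.int(max(1, 1 - dr), min(nr, nr - dr))
  ci <- seq.int(max(1, 1 - dc), min(nc, nc - dc))
  if (!length(ri) || !length(ci)) return(matrix(0, n_levels, n_levels))
  a <- lv[ri, ci, drop = FALSE]
  b <- lv[ri + dr, ci + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, n_levels, n_levels))
  counts <- tabulate(a[ok] * n_levels + b[ok] + 1L, nbins = n_levels^2)
  matrix(counts, n_levels, n_levels, byrow = TRUE)
}

glcm_features_from_p <- function(p) {
  idx <- seq_len(nrow(p)) - 1
  dif2 <- outer(idx, idx, function(a, b) (a - b)^2)
  pi_ <- rowSums(p); pj <- colSums(p)
  mi <- sum(idx * pi_); mj <- sum(idx * pj)
  vi <- sum((idx - mi)^2 * pi_); vj <- sum((idx - mj)^2 * pj)
  corr <- if (vi <= 0 || vj <= 0) 0 else
    (sum(p * outer(idx, idx)) - mi * mj) / sqrt(vi * vj)
  pp <- p[p > 0]
  c(contrast = sum(p * dif2),
    correlation = corr,
    energy = sum(p^2),
    homogeneity = sum(p / (1 + dif2)),
    entropy = -sum(pp * log2(pp)))
}

#' Gray-level co-occurrence matrix features
#'
#' Co-occurrence counts are accumulated between pairs of in-mask voxels at
#' distance 1 along the four 2D directions (0/45/90/135 degrees); each
#' directional matrix is symmetrized and normalized to sum 1, the five
#' Haralick-type features (contrast, correlation, energy, homogeneity,
#' entropy; entropy in bits, homogeneity as the inverse difference moment)
#' are computed per direction and averaged over directions that contain at
#' least one pair. A constant ROI gives contrast 0, energy 1, homogeneity 1,
#' entropy 0 and correlation 0 (the degenerate-variance convention).
#'
#' @param levels Integer level matrix from [quantize()] (`NA` = outside ROI).
#' @param mask Optional logical matrix; `FALSE` voxels are excluded.
#' @param n_levels Number of gray levels; defaults to `max(levels) + 1`.
#' @param distance Pair offset in voxels along each direction.
#' @param angles Directions in degrees, subset of `c(0, 45, 90, 135)`;
#'   0 degrees runs along a matrix row.
#' @return Named numeric vector of the 5 features.
#' @export
glcm_features <- function(levels, mask = NULL, n_levels = NULL,
                          distance = 1L, angles = c(0, 45, 90, 135)) {
  lv <- masked_levels(levels, mask)
  if (all(is.na(lv))) stop("ROI error: empty level image", call. = FALSE)
  if (is.null(n_levels)) n_levels <- max(lv, na.rm = TRUE) + 1L
  acc <- NULL; used <- 0L
  for (off in angle_offsets(angles)) {
    cnt <- glcm_counts(lv, off[1] * distance, off[2] * distance, n_levels)
    cnt <- cnt + t(cnt)
    tot <- sum(cnt)
    if (tot == 0) next
    f <- glcm_features_from_p(cnt / tot)
    acc <- if (is.null(acc)) f else acc + f
    used <- used + 1L
  }
  if (used == 0L)
    stop("ROI error: no in-mask voxel pairs for GLCM", call. = FALSE)
  acc / used
}

extract_lines <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  if (dr == 0L && dc == 1L)
    return(lapply(seq_len(nr), function(i) m[i, ]))
  if (dr == 1L && dc == 0L)
    return(lapply(seq_len(nc), function(j) m[, j]))
  lines <- vector("list", nr + nc - 1L)
  if (dr == 1L && dc == 1L) {
    for (s in seq.int(-(nr - 1L), nc - 1L)) {
      i <- seq_len(nr); j <- i + s
      ok <- j >= 1 & j <= nc
      lines[[s + nr]] <- m[cbind(i[ok], j[ok])]
    }
  } else {  # dr == 1, dc == -1
    for (s in seq.int(2L, nr + nc)) {
      i <- seq_len(nr); j <- s - i
      ok <- j >= 1 & j <= nc
      lines[[s - 1L]] <- m[cbind(i[ok], j[ok])]
    }
  }
  lines
}

glrl_matrix <- function(lv, dr, dc, n_levels) {
  P <- matrix(0, n_levels, max(dim(lv)))
  for (ln in extract_lines(lv, dr, dc)) {
    if (!length(ln)) next
    r <- rle(ifelse(is.na(ln), -1L, ln))
    keep <- r$values >= 0
    for (k in which(keep))
      P[r$values[k] + 1L, r$lengths[k]] <- P[r$values[k] + 1L, r$lengths[k]] + 1
  }
  P
}

glrl_features_from_matrix <- function(P, n_pixels) {
  Nr <- sum(P)
  i2 <- seq_len(nrow(P))^2
  j2 <- seq_len(ncol(P))^2
  pi_ <- rowSums(P); pj <- colSums(P)
  c(SRE = sum(pj / j2) / Nr,
    LRE = sum(pj * j2) / Nr,
    GLN = sum(pi_^2) / Nr,
    RLN = sum(pj^2) / Nr,
    RP = Nr / n_pixels,
    LGRE = sum(pi_ / i2) / Nr,
    HGRE = sum(pi_ * i2) / Nr,
    SRLGE = sum(P * outer(1 / i2, 1 / j2)) / Nr,
    SRHGE = sum(P * outer(i2, 1 / j2)) / Nr,
    LRLGE = sum(P * outer(1 / i2, j2)) / Nr,
    LRHGE = sum(P * outer(i2, j2)) / Nr)
}

#' Gray-level run-length features
#'
#' Run-length matrices are built from maximal constant-level runs restricted
#' to the mask (runs break at mask boundaries) along the four 2D directions;
#' the eleven Galloway/Chu/Dasarathy features (SRE, LRE, GLN, RLN, RP, LGRE,
#' HGRE, SRLGE, SRHGE, LRLGE, LRHGE) are computed per direction and averaged.
#' Gray levels are indexed 1-based inside the run-length matrix so that the
#' low-gray-level emphases are defined for level 0.
#'
#' @inheritParams glcm_features
#' @param directions Run directions in degrees, subset of `c(0, 45, 90, 135)`.
#' @return Named numeric vector of the 11 features.
#' @export
glrl_features <- function(levels, mask = NULL, n_levels = NULL,
                          directions = c(0, 45, 90, 135)) {
  lv <- masked_levels(levels, mask)
  n_pixels <- sum(!is.na(lv))
  if (n_pixels == 0) stop("ROI error: empty level image", call. = FALSE)
  if (is.null(n_levels)) n_levels <- max(lv, na.rm = TRUE) + 1L
  offs <- angle_offsets(directions)
  acc <- NULL
  for (off in offs) {
    P <- glrl_matrix(lv, off[1], off[2], n_levels)
    f <- glrl_features_from_matrix(P, n_pixels)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / length(offs)
}

interior_mask <- function(mask, connectivity = c("cross", "square")) {
  connectivity <- match.arg(connectivity)
  nr <- nrow(mask); nc <- ncol(mask)
  if (nr < 3 || nc < 3) return(matrix(FALSE, nr, nc))
  core <- mask
  core[c(1, nr), ] <- FALSE
  core[, c(1, nc)] <- FALSE
  shift_ok <- function(dr, dc) {
    s <- matrix(FALSE, nr, nc)
    s[seq.int(max(1, 1 - dr), min(nr, nr - dr)),
      seq.int(max(1, 1 - dc), min(nc, nc - dc))] <-
      mask[seq.int(max(1, 1 + dr), min(nr, nr + dr)),
           seq.int(max(1, 1 + dc), min(nc, nc + dc)), drop = FALSE]
    s
  }
  offs <- if (connectivity == "cross")
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  else
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
         c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (o in offs) core <- core & shift_ok(o[1], o[2])
  core
}

#' Gray-level gradient features
#'
#' Per-voxel gradient magnitudes by central differences,
#' `g = sqrt(((I[r+1,c]-I[r-1,c])/(2*s1))^2 + ((I[r,c+1]-I[r,c-1])/(2*s2))^2)`,
#' evaluated at interior voxels (all four neighbours inside the mask), with
#' the in-plane voxel spacing applied per axis. The four features are the
#' mean gradient (MGR), the variance of gradients (VGR) and the skewness and
#' kurtosis of the gradient distribution; population moment definitions,
#' with skewness/kurtosis set to 0 when the gradients are constant.
#'
#' @param x Numeric intensity matrix (raw HU, not quantized).
#' @param mask Logical matrix marking the ROI.
#' @param spacing In-plane voxel spacing, length 2 (rows, columns), in mm.
#' @return Named numeric vector: `MGR`, `VGR`, `skewness`, `kurtosis`.
#' @export
glgm_features <- function(x, mask = NULL, spacing = c(1, 1)) {
  if (is.null(mask)) mask <- !is.na(x)
  stopifnot(identical(dim(mask), dim(x)), length(spacing) == 2)
  core <- interior_mask(mask, "cross")
  if (!any(core))
    stop("ROI error: no interior voxels for gradient computation", call. = FALSE)
  idx <- which(core, arr.ind = TRUE)
  r <- idx[, 1]; c_ <- idx[, 2]
  gr <- (x[cbind(r + 1L, c_)] - x[cbind(r - 1L, c_)]) / (2 * spacing[1])
  gc <- (x[cbind(r, c_ + 1L)] - x[cbind(r, c_ - 1L)]) / (2 * spacing[2])
  g <- sqrt(gr^2 + gc^2)
  m <- mean(g)
  v <- mean((g - m)^2)
  sk <- pop_skew_kurt(g)
  c(MGR = m, VGR = v, skewness = unname(sk["skewness"]),
    kurtosis = unname(sk["kurtosis"]))
}

laws_kernels <- function() {
  v <- list(L3 = c(1, 2, 1), E3 = c(-1, 0, 1), S3 = c(-1, 2, -1))
  ks <- list()
  for (a in names(v)) for (b in names(v))
    # first-named 1-D kernel acts along columns (in-plane x), second along rows
    ks[[paste0(a, b)]] <- outer(v[[b]], v[[a]])
  ks
}

#' Laws texture energy features
#'
#' The ROI intensities are mean-centred, cross-correlated with the nine 3x3
#' kernels formed as outer products of the level/edge/spot vectors
#' L3 = (1,2,1), E3 = (-1,0,1), S3 = (-1,2,-1) (the first-named kernel acting
#' along the in-plane x axis), and each feature is the mean absolute response
#' over voxels whose full 3x3 support lies inside the mask. Mean-centring
#' makes the L3L3 response vanish on constant ROIs.
#'
#' @inheritParams glgm_features
#' @return Named numeric vector of the 9 features (`L3L3` ... `S3S3`).
#' @export
laws_features <- function(x, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(x)
  stopifnot(identical(dim(mask), dim(x)))
  core <- interior_mask(mask, "square")
  if (!any(core))
    stop("ROI error: no voxels with full 3x3 support", call. = FALSE)
  xm <- x - mean(x[mask])
  xm[!mask] <- 0  # never read at core voxels, but keep arithmetic clean
  idx <- which(core, arr.ind = TRUE)
  r <- idx[, 1]; c_ <- idx[, 2]
  out <- numeric(9)
  ks <- laws_kernels()
  names(out) <- names(ks)
  for (nm in names(ks)) {
    k <- ks[[nm]]
    resp <- numeric(nrow(idx))
    for (u in -1:1) for (v in -1:1)
      resp <- resp + k[u + 2, v + 2] * xm[cbind(r + u, c_ + v)]
    out[nm] <- mean(abs(resp))
  }
  out
}

slice_features <- function(sl, msk, spacing2, n_levels,
                           families = names(.feature_families)) {
  out <- list()
  vals <- sl[msk]
  if ("histogram" %in% families)
    out$histogram <- histogram_features(vals)
  if (any(c("glcm", "glrl") %in% families)) {
    lv <- quantize(sl, n_levels = n_levels, range = range(vals))
    lv[!msk] <- NA_integer_
    if ("glcm" %in% families)
      out$glcm <- tryCatch(glcm_features(lv, n_levels = n_levels),
                           error = function(e) NULL)
    if ("glrl" %in% families)
      out$glrl <- glrl_features(lv, n_levels = n_levels)
  }
  if ("glgm" %in% families)
    out$glgm <- tryCatch(glgm_features(sl, msk, spacing2),
                         error = function(e) NULL)
  if ("laws" %in% families)
    out$laws <- tryCatch(laws_features(sl, msk), error = function(e) NULL)
  full <- rep(NA_real_, sum(vapply(.feature_families[families], length, 1L)))
  names(full) <- dect_feature_names(families)
  for (f in names(out))
    if (!is.null(out[[f]]))
      full[paste(f, names(out[[f]]), sep = ".")] <- out[[f]]
  full
}

#' Texture features of one nodule at one energy
#'
#' Computes the requested feature families per artifact-free axial slice
#' containing at least `min_voxels` in-mask voxels, then averages each
#' feature (unweighted) across those slices. Histogram features are computed
#' on raw HU; GLCM/GLRL on intensities quantized per slice to `n_levels`
#' over the slice's in-ROI min--max; GLGM and Laws on raw HU. Slices where a
#' spatial family has no valid support (no interior voxels) do not
#' contribute to that family's average.
#'
#' @param stack A [vmi_stack()].
#' @param mask A [roi_mask()] congruent with the stack.
#' @param energy Energy in keV; must be present in the stack.
#' @param n_levels Gray levels for quantization (default 64).
#' @param min_voxels Minimum in-mask voxels for a slice to be used.
#' @param families Feature families to compute.
#' @return Named numeric vector of features, with attributes `n_slices`
#'   (slices used), `nodule_id` and `energy_keV`.
#' @export
nodule_features <- function(stack, mask, energy, n_levels = 64L,
                            min_voxels = 9L,
                            families = names(.feature_families)) {
  stopifnot(inherits(stack, "vmi_stack"))
  families <- match.arg(families, names(.feature_families), several.ok = TRUE)
  e <- as.character(energy)
  if (!e %in% names(stack$volumes))
    stop("input error: energy ", e, " keV not present in stack", call. = FALSE)
  m <- as_mask_array(mask)
  if (!identical(dim(m), stack$dim))
    stop("coregistration error: mask shape differs from stack", call. = FALSE)
  vol <- stack$volumes[[e]]
  sp2 <- stack$spacing[1:2]
  rows <- list()
  for (z in seq_len(dim(m)[3])) {
    msk <- m[, , z]
    if (sum(msk) < min_voxels) next
    rows[[length(rows) + 1L]] <- slice_features(vol[, , z], msk, sp2,
                                                n_levels, families)
  }
  if (!length(rows))
    stop("ROI error: no usable slice (need >= ", min_voxels,
         " voxels per slice)", call. = FALSE)
  mat <- do.call(rbind, rows)
  out <- colMeans(mat, na.rm = TRUE)
  if (anyNA(out) || any(!is.finite(out)))
    stop("ROI error: some features undefined on every usable slice", call. = FALSE)
  structure(out, n_slices = length(rows),
            nodule_id = if (inherits(mask, "roi_mask")) mask$nodule_id else NA,
            energy_keV = as.numeric(e))
}

#' Texture feature table for a cohort
#'
#' Runs [nodule_features()] for every nodule and requested energy and
#' returns a wide table with one row per nodule x energy and one column per
#' feature.
#'
#' @param x A `dect_cohort` from [generate_cohort()] or a list of loaded
#'   nodules from [load_cohort()].
#' @param energies Energies (keV) at which to extract texture; default the
#'   three analysis energies 40/60/80.
#' @inheritParams nodule_features
#' @return `data.frame` with columns `nodule_id`, `label`, `energy_keV`,
#'   `n_slices` and one column per feature key.
#' @export
extract_features <- function(x, energies = c(40, 60, 80), n_levels = 64L,
                             min_voxels = 9L,
                             families = names(.feature_families)) {
  items <- if (inherits(x, "dect_cohort")) lapply(x, as_vmi_stack) else x
  rows <- list()
  for (it in items) {
    for (e in energies) {
      fv <- nodule_features(it$stack, it$mask, e, n_levels = n_levels,
                            min_voxels = min_voxels, families = families)
      rows[[length(rows) + 1L]] <- data.frame(
        nodule_id = it$nodule_id, label = it$label, energy_keV = e,
        n_slices = attr(fv, "n_slices"),
        as.list(structure(as.numeric(fv), names = names(fv))),
        check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Reshape a wide feature table to long format
#'
#' @param wide Output of [extract_features()].
#' @return `data.frame` with columns `nodule_id,label,energy_keV,feature,value`.
#' @export
features_long <- function(wide) {
  keys <- intersect(dect_feature_names(), names(wide))
  do.call(rbind, lapply(keys, function(k)
    data.frame(nodule_id = wide$nodule_id, label = wide$label,
               energy_keV = wide$energy_keV, feature = k, value = wide[[k]])))
}
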