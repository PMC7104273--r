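#' Configuration for the synthetic DECT phantom cohort
#'
#' Builds a validated configuration object for [generate_cohort()]. The
#' phantom emulates a two-class thyroid-nodule cohort imaged with dual-energy
#' CT: each nodule is an ellipsoidal solid lesion carrying a class-dependent
#' iodine concentration and a class-dependent heterogeneity texture, rendered
#' as virtual monochromatic images (VMIs) across a sweep of energies together
#' with an iodine-density map and a binary ROI mask on a shared voxel grid.
#'
#' Inside the nodule the expected voxel intensity at energy `E` is
#' `base_tissue_HU(E) + iodine * enhancement(E) + texture`, where `texture` is
#' a zero-mean Gaussian random field shared across energies (a tissue
#' property), and independent Gaussian read-out noise is added per energy.
#' The iodine enhancement table must be strictly decreasing with energy:
#' iodine attenuates strongly at low keV, which is what makes the HU-vs-keV
#' curve slope an iodine surrogate.
#'
#' @param image_shape Integer vector of length 3: voxels per axis (x, y, z).
#' @param voxel_size_mm Numeric length 3: voxel spacing in mm.
#' @param energies_keV Energies (keV) at which VMIs are synthesised. The
#'   default 40--190 keV sweep in 10 keV steps covers both the three texture
#'   energies (40/60/80) and the attenuation-slope sweep.
#' @param n_benign,n_malignant Nodules per class.
#' @param nodule_axes_mm Length-2 range from which ellipsoid semi-axes (mm)
#'   are drawn uniformly.
#' @param iodine_mean_benign,iodine_mean_malignant Class mean iodine
#'   concentration (mg/mL).
#' @param iodine_sd Between-nodule SD of true iodine concentration (mg/mL);
#'   draws are truncated at zero.
#' @param iodine_map_noise_sd Voxelwise SD (mg/mL) of noise on the emitted
#'   iodine map.
#' @param texture_correlation_length_mm Named numeric (`benign`, `malignant`):
#'   correlation length (mm) of the heterogeneity field. Malignant tissue is
#'   conventionally given the shorter length (finer-grained heterogeneity).
#' @param texture_amplitude_HU Named numeric (`benign`, `malignant`): SD (HU)
#'   of the heterogeneity field.
#' @param noise_sd_HU Per-energy noise SD (HU), named by energy. Default
#'   `1200 / E`, falling with keV as high-energy VMIs are less noisy.
#' @param iodine_enhancement_table Per-energy HU increase per mg/mL iodine,
#'   named by energy; must be strictly decreasing in energy. Default decays
#'   exponentially from 50 at 40 keV to 5 at 190 keV.
#' @param base_tissue_HU Per-energy baseline tissue intensity, named by
#'   energy. Default is flat at 1055 so that the nodule's spectral contrast
#'   is carried entirely by its iodine content.
#' @param rng_seed Integer seed making cohort generation a pure function of
#'   the configuration.
#'
#' @return An object of class `phantom_config` (a validated list).
#' @seealso [generate_cohort()], [gaussian_random_field()]
#' @export
#' @examples
#' cfg <- phantom_config(n_benign = 2, n_malignant = 3,
#'                       image_shape = c(32, 32, 3), energies_keV = c(40, 80))
#' cohort <- generate_cohort(cfg)
#' length(cohort)
phantom_config <- function(image_shape = c(64L, 64L, 5L),
                           voxel_size_mm = c(1, 1, 3),
                           energies_keV = seq(40, 190, by = 10),
                           n_benign = 14L,
                           n_malignant = 20L,
                           nodule_axes_mm = c(6, 12),
                           iodine_mean_benign = 0.54,
                           iodine_mean_malignant = 0.437,
                           iodine_sd = 0.37,
                           iodine_map_noise_sd = 0.05,
                           texture_correlation_length_mm = c(benign = 3, malignant = 1.5),
                           texture_amplitude_HU = c(benign = 20, malignant = 30),
                           noise_sd_HU = NULL,
                           iodine_enhancement_table = NULL,
                           base_tissue_HU = NULL,
                           rng_seed = 1L) {
  stopifnot(length(image_shape) == 3, length(voxel_size_mm) == 3)
  image_shape <- as.integer(image_shape)
  if (any(image_shape < 1) || any(voxel_size_mm <= 0))
    stop("image dimensions and voxel sizes must be positive", call. = FALSE)
  if (n_benign < 0 || n_malignant < 0)
    stop("class sizes must be non-negative", call. = FALSE)
  energies_keV <- as.numeric(energies_keV)
  if (any(energies_keV <= 0) || anyDuplicated(energies_keV))
    stop("energies must be positive and unique", call. = FALSE)
  energies_keV <- sort(energies_keV)
  if (length(nodule_axes_mm) != 2 || any(nodule_axes_mm <= 0) ||
      nodule_axes_mm[1] > nodule_axes_mm[2])
    stop("nodule_axes_mm must be an increasing positive range", call. = FALSE)
  half_extent <- image_shape * voxel_size_mm / 2
  if (nodule_axes_mm[2] > min(half_extent[1:2]))
    stop("nodule larger than image: reduce nodule_axes_mm or enlarge the grid",
         call. = FALSE)
  for (nm in c("texture_correlation_length_mm", "texture_amplitude_HU")) {
    v <- get(nm)
    if (!all(c("benign", "malignant") %in% names(v)))
      stop(nm, " must be named with 'benign' and 'malignant'", call. = FALSE)
  }
  if (any(texture_correlation_length_mm <= 0))
    stop("texture correlation lengths must be positive", call. = FALSE)
  if (any(texture_amplitude_HU < 0))
    stop("texture amplitudes must be non-negative", call. = FALSE)
  if (iodine_sd < 0 || iodine_map_noise_sd < 0)
    stop("iodine dispersions must be non-negative", call. = FALSE)

  e_names <- as.character(energies_keV)
  default_by_energy <- function(x, default_fun, what) {
    if (is.null(x)) {
      x <- default_fun(energies_keV)
      names(x) <- e_names
    }
    if (is.null(names(x)) && length(x) %in% c(1L, length(energies_keV))) {
      x <- rep_len(x, length(energies_keV))
      names(x) <- e_names
    }
    if (!all(e_names %in% names(x)))
      stop(what, " must cover every configured energy", call. = FALSE)
    x[e_names]
  }
  noise_sd_HU <- default_by_energy(noise_sd_HU, function(e) 1200 / e,
                                   "noise_sd_HU")
  iodine_enhancement_table <- default_by_energy(
    iodine_enhancement_table,
    function(e) 50 * (5 / 50)^((e - 40) / 150),
    "iodine_enhancement_table")
  base_tissue_HU <- default_by_energy(base_tissue_HU, function(e) rep(1055, length(e)),
                                      "base_tissue_HU")
  if (any(noise_sd_HU < 0)) stop("noise SDs must be non-negative", call. = FALSE)
  if (any(diff(iodine_enhancement_table) >= 0))
    stop("iodine_enhancement_table must be strictly decreasing with energy",
         call. = FALSE)

  structure(list(
    image_shape = image_shape,
    voxel_size_mm = as.numeric(voxel_size_mm),
    energies_keV = energies_keV,
    n_benign = as.integer(n_benign),
    n_malignant = as.integer(n_malignant),
    nodule_axes_mm = as.numeric(nodule_axes_mm),
    iodine_mean_benign = iodine_mean_benign,
    iodine_mean_malignant = iodine_mean_malignant,
    iodine_sd = iodine_sd,
    iodine_map_noise_sd = iodine_map_noise_sd,
    texture_correlation_length_mm = texture_correlation_length_mm,
    texture_amplitude_HU = texture_amplitude_HU,
    noise_sd_HU = noise_sd_HU,
    iodine_enhancement_table = iodine_enhancement_table,
    base_tissue_HU = base_tissue_HU,
    rng_seed = as.integer(rng_seed)
  ), class = "phantom_config")
}

#' Zero-mean Gaussian random field with controllable correlation length
#'
#' White Gaussian noise smoothed by an isotropic Gaussian kernel whose width
#' equals `correlation_length` (in pixels), then recentred to zero mean and
#' rescaled so its empirical SD equals `amplitude`. Smoothing uses circular
#' (FFT) convolution, so the field is stationary across the grid.
#'
#' @param shape Integer vector of length 2 (rows, columns).
#' @param correlation_length Gaussian kernel SD in pixel units; > 0.
#' @param amplitude Target field SD; 0 gives an identically zero field.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (this is how [generate_cohort()] keeps the whole cohort a function
#'   of a single seed).
#' @return A `shape[1]` x `shape[2]` numeric matrix.
#' @export
gaussian_random_field <- function(shape, correlation_length, amplitude,
                                  seed = NULL) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  if (correlation_length <= 0)
    stop("correlation_length must be positive", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (amplitude == 0) return(matrix(0, shape[1], shape[2]))
  z <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  # circular distances for a wrap-around Gaussian kernel
  d1 <- pmin(0:(shape[1] - 1), shape[1] - 0:(shape[1] - 1))
  d2 <- pmin(0:(shape[2] - 1), shape[2] - 0:(shape[2] - 1))
  k <- exp(-outer(d1^2, d2^2, "+") / (2 * correlation_length^2))
  f <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE))
  f <- f - mean(f)
  s <- stats::sd(as.vector(f))
  if (s == 0) return(matrix(0, shape[1], shape[2]))  # 1x1 and constant cases
  f * (amplitude / s)
}

#' Generate a synthetic DECT nodule cohort
#'
#' Draws `n_benign + n_malignant` phantom nodules according to a
#' [phantom_config()]. Each nodule carries per-energy VMI volumes, an iodine
#' map, its ROI mask, the class label and the true iodine concentration. The
#' generation is deterministic given `config$rng_seed`.
#'
#' @param config A [phantom_config()] object.
#' @return A list of class `dect_cohort`; each element is a `phantom_nodule`
#'   list with fields `nodule_id`, `class_label`, `true_iodine`, `volumes`
#'   (named by energy), `iodine_map`, `mask`, `spacing`, `diameter_mm`,
#'   `eligible`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$rng_seed)
  dims <- config$image_shape
  sp <- config$voxel_size_mm
  labels <- c(rep("benign", config$n_benign), rep("malignant", config$n_malignant))
  centre <- (dims + 1) / 2  # voxel-index centre; voxel centres at integer indices
  e_names <- as.character(config$energies_keV)

  # coordinate grids in mm relative to centre, voxel centres
  xs <- (seq_len(dims[1]) - centre[1]) * sp[1]
  ys <- (seq_len(dims[2]) - centre[2]) * sp[2]
  zs <- (seq_len(dims[3]) - centre[3]) * sp[3]

  cohort <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    ax <- stats::runif(3, config$nodule_axes_mm[1], config$nodule_axes_mm[2])
    # keep the through-plane semi-axis inside the slab
    ax[3] <- min(ax[3], 0.95 * dims[3] * sp[3] / 2)
    mu <- if (lab == "benign") config$iodine_mean_benign else config$iodine_mean_malignant
    iod <- max(0, stats::rnorm(1, mu, config$iodine_sd))

    ell <- outer(outer((xs / ax[1])^2, (ys / ax[2])^2, "+"), (zs / ax[3])^2, "+")
    mask <- ell <= 1
    if (!any(mask))
      stop("degenerate phantom nodule: empty mask (grid too coarse)", call. = FALSE)

    corr_px <- config$texture_correlation_length_mm[[lab]] / sp[1]
    amp <- config$texture_amplitude_HU[[lab]]
    texture <- array(0, dims)
    for (z in seq_len(dims[3]))
      texture[, , z] <- gaussian_random_field(dims[1:2], corr_px, amp)

    volumes <- vector("list", length(e_names))
    names(volumes) <- e_names
    nvox <- prod(dims)
    for (e in e_names) {
      vol <- array(config$base_tissue_HU[[e]], dims)
      vol[mask] <- vol[mask] + iod * config$iodine_enhancement_table[[e]] +
        texture[mask]
      if (config$noise_sd_HU[[e]] > 0)
        vol <- vol + array(stats::rnorm(nvox, 0, config$noise_sd_HU[[e]]), dims)
      volumes[[e]] <- vol
    }
    imap <- array(0, dims)
    imap[mask] <- iod
    if (config$iodine_map_noise_sd > 0)
      imap <- imap + array(stats::rnorm(nvox, 0, config$iodine_map_noise_sd), dims)

    diam <- max_inplane_diameter(mask, sp)
    cohort[[i]] <- structure(list(
      nodule_id = sprintf("N%03d", i),
      class_label = lab,
      true_iodine = iod,
      volumes = volumes,
      iodine_map = imap,
      mask = mask,
      spacing = sp,
      diameter_mm = diam,
      eligible = diam >= 10
    ), class = "phantom_nodule")
  }
  structure(cohort, class = "dect_cohort", config = config)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config>\n")
  cat(sprintf("  grid %s voxels at %s mm, %d energies (%g-%g keV)\n",
              paste(x$image_shape, collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x"),
              length(x$energies_keV), min(x$energies_keV), max(x$energies_keV)))
  cat(sprintf("  cohort %d benign / %d malignant; iodine %0.3f / %0.3f (SD %0.2f) mg/mL\n",
              x$n_benign, x$n_malignant,
              x$iodine_mean_benign, x$iodine_mean_malignant, x$iodine_sd))
  invisible(x)
}

#' @export
print.dect_cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "class_label")
  cat(sprintf("<dect_cohort> %d nodules (%d benign, %d malignant)\n",
              length(x), sum(labs == "benign"), sum(labs == "malignant")))
  invisible(x)
}
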