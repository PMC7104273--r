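#' Coregistered VMI stack
#'
#' Container for one nodule's virtual monochromatic volumes (one 3D HU array
#' per energy), an optional iodine-density map, and the shared voxel spacing.
#' All arrays must be congruent: VMIs reconstructed from one DECT acquisition
#' are naturally coregistered, and this container enforces it.
#'
#' @param volumes Named list of 3D numeric arrays; names are energies in keV.
#' @param iodine Optional 3D array (mg/mL) on the same grid.
#' @param spacing Voxel spacing in mm, length 3.
#' @return An object of class `vmi_stack`.
#' @export
vmi_stack <- function(volumes, iodine = NULL, spacing = c(1, 1, 1)) {
  if (length(volumes) < 1) stop("at least one energy volume required", call. = FALSE)
  energies <- suppressWarnings(as.numeric(names(volumes)))
  if (anyNA(energies) || any(energies <= 0) || anyDuplicated(energies))
    stop("volume names must be unique positive energies in keV", call. = FALSE)
  ord <- order(energies)
  volumes <- volumes[ord]
  energies <- energies[ord]
  dims <- dim(volumes[[1]])
  if (length(dims) != 3) stop("volumes must be 3D arrays", call. = FALSE)
  for (v in volumes)
    if (!identical(dim(v), dims))
      stop("coregistration error: energy volumes have mismatched shapes", call. = FALSE)
  if (!is.null(iodine) && !identical(dim(iodine), dims))
    stop("coregistration error: iodine map shape differs from VMI volumes", call. = FALSE)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  structure(list(volumes = volumes, energies = energies, iodine = iodine,
                 spacing = as.numeric(spacing), dim = dims),
            class = "vmi_stack")
}

#' Binary ROI mask for one nodule's solid component
#'
#' @param mask Logical (or 0/1) 3D array; the same mask is applied to every
#'   energy of the stack it accompanies.
#' @param nodule_id Identifier carried through the pipeline.
#' @param excluded_slices Axial (third-axis) slice indices excluded from
#'   analysis, e.g. because of artifacts.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, nodule_id = "roi", excluded_slices = integer(0)) {
  if (length(dim(mask)) != 3) stop("mask must be a 3D array", call. = FALSE)
  mask <- array(as.logical(mask), dim(mask))
  if (length(excluded_slices)) {
    excluded_slices <- sort(unique(as.integer(excluded_slices)))
    if (any(excluded_slices < 1 | excluded_slices > dim(mask)[3]))
      stop("excluded slice indices out of range", call. = FALSE)
    mask[, , excluded_slices] <- FALSE
  }
  if (!any(mask))
    stop("ROI error: mask is empty after slice exclusion", call. = FALSE)
  structure(list(mask = mask, nodule_id = nodule_id,
                 excluded_slices = excluded_slices),
            class = "roi_mask")
}

as_mask_array <- function(mask) {
  if (inherits(mask, "roi_mask")) mask$mask else array(as.logical(mask), dim(mask))
}

#' Maximum in-plane diameter of a mask
#'
#' The maximum, over axial slices, of the largest pairwise distance between
#' in-slice voxel centres, in mm. This is the size statistic used for the
#' >= 10 mm solid-component eligibility rule (the minimum fine-needle
#' aspiration size in ACR TI-RADS). A single-voxel mask has diameter 0:
#' distances are measured centre-to-centre.
#'
#' @param mask A `roi_mask` or logical 3D array.
#' @param spacing Voxel spacing in mm (length 3; only in-plane entries used).
#' @return Diameter in mm.
#' @export
max_inplane_diameter <- function(mask, spacing = c(1, 1, 1)) {
  m <- as_mask_array(mask)
  if (!any(m)) stop("ROI error: empty mask", call. = FALSE)
  best <- 0
  for (z in seq_len(dim(m)[3])) {
    idx <- which(m[, , z], arr.ind = TRUE)
    n <- nrow(idx)
    if (n < 2) next
    pts <- cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2])
    if (n > 3) {
      hull <- grDevices::chull(pts)
      pts <- pts[hull, , drop = FALSE]
    }
    d2 <- stats::dist(pts)
    best <- max(best, max(d2))
  }
  best
}

#' Solid-component size eligibility
#'
#' @inheritParams max_inplane_diameter
#' @param threshold_mm Eligibility threshold; defaults to the 10 mm
#'   fine-needle-aspiration minimum.
#' @return `TRUE` when the maximum in-plane diameter reaches the threshold.
#' @export
eligible <- function(mask, spacing = c(1, 1, 1), threshold_mm = 10) {
  max_inplane_diameter(mask, spacing) >= threshold_mm
}

#' Exclude artifact-affected axial slices from a mask
#'
#' @param mask A `roi_mask` or logical 3D array.
#' @param slice_indices Axial slice indices to zero out.
#' @return A `roi_mask` with the slices removed and recorded.
#' @export
exclude_slices <- function(mask, slice_indices) {
  if (inherits(mask, "roi_mask")) {
    roi_mask(mask$mask, mask$nodule_id,
             union(mask$excluded_slices, as.integer(slice_indices)))
  } else {
    roi_mask(mask, excluded_slices = slice_indices)
  }
}

nifti_write <- function(arr, path, spacing, datatype = "double") {
  img <- RNifti::asNifti(arr * 1)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a phantom cohort to disk as a NIfTI + CSV run directory
#'
#' Writes, per nodule, one NIfTI volume per energy, the iodine map and the
#' mask, plus a cohort manifest CSV with columns
#' `nodule_id,label,mask_path,iodine_path,e<keV>_path,...,true_iodine` and a
#' YAML echo of the generating configuration (provenance).
#'
#' @param cohort A `dect_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dect_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- attr(cohort, "config")
  rows <- lapply(cohort, function(nod) {
    sp <- nod$spacing
    paths <- list()
    for (e in names(nod$volumes)) {
      p <- sprintf("%s_e%s.nii.gz", nod$nodule_id, e)
      nifti_write(nod$volumes[[e]], file.path(dir, p), sp)
      paths[[sprintf("e%s_path", e)]] <- p
    }
    ip <- sprintf("%s_iodine.nii.gz", nod$nodule_id)
    nifti_write(nod$iodine_map, file.path(dir, ip), sp)
    mp <- sprintf("%s_mask.nii.gz", nod$nodule_id)
    nifti_write(nod$mask, file.path(dir, mp), sp, datatype = "uint8")
    c(list(nodule_id = nod$nodule_id, label = nod$class_label,
           mask_path = mp, iodine_path = ip), paths,
      list(true_iodine = nod$true_iodine))
  })
  manifest <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg <- lapply(cfg, function(x) if (is.numeric(x) && !is.null(names(x)))
      as.list(x) else x)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  invisible(manifest_path)
}

#' Load one nodule's VMI stack and mask from files
#'
#' Reads per-energy NIfTI volumes, an optional iodine map and the ROI mask,
#' validating that all arrays share shape and voxel spacing (the
#' coregistration contract) and that the mask is non-empty.
#'
#' @param energy_paths Named character vector of NIfTI paths; names are
#'   energies in keV.
#' @param iodine_path Optional iodine-map NIfTI path.
#' @param mask_path Mask NIfTI path.
#' @param nodule_id Identifier for the returned mask.
#' @return `list(stack = vmi_stack, mask = roi_mask)`.
#' @export
load_stack <- function(energy_paths, iodine_path = NULL, mask_path,
                       nodule_id = "roi") {
  if (is.null(names(energy_paths)) || any(!nzchar(names(energy_paths))))
    stop("energy_paths must be named by energy in keV", call. = FALSE)
  for (p in c(energy_paths, iodine_path, mask_path))
    if (!file.exists(p)) stop("input error: file not found: ", p, call. = FALSE)
  read1 <- function(p) {
    img <- RNifti::readNifti(p)
    list(arr = as.array(img), spacing = RNifti::pixdim(img)[1:3])
  }
  vols <- lapply(energy_paths, read1)
  spacing <- vols[[1]]$spacing
  dims <- dim(vols[[1]]$arr)
  check <- function(x, what) {
    if (!identical(dim(x$arr), dims) || max(abs(x$spacing - spacing)) > 1e-4)
      stop("coregistration error: ", what,
           " grid differs from the first energy volume", call. = FALSE)
    x$arr
  }
  volumes <- Map(check, vols, paste0(names(energy_paths), " keV"))
  names(volumes) <- names(energy_paths)
  iodine <- if (!is.null(iodine_path)) check(read1(iodine_path), "iodine map")
  mraw <- check(read1(mask_path), "mask")
  stack <- vmi_stack(volumes, iodine = iodine, spacing = spacing)
  mask <- roi_mask(mraw != 0, nodule_id = nodule_id)
  list(stack = stack, mask = mask)
}

#' Load a written cohort back from its manifest
#'
#' @param manifest_path Path to the manifest CSV written by [write_cohort()]
#'   (energy columns follow the `e<keV>_path` pattern).
#' @return A list with one element per nodule:
#'   `list(stack, mask, label, nodule_id, true_iodine)`.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("input error: manifest not found: ", manifest_path, call. = FALSE)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("nodule_id", "label", "mask_path")
  if (!all(need %in% names(man)))
    stop("input error: manifest lacks required columns ",
         paste(setdiff(need, names(man)), collapse = ", "), call. = FALSE)
  ecols <- grep("^e[0-9]+_path$", names(man), value = TRUE)
  if (!length(ecols)) stop("input error: manifest has no e<keV>_path columns",
                           call. = FALSE)
  energies <- sub("^e([0-9]+)_path$", "\\1", ecols)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    paths <- file.path(base, unlist(man[i, ecols]))
    names(paths) <- energies
    ipath <- if ("iodine_path" %in% names(man))
      file.path(base, man$iodine_path[i])
    lm <- load_stack(paths, ipath, file.path(base, man$mask_path[i]),
                     nodule_id = man$nodule_id[i])
    lm$label <- man$label[i]
    lm$nodule_id <- man$nodule_id[i]
    lm$true_iodine <- if ("true_iodine" %in% names(man)) man$true_iodine[i]
    lm
  })
}

# Uniform view of a phantom nodule as (stack, mask) for downstream modules.
#' Convert a phantom nodule to a VMI stack and ROI mask
#' @param nodule A `phantom_nodule` from [generate_cohort()].
#' @return `list(stack, mask, label, nodule_id, true_iodine)`.
#' @export
as_vmi_stack <- function(nodule) {
  stopifnot(inherits(nodule, "phantom_nodule"))
  list(stack = vmi_stack(nodule$volumes, iodine = nodule$iodine_map,
                         spacing = nodule$spacing),
       mask = roi_mask(nodule$mask, nodule_id = nodule$nodule_id),
       label = nodule$class_label,
       nodule_id = nodule$nodule_id,
       true_iodine = nodule$true_iodine)
}
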