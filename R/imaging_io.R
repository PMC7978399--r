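# Volume containers, NIfTI input/output and the preprocessing steps of the
# translation pipeline: [0,1] intensity normalization, body (air) masking,
# left/right flip augmentation and transverse slice extraction.
#
# Coordinate convention: in a (H, W, S) array the first axis is
# left-right, the second anterior-posterior, the third the transverse
# slice index (0-based in slice objects). Left/right flipping reverses the
# first axis.

#' Voxel volume container
#'
#' A 3-D intensity array with voxel spacing, modality and intensity-domain
#' bookkeeping. CT volumes carry Hounsfield Units; MR volumes arbitrary
#' scanner units; after normalization the domain is `"normalized"` and all
#' values lie in \[0, 1\].
#'
#' @param data numeric 3-D array.
#' @param spacing_mm positive length-3 voxel spacing in mm.
#' @param modality one of `"MR"`, `"CT"`, `"SCT"`.
#' @param intensity_domain one of `"HU"`, `"normalized"`, `"arbitrary"`.
#' @return object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing_mm = c(1, 1, 1),
                         modality = c("MR", "CT", "SCT"),
                         intensity_domain = c("arbitrary", "HU", "normalized")) {
  modality <- match.arg(modality)
  intensity_domain <- match.arg(intensity_domain)
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 3L) stop("volume data must be a 3-D array")
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be a positive length-3 vector")
  if (intensity_domain == "normalized" &&
      (min(data) < -1e-9 || max(data) > 1 + 1e-9))
    stop("normalized volumes must have values in [0, 1]")
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 modality = modality, intensity_domain = intensity_domain),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume %s [%s] %s, spacing %s mm>\n", x$modality,
              x$intensity_domain, paste(dim(x$data), collapse = "x"),
              paste(x$spacing_mm, collapse = " x ")))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

#' Structure mask set
#'
#' Named binary masks (GTV, femur_R, femur_L, bladder, anorectum, body) on
#' a common grid.
#'
#' @param masks named list of logical/0-1 arrays of identical dimension.
#' @return object of class `structure_mask_set`.
#' @export
structure_mask_set <- function(masks) {
  if (!length(masks) || is.null(names(masks)) || any(names(masks) == ""))
    stop("masks must be a named list")
  d <- dim(masks[[1]])
  masks <- lapply(masks, function(m) {
    if (!identical(dim(m), d)) stop("all masks must share the grid dimensions")
    storage.mode(m) <- "logical"
    m
  })
  structure(list(masks = masks, dim = d), class = "structure_mask_set")
}

#' Paired, co-registered MR/CT case
#'
#' @param subject_id identifier.
#' @param mr,ct [voxel_volume()] objects sharing grid and spacing.
#' @param masks a [structure_mask_set()] on the same grid.
#' @return object of class `paired_case`.
#' @export
paired_case <- function(subject_id, mr, ct, masks) {
  stopifnot(inherits(mr, "voxel_volume"), inherits(ct, "voxel_volume"))
  if (!identical(dim(mr$data), dim(ct$data)))
    stop("MR and CT must share grid dimensions")
  if (!isTRUE(all.equal(mr$spacing_mm, ct$spacing_mm)))
    stop("MR and CT must share voxel spacing")
  if (!is.null(masks)) {
    stopifnot(inherits(masks, "structure_mask_set"))
    if (!identical(masks$dim, dim(ct$data)))
      stop("masks must match the case grid")
  }
  structure(list(subject_id = subject_id, mr = mr, ct = ct, masks = masks),
            class = "paired_case")
}

#' @export
print.paired_case <- function(x, ...) {
  cat(sprintf("<paired_case %s: %s, %d masks>\n", x$subject_id,
              paste(dim(x$ct$data), collapse = "x"),
              if (is.null(x$masks)) 0L else length(x$masks$masks)))
  invisible(x)
}

# ---- NIfTI / DICOM ---------------------------------------------------------

#' Read an image volume
#'
#' Reads a NIfTI volume with voxel spacing taken from the header. CT
#' volumes are tagged as Hounsfield-Unit domain, MR as arbitrary.
#'
#' @param path file path.
#' @param format `"nifti"`. (`"dicom"` is declared for interface
#'   completeness; DICOM series import is not available in this build and
#'   raises an informative error.)
#' @param modality `"MR"`, `"CT"` or `"SCT"`.
#' @return a [voxel_volume()].
#' @export
read_volume <- function(path, format = c("nifti", "dicom"),
                        modality = c("CT", "MR", "SCT")) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  if (format == "dicom")
    stop("DICOM series import is not available in this build; ",
         "convert the series to NIfTI first")
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  voxel_volume(array(as.numeric(img), dim(img)[1:3]), spacing, modality,
               intensity_domain = if (modality %in% c("CT", "SCT")) "HU" else "arbitrary")
}

#' Write a volume (or mask) as NIfTI
#'
#' @param v a [voxel_volume()] or a logical/numeric 3-D array (mask).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing_mm spacing used when `v` is a bare array.
#' @return the path, invisibly.
#' @export
write_volume <- function(v, path, spacing_mm = c(1, 1, 1)) {
  if (inherits(v, "voxel_volume")) {
    data <- v$data; spacing_mm <- v$spacing_mm
  } else {
    data <- array(as.numeric(v), dim(v))
  }
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- intensity normalization ----------------------------------------------

#' Intensity scale record
#'
#' The affine scale used to normalize a volume to \[0, 1\]; kept so the
#' normalization can be inverted to report synthetic CT in Hounsfield
#' Units.
#'
#' @param lo,hi scalars with `hi > lo`.
#' @return object of class `intensity_scale`.
#' @export
intensity_scale <- function(lo, hi) {
  if (!(hi > lo)) stop("intensity scale requires hi > lo")
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi)),
            class = "intensity_scale")
}

#' Min-max normalization to the unit interval
#'
#' Maps a volume to `(v - min) / (max - min)` and records the scale so the
#' transform can be inverted by [denormalize()]. Normalization is per
#' volume.
#'
#' @param v a [voxel_volume()].
#' @return list with elements `volume` (normalized [voxel_volume()]) and
#'   `scale` (an [intensity_scale()]).
#' @export
normalize_to_unit <- function(v) {
  stopifnot(inherits(v, "voxel_volume"))
  lo <- min(v$data); hi <- max(v$data)
  if (hi <= lo) stop("cannot normalize a constant volume")
  out <- voxel_volume((v$data - lo) / (hi - lo), v$spacing_mm, v$modality,
                      intensity_domain = "normalized")
  list(volume = out, scale = intensity_scale(lo, hi))
}

#' Invert unit normalization
#'
#' @param v a normalized [voxel_volume()].
#' @param scale the [intensity_scale()] to invert with.
#' @param modality modality tag of the result.
#' @param intensity_domain domain tag of the result (`"HU"` when the scale
#'   came from a CT).
#' @return a [voxel_volume()].
#' @export
denormalize <- function(v, scale, modality = v$modality,
                        intensity_domain = "HU") {
  stopifnot(inherits(v, "voxel_volume"), inherits(scale, "intensity_scale"))
  voxel_volume(v$data * (scale$hi - scale$lo) + scale$lo, v$spacing_mm,
               modality, intensity_domain = intensity_domain)
}

# ---- body (air) mask -------------------------------------------------------

# 3-D connected-component labelling, 6-connectivity: 2-D labelling per
# slice (EBImage) merged across slices with union-find.
label_components_3d <- function(mask) {
  d <- dim(mask)
  labs <- array(0L, d)
  offset <- 0L
  n_per_slice <- integer(d[3])
  for (s in seq_len(d[3])) {
    l2 <- EBImage::bwlabel(mask[, , s] * 1)
    n <- max(l2)
    l2[l2 > 0] <- l2[l2 > 0] + offset
    labs[, , s] <- l2
    n_per_slice[s] <- n
    offset <- offset + n
  }
  if (offset == 0L) return(labs)
  parent <- seq_len(offset)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (d[3] > 1L) for (s in seq_len(d[3] - 1L)) {
    a <- labs[, , s]; b <- labs[, , s + 1L]
    ov <- a > 0L & b > 0L
    if (!any(ov)) next
    pairs <- unique(cbind(a[ov], b[ov]))
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(offset), find, integer(1))
  relab <- match(root, unique(root))
  pos <- labs > 0L
  labs[pos] <- relab[labs[pos]]
  labs
}

#' Body mask by exterior-air exclusion
#'
#' Thresholds the CT at `hu_threshold`, closes the result morphologically
#' (in-plane), keeps the largest 3-D connected component as the body, and
#' fills enclosed cavities so that interior air (e.g. bowel or rectal
#' lumen) stays inside the mask while air outside the body is excluded.
#'
#' @param ct a [voxel_volume()] in HU domain.
#' @param hu_threshold threshold separating air from tissue (default -400
#'   HU).
#' @param closing_radius radius (voxels) of the in-plane closing brush.
#' @return logical 3-D array: `TRUE` inside the body.
#' @export
compute_air_mask <- function(ct, hu_threshold = -400, closing_radius = 2L) {
  stopifnot(inherits(ct, "voxel_volume"))
  if (ct$intensity_domain != "HU")
    stop("air masking operates on HU-domain volumes")
  fg <- ct$data > hu_threshold
  if (!any(fg)) stop("no voxel above threshold: volume appears to be all air")
  d <- dim(fg)
  if (closing_radius > 0L) {
    brush <- EBImage::makeBrush(2L * closing_radius + 1L, shape = "disc")
    for (s in seq_len(d[3]))
      fg[, , s] <- EBImage::closing(fg[, , s] * 1, brush) > 0
  }
  labs <- label_components_3d(fg)
  tab <- tabulate(labs[labs > 0L])
  body <- labs == which.max(tab)
  # fill enclosed cavities: background components are exterior only if they
  # reach the in-plane image boundary (transverse volumes are truncated in
  # z, so the z faces do not count -- an air lumen spanning all slices is
  # still interior)
  bg_labs <- label_components_3d(!body)
  border <- unique(c(bg_labs[1, , ], bg_labs[d[1], , ], bg_labs[, 1, ],
                     bg_labs[, d[2], ]))
  border <- border[border > 0L]
  exterior <- array(bg_labs %in% border, d)
  !exterior
}

# ---- slices and augmentation ----------------------------------------------

#' Paired transverse slice
#'
#' @param subject_id identifier.
#' @param slice_index 0-based transverse index.
#' @param mr_slice,ct_slice matrices of identical shape.
#' @return object of class `paired_slice`.
#' @export
paired_slice <- function(subject_id, slice_index, mr_slice, ct_slice) {
  if (!identical(dim(mr_slice), dim(ct_slice)))
    stop("mr_slice and ct_slice must have the same shape")
  structure(list(subject_id = subject_id, slice_index = as.integer(slice_index),
                 mr_slice = mr_slice, ct_slice = ct_slice),
            class = "paired_slice")
}

#' Left/right flip of a paired slice
#'
#' Reflects both the MR and the CT slice about the left-right axis (the
#' first in-plane axis), preserving voxelwise pairing. Used for data
#' augmentation; an involution.
#'
#' @param s a [paired_slice()].
#' @return the flipped [paired_slice()].
#' @export
flip_lr <- function(s) {
  stopifnot(inherits(s, "paired_slice"))
  rev1 <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  paired_slice(s$subject_id, s$slice_index, rev1(s$mr_slice), rev1(s$ct_slice))
}

#' Extract transverse slices from a paired case
#'
#' @param case a [paired_case()].
#' @return list of [paired_slice()], ordered by slice index (0-based),
#'   one per transverse plane.
#' @export
extract_slices <- function(case) {
  stopifnot(inherits(case, "paired_case"))
  d <- dim(case$ct$data)
  lapply(seq_len(d[3]), function(s)
    paired_slice(case$subject_id, s - 1L,
                 case$mr$data[, , s], case$ct$data[, , s]))
}

#' Reassemble slices into a volume array
#'
#' Inverse of [extract_slices()] for one modality; mainly used to check
#' that slice extraction is lossless.
#'
#' @param slices list of [paired_slice()].
#' @param which `"mr"` or `"ct"`.
#' @return 3-D array.
#' @export
stack_slices <- function(slices, which = c("ct", "mr")) {
  which <- match.arg(which)
  field <- paste0(which, "_slice")
  mats <- lapply(slices, `[[`, field)
  array(unlist(mats), c(dim(mats[[1]]), length(mats)))
}
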