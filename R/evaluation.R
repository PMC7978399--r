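# Image-quality metrics for synthetic CT against measured CT: MAPE, RMSE,
# PSNR and a global SSIM statistic, evaluated over a binary mask (body
# mask for whole-volume metrics, structure masks for per-contour
# metrics), plus HU histograms and cohort summary tables.
#
# Naming note: "MAPE" follows the field's usage for the mean absolute
# prediction error *in Hounsfield Units* -- it is a mean absolute error,
# not a percentage.

masked_pair <- function(ct, sct, mask) {
  ctd <- if (inherits(ct, "voxel_volume")) ct$data else ct
  sctd <- if (inherits(sct, "voxel_volume")) sct$data else sct
  if (!identical(dim(ctd), dim(sctd)) || length(ctd) != length(sctd))
    stop("volumes must share dimensions")
  if (is.null(mask)) mask <- rep(TRUE, length(ctd))
  if (length(mask) != length(ctd) ||
      (!is.null(dim(ctd)) && !is.null(dim(mask)) &&
       !identical(dim(mask), dim(ctd))))
    stop("mask must match the volume grid")
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  list(ct = ctd[mask], sct = sctd[mask])
}

#' Mean absolute prediction error (HU)
#'
#' Mean over masked voxels of `|HU_CT - HU_sCT|`.
#'
#' @param ct,sct CT and synthetic-CT volumes (arrays or [voxel_volume()]s)
#'   in HU.
#' @param mask binary volume selecting the voxels to evaluate; `NULL` for
#'   all voxels.
#' @return scalar in HU.
#' @export
mape <- function(ct, sct, mask = NULL) {
  p <- masked_pair(ct, sct, mask)
  mean(abs(p$ct - p$sct))
}

#' Root mean square error (HU)
#'
#' @inheritParams mape
#' @return scalar in HU; always `>= mape()` on the same input.
#' @export
rmse <- function(ct, sct, mask = NULL) {
  p <- masked_pair(ct, sct, mask)
  sqrt(mean((p$ct - p$sct)^2))
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 log10(MAX^2 / MSE)` over the masked voxels. `MAX` defaults to the
#' maximum measured-CT intensity over the mask. Identical volumes give
#' `Inf` (zero error), not an exception.
#'
#' @inheritParams mape
#' @param max_value peak intensity `MAX`; default `max(ct[mask])`.
#' @return scalar in decibels (possibly `Inf`).
#' @export
psnr <- function(ct, sct, mask = NULL, max_value = NULL) {
  p <- masked_pair(ct, sct, mask)
  mse <- mean((p$ct - p$sct)^2)
  if (is.null(max_value)) max_value <- max(p$ct)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

#' SSIM stabilizer constants
#'
#' The standard stabilizers `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` derived
#' from the dynamic range `L` of the CT domain.
#'
#' @param dynamic_range scalar `L` (default 4095, the span of the default
#'   -1024..3071 HU scale).
#' @param c1,c2 explicit overrides.
#' @return object of class `ssim_params`.
#' @export
ssim_params <- function(dynamic_range = 4095,
                        c1 = (0.01 * dynamic_range)^2,
                        c2 = (0.03 * dynamic_range)^2) {
  if (c1 <= 0 || c2 <= 0) stop("SSIM stabilizers must be positive")
  structure(list(c1 = c1, c2 = c2, dynamic_range = dynamic_range),
            class = "ssim_params")
}

#' Global structural similarity index
#'
#' The single global (non-windowed) SSIM statistic over the masked voxels:
#' `(2 mu_s mu_c + c1)(2 cov + c2) / ((mu_s^2 + mu_c^2 + c1)(var_s +
#' var_c + c2))` with means, variances and covariance computed over the
#' mask.
#'
#' @inheritParams mape
#' @param params an [ssim_params()].
#' @return dimensionless scalar in \[-1, 1\]; 1 when the volumes agree on
#'   the mask.
#' @export
ssim_global <- function(ct, sct, mask = NULL, params = ssim_params()) {
  p <- masked_pair(ct, sct, mask)
  n <- length(p$ct)
  mu_c <- mean(p$ct); mu_s <- mean(p$sct)
  var_c <- mean((p$ct - mu_c)^2)
  var_s <- mean((p$sct - mu_s)^2)
  cov_sc <- mean((p$ct - mu_c) * (p$sct - mu_s))
  ((2 * mu_s * mu_c + params$c1) * (2 * cov_sc + params$c2)) /
    ((mu_s^2 + mu_c^2 + params$c1) * (var_s + var_c + params$c2))
}

#' Per-contour and whole-body metrics report
#'
#' Computes MAPE, RMSE, PSNR and global SSIM for each structure mask of a
#' case and for the whole body (air outside the body excluded via the
#' body mask). Missing structures are skipped with a warning.
#'
#' @param case a [paired_case()] with masks.
#' @param sct synthetic-CT [voxel_volume()] on the case grid, HU domain.
#' @param params an [ssim_params()].
#' @param max_value PSNR peak intensity; default the masked measured-CT
#'   maximum of each region's evaluation (see [psnr()]).
#' @param structures structure names to report.
#' @return tibble with one row per region: `subject_id`, `region`,
#'   `mape`, `rmse`, `psnr`, `ssim`, `n_voxels`.
#' @export
contour_metrics <- function(case, sct, params = ssim_params(),
                            max_value = NULL,
                            structures = c("GTV", "femur_R", "femur_L",
                                           "bladder", "anorectum")) {
  stopifnot(inherits(case, "paired_case"), inherits(sct, "voxel_volume"))
  if (!identical(dim(sct$data), dim(case$ct$data)))
    stop("synthetic CT must be on the case grid")
  regions <- c("body", structures)
  rows <- list()
  for (rg in regions) {
    m <- case$masks$masks[[rg]]
    if (is.null(m)) {
      warning("missing structure mask: ", rg, " (skipped)")
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      subject_id = case$subject_id,
      region = rg,
      mape = mape(case$ct$data, sct$data, m),
      rmse = rmse(case$ct$data, sct$data, m),
      psnr = psnr(case$ct$data, sct$data, m, max_value),
      ssim = ssim_global(case$ct$data, sct$data, m, params),
      n_voxels = sum(m > 0))
  }
  do.call(rbind, rows)
}

#' HU histogram over a mask
#'
#' Counts masked voxels per bin; out-of-range voxels are clipped into the
#' end bins so counts always sum to the masked voxel count.
#'
#' @param volume HU volume (array or [voxel_volume()]).
#' @param mask binary mask (`NULL` for all voxels).
#' @param bin_edges strictly increasing bin edges; default 50 uniform bins
#'   spanning -1024..1600 HU.
#' @return tibble with `bin_lo`, `bin_hi`, `count`.
#' @export
hu_histogram <- function(volume, mask = NULL,
                         bin_edges = seq(-1024, 1600, length.out = 51)) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  v <- if (inherits(volume, "voxel_volume")) volume$data else volume
  if (is.null(mask)) mask <- array(TRUE, dim(v))
  if (!any(mask > 0)) stop("empty mask")
  x <- v[mask > 0]
  x <- clamp(x, bin_edges[1], bin_edges[length(bin_edges)])
  counts <- hist(x, breaks = bin_edges, plot = FALSE)$counts
  tibble::tibble(bin_lo = bin_edges[-length(bin_edges)],
                 bin_hi = bin_edges[-1],
                 count = counts)
}

#' Cohort summary of metric reports
#'
#' Mean and sample standard deviation of each metric across subjects, per
#' region ("Mean +/- SD" convention). With a single subject the SD is
#' reported as 0 and flagged.
#'
#' @param reports tibble of per-subject [contour_metrics()] rows.
#' @return tibble with `region`, `metric`, `mean`, `sd`, `n_subjects`,
#'   `single_subject`.
#' @export
summarize_cohort <- function(reports) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1L)
  metrics <- c("mape", "rmse", "psnr", "ssim")
  out <- list()
  for (rg in unique(reports$region)) {
    sub <- reports[reports$region == rg, ]
    for (m in metrics) {
      v <- sub[[m]]
      out[[length(out) + 1L]] <- tibble::tibble(
        region = rg, metric = m,
        mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else 0,
        n_subjects = length(v),
        single_subject = length(v) == 1L)
    }
  }
  do.call(rbind, out)
}
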