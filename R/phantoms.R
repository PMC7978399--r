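# Digital pelvis phantom: seed-reproducible cohorts of paired pseudo-MR /
# pseudo-CT volumes with the five contoured structures (GTV, both femurs,
# bladder, anorectum) plus a body mask.
#
# The phantom is a deliberately simple ellipse-and-blob procedural model:
# an elliptical torso with a subcutaneous fat rim, two circular femurs
# with a cortical rim and a medullary core, an ellipsoidal fluid-filled
# bladder, a tubular anorectum with an air lumen, and a tumor blob between
# bladder and anorectum. It is not anatomically realistic; it exists so
# that every tissue regime (air / soft tissue / fat / fluid / bone) and
# every per-contour metric is exercised by data with a known ground-truth
# MR-to-CT mapping.
#
# MR and CT intensities are linked voxelwise: each voxel gets a latent
# texture value u in [0, 1] and its tissue class; MR = mr_lo + u * (mr_hi -
# mr_lo) and CT = hu_lo + u * (hu_hi - hu_lo) from the tissue table, plus
# optional Gaussian noise. With zero noise the CT therefore equals
# true_forward_map(MR) exactly, which is what the mapping-recovery tests
# rely on. MR contrast is T2-like: fluid brightest, then tumor, soft
# tissue, fat, with bone and air dark.

#' Default tissue intensity table
#'
#' Maps each tissue class to its CT Hounsfield-Unit range and its (unitless)
#' MR intensity range. The MR ordering is T2-like: fluid > tumor >
#' soft tissue > fat > bone ~ air.
#'
#' @return data.frame with columns `name`, `hu_lo`, `hu_hi`, `mr_lo`,
#'   `mr_hi`.
#' @export
default_tissue_table <- function() {
  data.frame(
    name = c("air", "soft_tissue", "fat", "bone", "fluid", "tumor"),
    hu_lo = c(-1010, 20, -120, 200, -5, 30),
    hu_hi = c(-990, 60, -80, 1300, 15, 70),
    mr_lo = c(0.00, 0.35, 0.25, 0.02, 0.80, 0.55),
    mr_hi = c(0.05, 0.55, 0.35, 0.18, 1.00, 0.75),
    stringsAsFactors = FALSE
  )
}

#' Phantom cohort configuration
#'
#' The defaults emulate the study cohort geometry: 11 subjects on a
#' 144 x 144 in-plane grid with 44 or 50 transverse slices per subject
#' (subjects 1, 2, 3 and 5 have 50, the others 44, for 508 slices in
#' total) and 3.2 x 3.2 x 5 mm voxel spacing.
#'
#' @param n_subjects number of subjects (>= 2 so that leave-one-out is
#'   defined).
#' @param grid in-plane dimensions; both must be divisible by 4 so two 2x2
#'   poolings are exact.
#' @param slice_count_choices admissible per-subject slice counts.
#' @param slice_counts explicit per-subject slice counts, or `NULL` to
#'   assign by rule: the default 11-subject cohort uses the fixed pattern
#'   above; any other configuration draws counts from
#'   `slice_count_choices` under the cohort seed.
#' @param spacing_mm voxel spacing triple in mm.
#' @param tissue_table tissue intensity table, see [default_tissue_table()].
#' @param noise_sd named additive Gaussian noise scales, `c(mr = ..., ct =
#'   ...)`; `mr` is in normalized MR units, `ct` in HU.
#' @param seed integer cohort seed; subject `i` uses `seed + i`.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(n_subjects = 11L,
                           grid = c(144L, 144L),
                           slice_count_choices = c(44L, 50L),
                           slice_counts = NULL,
                           spacing_mm = c(3.2, 3.2, 5),
                           tissue_table = default_tissue_table(),
                           noise_sd = c(mr = 0.02, ct = 10),
                           seed = 1L) {
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid %% 4L != 0L))
    stop("grid dimensions must be divisible by 4")
  if (any(slice_count_choices <= 0L)) stop("slice counts must be positive")
  req <- c("name", "hu_lo", "hu_hi", "mr_lo", "mr_hi")
  if (!all(req %in% names(tissue_table))) stop("malformed tissue table")
  if (anyDuplicated(tissue_table$name)) stop("tissue names must be unique")
  if (any(tissue_table$hu_hi <= tissue_table$hu_lo))
    stop("all HU ranges must be ordered (lo < hi)")
  if (any(tissue_table$mr_hi <= tissue_table$mr_lo))
    stop("all MR ranges must be ordered (lo < hi)")
  if (!all(c("mr", "ct") %in% names(noise_sd)) || any(noise_sd < 0))
    stop("noise_sd must be c(mr = ..., ct = ...) with non-negative values")
  if (!is.null(slice_counts)) {
    if (length(slice_counts) != n_subjects)
      stop("slice_counts must have one entry per subject")
    if (!all(slice_counts %in% slice_count_choices))
      stop("slice_counts must be drawn from slice_count_choices")
  }
  structure(list(n_subjects = as.integer(n_subjects), grid = grid,
                 slice_count_choices = as.integer(sort(slice_count_choices)),
                 slice_counts = if (!is.null(slice_counts)) as.integer(slice_counts),
                 spacing_mm = as.numeric(spacing_mm),
                 tissue_table = tissue_table,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

tissue_row <- function(config_or_table, name) {
  tt <- if (inherits(config_or_table, "phantom_config"))
    config_or_table$tissue_table else config_or_table
  i <- match(name, tt$name)
  if (is.na(i)) stop("unknown tissue name: ", name)
  as.list(tt[i, ])
}

#' Ground-truth MR-to-CT mapping of the phantom
#'
#' The per-tissue linear map used to construct the phantom: an MR value at
#' fraction `u` of the tissue's MR range maps to the same fraction of the
#' tissue's HU range. Deterministic and monotone within a tissue class,
#' and the exact inverse of the phantom construction when `noise_sd = 0`.
#'
#' @param mr_value MR intensity (scalar or array).
#' @param tissue a tissue name (looked up in `tissue_table`) or a row of
#'   the tissue table as a list.
#' @param tissue_table tissue table used when `tissue` is a name.
#' @return CT value(s) in HU.
#' @export
true_forward_map <- function(mr_value, tissue,
                             tissue_table = default_tissue_table()) {
  tr <- if (is.character(tissue)) tissue_row(tissue_table, tissue) else tissue
  u <- (mr_value - tr$mr_lo) / (tr$mr_hi - tr$mr_lo)
  tr$hu_lo + u * (tr$hu_hi - tr$hu_lo)
}

# elliptic/circular region helper on the in-plane grid
in_ellipse <- function(X, Y, cx, cy, a, b) ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1

#' Generate one phantom subject
#'
#' Builds a paired MR/CT volume with the five structure masks plus the
#' body mask. Deterministic for fixed `(config, subject_id, n_slices)`.
#'
#' @param config a [phantom_config()].
#' @param subject_id subject identifier; the default ids are `"S01"`,
#'   `"S02"`, ... and the numeric suffix selects the per-subject seed
#'   `config$seed + index`.
#' @param n_slices slice count; must be one of
#'   `config$slice_count_choices`.
#' @param seed optional explicit seed overriding the id-derived one.
#' @return a [paired_case()].
#' @export
generate_subject <- function(config, subject_id, n_slices, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (!(n_slices %in% config$slice_count_choices))
    stop("n_slices must be one of the configured slice_count_choices")
  if (is.null(seed)) {
    idx <- suppressWarnings(as.integer(gsub("[^0-9]", "", subject_id)))
    if (is.na(idx)) idx <- 0L
    seed <- config$seed + idx
  }
  H <- config$grid[1]; W <- config$grid[2]; S <- as.integer(n_slices)
  tt <- config$tissue_table
  with_preserved_rng({
    set.seed(as.integer(seed))
    jit <- function(x, frac) x * stats::runif(1, 1 - frac, 1 + frac)
    cx <- H / 2 + stats::runif(1, -2, 2)     # left-right centre
    cy <- W * 0.52 + stats::runif(1, -2, 2)  # anterior-posterior centre
    a0 <- jit(0.40 * H, 0.05)                # torso LR semi-axis
    b0 <- jit(0.30 * W, 0.05)                # torso AP semi-axis
    fem_r <- jit(0.085 * H, 0.10)            # femur radius
    fem_dx <- 0.55 * a0
    fem_cy <- cy + 0.15 * b0
    bla_cx <- cx; bla_cy <- cy - 0.45 * b0
    bla_a <- jit(0.12 * H, 0.10); bla_b <- jit(0.10 * W, 0.10)
    ano_cy <- cy + 0.62 * b0
    ano_r <- jit(0.040 * H, 0.10)
    gtv_cx <- cx + stats::runif(1, -1, 1)
    gtv_cy <- (bla_cy + ano_cy) / 2
    gtv_r <- jit(0.055 * H, 0.10)
    zc <- (S + 1) / 2

    X <- matrix(seq_len(H), H, W)
    Y <- matrix(seq_len(W), H, W, byrow = TRUE)

    lab <- array(1L, c(H, W, S))          # tissue-class index per voxel
    names_idx <- stats::setNames(seq_len(nrow(tt)), tt$name)
    masks <- list(GTV = array(FALSE, c(H, W, S)),
                  femur_R = array(FALSE, c(H, W, S)),
                  femur_L = array(FALSE, c(H, W, S)),
                  bladder = array(FALSE, c(H, W, S)),
                  anorectum = array(FALSE, c(H, W, S)),
                  body = array(FALSE, c(H, W, S)))
    rim_dist <- array(0, c(H, W, S))      # femur radial fraction for texture

    for (s in seq_len(S)) {
      zfrac <- (s - zc) / (S / 2)
      sc <- 1 - 0.10 * zfrac^2            # mild taper along z
      body <- in_ellipse(X, Y, cx, cy, a0 * sc, b0 * sc)
      inner <- in_ellipse(X, Y, cx, cy, 0.88 * a0 * sc, 0.86 * b0 * sc)
      fat <- body & !inner
      femR <- in_ellipse(X, Y, cx - fem_dx * sc, fem_cy, fem_r, fem_r) & inner
      femL <- in_ellipse(X, Y, cx + fem_dx * sc, fem_cy, fem_r, fem_r) & inner
      # bladder and GTV on the central slices only
      bl_z <- 1 - (zfrac / 0.65)^2
      bla <- if (bl_z > 0)
        in_ellipse(X, Y, bla_cx, bla_cy, bla_a * sqrt(bl_z), bla_b * sqrt(bl_z)) & inner
      else matrix(FALSE, H, W)
      gt_z <- 1 - (zfrac / 0.55)^2
      gtv <- if (gt_z > 0)
        in_ellipse(X, Y, gtv_cx, gtv_cy, gtv_r * sqrt(gt_z), gtv_r * sqrt(gt_z)) & inner
      else matrix(FALSE, H, W)
      ano <- in_ellipse(X, Y, cx, ano_cy, ano_r, ano_r) & body
      lum <- in_ellipse(X, Y, cx, ano_cy, 0.45 * ano_r, 0.45 * ano_r) & body

      # pairwise disjointness by priority: femurs, bladder, anorectum, GTV
      bla <- bla & !femR & !femL
      ano <- ano & !femR & !femL & !bla
      lum <- lum & ano
      gtv <- gtv & !femR & !femL & !bla & !ano

      sl <- matrix(names_idx[["air"]], H, W)
      sl[body] <- names_idx[["soft_tissue"]]
      sl[fat] <- names_idx[["fat"]]
      sl[femR | femL] <- names_idx[["bone"]]
      sl[bla] <- names_idx[["fluid"]]
      sl[gtv] <- names_idx[["tumor"]]
      sl[ano] <- names_idx[["soft_tissue"]]
      sl[lum] <- names_idx[["air"]]
      lab[, , s] <- sl

      rd <- matrix(0, H, W)
      dR <- sqrt(((X - (cx - fem_dx * sc)))^2 + ((Y - fem_cy))^2) / fem_r
      dL <- sqrt(((X - (cx + fem_dx * sc)))^2 + ((Y - fem_cy))^2) / fem_r
      rd[femR] <- dR[femR]; rd[femL] <- dL[femL]
      rim_dist[, , s] <- rd

      masks$GTV[, , s] <- gtv
      masks$femur_R[, , s] <- femR
      masks$femur_L[, , s] <- femL
      masks$bladder[, , s] <- bla
      masks$anorectum[, , s] <- ano | lum
      masks$body[, , s] <- body
    }

    # latent texture: uniform, except femurs where the cortical rim is
    # mapped high in the bone range and the medulla low
    u <- array(stats::runif(H * W * S), c(H, W, S))
    bone_vox <- lab == names_idx[["bone"]]
    rim <- bone_vox & rim_dist > 0.6
    med <- bone_vox & !rim
    u[rim] <- 0.60 + 0.40 * u[rim]
    u[med] <- 0.30 * u[med]

    mr <- array(0, c(H, W, S)); ct <- array(0, c(H, W, S))
    for (i in seq_len(nrow(tt))) {
      sel <- lab == i
      mr[sel] <- tt$mr_lo[i] + u[sel] * (tt$mr_hi[i] - tt$mr_lo[i])
      ct[sel] <- tt$hu_lo[i] + u[sel] * (tt$hu_hi[i] - tt$hu_lo[i])
    }
    if (config$noise_sd[["mr"]] > 0)
      mr <- mr + stats::rnorm(length(mr), 0, config$noise_sd[["mr"]])
    if (config$noise_sd[["ct"]] > 0)
      ct <- ct + stats::rnorm(length(ct), 0, config$noise_sd[["ct"]])

    paired_case(subject_id,
                voxel_volume(mr, config$spacing_mm, "MR", "arbitrary"),
                voxel_volume(ct, config$spacing_mm, "CT", "HU"),
                structure_mask_set(masks))
  })
}

cohort_slice_counts <- function(config) {
  if (!is.null(config$slice_counts)) return(config$slice_counts)
  n <- config$n_subjects
  ch <- config$slice_count_choices
  if (n == 11L && identical(ch, c(44L, 50L))) {
    # the reference cohort pattern: subjects 1, 2, 3, 5 have 50 slices
    ifelse(seq_len(n) %in% c(1L, 2L, 3L, 5L), 50L, 44L)
  } else {
    with_preserved_rng({
      set.seed(config$seed)
      sample(ch, n, replace = TRUE)
    })
  }
}

#' Generate a phantom cohort
#'
#' Produces `n_subjects` paired cases with deterministic per-subject seeds
#' (`config$seed + i`) and unique identifiers `"S01"`, `"S02"`, ... Under
#' the default configuration the per-subject slice counts follow the
#' reference cohort pattern (50 slices for subjects 1, 2, 3 and 5; 44
#' otherwise; 508 slices in total).
#'
#' @param config a [phantom_config()].
#' @return list of [paired_case()] objects.
#' @export
generate_cohort <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$n_subjects < 2L)
    stop("a cohort needs at least 2 subjects (leave-one-out is undefined otherwise)")
  counts <- cohort_slice_counts(config)
  lapply(seq_len(config$n_subjects), function(i)
    generate_subject(config, sprintf("S%02d", i), counts[i],
                     seed = config$seed + i))
}
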