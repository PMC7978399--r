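# Volume I/O, normalization, body masking, flips and slice handling.

test_that("NIfTI round trip preserves data and spacing", {
  v <- voxel_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)),
                    spacing_mm = c(3.2, 3.2, 5), modality = "CT",
                    intensity_domain = "HU")
  tf <- tempfile(fileext = ".nii.gz")
  write_volume(v, tf)
  r <- read_volume(tf, modality = "CT")
  expect_equal(r$data, v$data, tolerance = 1e-6)
  expect_equal(r$spacing_mm, c(3.2, 3.2, 5), tolerance = 1e-6)
  expect_equal(r$intensity_domain, "HU")
  rmr <- read_volume(tf, modality = "MR")
  expect_equal(rmr$intensity_domain, "arbitrary")
})

test_that("missing files and unsupported formats raise clear errors", {
  expect_error(read_volume(tempfile()), "no such file")
  expect_error(read_volume(tempfile(), format = "dicom"), "DICOM")
})

test_that("unit normalization follows (v - lo) / (hi - lo) and is invertible", {
  v <- voxel_volume(array(c(-1000, 0, 1000, 500, -500, 250, 750, -250),
                          c(2, 2, 2)), modality = "CT", intensity_domain = "HU")
  n <- normalize_to_unit(v)
  expect_equal(n$scale$lo, -1000)
  expect_equal(n$scale$hi, 1000)
  expect_equal(sort(unique(as.numeric(n$volume$data)))[c(1, 4, 8)],
               c(0, 0.5, 1))
  expect_equal(n$volume$intensity_domain, "normalized")
  back <- denormalize(n$volume, n$scale, modality = "CT")
  expect_equal(back$data, v$data, tolerance = 1e-6 * 2000)
  # already normalized input with min 0 and max 1 is unchanged
  u <- voxel_volume(array(c(0, 0.25, 0.5, 1, 0.75, 0.1, 0.9, 0.3), c(2, 2, 2)))
  expect_equal(normalize_to_unit(u)$volume$data, u$data)
  # denormalizing 0.5 on scale (-1000, 1000) gives 0 HU; 0 gives lo
  s <- intensity_scale(-1000, 1000)
  half <- voxel_volume(array(0.5, c(1, 1, 1)), intensity_domain = "normalized")
  expect_equal(as.numeric(denormalize(half, s)$data), 0)
  zero <- voxel_volume(array(0, c(1, 1, 1)), intensity_domain = "normalized")
  expect_equal(as.numeric(denormalize(zero, s)$data), -1000)
  # constant volume is degenerate
  cst <- voxel_volume(array(5, c(2, 2, 2)))
  expect_error(normalize_to_unit(cst), "constant")
})

test_that("air mask recovers the phantom body and keeps interior air", {
  case <- small_cohort()[[1]]
  m <- compute_air_mask(case$ct, hu_threshold = -400, closing_radius = 0L)
  expect_identical(m, case$masks$masks$body)
  # anorectal lumen is air yet inside the mask
  lumen <- case$masks$masks$anorectum & case$ct$data < -400
  expect_gt(sum(lumen), 0)
  expect_true(all(m[lumen]))
  # idempotence: masking a masked volume changes nothing
  ctm <- case$ct$data
  ctm[!m] <- -1000
  m2 <- compute_air_mask(voxel_volume(ctm, case$ct$spacing_mm, "CT", "HU"),
                         hu_threshold = -400, closing_radius = 0L)
  expect_identical(m2, m)
  # default closing changes at most a thin boundary layer
  mc <- compute_air_mask(case$ct, hu_threshold = -400)
  expect_gt(mean(mc == case$masks$masks$body), 0.99)
  # degenerate input: all air
  allair <- voxel_volume(array(-1000, c(8, 8, 2)), modality = "CT",
                         intensity_domain = "HU")
  expect_error(compute_air_mask(allair), "all air")
  # domain check
  expect_error(compute_air_mask(voxel_volume(array(0.5, c(4, 4, 2)))), "HU")
})

test_that("left/right flip is an involution that preserves pairing and histograms", {
  case <- small_cohort()[[1]]
  s <- extract_slices(case)[[2]]
  f <- flip_lr(s)
  expect_identical(flip_lr(f)$mr_slice, s$mr_slice)
  expect_identical(flip_lr(f)$ct_slice, s$ct_slice)
  expect_equal(sort(as.numeric(f$ct_slice)), sort(as.numeric(s$ct_slice)))
  # voxelwise pairing preserved: flipped MR row i equals original row n+1-i
  n <- nrow(s$mr_slice)
  expect_identical(f$mr_slice[1, ], s$mr_slice[n, ])
  expect_identical(f$ct_slice[1, ], s$ct_slice[n, ])
  # right femur maps onto left femur coordinates
  sl <- which(apply(case$masks$masks$femur_R, 3, any))[1]
  femR <- case$masks$masks$femur_R[, , sl]
  femL <- case$masks$masks$femur_L[, , sl]
  flippedR <- femR[rev(seq_len(nrow(femR))), ]
  ovl <- sum(flippedR & femL) / sum(femR)
  expect_gt(ovl, 0.5)
})

test_that("slice extraction is lossless and ordered", {
  case <- small_cohort()[[1]]
  sl <- extract_slices(case)
  expect_length(sl, dim(case$ct$data)[3])
  expect_equal(vapply(sl, `[[`, 0L, "slice_index"), 0:(length(sl) - 1L))
  expect_identical(stack_slices(sl, "ct"), case$ct$data)
  expect_identical(stack_slices(sl, "mr"), case$mr$data)
})

test_that("slice counts equal the third grid dimension for cohort-shaped cases", {
  cfg <- phantom_config()
  for (n in c(44L, 50L)) {
    case <- generate_subject(cfg, "S04", n)
    expect_length(extract_slices(case), n)
  }
})
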