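# Evaluation metrics: closed-form examples, inequalities and invariances.

test_that("mape and rmse follow their definitions", {
  full <- NULL
  expect_equal(mape(c(0, 100), c(10, 90), NULL), 10)
  expect_equal(mape(c(0, 0), c(3, 4), NULL), 3.5)
  expect_equal(rmse(c(0, 0), c(3, 4), NULL), sqrt(12.5))
  x <- array(rnorm(8), c(2, 2, 2))
  expect_equal(mape(x, x), 0)
  expect_equal(rmse(x, x), 0)
  expect_error(mape(x, x, array(FALSE, dim(x))), "empty mask")
})

test_that("mape <= rmse with equality only for constant absolute error", {
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(50); b <- rnorm(50)
    expect_lte(mape(a, b, NULL), rmse(a, b, NULL) + 1e-12)
  }
  expect_equal(mape(c(0, 0), c(2, -2), NULL), rmse(c(0, 0), c(2, -2), NULL))
})

test_that("psnr identities hold", {
  # MAX = 1, MSE = 0.01 -> 20 dB
  ct <- rep(0, 100); sct <- rep(0.1, 100)
  expect_equal(psnr(ct, sct, NULL, max_value = 1), 20)
  # identical volumes give the infinite sentinel, not an error
  expect_identical(psnr(ct, ct, NULL, max_value = 1), Inf)
  # halving all errors adds 10 log10(4) dB
  set.seed(4)
  a <- rnorm(200); e <- rnorm(200)
  p1 <- psnr(a, a + e, NULL, max_value = 10)
  p2 <- psnr(a, a + e / 2, NULL, max_value = 10)
  expect_equal(p2 - p1, 10 * log10(4))
  # monotone decreasing in MSE at fixed MAX
  p3 <- psnr(a, a + 2 * e, NULL, max_value = 10)
  expect_true(p3 < p1 && p1 < p2)
})

test_that("global SSIM matches its closed form and bounds", {
  # constant volumes: second factor 1, first factor per the formula
  a <- rep(2, 10); b <- rep(4, 10)
  p <- ssim_params(c1 = 0.01, c2 = 0.01)
  expect_equal(ssim_global(a, b, NULL, p), 16.01 / 20.01)
  set.seed(5)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(ssim_global(x, y, NULL), ssim_global(y, x, NULL))
  expect_equal(ssim_global(x, x, NULL), 1, tolerance = 1e-9)
  for (i in 1:10) {
    u <- rnorm(50, sd = runif(1, 0.5, 3)); v <- rnorm(50, sd = runif(1, 0.5, 3))
    s <- ssim_global(u, v, NULL)
    expect_true(s >= -1 - 1e-12 && s <= 1 + 1e-12)
  }
})

test_that("metrics are invariant under a common voxel permutation", {
  set.seed(6)
  ct <- array(rnorm(4 * 4 * 3, 0, 100), c(4, 4, 3))
  sct <- ct + array(rnorm(48, 0, 20), c(4, 4, 3))
  mask <- array(runif(48) > 0.3, c(4, 4, 3))
  perm <- sample(48)
  pct <- array(ct[perm], dim(ct)); psct <- array(sct[perm], dim(ct))
  pmask <- array(mask[perm], dim(ct))
  expect_equal(mape(ct, sct, mask), mape(pct, psct, pmask))
  expect_equal(rmse(ct, sct, mask), rmse(pct, psct, pmask))
  expect_equal(psnr(ct, sct, mask, 100), psnr(pct, psct, pmask, 100))
  expect_equal(ssim_global(ct, sct, mask), ssim_global(pct, psct, pmask))
})

test_that("contour metrics agree with direct mask calls and count body voxels", {
  case <- small_cohort()[[1]]
  sct <- voxel_volume(case$ct$data + array(rnorm(length(case$ct$data), 0, 30),
                                           dim(case$ct$data)),
                      case$ct$spacing_mm, "SCT", "HU")
  rep <- contour_metrics(case, sct)
  expect_setequal(rep$region, c("body", "GTV", "femur_R", "femur_L",
                                "bladder", "anorectum"))
  bl <- rep[rep$region == "bladder", ]
  expect_equal(bl$mape, mape(case$ct$data, sct$data, case$masks$masks$bladder))
  expect_equal(rep[rep$region == "body", ]$n_voxels,
               sum(case$masks$masks$body))
  # perfect prediction: zero error, unit similarity in every region
  perfect <- contour_metrics(case, case$ct)
  expect_true(all(perfect$mape == 0))
  expect_true(all(perfect$ssim == 1))
  expect_true(all(is.infinite(perfect$psnr)))
  # missing mask is skipped with a warning
  case2 <- case
  case2$masks$masks$GTV <- NULL
  expect_warning(rep2 <- contour_metrics(case2, sct), "GTV")
  expect_false("GTV" %in% rep2$region)
})

test_that("HU histograms conserve counts and clip out-of-range voxels", {
  case <- small_cohort()[[1]]
  m <- case$masks$masks$femur_R
  h <- hu_histogram(case$ct, m)
  expect_equal(sum(h$count), sum(m))
  # single value -> one bin
  v <- array(100, c(3, 3, 2))
  h1 <- hu_histogram(v, NULL)
  expect_equal(sum(h1$count > 0), 1L)
  # clipping: far out-of-range mass lands in the end bins
  v2 <- array(c(-5000, 5000), c(1, 1, 2))
  h2 <- hu_histogram(v2, NULL)
  expect_equal(h2$count[1], 1L)
  expect_equal(h2$count[nrow(h2)], 1L)
  # permutation invariance via flip
  sl <- extract_slices(case)[[1]]
  f <- flip_lr(sl)
  expect_equal(hu_histogram(array(sl$ct_slice, c(dim(sl$ct_slice), 1)))$count,
               hu_histogram(array(f$ct_slice, c(dim(f$ct_slice), 1)))$count)
  expect_error(hu_histogram(v, NULL, bin_edges = c(0, 0, 1)), "increasing")
})

test_that("cohort summaries report mean and sample SD per region", {
  reps <- do.call(rbind, lapply(1:3, function(i) tibble::tibble(
    subject_id = paste0("S", i), region = "body",
    mape = i, rmse = i + 1, psnr = 60 + i, ssim = 0.8, n_voxels = 100)))
  s <- summarize_cohort(reps)
  row <- s[s$metric == "mape", ]
  expect_equal(row$mean, 2)
  expect_equal(row$sd, 1)
  # permutation of subjects leaves the summary unchanged
  s2 <- summarize_cohort(reps[c(3, 1, 2), ])
  expect_equal(s, s2)
  # single subject: SD 0 by convention, flagged
  s1 <- summarize_cohort(reps[1, ])
  expect_true(all(s1$sd == 0))
  expect_true(all(s1$single_subject))
})
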