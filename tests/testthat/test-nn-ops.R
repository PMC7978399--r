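# Low-level tensor operations against naive loop oracles and finite
# differences.

test_that("convolution matches the naive direct oracle", {
  set.seed(11)
  for (case in list(list(h = 6, w = 8, cin = 2, cout = 3, k = 3, s = 1),
                    list(h = 8, w = 8, cin = 1, cout = 2, k = 4, s = 1),
                    list(h = 8, w = 6, cin = 3, cout = 2, k = 3, s = 2),
                    list(h = 10, w = 10, cin = 2, cout = 1, k = 2, s = 1))) {
    x <- array(rnorm(case$h * case$w * case$cin), c(case$h, case$w, case$cin))
    w <- array(rnorm(case$k^2 * case$cin * case$cout),
               c(case$k, case$k, case$cin, case$cout))
    b <- rnorm(case$cout)
    got <- sucgan:::conv2d_forward(x, w, b, case$s)$out
    want <- naive_conv2d(x, w, b, case$s)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("convolution backward agrees with finite differences", {
  set.seed(12)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  w <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  b <- rnorm(2)
  f <- sucgan:::conv2d_forward(x, w, b, 1L)
  dout <- array(rnorm(length(f$out)), dim(f$out))
  bk <- sucgan:::conv2d_backward(dout, w, f$cache)
  loss <- function(xx, ww, bb) sum(sucgan:::conv2d_forward(xx, ww, bb, 1L)$out * dout)
  eps <- 1e-6
  for (i in sample(length(x), 5)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal(bk$dx[i], (loss(xp, w, b) - loss(xm, w, b)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (i in sample(length(w), 5)) {
    wp <- w; wp[i] <- wp[i] + eps
    wm <- w; wm[i] <- wm[i] - eps
    expect_equal(bk$dw[i], (loss(x, wp, b) - loss(x, wm, b)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("transposed convolution doubles spatial size and is the conv adjoint", {
  set.seed(13)
  h <- 5; w_ <- 4; cin <- 3; cout <- 2; k <- 4
  x <- array(rnorm(h * w_ * cin), c(h, w_, cin))
  w <- array(rnorm(k * k * cout * cin), c(k, k, cout, cin))
  f <- sucgan:::tconv2d_forward(x, w, NULL)
  expect_equal(dim(f$out), c(2 * h, 2 * w_, cout))
  # adjoint identity: <tconv(x), y> == <x, conv_s2(y)> with tied weights
  y <- array(rnorm(length(f$out)), dim(f$out))
  wc <- aperm(w, c(1, 2, 3, 4))            # (k,k,cout,cin) as conv (k,k,cout->cin)
  cy <- sucgan:::conv2d_forward(y, wc, NULL, 2L)$out
  expect_equal(sum(f$out * y), sum(x * cy), tolerance = 1e-10)
  # backward vs finite differences
  bk <- sucgan:::tconv2d_backward(y, w, f$cache)
  loss <- function(xx, ww) sum(sucgan:::tconv2d_forward(xx, ww, NULL)$out * y)
  eps <- 1e-6
  for (i in sample(length(x), 4)) {
    xp <- x; xp[i] <- xp[i] + eps; xm <- x; xm[i] <- xm[i] - eps
    expect_equal(bk$dx[i], (loss(xp, w) - loss(xm, w)) / (2 * eps), tolerance = 1e-5)
  }
  for (i in sample(length(w), 4)) {
    wp <- w; wp[i] <- wp[i] + eps; wm <- w; wm[i] <- wm[i] - eps
    expect_equal(bk$dw[i], (loss(x, wp) - loss(x, wm)) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("2x2 max pooling halves dimensions and routes gradients to argmax", {
  set.seed(14)
  x <- array(rnorm(6 * 8 * 2), c(6, 8, 2))
  f <- sucgan:::maxpool2_forward(x)
  expect_equal(dim(f$out), c(3, 4, 2))
  for (i in 1:3) for (j in 1:4) for (c in 1:2)
    expect_equal(f$out[i, j, c],
                 max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c]))
  dout <- array(rnorm(length(f$out)), dim(f$out))
  dx <- sucgan:::maxpool2_backward(dout, f$cache)
  expect_equal(sum(dx != 0), length(dout))    # one winner per window
  expect_equal(sum(dx), sum(dout))
})

test_that("batch norm standardizes in training mode and its backward matches FD", {
  set.seed(15)
  x <- array(rnorm(8 * 8 * 3, mean = 2, sd = 3), c(8, 8, 3))
  g <- runif(3, 0.5, 1.5); b <- rnorm(3)
  f <- sucgan:::batchnorm_forward(x, g, b, numeric(3), rep(1, 3), TRUE)
  for (c in 1:3) {
    z <- (f$out[, , c] - b[c]) / g[c]
    expect_equal(mean(z), 0, tolerance = 1e-8)
    expect_equal(mean(z^2), 1, tolerance = 1e-3)
  }
  dout <- array(rnorm(length(x)), dim(x))
  bk <- sucgan:::batchnorm_backward(dout, g, f$cache)
  loss <- function(xx) sum(sucgan:::batchnorm_forward(xx, g, b, numeric(3),
                                                      rep(1, 3), TRUE)$out * dout)
  eps <- 1e-5
  for (i in sample(length(x), 5)) {
    xp <- x; xp[i] <- xp[i] + eps; xm <- x; xm[i] <- xm[i] - eps
    expect_equal(bk$dx[i], (loss(xp) - loss(xm)) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("relu follows its closed form", {
  expect_equal(relu(-2), 0)
  expect_equal(relu(3), 3)
  expect_equal(relu(0), 0)
  x <- array(c(-1, 2, 0, -3), c(2, 2, 1))
  expect_equal(relu(x), array(c(0, 2, 0, 0), c(2, 2, 1)))
})
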