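# Low-level tensor operations for 2-D convolutional networks.
#
# Tensors are plain numeric arrays of dim (H, W, C), minibatch size 1.
# Convolutions gather an im2col patch matrix with compiled code
# (src/conv.cpp) and reduce to BLAS matrix products; gradients reuse the
# same gather and its scatter-add adjoint.

# 'same' padding bookkeeping: output size ceil(H / stride)
same_pads <- function(n, k, stride) {
  out <- ceiling(n / stride)
  tot <- max(0L, (out - 1L) * stride + k - n)
  before <- tot %/% 2L
  list(out = out, before = before, after = tot - before)
}

pad3 <- function(x, pt, pb, pl, pr) {
  d <- dim(x)
  if (pt + pb + pl + pr == 0L) return(x)
  out <- array(0, c(d[1] + pt + pb, d[2] + pl + pr, d[3]))
  out[pt + seq_len(d[1]), pl + seq_len(d[2]), ] <- x
  out
}

as_mat <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1] * d[2], d[3])
  a
}

#' Rectified linear unit
#'
#' Elementwise `max(0, x)`, the activation used throughout both the
#' generator and the discriminator.
#'
#' @param x numeric scalar, vector or array.
#' @return object of the same shape with negative entries replaced by 0.
#' @export
#' @examples
#' relu(c(-2, 0, 3))
relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- convolution -----------------------------------------------------------
#
# The im2col gather and its scatter-add adjoint are compiled (src/conv.cpp);
# the matrix products run on BLAS.

# x: (H, W, Cin); w: (k, k, Cin, Cout); b: length Cout or NULL.
# Returns list(out, cache); cache carries the patch matrix for backward
# unless keep_cols = FALSE (inference).
conv2d_forward <- function(x, w, b, stride = 1L, keep_cols = TRUE) {
  d <- dim(x); k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  stopifnot(d[3] == cin)
  ph <- same_pads(d[1], k, stride); pw <- same_pads(d[2], k, stride)
  cols <- cpp_im2col(x, d[1], d[2], cin, k, stride, ph$before, pw$before,
                     ph$out, pw$out)
  out <- cols %*% matrix(w, k * k * cin, cout)
  if (!is.null(b)) out <- out + rep(b, each = nrow(out))
  dim(out) <- c(ph$out, pw$out, cout)
  list(out = out,
       cache = list(cols = if (keep_cols) cols, in_dim = d,
                    stride = stride, ph = ph, pw = pw))
}

conv2d_backward <- function(dout, w, cache) {
  k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  ph <- cache$ph; pw <- cache$pw
  d <- cache$in_dim
  dmat <- as_mat(dout)
  dw <- crossprod(cache$cols, dmat)
  dim(dw) <- dim(w)
  dcols <- tcrossprod(dmat, matrix(w, k * k * cin, cout))
  dx <- cpp_col2im(dcols, d[1], d[2], cin, k, cache$stride,
                   ph$before, pw$before, ph$out, pw$out)
  dim(dx) <- d
  list(dx = dx, dw = dw, db = colSums(dmat))
}

# ---- transposed convolution (stride 2, exact x2 upsampling) ---------------

# x: (H, W, Cin); w: (k, k, Cout, Cin); output (2H, 2W, Cout).
# Defined as the linear adjoint of a stride-2 'same' convolution mapping
# (2H, 2W, Cout) -> (H, W, Cin), which is the standard up-convolution.
tconv2d_forward <- function(x, w, b) {
  d <- dim(x); k <- dim(w)[1]; cout <- dim(w)[3]; cin <- dim(w)[4]
  stopifnot(d[3] == cin)
  oh <- 2L * d[1]; ow <- 2L * d[2]
  ph <- same_pads(oh, k, 2L); pw <- same_pads(ow, k, 2L)
  stopifnot(ph$out == d[1], pw$out == d[2])
  xm <- as_mat(x)
  dcols <- tcrossprod(xm, matrix(w, k * k * cout, cin))
  out <- cpp_col2im(dcols, oh, ow, cout, k, 2L, ph$before, pw$before,
                    d[1], d[2])
  dim(out) <- c(oh, ow, cout)
  if (!is.null(b)) out <- out + rep(b, each = oh * ow)
  list(out = out, cache = list(xm = xm, in_dim = d, ph = ph, pw = pw,
                               out_dim = c(oh, ow, cout)))
}

tconv2d_backward <- function(dout, w, cache) {
  k <- dim(w)[1]; cout <- dim(w)[3]; cin <- dim(w)[4]
  od <- cache$out_dim; d <- cache$in_dim
  cols <- cpp_im2col(dout, od[1], od[2], cout, k, 2L,
                     cache$ph$before, cache$pw$before, d[1], d[2])
  dx <- cols %*% matrix(w, k * k * cout, cin)
  dim(dx) <- d
  dw <- crossprod(cols, cache$xm)
  dim(dw) <- dim(w)
  list(dx = dx, dw = dw, db = colSums(as_mat(dout)))
}

# ---- 2x2 max pooling -------------------------------------------------------

maxpool2_forward <- function(x) {
  d <- dim(x)
  stopifnot(d[1] %% 2L == 0L, d[2] %% 2L == 0L)
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  s <- list(x[ro, co, , drop = FALSE], x[re, co, , drop = FALSE],
            x[ro, ce, , drop = FALSE], x[re, ce, , drop = FALSE])
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  win <- array(4L, dim(out))
  win[s[[3]] == out] <- 3L
  win[s[[2]] == out] <- 2L
  win[s[[1]] == out] <- 1L
  list(out = out, cache = list(win = win, in_dim = d))
}

maxpool2_backward <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  sel <- list(list(ro, co), list(re, co), list(ro, ce), list(re, ce))
  for (m in 1:4) {
    g <- dout
    g[cache$win != m] <- 0
    dx[sel[[m]][[1]], sel[[m]][[2]], ] <- g
  }
  dx
}

# ---- batch normalization (spatial, minibatch 1) ---------------------------

batchnorm_forward <- function(x, gamma, beta, run_mean, run_var,
                              training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- as_mat(x)
  f <- cpp_batchnorm_forward(xm, gamma, beta, run_mean, run_var,
                             isTRUE(training), eps)
  out <- f$out
  dim(out) <- d
  if (training) {
    new_mean <- (1 - momentum) * run_mean + momentum * f$mu
    new_var <- (1 - momentum) * run_var + momentum * f$var * n / max(1, n - 1)
  } else {
    new_mean <- run_mean; new_var <- run_var
  }
  list(out = out,
       cache = list(xhat = f$xhat, istd = f$istd, d = d),
       run_mean = new_mean, run_var = new_var)
}

batchnorm_backward <- function(dout, gamma, cache) {
  d <- cache$d
  b <- cpp_batchnorm_backward(as_mat(dout), cache$xhat, cache$istd, gamma)
  dx <- b$dx
  dim(dx) <- d
  list(dx = dx, dgamma = b$dgamma, dbeta = b$dbeta)
}

# ---- dropout ---------------------------------------------------------------

dropout_forward <- function(x, rate) {
  if (rate <= 0) return(list(out = x, cache = NULL))
  mask <- array(stats::runif(length(x)) >= rate, dim(x)) / (1 - rate)
  list(out = x * mask, cache = mask)
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache)) return(dout)
  dout * cache
}
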