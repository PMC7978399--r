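# Shared fixtures: small phantom configurations and tiny networks used
# across test files. Everything is generated in code at test time.

small_phantom_config <- function(noise = TRUE, seed = 7L) {
  phantom_config(n_subjects = 3L, grid = c(32L, 32L),
                 slice_count_choices = c(4L, 6L),
                 slice_counts = c(4L, 4L, 4L),
                 noise_sd = if (noise) c(mr = 0.02, ct = 10) else c(mr = 0, ct = 0),
                 seed = seed)
}

# memoised small noise-free cohort (32x32, 3 subjects x 4 slices)
.fixture_env <- new.env()
small_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- generate_cohort(small_phantom_config(noise = FALSE))
  .fixture_env$cohort
}

tiny_gen_spec <- function(...) generator_spec(stage_features = c(4L, 8L, 16L),
                                              dropout_rate = 0, ...)
tiny_disc_spec <- function() discriminator_spec(block_features = c(4L, 8L, 16L))

# naive direct convolution oracle (zero-padded 'same', stride s)
naive_conv2d <- function(x, w, b, stride = 1L) {
  k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  ph <- sucgan:::same_pads(H, k, stride); pw <- sucgan:::same_pads(W, k, stride)
  xp <- array(0, c(H + ph$before + ph$after, W + pw$before + pw$after, cin))
  xp[ph$before + seq_len(H), pw$before + seq_len(W), ] <- x
  out <- array(0, c(ph$out, pw$out, cout))
  for (oc in seq_len(cout)) for (i in seq_len(ph$out)) for (j in seq_len(pw$out)) {
    acc <- 0
    for (kr in seq_len(k)) for (kc in seq_len(k)) for (ic in seq_len(cin))
      acc <- acc + xp[(i - 1) * stride + kr, (j - 1) * stride + kc, ic] *
        w[kr, kc, ic, oc]
    out[i, j, oc] <- acc + if (is.null(b)) 0 else b[oc]
  }
  out
}

expect_all_finite <- function(x) expect_true(all(is.finite(unlist(x))))
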