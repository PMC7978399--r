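# Network construction, parameter counting, He initialization and
# forward-pass contracts.

test_that("parameter counting matches hand counts on minimal layers", {
  # single 3x3 conv, 1 -> 8 channels, with bias: 3*3*1*8 + 8 = 80
  arch <- list(sucgan:::layer_conv("c", 3L, 1L, 8L))
  net <- sucgan:::new_network(list(), arch, "generator")
  expect_identical(count_trainable_parameters(net), 80L)
  # batch norm over C channels: 2C trainable (running stats excluded)
  arch <- list(sucgan:::layer_bn("b", 16L))
  net <- sucgan:::new_network(list(), arch, "generator")
  expect_identical(count_trainable_parameters(net), 32L)
  # empty network
  net <- sucgan:::new_network(list(), list(), "generator")
  expect_identical(count_trainable_parameters(net), 0L)
})

test_that("reference builds reproduce the published parameter totals", {
  g2 <- build_sunet_generator()
  g3 <- build_unet3_generator()
  d <- build_discriminator()
  expect_identical(count_trainable_parameters(list(g2, d)), 3163142L)
  expect_identical(count_trainable_parameters(list(g3, d)), 4868614L)
  n2 <- count_trainable_parameters(g2)
  n3 <- count_trainable_parameters(g3)
  expect_identical(n3 - n2, 1705472L)
  # the printed "35%" reduction
  expect_equal(1705472 / 4868614, 0.35, tolerance = 0.01)
})

test_that("parameter counts are invariant to input size and rebuild", {
  spec <- tiny_gen_spec()
  a <- build_sunet_generator(spec)
  b <- build_sunet_generator(spec)
  expect_identical(count_trainable_parameters(a), count_trainable_parameters(b))
  expect_identical(vapply(a$arch, `[[`, "", "name"),
                   vapply(b$arch, `[[`, "", "name"))
  # fully convolutional: the same network runs on several input sizes
  he_initialize(a, 3)
  for (n in c(16L, 32L)) {
    out <- sucgan:::forward_generator(a, array(0, c(n, n, 1L)),
                                      use_dropout = FALSE)$out
    expect_equal(dim(out), c(n, n, 1L))
  }
})

test_that("generator output shape equals input shape; indivisible inputs error", {
  gen <- he_initialize(build_sunet_generator(tiny_gen_spec()), 1)
  out <- sucgan:::forward_generator(gen, array(0, c(32, 32, 1)),
                                    use_dropout = FALSE)$out
  expect_equal(dim(out), c(32, 32, 1))
  expect_error(sucgan:::forward_generator(gen, array(0, c(30, 30, 1))),
               "divisible")
  g3 <- he_initialize(build_unet3_generator(
    generator_spec(depth = 3, stage_features = c(4L, 8L, 16L, 16L),
                   dropout_rate = 0)), 1)
  expect_error(sucgan:::forward_generator(g3, array(0, c(36, 36, 1))),
               "divisible")
  out3 <- sucgan:::forward_generator(g3, array(0, c(24, 24, 1)),
                                     use_dropout = FALSE)$out
  expect_equal(dim(out3), c(24, 24, 1))
})

test_that("reference generator maps a 144x144 slice to a 144x144 slice", {
  gen <- he_initialize(build_sunet_generator(), 1)
  out <- sucgan:::forward_generator(gen, array(rnorm(144 * 144), c(144, 144, 1)),
                                    use_dropout = FALSE)$out
  expect_equal(dim(out), c(144, 144, 1))
})

test_that("discriminator scores lie in [0,1]; zero weights give exactly 0.5", {
  d <- build_discriminator(tiny_disc_spec())
  x <- array(rnorm(32 * 32 * 2, sd = 5), c(32, 32, 2))
  s0 <- sucgan:::forward_discriminator(d, x)$score   # zero-initialised
  expect_true(all(s0 == 0.5))
  he_initialize(d, 4)
  s <- sucgan:::forward_discriminator(d, x)$score
  expect_true(all(s >= 0 & s <= 1))
  # fully convolutional: doubling input size scales the score map only
  s2 <- sucgan:::forward_discriminator(d, array(0, c(64, 64, 2)))$score
  expect_equal(dim(s2)[1:2], 2L * dim(s)[1:2])
  # conditional discriminator rejects single-channel input
  expect_error(sucgan:::forward_discriminator(d, array(0, c(32, 32, 1))),
               "channel")
})

test_that("He initialization has the stated variance, zero mean, determinism", {
  spec <- generator_spec(stage_features = c(64L, 64L, 64L), kernel_size = 3L,
                         dropout_rate = 0)
  gen <- build_sunet_generator(spec)
  he_initialize(gen, 99)
  w <- sucgan:::get_p(gen, "enc2_conv1")$w   # 3x3, 64 -> 64: fan_in = 576
  expect_gt(length(w), 1e4)
  expect_equal(stats::var(as.numeric(w)), 2 / 576, tolerance = 0.1)
  se <- sqrt(2 / 576 / length(w))
  expect_lt(abs(mean(w)), 3 * se)
  gen2 <- he_initialize(build_sunet_generator(spec), 99)
  expect_identical(sucgan:::get_p(gen, "enc2_conv1")$w,
                   sucgan:::get_p(gen2, "enc2_conv1")$w)
})

test_that("specs serialize round-trip and checkpoints are self-describing", {
  tf <- tempfile(fileext = ".json")
  spec <- tiny_gen_spec()
  write_spec(spec, tf)
  expect_equal(read_spec(tf), spec)
  gen <- he_initialize(build_sunet_generator(spec), 5)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(gen, ck)
  gen2 <- load_checkpoint(ck)
  x <- array(rnorm(16 * 16), c(16, 16, 1))
  expect_identical(sucgan:::forward_generator(gen, x, use_dropout = FALSE)$out,
                   sucgan:::forward_generator(gen2, x, use_dropout = FALSE)$out)
})
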