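test_that("specification strings parse, validate and round-trip", {
  strings <- c(
    paste(c("CIR64F7", "CIR128F3", "CIR256F3", rep("Res256", 9),
            "DCIR128F3", "DCIR64F3", "C1F7"), collapse = "-"),
    "CLR64F4-CILR128F4-CILR256F4-CILR512F4-CILR512F4-CILR512F4-C1F4",
    "CLR64F4-CILR128F4-CILR256F4-CILR512F4-CILR512F4-C1F4")
  for (s in strings)
    expect_identical(render_network_spec(network_spec(s)), s)
  expect_identical(render_network_spec(generator_spec()), strings[1])
  expect_identical(render_network_spec(global_discriminator_spec()), strings[2])
  expect_identical(render_network_spec(local_discriminator_spec()), strings[3])
  expect_error(network_spec("CIR64F7-Foo12"), "cannot parse")
  expect_error(network_spec("CIR64-Res256"), "missing a filter size")
})

test_that("generator structure matches its specification", {
  g <- build_generator(6L, generator_spec(1 / 8))
  expect_equal(res_block_count(g), 9L)
  enc <- network_widths(g)
  expect_equal(enc, c(8L, 16L, 32L, 16L, 8L, 1L))   # scaled 64/128/256 stem+head
  expect_error(build_generator(6L, global_discriminator_spec()),
               "exactly 9 Res tokens")

  x <- array(runif(64 * 64 * 6 * 2), c(64, 64, 6, 2))
  y <- network_apply(g, x)
  expect_equal(dim(y), c(64L, 64L, 1L, 2L))
  expect_true(all(y >= 0 & y <= 1))                 # sigmoid head
  expect_error(network_apply(g, array(0, c(30, 30, 6, 1))), "divisible by 4")

  # fully convolutional: doubling the input doubles the output
  x2 <- array(runif(128 * 128 * 6), c(128, 128, 6, 1))
  expect_equal(dim(network_apply(g, x2))[1:2], c(128L, 128L))
})

test_that("discriminators have the prescribed depth and patch outputs", {
  dg <- build_global_discriminator(6L, global_discriminator_spec(1))
  expect_equal(conv_layer_count(dg), 7L)
  expect_equal(network_widths(dg), c(64L, 128L, 256L, 512L, 512L, 512L, 1L))

  dg8 <- build_global_discriminator(6L, global_discriminator_spec(1 / 8))
  out <- network_apply(dg8, array(runif(64 * 64 * 6), c(64, 64, 6, 1)))
  expect_equal(dim(out)[3], 1L)
  expect_gt(prod(dim(out)[1:2]), 1)                 # a patch map, not a scalar
  expect_error(network_apply(dg8, array(0, c(16, 16, 6, 1))), "footprint")

  dl <- build_local_discriminator(local_discriminator_spec(1))
  expect_equal(conv_layer_count(dl), 6L)
  expect_equal(network_widths(dl), c(64L, 128L, 256L, 512L, 512L, 1L))
  dl8 <- build_local_discriminator(local_discriminator_spec(1 / 8))
  expect_silent(network_apply(dl8, array(runif(64 * 64), c(64, 64, 1, 1))))
  expect_error(network_apply(dl8, array(0, c(256, 256, 1, 1))),
               "expects 64x64")
})

test_that("feature extractor is deterministic with monotone spatial dims", {
  ex1 <- feature_extractor(base_width_scale = 1 / 8, seed = 12)
  ex2 <- feature_extractor(base_width_scale = 1 / 8, seed = 12)
  img <- matrix(runif(64 * 64), 64, 64)
  f1 <- extract_features(ex1, img)
  f2 <- extract_features(ex2, img)
  expect_identical(f1, f2)
  expect_true(all(dim(f1$conv4_4)[1:2] <= dim(f1$conv3_4)[1:2]))
  expect_error(extract_features(ex1, img, "conv9_9"), "unknown feature tag")

  # identical inputs give identical features at every requested tag
  f3 <- extract_features(ex1, img, c("conv1_1", "conv2_2", "conv3_4"))
  f4 <- extract_features(ex1, img, c("conv1_1", "conv2_2", "conv3_4"))
  expect_identical(f3, f4)
})
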