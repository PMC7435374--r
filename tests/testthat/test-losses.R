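test_that("masked_image multiplies elementwise and zeroes outside", {
  img <- matrix(runif(16), 4, 4)
  expect_equal(masked_image(img, matrix(1, 4, 4)), img)
  expect_equal(masked_image(img, matrix(0, 4, 4)), matrix(0, 4, 4))
  m <- matrix(c(1, 0, 0, 1, 1, 0, 0, 1, 1, 0, 0, 1, 1, 0, 0, 1), 4, 4)
  expect_equal(masked_image(img, m), img * m)
  expect_error(masked_image(img, matrix(1, 3, 3)), "shape mismatch")
})

test_that("loss weights default to the prescribed ratios", {
  w <- loss_weights()
  expect_equal(c(w$lambda1, w$lambda2, w$lambda3) / w$lambda1, c(1, 100, 100))
  expect_equal(c(w$lam, w$mu, w$gamma) / w$lam, c(1, 1000, 1000))
  expect_error(loss_weights(lambda1 = -1), "non-negative")
})

test_that("regional L1 loss matches hand computations", {
  y <- matrix(runif(64), 8, 8)
  expect_equal(regional_l1_loss(y, y, matrix(1, 8, 8)), 0)
  expect_equal(regional_l1_loss(y, 1 - y, matrix(0, 8, 8)), 0)
  # 2x2 toy: only the top-left pixel is in the mask
  y2 <- matrix(c(0.5, 0, 0, 0), 2, 2)
  x2 <- matrix(c(0.25, 9, 9, 9), 2, 2)
  m2 <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(regional_l1_loss(y2, x2, m2), 0.0625)  # |0.5 - 0.25| / 4
})

test_that("least-squares adversarial losses hit their reference points", {
  p1 <- array(1, c(3, 3, 1, 1)); p0 <- array(0, c(3, 3, 1, 1))
  ph <- array(0.5, c(3, 3, 1, 1))
  expect_equal(lsgan_d_loss(p1, p0), 0)
  expect_equal(lsgan_d_loss(p0, p1), 2)
  expect_equal(lsgan_d_loss(ph, ph), 0.5)
  expect_equal(lsgan_g_loss(p1), 0)
  expect_equal(lsgan_g_loss(p0), 1)
  expect_equal(lsgan_g_loss(ph), 0.25)
})

test_that("total loss is the stated weighted sum and linear in components", {
  expect_equal(total_loss(1, 1, 1), 2001)
  expect_equal(total_loss(0, 0, 0), 0)
  expect_equal(total_loss(2, 0.001, 0.0005), 3.5)
  a <- total_loss(1, 2, 3); b <- total_loss(2, 2, 3)
  expect_equal(b - a, 1)                              # slope lam = 1 in l_rp
  expect_error(total_loss(NaN, 0, 0), "non-finite")
})

test_that("regional perceptual loss vanishes on agreement and ignores unmasked pixels", {
  ex <- tiny_extractor()
  tags <- c("conv1_2", "conv2_2")
  s_a <- toy_label(32, tumor_at = c(12, 12), tumor_size = 6)
  s_b <- toy_label(32, tumor_at = c(20, 20), tumor_size = 5)
  masks <- region_masks(s_a, s_b)
  set.seed(2)
  x_a <- matrix(runif(32 * 32), 32, 32)
  x_b <- matrix(runif(32 * 32), 32, 32)
  y <- x_b * masks$tissue_mask + x_a * masks$tumor_mask

  expect_lt(regional_perceptual_loss(y, x_b, x_a, masks, ex, tags = tags), 1e-12)
  w0 <- loss_weights(lambda1 = 0, lambda2 = 0, lambda3 = 0)
  yr <- matrix(runif(32 * 32), 32, 32)
  expect_equal(regional_perceptual_loss(yr, x_b, x_a, masks, ex, w0, tags), 0)

  # invariance to values outside the two regions (masking precedes features)
  outside <- !(masks$tissue_mask | masks$tumor_mask)
  y2 <- y; y2[outside] <- runif(sum(outside))
  l1v <- regional_perceptual_loss(yr, x_b, x_a, masks, ex, tags = tags)
  yr2 <- yr; yr2[outside] <- runif(sum(outside))
  expect_equal(regional_perceptual_loss(yr2, x_b, x_a, masks, ex, tags = tags),
               l1v)
})

test_that("regional losses agree with an independent term-by-term oracle", {
  ex <- tiny_extractor()
  tags <- c("conv1_2", "conv2_2")
  w <- loss_weights()
  set.seed(31)
  for (rep in 1:6) {
    s_a <- toy_label(16, tumor_at = c(sample(5:9, 1), sample(5:9, 1)))
    s_b <- toy_label(16, tumor_at = c(sample(5:9, 1), sample(5:9, 1)),
                     brain_radius = runif(1, 0.35, 0.45))
    masks <- region_masks(s_a, s_b)
    y <- matrix(runif(256), 16, 16)
    x_a <- matrix(runif(256), 16, 16)
    x_b <- matrix(runif(256), 16, 16)

    # oracle: mask, extract each feature map, average squared differences
    mse <- function(a, b) mean((a - b)^2)
    f_y_tis <- extract_features(ex, y * masks$tissue_mask, tags)
    f_x_tis <- extract_features(ex, x_b * masks$tissue_mask, tags)
    f_y_tum <- extract_features(ex, y * masks$tumor_mask, tags)
    f_x_tum <- extract_features(ex, x_a * masks$tumor_mask, tags)
    oracle <- w$lambda1 * mse(f_y_tis[[tags[1]]], f_x_tis[[tags[1]]]) +
      w$lambda2 * mse(f_y_tis[[tags[2]]], f_x_tis[[tags[2]]]) +
      w$lambda3 * mse(f_y_tum[[tags[2]]], f_x_tum[[tags[2]]])
    got <- regional_perceptual_loss(y, x_b, x_a, masks, ex, w, tags)
    expect_equal(got, oracle, tolerance = 1e-6)

    l1_oracle <- sum(abs(y * masks$tissue_mask - x_b * masks$tissue_mask)) / 256
    expect_equal(regional_l1_loss(y, x_b, masks$tissue_mask), l1_oracle,
                 tolerance = 1e-6)
  }
})

test_that("perceptual-loss gradients match finite differences", {
  ex <- feature_extractor(blocks = c(1L, 1L), widths = c(4L, 6L), seed = 5)
  tags <- c("conv1_1", "conv2_1")
  s_a <- toy_label(8, tumor_at = c(4, 4), tumor_size = 2, brain_radius = 0.5)
  s_b <- toy_label(8, tumor = FALSE, brain_radius = 0.5)
  masks <- region_masks(s_a, s_b)
  set.seed(9)
  y <- matrix(runif(64), 8, 8)
  x_a <- matrix(runif(64), 8, 8)
  x_b <- matrix(runif(64), 8, 8)
  w <- loss_weights()
  r <- lesiongan:::rp_loss_terms(y, x_b, x_a, masks, ex, w, tags, grad = TRUE)
  num <- matrix(0, 8, 8)
  eps <- 1e-5
  for (i in seq_len(64)) {
    yp <- y; yp[i] <- yp[i] + eps
    ym <- y; ym[i] <- ym[i] - eps
    num[i] <- (regional_perceptual_loss(yp, x_b, x_a, masks, ex, w, tags) -
                 regional_perceptual_loss(ym, x_b, x_a, masks, ex, w, tags)) / (2 * eps)
  }
  expect_equal(as.vector(r$grad_y), as.vector(num), tolerance = 1e-5)
})
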