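test_that("dice score matches direct overlap counting", {
  a <- matrix(0, 10, 10); a[1:10, 1:10] <- 1
  expect_equal(dice_score(a, a), 200 / (200 + 1e-6))
  b <- matrix(0, 10, 10); b[1, 1] <- 1
  d <- matrix(0, 10, 10); d[10, 10] <- 1
  expect_equal(dice_score(b, d), 0)
  # |true| = 10, |pred| = 6, overlap = 4 on an 8x8 grid
  t8 <- matrix(0, 8, 8); t8[1:10] <- 1
  p8 <- matrix(0, 8, 8); p8[7:12] <- 1
  expect_equal(sum(t8), 10); expect_equal(sum(p8), 6)
  expect_equal(sum(t8 * p8), 4)
  expect_equal(dice_score(t8, p8, eps = 0), 0.5)
  expect_error(dice_score(t8, matrix(0, 4, 4)), "shape mismatch")
})

test_that("dice equals brute-force counting on every 3x3 mask pair", {
  grids <- as.matrix(expand.grid(rep(list(0:1), 9)))
  for (i in seq_len(nrow(grids))) {
    ti <- grids[i, ]
    si <- sum(ti)
    for (j in seq_len(nrow(grids))) {
      pj <- grids[j, ]
      denom <- si + sum(pj)
      expected <- if (denom == 0) 0
      else 2 * length(intersect(which(ti == 1), which(pj == 1))) / denom
      if (abs(dice_score(ti, pj) - expected) > 1e-5)
        fail(sprintf("mismatch at pair (%d, %d)", i, j))
    }
  }
  succeed()
})

test_that("per-region dice groups codes as whole/core/enhancing", {
  s <- toy_label(16)
  r <- region_dice(s, s)
  expect_true(all(unlist(r[c("whole", "core", "en")]) > 0.9999))
  r0 <- region_dice(s, semantic_label(matrix(0L, 16, 16)))
  expect_equal(unlist(r0[c("whole", "core", "en")]), c(whole = 0, core = 0, en = 0))
  expect_equal(r0$mean, 0)

  # hand-counted toy: true has 4/2/1 pixels in whole/core/en terms
  ct <- matrix(1L, 4, 4); ct[1, 1] <- 2L; ct[1, 2] <- 2L; ct[2, 1] <- 3L; ct[2, 2] <- 4L
  cp <- matrix(1L, 4, 4); cp[1, 1] <- 2L; cp[2, 1] <- 4L; cp[2, 2] <- 4L
  rr <- region_dice(ct, cp, eps = 0)
  expect_equal(rr$whole, 2 * 3 / (4 + 3))   # overlap {11,21,22}
  expect_equal(rr$core, 2 * 2 / (2 + 2))    # overlap {21,22}
  expect_equal(rr$en, 2 * 1 / (1 + 2))      # overlap {22}
  expect_equal(rr$mean, mean(c(rr$whole, rr$core, rr$en)))
})

test_that("frechet distance is a symmetric premetric recovering the Gaussian closed form", {
  set.seed(6)
  x <- matrix(rnorm(200 * 4), 200, 4)
  expect_lt(frechet_distance(x, x), 1e-6)
  y <- matrix(rnorm(200 * 4, 1), 200, 4)
  expect_equal(frechet_distance(x, y), frechet_distance(y, x))
  expect_gt(frechet_distance(x, y), 0)

  set.seed(1234)
  g1 <- matrix(rnorm(10000, 0, 1), ncol = 1)
  g2 <- matrix(rnorm(10000, 2, 3), ncol = 1)
  closed <- (0 - 2)^2 + (1 - 3)^2
  expect_lt(abs(frechet_distance(g1, g2) - closed) / closed, 0.05)

  expect_error(frechet_distance(x, matrix(0, 10, 3)), "dimension mismatch")
  expect_error(frechet_distance(x[1, , drop = FALSE], x), "at least 2")
})

test_that("image-set FID is zero on itself, symmetric, and monotone in corruption", {
  ex <- tiny_extractor()
  set.seed(40)
  real <- lapply(1:6, function(i) matrix(runif(32 * 32), 32, 32))
  expect_lt(fid_images(real, real, ex, tag = "conv2_2"), 1e-6)

  noisy <- function(sigma) lapply(real, function(m)
    pmin(pmax(m + matrix(rnorm(length(m), 0, sigma), nrow(m)), 0), 1))
  set.seed(41); f1 <- noisy(0.05)
  set.seed(41); f2 <- noisy(0.2)
  set.seed(41); f3 <- noisy(0.6)
  d1 <- fid_images(real, f1, ex, tag = "conv2_2")
  d2 <- fid_images(real, f2, ex, tag = "conv2_2")
  d3 <- fid_images(real, f3, ex, tag = "conv2_2")
  expect_true(d1 < d2 && d2 < d3)
  expect_equal(fid_images(f1, real, ex, tag = "conv2_2"), d1,
               tolerance = 1e-6)
})
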