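test_that("min-max normalization matches the formula and rejects constants", {
  img <- matrix(c(0, 51, 255, 0), 2, 2)
  expect_equal(normalize_intensity(img), matrix(c(0, 0.2, 1, 0), 2, 2))
  r <- normalize_intensity(matrix(runif(64, 3, 9), 8, 8))
  expect_equal(min(r), 0)
  expect_equal(max(r), 1)
  # idempotent on already-normalized images
  expect_equal(normalize_intensity(r), r)
  expect_error(normalize_intensity(matrix(2, 4, 4)), "constant image")
  expect_error(normalize_intensity(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
})

test_that("slice window is half-open and validated", {
  vol <- array(seq_len(155 * 4 * 4), c(155, 4, 4))
  sl <- extract_slices(vol)
  expect_length(sl, 80L)
  expect_identical(names(sl)[1], "30")
  expect_identical(names(sl)[80], "109")
  expect_equal(sl[["30"]], vol[31, , ])
  expect_length(extract_slices(vol, 0, 155), 155L)
  expect_error(extract_slices(array(0, c(50, 4, 4))), "depth 50")
})

test_that("resizing keeps label code sets and intensity structure", {
  lab <- matrix(0L, 12, 12); lab[4:9, 4:9] <- 1L; lab[5:7, 5:7] <- 2L
  r <- resize_slice(lab, 31, is_label = TRUE)
  expect_true(all(r %in% c(0L, 1L, 2L)))
  expect_equal(dim(r), c(31L, 31L))
  expect_true(all(resize_slice(matrix(0.3, 20, 20), 16) == 0.3))
  expect_equal(dim(resize_slice(matrix(runif(128^2), 128, 128), 256)),
               c(256L, 256L))
  expect_error(resize_slice(matrix(0, 4, 4), 8), "size")
})

test_that("label encoding maps raw codes and inverts exactly", {
  bm <- matrix(TRUE, 4, 4); bm[1, ] <- FALSE
  raw <- matrix(0L, 4, 4)
  raw[2, 2] <- 2L; raw[3, 3] <- 1L; raw[4, 4] <- 4L
  s <- encode_label(raw, bm)
  expect_equal(s$classes[1, ], rep(0L, 4))       # outside brain
  expect_equal(s$classes[2, 1], 1L)              # plain tissue
  expect_equal(s$classes[2, 2], 2L)              # edema keeps its code
  expect_equal(s$classes[3, 3], 3L)              # raw core 1 -> class 3
  expect_equal(s$classes[4, 4], 4L)
  expect_identical(decode_label(s), raw)

  all0 <- encode_label(matrix(0L, 4, 4), matrix(TRUE, 4, 4))
  expect_true(all(all0$classes == 1L))
  bad <- matrix(0L, 4, 4); bad[1, 1] <- 4L
  expect_error(encode_label(bad, bm), "outside the brain")
  expect_error(encode_label(matrix(3L, 4, 4), matrix(TRUE, 4, 4)),
               "unexpected raw label")
})

test_that("brain mask keeps the largest component and fills holes", {
  expect_error(brain_mask_from_image(matrix(0, 8, 8)), "empty brain mask")

  disk <- matrix(0, 16, 16)
  disk[4:12, 4:12] <- 1
  disk[8, 8] <- 0                                 # interior hole
  m <- brain_mask_from_image(disk)
  expect_true(m[8, 8])                            # filled
  expect_equal(sum(m), 81)

  # two components on an 8x8 grid: brute-force expectation keeps the larger
  two <- matrix(0, 8, 8)
  two[2:4, 2:4] <- 1                              # 9 pixels
  two[6:7, 6:7] <- 1                              # 4 pixels
  m2 <- brain_mask_from_image(two)
  expect_equal(sum(m2), 9)
  expect_true(all(m2[2:4, 2:4]))
  expect_false(any(m2[6:7, 6:7]))
})

test_that("region masks follow the set formula and stay disjoint", {
  s_a <- toy_label(16, tumor_at = c(7, 7))
  s_b <- toy_label(16, tumor_at = c(9, 9))
  rm <- region_masks(s_a, s_b)
  # independent pixel-by-pixel evaluation of the set definition
  ca <- s_a$classes; cb <- s_b$classes
  exp_tum <- matrix(FALSE, 16, 16); exp_tis <- matrix(FALSE, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    exp_tum[i, j] <- ca[i, j] %in% 2:4
    exp_tis[i, j] <- cb[i, j] %in% 1:4 && !(ca[i, j] %in% 2:4) &&
      !(cb[i, j] %in% 2:4)
  }
  expect_identical(rm$tumor_mask, exp_tum)
  expect_identical(rm$tissue_mask, exp_tis)
  expect_false(any(rm$tumor_mask & rm$tissue_mask))

  # tumor-free donor A: tissue mask is B's brain minus B's tumor
  s_a0 <- toy_label(16, tumor = FALSE)
  rm0 <- region_masks(s_a0, s_b)
  expect_false(any(rm0$tumor_mask))
  expect_identical(rm0$tissue_mask, cb >= 1L & !(cb %in% 2:4))

  # self-pairing: masks partition the brain
  rms <- region_masks(s_a, s_a)
  expect_identical(rms$tumor_mask | rms$tissue_mask, ca >= 1L)
  expect_error(region_masks(s_a, toy_label(12)), "shape mismatch")
})

test_that("mask properties hold over random label pairs", {
  set.seed(17)
  for (rep in 1:8) {
    s_a <- toy_label(16, tumor_at = c(sample(4:10, 1), sample(4:10, 1)),
                     tumor_size = sample(3:5, 1))
    s_b <- toy_label(16, tumor_at = c(sample(4:10, 1), sample(4:10, 1)),
                     brain_radius = runif(1, 0.3, 0.45))
    rm <- region_masks(s_a, s_b)
    expect_false(any(rm$tumor_mask & rm$tissue_mask))
    both_brains <- (s_a$classes >= 1L) | (s_b$classes >= 1L)
    expect_true(all(both_brains[rm$tumor_mask | rm$tissue_mask]))
  }
})
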