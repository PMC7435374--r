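test_that("random crops are in-bounds, deterministic, and identity at full size", {
  img <- matrix(runif(32 * 32), 32, 32)
  set.seed(1)
  r <- random_crop(img, 32)
  expect_identical(r$crop, img)
  expect_equal(c(r$row0, r$col0), c(0L, 0L))

  set.seed(7); a <- random_crop(img, 8)
  set.seed(7); b <- random_crop(img, 8)
  expect_identical(a, b)

  set.seed(3)
  for (i in 1:200) {
    cr <- random_crop(img, 8)
    expect_true(cr$row0 >= 0 && cr$row0 <= 24 && cr$col0 >= 0 && cr$col0 <= 24)
  }
  expect_error(random_crop(img, 64), "exceeds")
})

test_that("batch composition produces disjoint masks and valid one-hot labels", {
  ds <- small_dataset()
  set.seed(11)
  b <- make_batch(ds, batch_size = 2)
  expect_equal(dim(b$x_a), c(48L, 48L, 1L, 2L))
  expect_equal(dim(b$s_ab), c(48L, 48L, 5L, 2L))
  expect_true(all(apply(b$s_ab, c(1, 2, 4), sum) == 1))  # one-hot partition
  expect_false(any(b$tissue * b$tumor != 0))             # disjoint per element
  expect_equal(nrow(b$meta), 2L)
  expect_false(any(b$meta$tumor_donor == b$meta$background_donor))

  set.seed(11)
  b2 <- make_batch(ds, batch_size = 2)
  expect_identical(b, b2)                                # seed-stable

  one_pat <- slice_dataset(ds$entries[vapply(ds$entries, function(e)
    e$patient_id == "P001", logical(1))], ds$modality)
  expect_error(make_batch(one_pat), ">= 2 patients")
})

test_that("a training step yields finite losses and respects zero learning rate", {
  ds <- small_dataset()
  cfg <- small_config()
  set.seed(cfg$seed)
  nets <- lesiongan:::new_gan_nets(cfg)
  opt <- lesiongan:::new_opt_state(nets)
  batch <- make_batch(ds, 1)
  r <- train_step(batch, nets, opt, cfg, cfg$extractor)
  expect_true(all(is.finite(unlist(r$record))))
  expect_equal(r$record$l_adv, r$record$l_g + r$record$l_l)
  w <- cfg$weights
  expect_equal(r$record$total,
               w$lam * r$record$l_rp + w$mu * r$record$l_1 +
                 w$gamma * r$record$l_adv)

  cfg0 <- small_config(learning_rate = 0)
  r0 <- train_step(batch, nets, opt, cfg0, cfg0$extractor)
  expect_identical(r0$nets$G$layers[[1]]$w, nets$G$layers[[1]]$w)
  expect_identical(r0$nets$Dg$layers[[1]]$w, nets$Dg$layers[[1]]$w)
  # and a real step changes G but D updates never touch G weights in-step
  expect_false(identical(r$nets$G$layers[[1]]$w, nets$G$layers[[1]]$w))
})

test_that("short runs are fully deterministic and resumable", {
  ds <- small_dataset()
  f1 <- fit_lesion_gan(ds, small_config(iterations = 4))
  f2 <- fit_lesion_gan(ds, small_config(iterations = 4))
  expect_identical(f1$log, f2$log)
  expect_identical(f1$generator$layers[[1]]$w, f2$generator$layers[[1]]$w)

  dir <- withr::local_tempdir()
  full <- fit_lesion_gan(ds, small_config(iterations = 4),
                         checkpoint_dir = dir, checkpoint_every = 2)
  resumed <- fit_lesion_gan(ds, resume = file.path(dir, "checkpoint_000002.rds"))
  expect_equal(resumed$log, full$log)
})

test_that("the fitted model exposes the standard accessors", {
  ds <- small_dataset()
  fit <- fit_lesion_gan(ds, small_config(iterations = 2))
  expect_s3_class(fit, "lesion_gan")
  expect_output(print(fit), "Lesion-synthesis GAN")
  s <- summary(fit)
  expect_s3_class(s, "summary.lesion_gan")

  e <- ds$entries[[1]]
  donor <- Find(function(x) x$patient_id != e$patient_id &&
                  sum(x$label$classes >= 2L) > 0, ds$entries)
  comp <- composite_label(donor$label, e$label, max_dropped = 1)
  y <- predict(fit, comp, donor$image)
  expect_equal(dim(y), dim(e$image))
  expect_true(all(y >= 0 & y <= 1))

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
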