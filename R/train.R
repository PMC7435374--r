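# Adversarial training loop: alternate discriminator/generator updates over
# composited batches, with 64x64 local crops for the second discriminator.

#' Training configuration
#'
#' @param iterations Number of optimization steps (one D and one G update
#'   each).
#' @param batch_size Composited pairs per step.
#' @param learning_rate,beta1,beta2 Adam settings (2e-4, 0.5, 0.999: the
#'   defaults of the encoder-decoder translation family this architecture
#'   derives from).
#' @param crop_size Side length of the local discriminator's crops.
#' @param image_size Slice side length the model is trained at.
#' @param base_width_scale Channel-width multiplier for all three networks
#'   (1 = full scale; reduced widths make CPU runs practical).
#' @param seed Seed governing initialization, batch composition and crops;
#'   a full run is deterministic on CPU for a fixed seed.
#' @param modality Modality this model is trained for (one model per
#'   modality).
#' @param weights [loss_weights()].
#' @param max_dropped Pair-admissibility threshold for the compositor.
#' @param extractor Optional [feature_extractor()]; by default a fixed-seed
#'   extractor at `base_width_scale` width is built.
#' @param perceptual_tags Feature tags used by the regional perceptual loss.
#' @return Object of class `gan_config`.
#' @export
gan_config <- function(iterations = 200L, batch_size = 1L,
                       learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                       crop_size = 64L, image_size = 256L,
                       base_width_scale = 1, seed = 1L, modality = "flair",
                       weights = loss_weights(), max_dropped = 0.05,
                       extractor = NULL,
                       perceptual_tags = c("conv3_4", "conv4_4")) {
  stopifnot(iterations >= 1L, batch_size >= 1L, learning_rate >= 0,
            crop_size >= 1L, image_size >= 4L)
  if (crop_size > image_size)
    stop("crop_size must not exceed image_size")
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 crop_size = as.integer(crop_size),
                 image_size = as.integer(image_size),
                 base_width_scale = base_width_scale, seed = as.integer(seed),
                 modality = modality, weights = weights,
                 max_dropped = max_dropped, extractor = extractor,
                 perceptual_tags = perceptual_tags),
            class = "gan_config")
}

#' Random square crop
#'
#' Uniform top-left corner; deterministic under the current RNG state.
#'
#' @param image Matrix or `(H, W, C, N)` array.
#' @param size Crop side length (at most both spatial dims).
#' @return List with `crop` (same type as `image`), and 0-based `row0`,
#'   `col0` top-left coordinates.
#' @export
random_crop <- function(image, size) {
  d <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  if (size > d[1L] || size > d[2L])
    stop("crop size ", size, " exceeds image dims ", d[1L], "x", d[2L])
  row0 <- sample.int(d[1L] - size + 1L, 1L) - 1L
  col0 <- sample.int(d[2L] - size + 1L, 1L) - 1L
  crop <- if (is.matrix(image))
    image[row0 + seq_len(size), col0 + seq_len(size)]
  else image[row0 + seq_len(size), col0 + seq_len(size), , , drop = FALSE]
  list(crop = crop, row0 = row0, col0 = col0)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

bind4 <- function(lst) {
  d <- dim(lst[[1L]])
  array(unlist(lst), c(d[1L], d[2L], d[3L], sum(vapply(lst, function(x) dim(x)[4L], numeric(1)))))
}

#' Compose a training batch
#'
#' Samples donor pairs (tumor donor A with a tumor-bearing slice, background
#' donor B with any slice), builds the composite label and region masks, and
#' one-hot encodes the labels. Inadmissible pairs (too much tumor dropped)
#' are skipped and resampled up to a bounded number of retries.
#'
#' @param dataset A [slice_dataset()] with at least 2 patients carrying
#'   tumor-bearing slices.
#' @param batch_size Number of composited elements.
#' @param max_dropped Compositor admissibility threshold.
#' @param max_retries Resampling budget per element.
#' @return List with arrays `x_a`, `x_b` `(H, W, 1, N)`, one-hot labels
#'   `s_ab`, `s_b` `(H, W, 5, N)`, masks `tissue`, `tumor` `(H, W, 1, N)`,
#'   and a provenance data frame `meta`.
#' @export
make_batch <- function(dataset, batch_size = 1L, max_dropped = 0.05,
                       max_retries = 25L) {
  stopifnot(inherits(dataset, "slice_dataset"))
  donors <- dataset_patients(dataset, tumor_only = TRUE)
  all_pat <- dataset_patients(dataset)
  if (length(donors) < 1L || length(all_pat) < 2L)
    stop("batch composition needs >= 2 patients and >= 1 tumor donor")
  xs_a <- xs_b <- sab <- sb <- mt <- mu_ <- vector("list", batch_size)
  meta <- vector("list", batch_size)
  for (i in seq_len(batch_size)) {
    comp <- NULL
    for (try in seq_len(max_retries)) {
      a <- donors[sample.int(length(donors), 1L)]
      b_pool <- setdiff(all_pat, a)
      b <- b_pool[sample.int(length(b_pool), 1L)]
      ea_pool <- dataset_entries_of(dataset, a, tumor_only = TRUE)
      eb_pool <- dataset_entries_of(dataset, b)
      ea <- ea_pool[[sample.int(length(ea_pool), 1L)]]
      eb <- eb_pool[[sample.int(length(eb_pool), 1L)]]
      comp <- tryCatch(composite_label(ea$label, eb$label, max_dropped),
                       lesiongan_inadmissible_pair = function(e) NULL)
      if (!is.null(comp)) break
    }
    if (is.null(comp))
      stop("no admissible donor pair found in ", max_retries, " attempts")
    masks <- region_masks(ea$label, eb$label)
    d <- dim(ea$image)
    xs_a[[i]] <- array(ea$image, c(d, 1L, 1L))
    xs_b[[i]] <- array(eb$image, c(d, 1L, 1L))
    sab[[i]] <- label_onehot(comp$label)
    sb[[i]] <- label_onehot(eb$label)
    mt[[i]] <- array(masks$tissue_mask + 0, c(d, 1L, 1L))
    mu_[[i]] <- array(masks$tumor_mask + 0, c(d, 1L, 1L))
    meta[[i]] <- data.frame(tumor_donor = comp$tumor_donor,
                            background_donor = comp$background_donor,
                            dropped_fraction = comp$dropped_fraction,
                            stringsAsFactors = FALSE)
  }
  list(x_a = bind4(xs_a), x_b = bind4(xs_b), s_ab = bind4(sab),
       s_b = bind4(sb), tissue = bind4(mt), tumor = bind4(mu_),
       meta = do.call(rbind, meta))
}

new_gan_nets <- function(config) {
  list(G = build_generator(6L, generator_spec(config$base_width_scale)),
       Dg = build_global_discriminator(6L, global_discriminator_spec(config$base_width_scale)),
       Dl = build_local_discriminator(local_discriminator_spec(config$base_width_scale),
                                      crop_size = config$crop_size))
}

new_opt_state <- function(nets) {
  list(g = nn_adam_init(nets$G$layers), dg = nn_adam_init(nets$Dg$layers),
       dl = nn_adam_init(nets$Dl$layers), t = 0L)
}

# per-sample independent crops of a (H, W, 1, N) stack -> (size, size, 1, N)
crop_stack <- function(x, size) {
  d <- dim(x)
  crops <- array(0, c(size, size, 1L, d[4L]))
  pos <- matrix(0L, d[4L], 2L)
  for (n in seq_len(d[4L])) {
    cr <- random_crop(x[, , 1L, n], size)
    crops[, , 1L, n] <- cr$crop
    pos[n, ] <- c(cr$row0, cr$col0)
  }
  list(crops = crops, pos = pos)
}

#' One alternating optimization step
#'
#' Updates the global discriminator on (image, label) concatenations, the
#' local discriminator on random crops, then the generator on the weighted
#' sum of regional perceptual, regional L1 and the generator-side
#' least-squares adversarial terms. Discriminator updates never touch
#' generator weights and vice versa.
#'
#' @param batch Output of [make_batch()].
#' @param nets List with `G`, `Dg`, `Dl` networks.
#' @param opt Optimizer state from the previous step.
#' @param config A [gan_config()].
#' @param extractor A [feature_extractor()].
#' @return List with updated `nets`, `opt` and a one-row `record` data
#'   frame (`l_rp`, `l_1`, `l_g`, `l_l`, `l_adv`, `total`).
#' @export
train_step <- function(batch, nets, opt, config, extractor) {
  w <- config$weights
  lr <- config$learning_rate
  opt$t <- opt$t + 1L

  # generator forward (cached; reused for the G update since D updates do
  # not modify G weights)
  g_in <- concat_ch(batch$s_ab, batch$x_a)
  check_network_input(nets$G, g_in)
  fwG <- nn_net_forward(nets$G$layers, g_in)
  y <- fwG$out

  # --- global discriminator update (y detached) ---
  real_in <- concat_ch(batch$x_b, batch$s_b)
  fake_in <- concat_ch(y, batch$s_ab)
  fw_r <- nn_net_forward(nets$Dg$layers, real_in)
  fw_f <- nn_net_forward(nets$Dg$layers, fake_in)
  l_g <- lsgan_d_loss(fw_r$out, fw_f$out)
  bw_r <- nn_net_backward(nets$Dg$layers, fw_r$caches,
                          2 * (fw_r$out - 1) / length(fw_r$out))
  bw_f <- nn_net_backward(nets$Dg$layers, fw_f$caches,
                          2 * fw_f$out / length(fw_f$out))
  gsum <- add_grads(bw_r$grads, bw_f$grads)
  st <- nn_adam_step(nets$Dg$layers, gsum, opt$dg, lr, config$beta1,
                     config$beta2, t = opt$t)
  nets$Dg$layers <- st$layers; opt$dg <- st$state

  # --- local discriminator update on independent crops ---
  cr_r <- crop_stack(batch$x_b, config$crop_size)
  cr_f <- crop_stack(y, config$crop_size)
  fw_lr <- nn_net_forward(nets$Dl$layers, cr_r$crops)
  fw_lf <- nn_net_forward(nets$Dl$layers, cr_f$crops)
  l_l <- lsgan_d_loss(fw_lr$out, fw_lf$out)
  bw_lr <- nn_net_backward(nets$Dl$layers, fw_lr$caches,
                           2 * (fw_lr$out - 1) / length(fw_lr$out))
  bw_lf <- nn_net_backward(nets$Dl$layers, fw_lf$caches,
                           2 * fw_lf$out / length(fw_lf$out))
  st <- nn_adam_step(nets$Dl$layers, add_grads(bw_lr$grads, bw_lf$grads),
                     opt$dl, lr, config$beta1, config$beta2, t = opt$t)
  nets$Dl$layers <- st$layers; opt$dl <- st$state

  # --- generator update ---
  masks <- list(tissue_mask = batch$tissue, tumor_mask = batch$tumor)
  rp <- rp_loss_terms(y, batch$x_b, batch$x_a, masks, extractor, w,
                      config$perceptual_tags, grad = TRUE)
  l_rp <- rp$loss
  l_1 <- regional_l1_loss(y, batch$x_b, batch$tissue)
  grad_y <- w$lam * rp$grad_y +
    w$mu * regional_l1_grad(y, batch$x_b, batch$tissue)

  # global adversarial term through the updated Dg
  fw_gf <- nn_net_forward(nets$Dg$layers, concat_ch(y, batch$s_ab))
  bw_gf <- nn_net_backward(nets$Dg$layers, fw_gf$caches,
                           2 * (fw_gf$out - 1) / length(fw_gf$out))
  grad_y <- grad_y + w$gamma * bw_gf$gx[, , 1L, , drop = FALSE]

  # local adversarial term on fresh crops
  cr_g <- crop_stack(y, config$crop_size)
  fw_lg <- nn_net_forward(nets$Dl$layers, cr_g$crops)
  bw_lg <- nn_net_backward(nets$Dl$layers, fw_lg$caches,
                           2 * (fw_lg$out - 1) / length(fw_lg$out))
  sz <- config$crop_size
  for (n in seq_len(dim(y)[4L])) {
    r0 <- cr_g$pos[n, 1L]; c0 <- cr_g$pos[n, 2L]
    grad_y[r0 + seq_len(sz), c0 + seq_len(sz), 1L, n] <-
      grad_y[r0 + seq_len(sz), c0 + seq_len(sz), 1L, n] +
      w$gamma * bw_lg$gx[, , 1L, n]
  }

  bwG <- nn_net_backward(nets$G$layers, fwG$caches, grad_y)
  st <- nn_adam_step(nets$G$layers, bwG$grads, opt$g, lr, config$beta1,
                     config$beta2, t = opt$t)
  nets$G$layers <- st$layers; opt$g <- st$state

  l_adv <- l_g + l_l
  record <- data.frame(l_rp = l_rp, l_1 = l_1, l_g = l_g, l_l = l_l,
                       l_adv = l_adv,
                       total = total_loss(l_rp, l_1, l_adv, w))
  if (!all(is.finite(unlist(record))))
    stop("non-finite loss encountered: ",
         paste(names(record), signif(unlist(record), 4), sep = "=",
               collapse = ", "))
  list(nets = nets, opt = opt, record = record)
}

add_grads <- function(a, b) {
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) next
    if (!is.null(a[[i]]$w)) {
      a[[i]]$w <- a[[i]]$w + b[[i]]$w
      a[[i]]$b <- a[[i]]$b + b[[i]]$b
    } else a[[i]] <- add_grads(a[[i]], b[[i]])
  }
  a
}

#' Fit the lesion-synthesis GAN
#'
#' Trains the conditional generator that renders a composite semantic label
#' (tumor of donor A pasted on the brain of donor B) plus the tumor donor's
#' image into a synthetic slice, against a global image-label patch
#' discriminator and a local crop discriminator. Returns a fitted-model
#' object with the usual accessors (`print`, `summary`, `plot`, `predict`,
#' `simulate`).
#'
#' @param dataset A [slice_dataset()]; its image size must match
#'   `config$image_size`.
#' @param config A [gan_config()].
#' @param checkpoint_dir Directory for periodic checkpoints (`NULL` = none).
#' @param checkpoint_every Steps between checkpoints.
#' @param resume Path to a checkpoint file to continue from.
#' @return Object of class `lesion_gan`.
#' @export
fit_lesion_gan <- function(dataset, config = gan_config(),
                           checkpoint_dir = NULL, checkpoint_every = 100L,
                           resume = NULL) {
  stopifnot(inherits(dataset, "slice_dataset"), inherits(config, "gan_config"))
  if (!is.null(checkpoint_dir))
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(resume)) {
    set.seed(config$seed)
    nets <- new_gan_nets(config)
    opt <- new_opt_state(nets)
    log <- NULL
    step0 <- 0L
  } else {
    ck <- readRDS(resume)
    nets <- ck$nets; opt <- ck$opt; log <- ck$log; step0 <- ck$step
    config <- ck$config
    assign(".Random.seed", ck$rng, envir = globalenv())
  }
  if (dataset$image_size != config$image_size)
    stop("dataset image size ", dataset$image_size,
         " != config image_size ", config$image_size)
  extractor <- config$extractor %||%
    feature_extractor(base_width_scale = config$base_width_scale,
                      seed = config$seed)

  for (step in (step0 + 1L):config$iterations) {
    batch <- make_batch(dataset, config$batch_size, config$max_dropped)
    r <- train_step(batch, nets, opt, config, extractor)
    nets <- r$nets; opt <- r$opt
    log <- rbind(log, cbind(step = step, r$record))
    if (!is.null(checkpoint_dir) &&
        (step %% checkpoint_every == 0L || step == config$iterations)) {
      saveRDS(list(nets = nets, opt = opt, log = log, step = step,
                   config = config, rng = get(".Random.seed", globalenv())),
              file.path(checkpoint_dir, sprintf("checkpoint_%06d.rds", step)))
    }
  }

  structure(list(generator = nets$G, discriminators = nets[c("Dg", "Dl")],
                 config = config, log = log, extractor = extractor,
                 modality = dataset$modality,
                 n_patients = length(dataset_patients(dataset))),
            class = "lesion_gan")
}

#' @export
print.lesion_gan <- function(x, ...) {
  cat(sprintf("Lesion-synthesis GAN (modality %s)\n", x$modality))
  cat(sprintf("  trained %d steps on %d patients at %dx%d, width scale %s\n",
              max(x$log$step), x$n_patients, x$config$image_size,
              x$config$image_size, format(x$config$base_width_scale)))
  last <- x$log[nrow(x$log), ]
  cat(sprintf("  final losses: rp %.4g | L1 %.4g | adv %.4g | total %.4g\n",
              last$l_rp, last$l_1, last$l_adv, last$total))
  invisible(x)
}

#' @export
summary.lesion_gan <- function(object, ...) {
  log <- object$log
  k <- min(20L, nrow(log))
  out <- list(
    modality = object$modality,
    steps = max(log$step),
    parameters = nn_param_count(object$generator$layers),
    first_l1_median = median(log$l_1[seq_len(k)]),
    last_l1_median = median(log$l_1[seq.int(nrow(log) - k + 1L, nrow(log))]),
    final = log[nrow(log), ])
  class(out) <- "summary.lesion_gan"
  out
}

#' @export
print.summary.lesion_gan <- function(x, ...) {
  cat(sprintf("Lesion-synthesis GAN, modality %s: %d steps, %s generator parameters\n",
              x$modality, x$steps, format(x$parameters, big.mark = ",")))
  cat(sprintf("  tissue L1 median: first 20 steps %.4g -> last 20 steps %.4g\n",
              x$first_l1_median, x$last_l1_median))
  print(x$final, row.names = FALSE)
  invisible(x)
}

#' Plot training loss trajectories
#'
#' @param x A `lesion_gan`.
#' @param which Loss columns to draw.
#' @param ... Passed to `matplot`-style base graphics.
#' @export
plot.lesion_gan <- function(x, which = c("l_rp", "l_1", "l_adv"), ...) {
  log <- x$log
  cols <- seq_along(which)
  first <- TRUE
  for (i in seq_along(which)) {
    v <- log[[which[i]]]
    if (first) {
      graphics::plot(log$step, v, type = "l", col = cols[i], log = "y",
                     xlab = "step", ylab = "loss", ...)
      first <- FALSE
    } else lines(log$step, v, col = cols[i])
  }
  legend("topright", legend = which, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Synthesize an image from a semantic label and a tumor-donor image
#'
#' @param object A fitted `lesion_gan`.
#' @param label A [semantic_label()] or [composite_label()].
#' @param image Tumor donor image `x_a` (normalized matrix).
#' @param ... Unused.
#' @return Matrix in `[0, 1]` of the same shape as the label.
#' @export
predict.lesion_gan <- function(object, label, image, ...) {
  if (inherits(label, "composite_label")) label <- label$label
  stopifnot(inherits(label, "semantic_label"), is.matrix(image))
  g_in <- concat_ch(label_onehot(label),
                    array(image, c(dim(image), 1L, 1L)))
  y <- network_apply(object$generator, g_in)
  matrix(y, dim(y)[1L], dim(y)[2L])
}

#' Simulate virtual image/label pairs from a fitted model
#'
#' Thin wrapper over [generate_augmented_dataset()] returning the in-memory
#' pairs; see that function for the on-disk variant.
#'
#' @param object A fitted `lesion_gan`.
#' @param nsim Number of virtual pairs.
#' @param seed Seed for pair sampling.
#' @param dataset The [slice_dataset()] providing donors.
#' @param ... Unused.
#' @return List of `nsim` lists with `image`, `label`, `tumor_donor`,
#'   `background_donor`.
#' @export
simulate.lesion_gan <- function(object, nsim = 1L, seed = 1L, dataset, ...) {
  generate_augmented_dataset(object, dataset, k = nsim, seed = seed,
                             out_dir = NULL)$pairs
}
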