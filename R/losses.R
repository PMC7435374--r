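# Training objectives: regional perceptual loss, regional L1 loss, the
# local/global least-squares adversarial pair, and their weighted total.
# Every expectation is the plain mean over batch and all feature/pixel
# elements, which keeps the losses scale-stable across image sizes.

#' Loss weights
#'
#' `lambda1:lambda2:lambda3` weight the three terms inside the regional
#' perceptual loss (defaults 1:100:100); `lam:mu:gamma` weight the perceptual,
#' L1 and adversarial components of the total objective (defaults
#' 1:1000:1000).
#'
#' @param lambda1,lambda2,lambda3 Non-negative weights of the perceptual
#'   terms (tissue conv3_4, tissue conv4_4, tumor conv4_4).
#' @param lam,mu,gamma Non-negative weights of the total objective.
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 1, lambda2 = 100, lambda3 = 100,
                         lam = 1, mu = 1000, gamma = 1000) {
  w <- list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
            lam = lam, mu = mu, gamma = gamma)
  if (any(unlist(w) < 0) || any(!is.finite(unlist(w))))
    stop("loss weights must be finite and non-negative")
  structure(w, class = "loss_weights")
}

#' Mask an image
#'
#' Elementwise product of an image with a binary region mask; pixels outside
#' the mask become exactly zero. A 2D mask is broadcast over the batch of a
#' 4D image.
#'
#' @param image Matrix or `(H, W, C, N)` array.
#' @param mask Binary/logical matrix or array of matching spatial shape.
#' @return Masked image, same shape as `image`.
#' @export
masked_image <- function(image, mask) {
  m <- mask + 0
  if (is.matrix(image)) {
    if (!is.matrix(m) || !all(dim(image) == dim(m)))
      stop("image/mask shape mismatch")
    return(image * m)
  }
  d <- dim(image)
  if (is.matrix(m)) {
    if (!all(d[1:2] == dim(m))) stop("image/mask shape mismatch")
    return(image * as.vector(m))   # (H, W) recycles over C = 1 and N
  }
  if (!all(dim(m) == d)) stop("image/mask shape mismatch")
  image * m
}

# promote masks to (H, W, 1, N)
mask_as_batch <- function(mask, n) {
  if (is.matrix(mask)) array(rep(mask + 0, n), c(dim(mask), 1L, n))
  else nn_as_batch(mask + 0)
}

#' Regional perceptual loss
#'
#' Feature-space mean-squared error computed on masked regions, with masking
#' applied *before* feature extraction: the tissue region of the output is
#' compared against the background donor's image at two feature depths, and
#' the tumor region against the tumor donor's image at the deeper one:
#' `lambda1 MSE(phi_a(y R_tis), phi_a(x_b R_tis)) +
#'  lambda2 MSE(phi_b(y R_tis), phi_b(x_b R_tis)) +
#'  lambda3 MSE(phi_b(y R_tum), phi_b(x_a R_tum))`,
#' with `(phi_a, phi_b)` the `tags` features (default `conv3_4`, `conv4_4`).
#'
#' @param y Generated image (matrix or `(H, W, 1, N)` array in `[0, 1]`).
#' @param x_b Background donor image (tissue reference), same shape.
#' @param x_a Tumor donor image (tumor reference), same shape.
#' @param masks A [region_masks()] object (or list with `tissue_mask`,
#'   `tumor_mask`); masks may be per-batch arrays.
#' @param extractor A [feature_extractor()].
#' @param w [loss_weights()].
#' @param tags Length-2 character vector: the shallower and deeper feature
#'   tags.
#' @return Non-negative scalar loss.
#' @export
regional_perceptual_loss <- function(y, x_b, x_a, masks, extractor,
                                     w = loss_weights(),
                                     tags = c("conv3_4", "conv4_4")) {
  rp <- rp_loss_terms(y, x_b, x_a, masks, extractor, w, tags, grad = FALSE)
  rp$loss
}

# shared computation; with grad = TRUE also returns dLoss/dy
rp_loss_terms <- function(y, x_b, x_a, masks, extractor, w, tags,
                          grad = FALSE) {
  stopifnot(inherits(extractor, "feature_extractor"), length(tags) == 2L)
  y <- nn_as_batch(y); x_b <- nn_as_batch(x_b); x_a <- nn_as_batch(x_a)
  n <- dim(y)[4L]
  r_tis <- mask_as_batch(masks$tissue_mask, n)
  r_tum <- mask_as_batch(masks$tumor_mask, n)

  if (w$lambda1 == 0 && w$lambda2 == 0 && w$lambda3 == 0)
    return(list(loss = 0,
                grad_y = if (grad) array(0, dim(y))))

  f_xb <- extract_features(extractor, x_b * r_tis, tags)
  f_xa <- extract_features(extractor, x_a * r_tum, tags[2L])
  fw_tis <- extractor_forward_cached(extractor, y * r_tis, tags)
  fw_tum <- extractor_forward_cached(extractor, y * r_tum, tags[2L])

  d1 <- fw_tis$features[[tags[1L]]] - f_xb[[tags[1L]]]
  d2 <- fw_tis$features[[tags[2L]]] - f_xb[[tags[2L]]]
  d3 <- fw_tum$features[[tags[2L]]] - f_xa[[tags[2L]]]
  loss <- w$lambda1 * mean(d1^2) + w$lambda2 * mean(d2^2) +
    w$lambda3 * mean(d3^2)

  grad_y <- NULL
  if (grad) {
    tg_tis <- setNames(list(w$lambda1 * 2 * d1 / length(d1),
                            w$lambda2 * 2 * d2 / length(d2)), tags)
    g_tis <- extractor_backward(extractor, fw_tis, tg_tis)
    tg_tum <- setNames(list(w$lambda3 * 2 * d3 / length(d3)), tags[2L])
    g_tum <- extractor_backward(extractor, fw_tum, tg_tum)
    grad_y <- g_tis * r_tis + g_tum * r_tum
  }
  list(loss = loss, grad_y = grad_y)
}

#' Regional L1 loss
#'
#' Mean absolute difference between the generated image and the background
#' donor image, both restricted to the tissue mask; the mean is over all
#' pixels (and batch), not only masked ones.
#'
#' @param y,x_b Images of one shape.
#' @param tissue_mask Binary tissue region mask.
#' @return Non-negative scalar.
#' @export
regional_l1_loss <- function(y, x_b, tissue_mask) {
  y <- nn_as_batch(y); x_b <- nn_as_batch(x_b)
  if (!all(dim(y) == dim(x_b))) stop("image shape mismatch")
  r <- mask_as_batch(tissue_mask, dim(y)[4L])
  mean(abs(y * r - x_b * r))
}

# gradient of regional_l1_loss wrt y
regional_l1_grad <- function(y, x_b, tissue_mask) {
  y <- nn_as_batch(y); x_b <- nn_as_batch(x_b)
  r <- mask_as_batch(tissue_mask, dim(y)[4L])
  sign(y * r - x_b * r) * r / length(y)
}

#' Least-squares adversarial losses
#'
#' Discriminator side: `mean((d_real - 1)^2) + mean(d_fake^2)`; generator
#' side: `mean((d_fake - 1)^2)`. Inputs are raw patch maps (no sigmoid).
#'
#' @param d_real_out,d_fake_out Discriminator patch outputs of equal shape.
#' @return Non-negative scalar.
#' @export
lsgan_d_loss <- function(d_real_out, d_fake_out) {
  if (!is.null(dim(d_real_out)) && !is.null(dim(d_fake_out)) &&
      !all(dim(d_real_out) == dim(d_fake_out)))
    stop("patch map shape mismatch")
  mean((d_real_out - 1)^2) + mean(d_fake_out^2)
}

#' @rdname lsgan_d_loss
#' @export
lsgan_g_loss <- function(d_fake_out) {
  mean((d_fake_out - 1)^2)
}

#' Weighted total loss
#'
#' `lam * l_rp + mu * l_1 + gamma * l_adv`.
#'
#' @param l_rp,l_1,l_adv Finite loss components.
#' @param w [loss_weights()].
#' @return Scalar.
#' @export
total_loss <- function(l_rp, l_1, l_adv, w = loss_weights()) {
  if (!all(is.finite(c(l_rp, l_1, l_adv))))
    stop("non-finite loss component")
  w$lam * l_rp + w$mu * l_1 + w$gamma * l_adv
}
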