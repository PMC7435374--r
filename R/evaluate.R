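# Output-quality and agreement metrics: Dice over the standard tumor region
# groupings, and the Frechet distance between Gaussian fits to deep features.

#' Dice overlap of two binary masks
#'
#' `2 sum(t * p) / (sum(t) + sum(p) + eps)`; the summation is voxel-wise and
#' `eps` guards against division by zero for a pair of empty masks.
#'
#' @param p_true,p_pred Binary/logical arrays of one shape.
#' @param eps Small stabilizing constant.
#' @return Score in `[0, 1)`.
#' @export
dice_score <- function(p_true, p_pred, eps = 1e-6) {
  if (!all((dim(p_true) %||% length(p_true)) == (dim(p_pred) %||% length(p_pred))))
    stop("mask shape mismatch")
  t <- p_true + 0; p <- p_pred + 0
  2 * sum(t * p) / (sum(t) + sum(p) + eps)
}

#' Per-region Dice report for semantic labels
#'
#' Scores the standard region groupings — whole tumor (codes 2, 3, 4), tumor
#' core (3, 4) and enhancing tumor (4) — and their arithmetic mean.
#'
#' @param true_label,pred_label [semantic_label()] objects (or class
#'   matrices) of one shape.
#' @param eps Stabilizing constant of [dice_score()].
#' @return Object of class `dice_report`: list with `whole`, `core`, `en`,
#'   `mean`.
#' @export
region_dice <- function(true_label, pred_label, eps = 1e-6) {
  ct <- if (inherits(true_label, "semantic_label")) true_label$classes else true_label
  cp <- if (inherits(pred_label, "semantic_label")) pred_label$classes else pred_label
  if (!all(dim(ct) == dim(cp))) stop("label shape mismatch")
  scores <- list(whole = dice_score(ct %in% c(2L, 3L, 4L), cp %in% c(2L, 3L, 4L), eps),
                 core = dice_score(ct %in% c(3L, 4L), cp %in% c(3L, 4L), eps),
                 en = dice_score(ct == 4L, cp == 4L, eps))
  scores$mean <- mean(unlist(scores))
  structure(scores, class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("Dice  whole %.3f | core %.3f | en %.3f | mean %.3f\n",
              x$whole, x$core, x$en, x$mean))
  invisible(x)
}

#' Frechet distance between two Gaussian-fitted feature sets
#'
#' `||mu_r - mu_f||^2 + tr(S_r + S_f - 2 (S_r S_f)^{1/2})` with moments
#' estimated from the rows of each matrix. The cross covariance square root
#' is computed as `tr((S_r^{1/2} S_f S_r^{1/2})^{1/2})` via symmetric
#' eigendecompositions, with negative eigenvalues clipped for numerical
#' stability.
#'
#' @param features_real,features_fake Numeric matrices (rows = samples,
#'   columns = feature dimensions; at least 2 rows each, equal dimension).
#' @return Non-negative scalar; 0 iff the two moment pairs coincide.
#' @export
frechet_distance <- function(features_real, features_fake) {
  fr <- as.matrix(features_real); ff <- as.matrix(features_fake)
  if (ncol(fr) != ncol(ff)) stop("feature dimension mismatch")
  if (nrow(fr) < 2L || nrow(ff) < 2L)
    stop("need at least 2 feature vectors per set")
  mu_d <- colMeans(fr) - colMeans(ff)
  s_r <- cov(fr); s_f <- cov(ff)
  er <- eigen((s_r + t(s_r)) / 2, symmetric = TRUE)
  sq_r <- er$vectors %*% (sqrt(pmax(er$values, 0)) * t(er$vectors))
  a <- sq_r %*% s_f %*% sq_r
  ea <- eigen((a + t(a)) / 2, symmetric = TRUE)
  tr_sqrt <- sum(sqrt(pmax(ea$values, 0)))
  max(sum(mu_d^2) + sum(diag(s_r)) + sum(diag(s_f)) - 2 * tr_sqrt, 0)
}

#' Frechet distance between two image sets
#'
#' Embeds every image with the extractor's deepest requested feature map,
#' global-average-pooled over space, then applies [frechet_distance()]. With
#' the package's fixed-seed extractor the values are internally consistent
#' (self-distance 0, symmetric, monotone in corruption) but not on the scale
#' of published scores from pretrained backbones.
#'
#' @param real_images,fake_images Lists of matrices (or `(H, W, 1, N)`
#'   arrays), at least 2 images each.
#' @param extractor A [feature_extractor()].
#' @param tag Feature tag used for the embedding.
#' @return Non-negative scalar.
#' @export
fid_images <- function(real_images, fake_images, extractor,
                       tag = "conv4_4") {
  embed <- function(images) {
    if (is.list(images))
      images <- bind4(lapply(images, function(m) array(m, c(dim(m), 1L, 1L))))
    images <- nn_as_batch(images)
    f <- extract_features(extractor, images, tag)[[tag]]
    d <- dim(f)
    t(apply(array(f, c(d[1L] * d[2L], d[3L], d[4L])), c(2L, 3L), mean))
  }
  frechet_distance(embed(real_images), embed(fake_images))
}
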