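# Network construction from compact layer-specification strings.
#
# Grammar (one token per layer, '-' separated):
#   CIR<m>F<n>   conv (m filters, n x n) + instance norm + ReLU
#   CLR<m>F<n>   conv + LeakyReLU (no norm; discriminator stem)
#   CILR<m>F<n>  conv + instance norm + LeakyReLU
#   Res<m>       residual block, two m-channel 3x3 convs
#   DCIR<m>F<n>  transposed conv + instance norm + ReLU (stride-2 upsample)
#   C<m>F<n>     plain conv (network head)
#
# Stride policy: in the generator the stem and head are stride 1 and the
# CIR/DCIR layers between them are the stride-2 down/up-samplers; in the
# discriminators the first three conv layers are stride 2 and the rest
# stride 1 (the patch-discriminator convention of the pix2pix family this
# architecture inherits from — the strings specify filters, not strides).

TOKEN_RE <- "^(CILR|CIR|CLR|DCIR|Res|C)([0-9]+)(?:F([0-9]+))?$"

#' Parse a network specification string
#'
#' @param string Layer tokens separated by `-` (a Unicode minus is also
#'   accepted).
#' @param base_width_scale Multiplier on every channel width (1 = full
#'   scale); scaled widths are rounded and floored at 1 so the same
#'   architecture can run at e.g. 1/8 width on a CPU.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(string, base_width_scale = 1) {
  stopifnot(is.character(string), length(string) == 1L, base_width_scale > 0)
  toks <- strsplit(gsub("−", "-", string), "-", fixed = TRUE)[[1L]]
  parsed <- lapply(toks, function(t) {
    m <- regmatches(t, regexec(TOKEN_RE, t))[[1L]]
    if (length(m) == 0L) stop("cannot parse layer token: '", t, "'")
    kind <- m[2L]; width <- as.integer(m[3L])
    filt <- if (m[4L] == "") NA_integer_ else as.integer(m[4L])
    if (kind == "Res") filt <- 3L
    else if (is.na(filt)) stop("token '", t, "' is missing a filter size")
    list(kind = kind, width = width, filter = filt)
  })
  structure(list(layer_tokens = parsed, base_width_scale = base_width_scale,
                 string = paste(vapply(parsed, render_token, character(1)),
                                collapse = "-")),
            class = "network_spec")
}

render_token <- function(tok) {
  if (tok$kind == "Res") sprintf("Res%d", tok$width)
  else sprintf("%s%dF%d", tok$kind, tok$width, tok$filter)
}

#' Render a parsed specification back to its string form
#'
#' Inverse of [network_spec()]: `render_network_spec(network_spec(s)) == s`.
#'
#' @param spec A `network_spec`.
#' @return Single string of `-`-separated tokens.
#' @export
render_network_spec <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  spec$string
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> ", x$string, "\n  base width scale: ",
      format(x$base_width_scale), "\n", sep = "")
  invisible(x)
}

#' Canonical architecture specifications
#'
#' The generator is a residual encoder–decoder with a nine-block bottleneck;
#' the global discriminator has seven conv layers and the local discriminator
#' (which judges 64x64 crops) one fewer.
#'
#' @param base_width_scale Channel-width multiplier, see [network_spec()].
#' @return A `network_spec`.
#' @export
#' @rdname canonical_specs
generator_spec <- function(base_width_scale = 1) {
  network_spec(paste(c("CIR64F7", "CIR128F3", "CIR256F3", rep("Res256", 9L),
                       "DCIR128F3", "DCIR64F3", "C1F7"), collapse = "-"),
               base_width_scale)
}

#' @export
#' @rdname canonical_specs
global_discriminator_spec <- function(base_width_scale = 1) {
  network_spec("CLR64F4-CILR128F4-CILR256F4-CILR512F4-CILR512F4-CILR512F4-C1F4",
               base_width_scale)
}

#' @export
#' @rdname canonical_specs
local_discriminator_spec <- function(base_width_scale = 1) {
  network_spec("CLR64F4-CILR128F4-CILR256F4-CILR512F4-CILR512F4-C1F4",
               base_width_scale)
}

scaled_width <- function(w, scale) max(1L, as.integer(round(w * scale)))

#' Build the generator network
#'
#' Conv–InstanceNorm–ReLU stem, two stride-2 downsampling stages, a nine-block
#' residual bottleneck, two stride-2 transposed-conv upsampling stages and a
#' sigmoid head, mapping `(H, W, in_channels, N)` to `(H, W, 1, N)` images in
#' `[0, 1]`. `H` and `W` must be divisible by 4.
#'
#' @param in_channels Input channels: the one-hot label channels plus one
#'   image channel.
#' @param spec A `network_spec`; defaults to the canonical generator.
#' @return Object of class `lesion_network`.
#' @export
build_generator <- function(in_channels, spec = generator_spec()) {
  stopifnot(inherits(spec, "network_spec"), in_channels >= 1L)
  n_res <- sum(vapply(spec$layer_tokens, function(t) t$kind == "Res", logical(1)))
  if (n_res != 9L)
    stop("generator specification must contain exactly 9 Res tokens, found ", n_res)
  layers <- list()
  ch <- in_channels
  first_conv <- TRUE
  for (tok in spec$layer_tokens) {
    w <- scaled_width(tok$width, spec$base_width_scale)
    k <- tok$filter
    switch(tok$kind,
      CIR = {
        layers <- c(layers,
                    list(nn_conv_layer(ch, w, k,
                                       stride = if (first_conv) 1L else 2L),
                         nn_inorm_layer(), nn_relu_layer()))
        ch <- w; first_conv <- FALSE
      },
      Res = {
        if (w != ch) stop("residual width ", w, " != current channels ", ch)
        layers <- c(layers, list(nn_res_layer(ch)))
      },
      DCIR = {
        layers <- c(layers, list(nn_convt_layer(ch, w, k),
                                 nn_inorm_layer(), nn_relu_layer()))
        ch <- w
      },
      C = {
        layers <- c(layers, list(nn_conv_layer(ch, w, k), nn_sigmoid_layer()))
        ch <- w
      },
      stop("token ", render_token(tok), " is not valid in a generator"))
  }
  new_lesion_network(layers, spec, in_channels, "generator")
}

#' Build the global (full-image) patch discriminator
#'
#' Seven 4x4 conv layers — LeakyReLU stem without normalization, then
#' Conv–InstanceNorm–LeakyReLU stages, then a 1-channel head. The output is a
#' patch map (no sigmoid; the adversarial objective is least-squares). It
#' judges the concatenation of an image with its one-hot semantic label.
#'
#' @param in_channels Input channels (1 image channel + label channels).
#' @param spec A `network_spec`; defaults to the canonical 7-layer string.
#' @return Object of class `lesion_network`.
#' @export
build_global_discriminator <- function(in_channels,
                                       spec = global_discriminator_spec()) {
  build_patch_discriminator(in_channels, spec, kind = "global_discriminator")
}

#' Build the local (crop) patch discriminator
#'
#' Same token semantics as the global discriminator but one conv layer fewer:
#' it judges 64x64 single-channel crops (images only, no label channels).
#'
#' @param spec A `network_spec`; defaults to the canonical 6-layer string.
#' @param in_channels Input channels (1: a cropped image).
#' @param crop_size Expected input side length; forward rejects other sizes
#'   when `strict`.
#' @param strict Enforce the crop size at forward time.
#' @return Object of class `lesion_network`.
#' @export
build_local_discriminator <- function(spec = local_discriminator_spec(),
                                      in_channels = 1L, crop_size = 64L,
                                      strict = TRUE) {
  net <- build_patch_discriminator(in_channels, spec, kind = "local_discriminator")
  net$crop_size <- if (strict) as.integer(crop_size) else NA_integer_
  net
}

build_patch_discriminator <- function(in_channels, spec, kind) {
  stopifnot(inherits(spec, "network_spec"), in_channels >= 1L)
  layers <- list()
  ch <- in_channels
  conv_i <- 0L
  for (tok in spec$layer_tokens) {
    w <- scaled_width(tok$width, spec$base_width_scale)
    k <- tok$filter
    conv_i <- conv_i + 1L
    stride <- if (conv_i <= 3L) 2L else 1L
    switch(tok$kind,
      CLR = layers <- c(layers, list(nn_conv_layer(ch, w, k, stride = stride),
                                     nn_lrelu_layer())),
      CILR = layers <- c(layers, list(nn_conv_layer(ch, w, k, stride = stride),
                                      nn_inorm_layer(), nn_lrelu_layer())),
      C = layers <- c(layers, list(nn_conv_layer(ch, w, k, stride = stride))),
      stop("token ", render_token(tok), " is not valid in a discriminator"))
    ch <- w
  }
  new_lesion_network(layers, spec, in_channels, kind)
}

new_lesion_network <- function(layers, spec, in_channels, kind) {
  structure(list(layers = layers, spec = spec,
                 in_channels = as.integer(in_channels), kind = kind),
            class = "lesion_network")
}

#' @export
print.lesion_network <- function(x, ...) {
  cat(sprintf("<lesion_network: %s> %s\n  in_channels: %d, conv layers: %d, residual blocks: %d, parameters: %s\n",
              x$kind, x$spec$string, x$in_channels, conv_layer_count(x),
              res_block_count(x), format(nn_param_count(x$layers), big.mark = ",")))
  invisible(x)
}

#' Count convolutional layers / residual blocks of a network
#'
#' `conv_layer_count()` counts top-level conv and transposed-conv layers
#' (residual-block internals are not counted: a block is one bottleneck
#' unit); `res_block_count()` counts residual blocks.
#'
#' @param net A `lesion_network`.
#' @return Integer count.
#' @export
conv_layer_count <- function(net) {
  sum(vapply(net$layers, function(l) l$type %in% c("conv", "convt"), logical(1)))
}

#' @rdname conv_layer_count
#' @export
res_block_count <- function(net) {
  sum(vapply(net$layers, function(l) l$type == "res", logical(1)))
}

# channel widths of the top-level conv/convt layers, in order
network_widths <- function(net) {
  unlist(lapply(net$layers, function(l) {
    if (l$type == "conv") dim(l$w)[4L]
    else if (l$type == "convt") dim(l$w)[3L]
  }))
}

#' Run a network forward (inference)
#'
#' @param net A `lesion_network`.
#' @param x Input: 2D matrix or `(H, W, C, N)` array.
#' @return Output array `(H', W', C', N)`.
#' @export
network_apply <- function(net, x) {
  x <- nn_as_batch(x)
  check_network_input(net, x)
  nn_net_apply(net$layers, x)
}

check_network_input <- function(net, x) {
  d <- dim(x)
  if (d[3L] != net$in_channels)
    stop(net$kind, " expects ", net$in_channels, " channels, got ", d[3L])
  if (net$kind == "generator" && (d[1L] %% 4L != 0L || d[2L] %% 4L != 0L))
    stop("generator input height/width must be divisible by 4, got ",
         d[1L], "x", d[2L])
  if (!is.null(net$crop_size) && !is.na(net$crop_size) &&
      (d[1L] != net$crop_size || d[2L] != net$crop_size))
    stop("local discriminator expects ", net$crop_size, "x", net$crop_size,
         " crops, got ", d[1L], "x", d[2L])
  invisible(TRUE)
}

## ---- pluggable feature extractor ------------------------------------------

#' Build a fixed convolutional feature extractor
#'
#' A VGG-style stack — blocks of 3x3 Conv+ReLU layers separated by 2x2
#' max-pools — whose post-ReLU activations are addressable by tags
#' `conv<block>_<layer>`. With the default topology the tags `conv3_4`
#' ("the fourth conv layer before the third max-pool") and `conv4_4` exist,
#' the pair used by the regional perceptual loss. Weights are He-initialized
#' from a fixed seed, so the extractor is a deterministic function; no
#' pretrained weights are required to define a perceptual metric, only a
#' fixed deep feature map. Inputs are single-channel images in `[0, 1]`,
#' replicated to three channels and standardized with the usual ImageNet
#' moments before the first convolution.
#'
#' @param blocks Integer vector: conv layers per block (VGG-19 layout
#'   `c(2, 2, 4, 4)` by default).
#' @param widths Channels per block, scaled by `base_width_scale`.
#' @param base_width_scale Width multiplier (tests run at reduced width).
#' @param seed Seed for the fixed random weights.
#' @return Object of class `feature_extractor`.
#' @export
feature_extractor <- function(blocks = c(2L, 2L, 4L, 4L),
                              widths = c(64L, 128L, 256L, 512L),
                              base_width_scale = 1, seed = 1L) {
  stopifnot(length(blocks) == length(widths), all(blocks >= 1L))
  with_seed(seed, {
    layers <- list()
    tags <- integer(0)
    ch <- 3L
    for (b in seq_along(blocks)) {
      w <- scaled_width(widths[b], base_width_scale)
      for (j in seq_len(blocks[b])) {
        layers <- c(layers, list(
          nn_conv_layer(ch, w, 3L, init_sd = sqrt(2 / (9 * ch))),
          nn_relu_layer()))
        ch <- w
        tags[sprintf("conv%d_%d", b, j)] <- length(layers)
      }
      if (b < length(blocks)) layers <- c(layers, list(nn_maxpool_layer()))
    }
    structure(list(layers = layers, tags = tags, blocks = blocks,
                   seed = as.integer(seed)),
              class = "feature_extractor")
  })
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf("<feature_extractor> %d conv layers in %d blocks, tags: %s\n",
              sum(x$blocks), length(x$blocks),
              paste(names(x$tags), collapse = ", ")))
  invisible(x)
}

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

# (H, W, 1, N) in [0,1] -> standardized (H, W, 3, N)
extractor_prep <- function(x) {
  x <- nn_as_batch(x)
  d <- dim(x)
  stopifnot(d[3L] == 1L)
  out <- array(0, c(d[1L], d[2L], 3L, d[4L]))
  for (c in 1:3)
    out[, , c, ] <- (x[, , 1L, ] - IMAGENET_MEAN[c]) / IMAGENET_SD[c]
  out
}

# adjoint of extractor_prep
extractor_prep_bwd <- function(g) {
  d <- dim(g)
  gx <- array(0, c(d[1L], d[2L], 1L, d[4L]))
  for (c in 1:3)
    gx[, , 1L, ] <- gx[, , 1L, ] + g[, , c, ] / IMAGENET_SD[c]
  gx
}

#' Extract named feature maps from an image
#'
#' @param extractor A [feature_extractor()].
#' @param image 2D matrix or `(H, W, 1, N)` array with values in `[0, 1]`.
#' @param tags Character vector of requested feature tags.
#' @return Named list of feature arrays `(H', W', C', N)`.
#' @export
extract_features <- function(extractor, image,
                             tags = c("conv3_4", "conv4_4")) {
  stopifnot(inherits(extractor, "feature_extractor"))
  unknown <- setdiff(tags, names(extractor$tags))
  if (length(unknown) > 0L)
    stop("unknown feature tag(s): ", paste(unknown, collapse = ", "),
         " (have: ", paste(names(extractor$tags), collapse = ", "), ")")
  x <- extractor_prep(image)
  depth <- max(extractor$tags[tags])
  outs <- vector("list", depth)
  for (i in seq_len(depth)) {
    x <- nn_layer_forward(extractor$layers[[i]], x)$out
    outs[[i]] <- x
  }
  setNames(lapply(tags, function(t) outs[[extractor$tags[[t]]]]), tags)
}

# forward keeping caches up to the deepest tag (for gradient computation)
extractor_forward_cached <- function(extractor, image, tags) {
  x <- extractor_prep(image)
  depth <- max(extractor$tags[tags])
  caches <- vector("list", depth)
  outs <- vector("list", depth)
  for (i in seq_len(depth)) {
    r <- nn_layer_forward(extractor$layers[[i]], x)
    caches[[i]] <- r$cache
    x <- r$out
    outs[[i]] <- x
  }
  list(features = setNames(lapply(tags, function(t) outs[[extractor$tags[[t]]]]), tags),
       caches = caches, depth = depth)
}

# backprop tag-gradients to the (single-channel) input image
extractor_backward <- function(extractor, fwd, tag_grads) {
  idx <- extractor$tags[names(tag_grads)]
  g <- NULL
  for (i in rev(seq_len(fwd$depth))) {
    at <- which(idx == i)
    if (length(at) > 0L) {
      add <- Reduce(`+`, tag_grads[at])
      g <- if (is.null(g)) add else g + add
    }
    if (is.null(g)) next
    g <- nn_layer_backward(extractor$layers[[i]], fwd$caches[[i]], g)$gx
  }
  extractor_prep_bwd(g)
}
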