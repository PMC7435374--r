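# Preprocessing: raw volumes -> normalized slices, 5-class semantic labels
# and the region masks consumed by the regional losses.
#
# Internal label encoding (class map):
#   0 outside brain, 1 brain tissue, 2 edema, 3 necrotic/non-enhancing core,
#   4 enhancing tumor.
# Raw challenge codes are {0 background, 1 core, 2 edema, 4 enhancing}; the
# explicit tissue class is derived from nonzero raw intensity (the volumes
# are skull-stripped).

#' Construct a semantic label object
#'
#' @param classes Integer matrix with codes in `0:4` (0 outside brain,
#'   1 tissue, 2 edema, 3 core, 4 enhancing).
#' @param patient_id,slice_index Provenance.
#' @return An object of class `semantic_label`.
#' @export
semantic_label <- function(classes, patient_id = NA_character_,
                           slice_index = NA_integer_) {
  stopifnot(is.matrix(classes))
  storage.mode(classes) <- "integer"
  if (!all(classes %in% 0:4)) stop("semantic label codes must be in 0:4")
  structure(list(classes = classes, patient_id = as.character(patient_id),
                 slice_index = as.integer(slice_index)),
            class = "semantic_label")
}

#' @export
print.semantic_label <- function(x, ...) {
  cat(sprintf("<semantic_label %s/slice %s> %dx%d, tumor pixels: %d\n",
              x$patient_id, x$slice_index, nrow(x$classes), ncol(x$classes),
              sum(x$classes >= 2L)))
  invisible(x)
}

label_tumor_mask <- function(s) s$classes >= 2L
label_brain_mask <- function(s) s$classes >= 1L

#' Min-max normalize an image to the unit interval
#'
#' `I_N = (I - I_min) / (I_max - I_min)`, applied per 2D slice.
#'
#' @param image Finite numeric matrix/array.
#' @return Array of the same shape with minimum 0 and maximum 1.
#' @export
normalize_intensity <- function(image) {
  if (!all(is.finite(image))) stop("image contains non-finite values")
  lo <- min(image); hi <- max(image)
  if (hi == lo) stop("constant image: intensity range is zero")
  (image - lo) / (hi - lo)
}

#' Extract an axial slice window from a volume
#'
#' Keeps the slices with (0-based) index in the half-open window
#' `[low, high)` along the first axis. The defaults keep 80 slices, the
#' tumor-bearing central portion of a standard 155-slice study.
#'
#' @param volume 3D array (depth x height x width).
#' @param low,high Window bounds, 0-based, half-open.
#' @return List of 2D matrices, named by 0-based slice index.
#' @export
extract_slices <- function(volume, low = 30L, high = 110L) {
  stopifnot(length(dim(volume)) == 3L, low >= 0L, high > low)
  depth <- dim(volume)[1L]
  if (depth < high)
    stop(sprintf("volume depth %d is smaller than the slice window [%d, %d)",
                 depth, low, high))
  idx <- seq.int(low, high - 1L)
  out <- lapply(idx, function(z) volume[z + 1L, , ])
  names(out) <- idx
  out
}

#' Resize a 2D slice
#'
#' Bilinear interpolation for intensity images; nearest neighbor for label
#' maps, so no new codes are invented.
#'
#' @param image 2D matrix.
#' @param size Target side length (output is `size` x `size`), at least 16.
#' @param is_label Use nearest-neighbor interpolation.
#' @return Resized matrix (integer-valued when `is_label`).
#' @export
resize_slice <- function(image, size, is_label = FALSE) {
  stopifnot(is.matrix(image), size >= 16L)
  if (all(dim(image) == size)) return(image)
  out <- EBImage::resize(EBImage::Image(image), w = size, h = size,
                         filter = if (is_label) "none" else "bilinear")
  out <- as.matrix(out)
  if (is_label) storage.mode(out) <- "integer"
  out
}

#' Brain mask from a raw skull-stripped image
#'
#' Skull-stripped volumes carry zero intensity outside the head, so the mask
#' is `image > 0`, reduced to its largest connected component with interior
#' holes filled.
#'
#' @param image Raw (pre-normalization) 2D intensity matrix.
#' @return Logical matrix.
#' @export
brain_mask_from_image <- function(image) {
  stopifnot(is.matrix(image))
  m <- image > 0
  if (!any(m)) stop("empty brain mask: image has no positive intensities")
  clean_mask(m)
}

#' Encode a raw label slice into the 5-class semantic map
#'
#' Raw codes map as 0 -> 0 outside the brain and 1 (tissue) inside it,
#' 2 -> 2 (edema), 1 -> 3 (core), 4 -> 4 (enhancing).
#'
#' @param raw_label Integer matrix with codes in `{0, 1, 2, 4}`.
#' @param brain_mask Logical/binary matrix of the same shape.
#' @param patient_id,slice_index Provenance, stored on the result.
#' @return A [semantic_label()].
#' @export
encode_label <- function(raw_label, brain_mask, patient_id = NA_character_,
                         slice_index = NA_integer_) {
  stopifnot(is.matrix(raw_label), all(dim(raw_label) == dim(brain_mask)))
  if (!all(raw_label %in% c(0L, 1L, 2L, 4L)))
    stop("unexpected raw label code(s): ",
         paste(setdiff(unique(as.vector(raw_label)), c(0, 1, 2, 4)), collapse = ", "))
  brain_mask <- brain_mask > 0
  if (any(raw_label != 0L & !brain_mask))
    stop("tumor voxel outside the brain mask")
  cls <- matrix(0L, nrow(raw_label), ncol(raw_label))
  cls[brain_mask] <- 1L
  cls[raw_label == 2L] <- 2L
  cls[raw_label == 1L] <- 3L
  cls[raw_label == 4L] <- 4L
  semantic_label(cls, patient_id, slice_index)
}

#' Decode a semantic label back to raw challenge codes
#'
#' Inverse of [encode_label()]: classes 0 and 1 both map to raw 0,
#' 2 -> 2, 3 -> 1, 4 -> 4.
#'
#' @param label A [semantic_label()].
#' @return Integer matrix of raw codes.
#' @export
decode_label <- function(label) {
  stopifnot(inherits(label, "semantic_label"))
  cls <- label$classes
  raw <- matrix(0L, nrow(cls), ncol(cls))
  raw[cls == 2L] <- 2L
  raw[cls == 3L] <- 1L
  raw[cls == 4L] <- 4L
  raw
}

#' Region masks driving the regional losses
#'
#' The tumor mask covers donor A's tumor; the tissue mask covers donor B's
#' brain excluding both donors' tumor sites, so the two masks are disjoint by
#' construction.
#'
#' @param s_a,s_b [semantic_label()] objects of one shape (tumor donor A,
#'   background donor B).
#' @return Object of class `region_masks`: list with logical `tumor_mask`
#'   and `tissue_mask`.
#' @export
region_masks <- function(s_a, s_b) {
  stopifnot(inherits(s_a, "semantic_label"), inherits(s_b, "semantic_label"))
  if (!all(dim(s_a$classes) == dim(s_b$classes)))
    stop("label shape mismatch: ", paste(dim(s_a$classes), collapse = "x"),
         " vs ", paste(dim(s_b$classes), collapse = "x"))
  tum_a <- label_tumor_mask(s_a)
  structure(list(tumor_mask = tum_a,
                 tissue_mask = label_brain_mask(s_b) & !tum_a & !label_tumor_mask(s_b)),
            class = "region_masks")
}

# one-hot encode a semantic label to (H, W, 5, 1)
label_onehot <- function(label) {
  cls <- if (inherits(label, "semantic_label")) label$classes else label
  d <- dim(cls)
  oh <- array(0, c(d[1L], d[2L], 5L, 1L))
  for (k in 0:4) oh[, , k + 1L, 1L] <- as.numeric(cls == k)
  oh
}
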