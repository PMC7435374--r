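# Virtual label synthesis: paste the tumor of donor A onto the brain
# background of donor B, and enumerate the n^2 - n ordered donor pairs.

#' Composite a virtual semantic label from two donors
#'
#' Starting from background donor B's label with B's own tumor relabelled to
#' plain tissue, donor A's tumor codes are pasted at their original pixel
#' coordinates wherever they land inside B's brain. The composite mimics a
#' virtual patient carrying B's anatomy with A's lesion. Tumor pixels of A
#' that fall outside B's brain are dropped; a pair whose dropped fraction
#' exceeds `max_dropped` is rejected as inadmissible (an implausible lesion
#' placement would poison the augmentation), with a condition of class
#' `lesiongan_inadmissible_pair` so callers can skip and resample.
#'
#' @param s_a Tumor donor [semantic_label()]; must contain at least one tumor
#'   pixel.
#' @param s_b Background donor [semantic_label()] of the same shape.
#' @param max_dropped Maximum tolerated fraction of A-tumor pixels falling
#'   outside B's brain (default 0.05).
#' @return Object of class `composite_label`: list with `label` (the
#'   composite [semantic_label()]), `tumor_donor`, `background_donor`
#'   (each `"<patient>:<slice>"`), and `dropped_fraction`.
#' @export
composite_label <- function(s_a, s_b, max_dropped = 0.05) {
  stopifnot(inherits(s_a, "semantic_label"), inherits(s_b, "semantic_label"))
  if (!all(dim(s_a$classes) == dim(s_b$classes)))
    stop("label shape mismatch")
  tum_a <- label_tumor_mask(s_a)
  n_tum <- sum(tum_a)
  if (n_tum == 0L) stop("tumor donor label has no tumor pixels")

  brain_b <- label_brain_mask(s_b)
  cls <- s_b$classes
  cls[label_tumor_mask(s_b)] <- 1L          # erase B's own tumor to tissue
  keep <- tum_a & brain_b
  cls[keep] <- s_a$classes[keep]
  dropped_fraction <- sum(tum_a & !brain_b) / n_tum
  if (dropped_fraction > max_dropped)
    stop_lesiongan(
      sprintf("inadmissible pair: %.1f%% of the donor tumor falls outside the background brain (threshold %.1f%%)",
              100 * dropped_fraction, 100 * max_dropped),
      "lesiongan_inadmissible_pair")

  structure(list(
    label = semantic_label(cls, s_b$patient_id, s_b$slice_index),
    tumor_donor = sprintf("%s:%s", s_a$patient_id, s_a$slice_index),
    background_donor = sprintf("%s:%s", s_b$patient_id, s_b$slice_index),
    dropped_fraction = dropped_fraction), class = "composite_label")
}

#' @export
print.composite_label <- function(x, ...) {
  cat(sprintf("<composite_label> tumor %s on background %s (dropped %.1f%%)\n",
              x$tumor_donor, x$background_donor, 100 * x$dropped_fraction))
  invisible(x)
}

#' Enumerate ordered donor pairs
#'
#' All ordered pairs `(a, b)` with `a != b` from `n` patients — the
#' `n * (n - 1)` virtual samples the compositor can address; 226 patients
#' yield 50,850 pairs.
#'
#' @param patient_ids Character/atomic vector of unique ids.
#' @return A `data.frame` with columns `tumor_donor` and `background_donor`,
#'   lexicographically sorted, no self-pairs.
#' @export
enumerate_pairs <- function(patient_ids) {
  if (anyDuplicated(patient_ids)) stop("patient ids must be unique")
  ids <- sort(as.character(patient_ids))
  n <- length(ids)
  if (n < 2L)
    return(data.frame(tumor_donor = character(0), background_donor = character(0),
                      stringsAsFactors = FALSE))
  g <- expand.grid(background_donor = ids, tumor_donor = ids,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)[, 2:1]
  g <- g[g$tumor_donor != g$background_donor, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Sample donor pairs without replacement
#'
#' @param pairs Data frame from [enumerate_pairs()].
#' @param k Number of pairs to draw.
#' @param seed Integer seed; the draw is deterministic per seed.
#' @return `k` rows of `pairs`, uniformly sampled without replacement.
#' @export
sample_pairs <- function(pairs, k, seed) {
  stopifnot(is.data.frame(pairs), k >= 0L)
  if (k > nrow(pairs))
    stop(sprintf("cannot sample %d pairs from %d available", k, nrow(pairs)))
  idx <- with_seed(seed, sample.int(nrow(pairs), k))
  out <- pairs[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
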