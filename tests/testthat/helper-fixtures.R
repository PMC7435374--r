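# shared fixtures, all built in code

# small fixed-seed extractor: two blocks of two 3x3 convs (tags conv1_*, conv2_*)
tiny_extractor <- function(seed = 99L) {
  feature_extractor(blocks = c(2L, 2L), widths = c(8L, 16L), seed = seed)
}

# hand-drawn semantic label: brain disk with an optional square tumor
toy_label <- function(n = 16L, tumor = TRUE, patient = "T", slice = 0L,
                      brain_radius = 0.42, tumor_at = c(7L, 7L),
                      tumor_size = 4L) {
  h <- matrix(seq_len(n), n, n); w <- t(h)
  ctr <- (n + 1) / 2
  cls <- matrix(0L, n, n)
  cls[sqrt((h - ctr)^2 + (w - ctr)^2) <= brain_radius * n] <- 1L
  if (tumor) {
    ri <- tumor_at[1L] + seq_len(tumor_size) - 1L
    ci <- tumor_at[2L] + seq_len(tumor_size) - 1L
    block <- cls[ri, ci] >= 1L
    sub <- cls[ri, ci]
    sub[block] <- 2L
    core <- block & row(block) > 1 & col(block) > 1
    sub[core] <- 3L
    sub[block & row(block) > 2 & col(block) > 2] <- 4L
    cls[ri, ci] <- sub
  }
  semantic_label(cls, patient, slice)
}

# cached small training dataset (32x32 slices, fast steps)
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- phantom_slice_dataset(3, seed = 5, shape = c(4L, 48L, 48L),
                                      modality = "t1ce")
    cache
  }
})

small_config <- function(iterations = 2L, seed = 3L, ...) {
  gan_config(iterations = iterations, image_size = 48L, crop_size = 32L,
             base_width_scale = 1 / 8, seed = seed, modality = "t1ce",
             extractor = tiny_extractor(),
             perceptual_tags = c("conv1_2", "conv2_2"), ...)
}
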