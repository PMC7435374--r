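# Emit virtual (image, label) pairs from a fitted generator.

#' Generate an augmented dataset of virtual pairs
#'
#' For each sampled donor pair (a, b): composite a's tumor onto b's brain,
#' run the generator on the composite label concatenated with a's image, and
#' collect (synthetic image, composite label) with full provenance.
#' Inadmissible pairs are skipped and replaced within a bounded budget. With
#' `out_dir` set, pairs are written as paired 8-bit PNGs (grayscale image in
#' `[0, 1]`; label codes 0-4 stored as gray levels `code/255`) plus a
#' `manifest.csv`.
#'
#' @param object A fitted [fit_lesion_gan()] model.
#' @param dataset The [slice_dataset()] providing donors.
#' @param k Number of virtual pairs to emit.
#' @param seed Seed; the manifest is identical across runs with one seed.
#' @param out_dir Output directory, or `NULL` for in-memory results only.
#' @param max_dropped Compositor admissibility threshold.
#' @return List with `manifest` (data frame: out_image, out_label,
#'   tumor_donor, background_donor, slice_index, modality) and `pairs`
#'   (list of `image`, `label`, donor ids).
#' @export
generate_augmented_dataset <- function(object, dataset, k, seed = 1L,
                                       out_dir = NULL, max_dropped = 0.05) {
  stopifnot(inherits(object, "lesion_gan"), inherits(dataset, "slice_dataset"),
            k >= 1L)
  donors <- dataset_patients(dataset, tumor_only = TRUE)
  all_pat <- dataset_patients(dataset)
  pair_pool <- enumerate_pairs(all_pat)
  pair_pool <- pair_pool[pair_pool$tumor_donor %in% donors, , drop = FALSE]
  if (k > nrow(pair_pool))
    stop("k = ", k, " exceeds the ", nrow(pair_pool), " admissible-candidate pairs")
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  with_seed(seed, {
    ord <- sample.int(nrow(pair_pool))   # random pair order, no replacement
    pairs <- list()
    manifest <- list()
    i <- 0L
    for (row in ord) {
      if (length(pairs) >= k) break
      a <- pair_pool$tumor_donor[row]; b <- pair_pool$background_donor[row]
      ea_pool <- dataset_entries_of(dataset, a, tumor_only = TRUE)
      eb_pool <- dataset_entries_of(dataset, b)
      ea <- ea_pool[[sample.int(length(ea_pool), 1L)]]
      eb <- eb_pool[[sample.int(length(eb_pool), 1L)]]
      comp <- tryCatch(composite_label(ea$label, eb$label, max_dropped),
                       lesiongan_inadmissible_pair = function(e) NULL)
      if (is.null(comp)) next
      y <- predict(object, comp, ea$image)
      i <- i + 1L
      rec <- list(image = y, label = comp$label,
                  tumor_donor = comp$tumor_donor,
                  background_donor = comp$background_donor)
      pairs[[i]] <- rec
      img_path <- lab_path <- NA_character_
      if (!is.null(out_dir)) {
        img_path <- file.path(out_dir, sprintf("virtual_%04d_image.png", i))
        lab_path <- file.path(out_dir, sprintf("virtual_%04d_label.png", i))
        png::writePNG(pmin(pmax(y, 0), 1), img_path)
        png::writePNG(decode_label(comp$label) / 255, lab_path)
      }
      manifest[[i]] <- data.frame(
        out_image = img_path, out_label = lab_path,
        tumor_donor = comp$tumor_donor,
        background_donor = comp$background_donor,
        slice_index = comp$label$slice_index,
        modality = dataset$modality, stringsAsFactors = FALSE)
    }
    if (length(pairs) < k)
      stop("admissible-pair budget exhausted: produced ", length(pairs),
           " of ", k, " requested pairs")
    manifest <- do.call(rbind, manifest)
    if (!is.null(out_dir))
      write.csv(manifest, file.path(out_dir, "manifest.csv"),
                row.names = FALSE)
    list(manifest = manifest, pairs = pairs)
  })
}

#' Read back one emitted virtual pair
#'
#' @param image_path,label_path Paths from the manifest.
#' @return List with `image` (matrix in `[0, 1]`) and `label_codes`
#'   (integer matrix of raw codes).
#' @export
read_augmented_pair <- function(image_path, label_path) {
  img <- png::readPNG(image_path)
  lab <- round(png::readPNG(label_path) * 255)
  storage.mode(lab) <- "integer"
  bad <- setdiff(unique(as.vector(lab)), c(0L, 1L, 2L, 4L))
  if (length(bad) > 0L)
    stop("unexpected label code(s) in ", basename(label_path), ": ",
         paste(bad, collapse = ", "))
  list(image = img, label_codes = lab)
}
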