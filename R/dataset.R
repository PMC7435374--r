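# In-memory slice dataset: the unit the trainer and augmenter consume.
# One dataset holds one modality (one model is trained per modality).

#' Build a slice dataset from preprocessed entries
#'
#' @param entries List of entries, each a list with `patient_id`,
#'   `slice_index`, `image` (normalized matrix in `[0, 1]`) and `label`
#'   (a [semantic_label()]).
#' @param modality Modality name the images belong to.
#' @return Object of class `slice_dataset`.
#' @export
slice_dataset <- function(entries, modality) {
  stopifnot(length(entries) > 0L)
  for (e in entries) {
    stopifnot(is.matrix(e$image), inherits(e$label, "semantic_label"))
    if (min(e$image) < 0 || max(e$image) > 1)
      stop("dataset images must be normalized to [0, 1]")
    if (!all(dim(e$image) == dim(e$label$classes)))
      stop("image/label shape mismatch for ", e$patient_id)
  }
  structure(list(entries = entries, modality = modality,
                 image_size = nrow(entries[[1L]]$image)),
            class = "slice_dataset")
}

#' @export
print.slice_dataset <- function(x, ...) {
  cat(sprintf("<slice_dataset> %d slices from %d patients, modality %s, %dx%d\n",
              length(x$entries), length(dataset_patients(x)), x$modality,
              x$image_size, x$image_size))
  invisible(x)
}

#' Patients present in a dataset
#' @param dataset A `slice_dataset`.
#' @param tumor_only Count only patients with at least one tumor-bearing
#'   slice.
#' @return Character vector of patient ids.
#' @export
dataset_patients <- function(dataset, tumor_only = FALSE) {
  keep <- if (tumor_only)
    vapply(dataset$entries, function(e) sum(label_tumor_mask(e$label)) > 0L,
           logical(1))
  else rep(TRUE, length(dataset$entries))
  unique(vapply(dataset$entries[keep], `[[`, character(1), "patient_id"))
}

#' Entries of one patient
#' @param dataset A `slice_dataset`.
#' @param patient_id Patient identifier.
#' @param tumor_only Keep only tumor-bearing slices.
#' @return List of dataset entries.
#' @export
dataset_entries_of <- function(dataset, patient_id, tumor_only = FALSE) {
  sel <- vapply(dataset$entries, function(e) {
    e$patient_id == patient_id &&
      (!tumor_only || sum(label_tumor_mask(e$label)) > 0L)
  }, logical(1))
  dataset$entries[sel]
}

#' Preprocess one case into dataset entries
#'
#' Runs the standard pipeline per axial slice: brain mask from the raw
#' intensities (largest component, holes filled), 5-class label encoding,
#' min-max normalization and optional square resize. Slices whose brain
#' region is tiny (fewer than `min_brain` pixels) are skipped.
#'
#' @param case A `phantom_case` (generated or read from NIfTI).
#' @param modality Which modality channel to use.
#' @param slice_low,slice_high Half-open slice window (0-based); defaults to
#'   the whole stack.
#' @param image_size Output side length; `NULL` keeps the native size.
#' @param min_brain Minimum brain-pixel count for a slice to be kept.
#' @return List of entries suitable for [slice_dataset()].
#' @export
preprocess_case <- function(case, modality, slice_low = 0L,
                            slice_high = dim(case$label_volume)[1L],
                            image_size = NULL, min_brain = 64L) {
  stopifnot(inherits(case, "phantom_case"))
  if (!modality %in% names(case$volumes))
    stop("case ", case$case_id, " has no modality '", modality, "'")
  imgs <- extract_slices(case$volumes[[modality]], slice_low, slice_high)
  labs <- extract_slices(case$label_volume, slice_low, slice_high)
  entries <- list()
  for (i in seq_along(imgs)) {
    raw <- imgs[[i]]
    if (sum(raw > 0) < min_brain) next
    bm <- brain_mask_from_image(raw)
    rl <- labs[[i]]
    storage.mode(rl) <- "integer"
    rl[!bm] <- 0L   # guard against mask cleanup clipping stray voxels
    lab <- encode_label(rl, bm, patient_id = case$case_id,
                        slice_index = as.integer(names(imgs)[i]))
    img <- normalize_intensity(raw)
    if (!is.null(image_size) && image_size != nrow(img)) {
      img <- resize_slice(img, image_size)
      cls <- resize_slice(lab$classes, image_size, is_label = TRUE)
      lab <- semantic_label(cls, lab$patient_id, lab$slice_index)
      img <- pmin(pmax(img, 0), 1)
    }
    entries[[length(entries) + 1L]] <-
      list(patient_id = case$case_id, slice_index = lab$slice_index,
           image = img, label = lab)
  }
  entries
}

#' Generate a ready-to-train phantom dataset
#'
#' Convenience wrapper: generates `n_patients` phantom cases (seeds
#' `seed, seed + 1, ...`) and preprocesses one modality into a
#' [slice_dataset()].
#'
#' @param n_patients Number of phantom patients.
#' @param seed Base seed; the dataset is deterministic.
#' @param shape Per-case volume shape `c(depth, height, width)`.
#' @param modality Modality to extract.
#' @param image_size Output slice size (default: native width).
#' @return A `slice_dataset`.
#' @export
phantom_slice_dataset <- function(n_patients, seed = 1L,
                                  shape = c(6L, 64L, 64L),
                                  modality = "t1ce", image_size = NULL) {
  entries <- list()
  for (i in seq_len(n_patients)) {
    case <- generate_phantom_case(seed + i - 1L, shape = shape,
                                  modalities = modality,
                                  case_id = sprintf("P%03d", i))
    entries <- c(entries, preprocess_case(case, modality,
                                          image_size = image_size))
  }
  slice_dataset(entries, modality)
}
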