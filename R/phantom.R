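#' Generate a synthetic multi-modal brain-slice case
#'
#' Builds a phantom that mimics the structure of a skull-stripped,
#' voxel-labelled multi-modal brain MRI study: each axial slice contains a
#' smooth closed brain region on a zero background, and (optionally) a tumor
#' composed of nested sub-regions — edema surrounding a necrotic/non-enhancing
#' core which in turn surrounds an enhancing rim. Raw label codes follow the
#' usual challenge convention: 0 background, 1 necrotic/non-enhancing core,
#' 2 edema, 4 enhancing tumor. Modality contrast is emulated coarsely; in
#' particular the contrast-enhanced T1 channel ("t1ce") renders the tumor
#' core brighter than the surrounding edema.
#'
#' The phantom is fully deterministic for a fixed `seed`: the brain outline is
#' a thresholded sum of random Gaussian bumps (largest connected component,
#' holes filled), the tumor an ellipse with two interior rings, and additive
#' Gaussian noise (sd = 3% of the intensity range, clipped at zero) keeps the
#' images from being piecewise constant. All tumor voxels lie strictly inside
#' the brain region, i.e. have positive intensity in every modality.
#'
#' @param seed Integer seed; the case is bit-identical across calls with the
#'   same arguments.
#' @param shape Integer vector `c(depth, height, width)`; height and width
#'   must be at least 32.
#' @param modalities Character vector drawn from
#'   `c("flair", "t1", "t1ce", "t2")`.
#' @param tumor_probability Probability that the case carries a tumor
#'   (default 1; the label compositor requires tumor donors).
#' @param case_id Identifier used in file names; defaults to a seed-derived id.
#' @return An object of class `phantom_case`: a list with `case_id`,
#'   `volumes` (named list of depth x height x width arrays), `label_volume`
#'   (integer array of raw codes), `modalities` and `seed`.
#' @examples
#' case <- generate_phantom_case(7, shape = c(4, 48, 48),
#'                               modalities = c("flair", "t1ce"))
#' table(case$label_volume)
#' @export
generate_phantom_case <- function(seed,
                                  shape = c(8L, 64L, 64L),
                                  modalities = c("flair", "t1", "t1ce", "t2"),
                                  tumor_probability = 1,
                                  case_id = sprintf("phantom%04d", seed)) {
  if (length(shape) != 3L || any(shape < 1L) || any(shape[2:3] < 32L))
    stop("`shape` must be c(depth, height, width) with height, width >= 32")
  known <- c("flair", "t1", "t1ce", "t2")
  if (length(modalities) == 0L || !all(modalities %in% known))
    stop("unknown modality name(s): ",
         paste(setdiff(modalities, known), collapse = ", "),
         " (expected flair, t1, t1ce, t2)")
  if (anyDuplicated(modalities)) stop("duplicated modality names")
  D <- shape[1L]; H <- shape[2L]; W <- shape[3L]

  with_seed(seed, {
    # smooth in-slice field: sum of Gaussian bumps near the image centre
    nb <- 6L
    ch <- runif(nb, 0.35, 0.65) * H
    cw <- runif(nb, 0.35, 0.65) * W
    sg <- runif(nb, 0.15, 0.25) * min(H, W)
    am <- runif(nb, 0.7, 1)
    hh <- matrix(seq_len(H), H, W)
    ww <- matrix(seq_len(W), H, W, byrow = TRUE)
    field <- 0
    for (k in seq_len(nb))
      field <- field + am[k] * exp(-((hh - ch[k])^2 + (ww - cw[k])^2) / (2 * sg[k]^2))
    field <- (field - min(field)) / (max(field) - min(field))

    # per-slice brain mask: area tapers towards the ends of the stack
    zc <- (D + 1) / 2
    zprof <- sqrt(pmax(0, 1 - ((seq_len(D) - zc) / (0.75 * D))^2))
    amax <- runif(1, 0.45, 0.65)
    brain <- array(FALSE, c(D, H, W))
    for (z in seq_len(D)) {
      frac <- amax * max(zprof[z], 0.15)
      m <- field >= stats::quantile(field, 1 - frac)
      m <- clean_mask(m)
      brain[z, , ] <- m
    }

    has_tumor <- runif(1) < tumor_probability
    label <- array(0L, c(D, H, W))
    if (has_tumor) {
      # tumor centre well inside the brain (high field value)
      cand <- which(field >= stats::quantile(field, 0.8), arr.ind = TRUE)
      ctr <- cand[sample.int(nrow(cand), 1L), ]
      r <- runif(1, 0.12, 0.2) * min(H, W)
      ar <- runif(1, 0.7, 1.3)          # axis ratio
      th <- runif(1, 0, pi)             # orientation
      u <- (hh - ctr[1L]) * cos(th) + (ww - ctr[2L]) * sin(th)
      v <- -(hh - ctr[1L]) * sin(th) + (ww - ctr[2L]) * cos(th)
      zt <- sample.int(D, 1L, prob = zprof + 0.01)
      lz <- max(1, round(0.35 * D))
      for (z in seq_len(D)) {
        sc <- 1 - (abs(z - zt) / lz)^2
        if (sc <= 0) next
        dd <- sqrt((u / (r * sqrt(sc)))^2 + (v / (r * ar * sqrt(sc)))^2)
        sl <- array(0L, c(H, W))
        sl[dd <= 1] <- 2L
        sl[dd <= 0.65] <- 1L
        sl[dd <= 0.35] <- 4L
        sl[!brain[z, , ]] <- 0L           # tumor cannot leave the brain
        label[z, , ] <- sl
      }
    }

    # modality-dependent mean intensities per region
    #               tissue edema core  enh
    contrast <- list(flair = c(0.40, 0.75, 0.55, 0.60),
                     t1    = c(0.55, 0.35, 0.30, 0.45),
                     t1ce  = c(0.50, 0.35, 0.55, 0.90),
                     t2    = c(0.45, 0.80, 0.65, 0.50))
    volumes <- list()
    for (mod in modalities) {
      cv <- contrast[[mod]]
      img <- array(0, c(D, H, W))
      img[brain] <- cv[1L]
      img[label == 2L] <- cv[2L]
      img[label == 1L] <- cv[3L]
      img[label == 4L] <- cv[4L]
      noise <- array(rnorm(length(img), 0, 0.03), dim(img))
      img <- pmax(img + noise, 0)
      img[brain] <- pmax(img[brain], 0.01)  # brain voxels stay strictly positive
      img[!brain] <- 0
      volumes[[mod]] <- img * round(runif(1, 500, 1500))
    }

    structure(list(case_id = case_id, volumes = volumes,
                   label_volume = label, modalities = modalities,
                   seed = as.integer(seed)),
              class = "phantom_case")
  })
}

# largest connected component with holes filled (per 2D slice)
clean_mask <- function(m) {
  img <- matrix(as.numeric(m), nrow(m))
  lab <- matrix(as.integer(EBImage::bwlabel(img)), nrow(m))
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    img <- matrix(as.numeric(lab == which.max(sizes)), nrow(m))
  }
  filled <- EBImage::fillHull(EBImage::Image(img))
  matrix(as.numeric(filled), nrow(m)) > 0
}

#' @export
print.phantom_case <- function(x, ...) {
  d <- dim(x$label_volume)
  cat(sprintf("<phantom_case '%s'> %dx%dx%d, modalities: %s, tumor voxels: %d\n",
              x$case_id, d[1], d[2], d[3],
              paste(x$modalities, collapse = ", "),
              sum(x$label_volume != 0L)))
  invisible(x)
}

#' Write a phantom (or real) case to NIfTI files
#'
#' One compressed NIfTI per modality plus one label file, following the
#' standard challenge layout `<case_id>_<modality>.nii.gz` /
#' `<case_id>_seg.nii.gz`. Intensities are stored as doubles and labels as
#' 16-bit integers so the pair round-trips exactly through
#' [read_case_nifti()].
#'
#' @param case A `phantom_case`.
#' @param directory Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_case_nifti <- function(case, directory) {
  stopifnot(inherits(case, "phantom_case"))
  if (length(case$volumes) == 0L) stop("case has no modality volumes")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (mod in names(case$volumes)) {
    p <- file.path(directory, sprintf("%s_%s.nii.gz", case$case_id, mod))
    RNifti::writeNifti(RNifti::asNifti(case$volumes[[mod]]), p, datatype = "double")
    paths <- c(paths, p)
  }
  p <- file.path(directory, sprintf("%s_seg.nii.gz", case$case_id))
  lab <- case$label_volume
  storage.mode(lab) <- "integer"
  RNifti::writeNifti(RNifti::asNifti(lab), p, datatype = "int16")
  paths <- c(paths, p)
  for (pp in paths) if (!file.exists(pp)) stop("failed to write ", pp)
  invisible(paths)
}

#' Read a case from NIfTI files
#'
#' Counterpart of [write_case_nifti()]; also serves as the reader for real
#' challenge-format cases laid out as `<case_id>_<modality>.nii.gz` plus
#' `<case_id>_seg.nii.gz`.
#'
#' @param directory Directory holding the files.
#' @param case_id Case identifier (file-name prefix).
#' @param modalities Modalities expected; `NULL` discovers every non-label
#'   modality file present.
#' @return A `phantom_case` (with `seed = NA` for cases read from disk).
#' @export
read_case_nifti <- function(directory, case_id, modalities = NULL) {
  seg_path <- file.path(directory, sprintf("%s_seg.nii.gz", case_id))
  found <- list.files(directory, pattern = paste0("^", case_id, "_.*\\.nii\\.gz$"))
  found_mods <- setdiff(sub(paste0("^", case_id, "_(.*)\\.nii\\.gz$"), "\\1", found), "seg")
  if (is.null(modalities)) modalities <- found_mods
  if (length(modalities) == 0L) stop("no modality files found for ", case_id)
  missing <- setdiff(modalities, found_mods)
  if (length(missing) > 0L || !file.exists(seg_path))
    stop(sprintf("missing files for case '%s': expected [%s], found [%s]%s",
                 case_id, paste(c(modalities, "seg"), collapse = ", "),
                 paste(c(found_mods, if (file.exists(seg_path)) "seg"), collapse = ", "),
                 if (!file.exists(seg_path)) sprintf("; no label file %s", basename(seg_path)) else ""))
  volumes <- list()
  for (mod in modalities) {
    p <- file.path(directory, sprintf("%s_%s.nii.gz", case_id, mod))
    volumes[[mod]] <- as.array(RNifti::readNifti(p))
  }
  lab <- as.array(RNifti::readNifti(seg_path))
  storage.mode(lab) <- "integer"
  bad <- setdiff(unique(as.vector(lab)), c(0L, 1L, 2L, 4L))
  if (length(bad) > 0L)
    stop("unexpected label code(s) in ", basename(seg_path), ": ",
         paste(bad, collapse = ", "))
  structure(list(case_id = case_id, volumes = volumes, label_volume = lab,
                 modalities = modalities, seed = NA_integer_),
            class = "phantom_case")
}

#' Export one slice as an 8-bit grayscale PNG
#'
#' @param image 2D numeric matrix; rescaled to `[0, 1]` unless already there.
#' @param path Output file.
#' @export
export_slice_png <- function(image, path) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (rng[1] < 0 || rng[2] > 1)
    image <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  png::writePNG(image, path)
  invisible(path)
}
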