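#' Read one patient's modalities and labels from NIfTI files
#'
#' Modalities are stacked in the fixed order T1, T1ce, T2, FLAIR; voxel
#' spacing is read from the headers. All five grids (and spacings) must
#' agree; label codes must be BraTS codes.
#'
#' @param paths named list or vector with entries `t1`, `t1ce`, `t2`,
#'   `flair` and `labels`.
#' @param id patient identifier to attach.
#' @return A list with `volume` (an [mm_volume()]), `labels`
#'   (a [label_volume()]) and `id` — the same shape the phantom generator
#'   produces.
#' @export
read_patient <- function(paths, id = "patient") {
  need <- c(modality_names(), "labels")
  missing <- setdiff(need, names(paths))
  if (length(missing))
    stop_rfs("missing path(s) for: %s", paste(missing, collapse = ", "))
  for (m in need)
    if (!file.exists(paths[[m]]))
      stop_rfs("file for '%s' not found: %s", m, paths[[m]])
  imgs <- lapply(need, function(m) RNifti::readNifti(paths[[m]]))
  names(imgs) <- need
  d <- dim(imgs$t1)
  sp <- RNifti::pixdim(imgs$t1)
  for (m in need) {
    if (!identical(dim(imgs[[m]]), d))
      stop_rfs("grid mismatch for '%s': %s vs %s", m,
               paste(dim(imgs[[m]]), collapse = "x"), paste(d, collapse = "x"))
    if (max(abs(RNifti::pixdim(imgs[[m]]) - sp)) > 1e-4)
      stop_rfs("voxel spacing mismatch for '%s'", m)
  }
  lab <- array(as.integer(round(imgs$labels)), d)
  check_label_codes(lab)
  vol <- mm_volume(t1 = array(as.numeric(imgs$t1), d),
                   t1ce = array(as.numeric(imgs$t1ce), d),
                   t2 = array(as.numeric(imgs$t2), d),
                   flair = array(as.numeric(imgs$flair), d),
                   spacing = as.numeric(sp))
  list(volume = vol, labels = label_volume(lab, as.numeric(sp)), id = id)
}

#' Write a mask or label volume as compressed NIfTI
#'
#' The reference supplies grid, spacing and orientation metadata; the grid
#' must match the array being written. Region masks are written as 0/1
#' integer volumes, label volumes with their BraTS codes.
#'
#' @param x logical/integer 3D array or a [label_volume()].
#' @param reference an [mm_volume()], a NIfTI image, or a spacing vector.
#' @param path output path (`.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(x, reference, path) {
  v <- if (inherits(x, "label_volume")) x$values else x
  v <- array(as.integer(v), dim(v))
  spacing <- if (inherits(reference, "mm_volume")) {
    if (!identical(dim(v), dim(reference$t1)))
      stop_rfs("mask grid does not match the reference grid")
    reference$spacing
  } else if (is.numeric(reference) && length(reference) >= 3) {
    as.numeric(reference)[1:3]
  } else {
    stop_rfs("reference must be an mm_volume or a spacing vector")
  }
  img <- RNifti::asNifti(v, pixdim = spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write one patient's volumes and labels to a directory
#'
#' BraTS-style file-per-modality layout: `<id>_t1.nii.gz`, ...,
#' `<id>_seg.nii.gz`.
#'
#' @param patient list with `$volume`, `$labels`, `$id`.
#' @param dir output directory (created).
#' @return Named vector of the written paths, invisibly.
#' @export
write_patient <- function(patient, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- patient$volume$spacing
  paths <- c()
  for (m in modality_names()) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", patient$id, m))
    RNifti::writeNifti(RNifti::asNifti(patient$volume[[m]], pixdim = sp), p)
    paths[m] <- p
  }
  p <- file.path(dir, sprintf("%s_seg.nii.gz", patient$id))
  write_mask(patient$labels, sp, p)
  paths["labels"] <- p
  invisible(paths)
}
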