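#' Patient-level train/validation/test split
#'
#' Shuffles patient ids with a fixed seed and assigns 70% to training,
#' 15% to validation and 15% to testing (round-half-up on the first two,
#' remainder to test). Splitting at patient level guarantees no slice of
#' one patient appears in two splits.
#'
#' @param ids character vector of at least 3 patient ids.
#' @param seed integer shuffle seed.
#' @return A `split_assignment`: lists `train`, `val`, `test`.
#' @export
split_patients <- function(ids, seed = 1L) {
  n <- length(ids)
  if (n < 3L) stop_rfs("need at least 3 patients to split, got %d", n)
  if (anyDuplicated(ids)) stop_rfs("patient ids must be unique")
  n_train <- floor(0.70 * n + 0.5)
  n_val <- floor(0.15 * n + 0.5)
  n_test <- n - n_train - n_val
  if (n_train < 1L || n_val < 1L || n_test < 1L)
    stop_rfs("split produced an empty partition (n = %d -> %d/%d/%d)",
             n, n_train, n_val, n_test)
  shuffled <- with_seed(as.integer(seed), sample(ids))
  structure(list(train = shuffled[seq_len(n_train)],
                 val = shuffled[n_train + seq_len(n_val)],
                 test = shuffled[n_train + n_val + seq_len(n_test)],
                 seed = as.integer(seed)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("patient split (seed %d): %d train / %d val / %d test\n",
              x$seed, length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

check_aligned <- function(volume, labels) {
  for (m in modality_names())
    if (!identical(dim(volume[[m]]), dim(volume$t1)))
      stop_rfs("modality grid mismatch: %s is %s but t1 is %s", m,
               paste(dim(volume[[m]]), collapse = "x"),
               paste(dim(volume$t1), collapse = "x"))
  v <- if (inherits(labels, "label_volume")) labels$values else labels
  if (!identical(dim(volume$t1), dim(v)))
    stop_rfs("label grid (%s) does not match modality grid (%s)",
             paste(dim(v), collapse = "x"), paste(dim(volume$t1), collapse = "x"))
  invisible(v)
}

slice_sample <- function(image, target_channels, approach, region,
                         patient_id, slice_index) {
  structure(list(image = image,
                 target = list(approach = approach, region = region,
                               channels = target_channels),
                 patient_id = patient_id, slice_index = slice_index),
            class = "slice_sample")
}

#' Collect 2D training samples (one per axial slice)
#'
#' Each axial slice yields an H x W x 4 image (the four modalities
#' concatenated as channels) and the matching target encoding slice. All
#' slices of the volume are collected.
#'
#' @param volume an [mm_volume()].
#' @param labels a [label_volume()] on the same grid.
#' @param approach,region target encoding, as in [encode_target()].
#' @param patient_id carried through to the samples.
#' @return List of `slice_sample` objects, one per axial slice.
#' @export
collect_2d <- function(volume, labels, approach = "multi_label",
                       region = NULL, patient_id = "") {
  check_aligned(volume, labels)
  d <- dim(volume$t1)
  if (d[3] < 1L) stop_rfs("volume has no axial slices")
  enc <- encode_target(labels, approach, region)
  nc <- dim(enc$channels)[4]
  lapply(seq_len(d[3]), function(z) {
    img <- array(0, c(d[1], d[2], 4L))
    for (k in seq_along(modality_names()))
      img[, , k] <- volume[[modality_names()[k]]][, , z]
    tgt <- array(enc$channels[, , z, ], c(d[1], d[2], nc))
    slice_sample(img, tgt, approach, region, patient_id, z)
  })
}

#' Collect 2.5D training samples (3-slice stacks per modality)
#'
#' For each axial slice N, every modality contributes the slice triplet
#' (N-1, N, N+1), giving 12 channels in modality-major order (T1 triplet,
#' T1ce triplet, T2 triplet, FLAIR triplet). At the first and last slice
#' the missing neighbor is an all-zero (fully black) slice.
#'
#' @inheritParams collect_2d
#' @return List of `slice_sample` objects with 12-channel images.
#' @export
collect_25d <- function(volume, labels, approach = "multi_label",
                        region = NULL, patient_id = "") {
  check_aligned(volume, labels)
  d <- dim(volume$t1)
  if (d[3] < 1L) stop_rfs("volume has no axial slices")
  enc <- encode_target(labels, approach, region)
  nc <- dim(enc$channels)[4]
  zero <- matrix(0, d[1], d[2])
  lapply(seq_len(d[3]), function(z) {
    img <- array(0, c(d[1], d[2], 12L))
    k <- 0L
    for (m in modality_names()) {
      for (dz in c(-1L, 0L, 1L)) {
        k <- k + 1L
        zs <- z + dz
        img[, , k] <- if (zs < 1L || zs > d[3]) zero else volume[[m]][, , zs]
      }
    }
    tgt <- array(enc$channels[, , z, ], c(d[1], d[2], nc))
    slice_sample(img, tgt, approach, region, patient_id, z)
  })
}

# Crop-or-pad a 3D array to `size`, centered at `center` (voxel coords).
crop_pad_3d <- function(a, size, center) {
  out <- array(0, size)
  start <- round(center - size / 2)          # 0-based start in source
  src_lo <- pmax(start + 1L, 1L)
  src_hi <- pmin(start + size, dim(a))
  dst_lo <- src_lo - start
  dst_hi <- dst_lo + (src_hi - src_lo)
  if (all(src_hi >= src_lo)) {
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      a[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  }
  out
}

#' Extract a 3D patch centered on the brain
#'
#' Crops a patch of `patch_size` centered on the brain-mask centroid,
#' zero-padding symmetrically where the volume is smaller than the patch.
#' Deterministic; a random-crop mode (jittered center) is available for
#' training.
#'
#' @inheritParams collect_2d
#' @param patch_size integer triple.
#' @param jitter optional maximum random shift (voxels) of the patch
#'   center per axis; 0 keeps the centroid placement.
#' @return List with `image` (H x W x D x 4 array), `target` (a
#'   [label_volume()] patch) and `center` (the patch center used).
#' @export
extract_3d_patch <- function(volume, labels, patch_size, jitter = 0,
                             patient_id = "") {
  v <- check_aligned(volume, labels)
  patch_size <- as.integer(patch_size)
  if (length(patch_size) != 3L || any(patch_size < 1L))
    stop_rfs("patch_size must be 3 positive integers")
  idx <- which(volume$mask, arr.ind = TRUE)
  center <- if (nrow(idx)) colMeans(idx) else dim(volume$t1) / 2
  if (jitter > 0) center <- center + runif(3, -jitter, jitter)
  img <- array(0, c(patch_size, 4L))
  for (k in seq_along(modality_names()))
    img[, , , k] <- crop_pad_3d(volume[[modality_names()[k]]], patch_size, center)
  tgt <- crop_pad_3d(v, patch_size, center)
  storage.mode(tgt) <- "integer"
  list(image = img, target = label_volume(tgt, labels$spacing %||% c(1, 1, 1)),
       center = center, patient_id = patient_id)
}

# Rotate a 2D plane about its center. Bilinear for images, nearest for masks.
rotate_plane <- function(m, angle_deg, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  h <- nrow(m); w <- ncol(m)
  th <- angle_deg * pi / 180
  cx <- (h + 1) / 2; cy <- (w + 1) / 2
  xo <- rep(seq_len(h), w) - cx
  yo <- rep(seq_len(w), each = h) - cy
  # inverse map: rotate output coords by -angle into the input frame
  xs <- cos(th) * xo + sin(th) * yo + cx
  ys <- -sin(th) * xo + cos(th) * yo + cy
  if (interp == "nearest") {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 1 & xi <= h & yi >= 1 & yi <= w
    out <- numeric(h * w)
    out[ok] <- m[cbind(xi[ok], yi[ok])]
    return(matrix(out, h, w))
  }
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  out <- numeric(h * w)
  for (dx in 0:1) for (dy in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy
    wgt <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy)
    ok <- xi >= 1 & xi <= h & yi >= 1 & yi <= w & wgt > 0
    if (any(ok))
      out[ok] <- out[ok] + wgt[ok] * m[cbind(xi[ok], yi[ok])]
  }
  matrix(out, h, w)
}

#' Augment a 2D slice sample
#'
#' Independent horizontal flip (p = 0.5), vertical flip (p = 0.5) and
#' rotation by an angle uniform in `[-max_angle, +max_angle]` degrees.
#' The same geometric transform is applied to image (bilinear) and target
#' (nearest neighbor, so encodings stay binary/one-hot). Deterministic
#' given `seed`.
#'
#' @param sample a `slice_sample`.
#' @param seed integer seed driving the three random draws.
#' @param max_angle rotation range in degrees.
#' @return The augmented `slice_sample`.
#' @export
augment <- function(sample, seed, max_angle = 15) {
  stopifnot(inherits(sample, "slice_sample"))
  with_seed(as.integer(seed), {
    hflip <- runif(1) < 0.5
    vflip <- runif(1) < 0.5
    angle <- runif(1, -max_angle, max_angle)
    img <- sample$image
    tgt <- sample$target$channels
    if (hflip) {
      img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
      tgt <- tgt[rev(seq_len(dim(tgt)[1])), , , drop = FALSE]
    }
    if (vflip) {
      img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
      tgt <- tgt[, rev(seq_len(dim(tgt)[2])), , drop = FALSE]
    }
    if (angle != 0) {
      for (k in seq_len(dim(img)[3]))
        img[, , k] <- rotate_plane(img[, , k], angle, "bilinear")
      for (k in seq_len(dim(tgt)[3]))
        tgt[, , k] <- rotate_plane(tgt[, , k], angle, "nearest")
      if (sample$target$approach == "multi_class") {
        # pixels rotated in from outside the grid are background
        tgt[, , 1] <- tgt[, , 1] + (rowSums(matrix(tgt, ncol = dim(tgt)[3])) == 0)
      }
    }
    out <- sample
    out$image <- img
    out$target$channels <- tgt
    out
  })
}
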