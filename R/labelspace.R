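#' Multi-modal MRI volume container
#'
#' Four co-registered single-modality 3D intensity arrays plus a brain mask
#' and voxel spacing. Modalities follow the fixed order T1, T1ce, T2, FLAIR.
#'
#' @param t1,t1ce,t2,flair 3D numeric arrays on a common grid.
#' @param mask logical 3D array; the brain (foreground) support.
#' @param spacing voxel spacing in mm per axis.
#' @return An object of class `mm_volume`.
#' @export
mm_volume <- function(t1, t1ce, t2, flair, mask = NULL, spacing = c(1, 1, 1)) {
  mods <- list(t1 = t1, t1ce = t1ce, t2 = t2, flair = flair)
  d <- dim(t1)
  if (length(d) != 3L) stop_rfs("modalities must be 3D arrays")
  for (m in names(mods))
    if (!identical(dim(mods[[m]]), d))
      stop_rfs("modality grid mismatch: %s is %s, expected %s", m,
               paste(dim(mods[[m]]), collapse = "x"), paste(d, collapse = "x"))
  if (is.null(mask))
    mask <- Reduce(`|`, lapply(mods, function(v) v != 0))
  if (!identical(dim(mask), d)) stop_rfs("mask grid mismatch")
  structure(c(mods, list(mask = mask, spacing = as.numeric(spacing))),
            class = "mm_volume")
}

modality_names <- function() c("t1", "t1ce", "t2", "flair")

#' @export
print.mm_volume <- function(x, ...) {
  cat(sprintf("mm_volume: %s grid, spacing %s mm, %d brain voxels%s\n",
              paste(dim(x$t1), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"), sum(x$mask),
              if (!is.null(attr(x, "normalization")))
                paste0(" [", attr(x, "normalization"), "-normalized]") else ""))
  invisible(x)
}

#' Ground-truth label volume with BraTS codes
#'
#' Integer 3D map over the non-overlapping codes 0 (background), 1 (NCR,
#' necrotic tumor), 2 (ED, peritumoral edema) and 4 (ET, enhancing tumor).
#'
#' @param values integer 3D array.
#' @param spacing voxel spacing in mm per axis.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(values, spacing = c(1, 1, 1)) {
  check_label_codes(values)
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "label_volume")
}

check_label_codes <- function(values) {
  bad <- setdiff(unique(as.vector(values)), c(0L, 1L, 2L, 4L))
  if (length(bad))
    stop_rfs("unknown label code(s): %s (allowed: 0, 1, 2, 4)",
             paste(sort(bad), collapse = ", "))
  invisible(TRUE)
}

#' Convert BraTS labels to the three overlapping evaluation regions
#'
#' ET is label 4; TC (tumor core) is labels 1 and 4; WT (whole tumor) is
#' labels 1, 2 and 4. The regions nest by construction: ET within TC
#' within WT.
#'
#' @param labels a [label_volume()] or an integer array of codes.
#' @return A `region_masks` object: logical arrays `et`, `tc`, `wt` plus
#'   `spacing`.
#' @export
labels_to_regions <- function(labels) {
  if (inherits(labels, "label_volume")) {
    v <- labels$values
    spacing <- labels$spacing
  } else {
    v <- labels
    spacing <- c(1, 1, 1)
  }
  check_label_codes(v)
  structure(list(et = v == 4L, tc = v == 1L | v == 4L,
                 wt = v == 1L | v == 2L | v == 4L, spacing = spacing),
            class = "region_masks")
}

#' Convert (possibly inconsistent) region masks back to BraTS labels
#'
#' The region hierarchy is enforced first (a predicted ET voxel forces TC,
#' a TC voxel forces WT), then codes are assigned outward: 4 where ET,
#' else 1 where TC, else 2 where WT, else 0. Keeping every predicted tumor
#' voxel is the conservative repair for networks whose sigmoid heads
#' disagree across regions.
#'
#' @param regions a `region_masks` object (or list with logical `et`, `tc`,
#'   `wt`).
#' @return A [label_volume()].
#' @export
regions_to_labels <- function(regions) {
  et <- regions$et
  tc <- regions$tc | et
  wt <- regions$wt | tc
  v <- array(0L, dim(et))
  v[wt] <- 2L
  v[tc] <- 1L
  v[et] <- 4L
  label_volume(v, regions$spacing %||% c(1, 1, 1))
}

region_names <- function() c("et", "tc", "wt")

#' Encode ground truth for one of the three segmentation approaches
#'
#' The multi-class approach uses mutually exclusive one-hot channels
#' (background, NCR, ED, ET); the multi-label approach stacks the three
#' overlapping region masks (ET, TC, WT); the binary approach carries the
#' single requested region.
#'
#' @param labels a [label_volume()] or integer code array.
#' @param approach `"multi_class"`, `"multi_label"` or `"binary"`.
#' @param region target region, required iff `approach = "binary"`.
#' @return A `target_encoding`: list with `approach`, `region` and
#'   `channels`, a numeric array whose last dimension indexes channels.
#' @export
encode_target <- function(labels, approach = c("multi_class", "multi_label",
                                               "binary"), region = NULL) {
  approach <- match.arg(approach)
  if (approach == "binary") {
    if (is.null(region)) stop_rfs("binary approach requires a target region")
    region <- match.arg(region, region_names())
  } else if (!is.null(region)) {
    stop_rfs("region must only be given for the binary approach")
  }
  v <- if (inherits(labels, "label_volume")) labels$values else labels
  check_label_codes(v)
  d <- dim(v)
  channels <- switch(approach,
    multi_class = {
      a <- array(0, c(d, 4L))
      codes <- c(0L, 1L, 2L, 4L)
      for (k in seq_along(codes)) {
        idx <- which(v == codes[k])
        a[idx + (k - 1L) * prod(d)] <- 1
      }
      dimnames(a) <- NULL
      a
    },
    multi_label = {
      r <- labels_to_regions(v)
      a <- array(0, c(d, 3L))
      a[ , , , 1] <- r$et
      a[ , , , 2] <- r$tc
      a[ , , , 3] <- r$wt
      a
    },
    binary = {
      r <- labels_to_regions(v)
      array(as.numeric(r[[region]]), c(d, 1L))
    })
  structure(list(approach = approach, region = region, channels = channels),
            class = "target_encoding")
}

#' Reduce a per-channel probability stack to one region's probability map
#'
#' Aligns heterogeneous candidate outputs on a single region so they can be
#' ensembled: a binary model passes its channel through, a multi-label
#' model contributes the region's channel, and a multi-class (softmax)
#' model contributes the sum of the class probabilities composing the
#' region (e.g. TC = p(NCR) + p(ET)).
#'
#' @param probs numeric array whose last dimension indexes channels
#'   (4 for multi_class: background, NCR, ED, ET; 3 for multi_label:
#'   ET, TC, WT; 1 for binary).
#' @param approach the approach that produced `probs`.
#' @param region target region (`"et"`, `"tc"` or `"wt"`).
#' @return A numeric array of per-voxel probabilities (channel dimension
#'   dropped).
#' @export
region_probability <- function(probs, approach = c("multi_class",
                                                   "multi_label", "binary"),
                               region = c("et", "tc", "wt")) {
  approach <- match.arg(approach)
  region <- match.arg(region)
  d <- dim(probs)
  nc <- d[length(d)]
  sdim <- d[-length(d)]
  m <- matrix(probs, ncol = nc)
  out <- switch(approach,
    binary = {
      if (nc != 1L) stop_rfs("binary stack must have 1 channel, got %d", nc)
      m[, 1]
    },
    multi_label = {
      if (nc != 3L) stop_rfs("multi_label stack must have 3 channels")
      m[, match(region, region_names())]
    },
    multi_class = {
      if (nc != 4L) stop_rfs("multi_class stack must have 4 channels")
      s <- rowSums(m)
      if (any(abs(s - 1) > 1e-3))
        stop_rfs("multi_class probabilities must sum to 1 per voxel (max |sum-1| = %.3g)",
                 max(abs(s - 1)))
      # channels: background, NCR(1), ED(2), ET(4)
      switch(region,
             et = m[, 4],
             tc = m[, 2] + m[, 4],
             wt = m[, 2] + m[, 3] + m[, 4])
    })
  if (length(sdim) > 1L) array(out, sdim) else out
}
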