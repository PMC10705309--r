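#' Z-score intensity normalization over a brain mask
#'
#' Standardizes a single-modality volume to zero mean and unit standard
#' deviation computed over the mask (skull-stripped foreground), then zeros
#' every voxel outside the mask. Invariant to positive affine changes of
#' the input intensities, which is what makes it a scanner harmonizer.
#'
#' @param volume 3D numeric array.
#' @param mask logical array of the same grid with at least 2 voxels.
#' @return Normalized array of the same dimensions.
#' @export
zscore_normalize <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask))) stop_rfs("volume/mask grid mismatch")
  fg <- volume[mask]
  if (length(fg) < 2L) stop_rfs("mask must contain at least 2 voxels")
  s <- stats::sd(fg)
  if (!is.finite(s) || s == 0)
    stop_rfs("degenerate input: zero intensity variance over the mask")
  out <- (volume - mean(fg)) / s
  out[!mask] <- 0
  out
}

default_nyul_ranks <- function() c(1, seq(10, 90, by = 10), 99)

# Bump ties so a landmark vector is strictly increasing.
strictly_increasing <- function(x) {
  eps <- 1e-8 * max(1, abs(diff(range(x))))
  for (i in seq_along(x)[-1]) if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + eps
  x
}

#' Train a Nyul piecewise-linear histogram standardization state
#'
#' For each training volume the foreground intensity percentiles at
#' `ranks` are computed and mapped affinely so that the first and last
#' landmark hit `standard_range`; the standard scale is the per-rank mean
#' of the mapped landmarks. The default ranks (1, 10, 20, ..., 90, 99) and
#' standard range (0, 100) follow the common configuration of the
#' normalization literature; both are configurable.
#'
#' @param volumes list of single-modality 3D arrays.
#' @param masks list of logical foreground masks, one per volume.
#' @param ranks strictly increasing percentile ranks in (0, 100).
#' @param standard_range numeric pair `(s_min, s_max)` of the standard
#'   intensity scale.
#' @return A `nyul_state`: `percentile_landmarks` (the ranks),
#'   `standard_scale_values` (strictly increasing) and `standard_range`.
#' @export
nyul_train <- function(volumes, masks, ranks = default_nyul_ranks(),
                       standard_range = c(0, 100)) {
  if (!length(volumes)) stop_rfs("need at least one training volume")
  if (length(masks) != length(volumes))
    stop_rfs("volumes and masks must have equal length")
  if (any(ranks <= 0) || any(ranks >= 100) || any(diff(ranks) <= 0))
    stop_rfs("ranks must be strictly increasing within (0, 100)")
  s_min <- standard_range[1]; s_max <- standard_range[2]
  if (s_max <= s_min) stop_rfs("standard_range must be increasing")
  mapped <- vapply(seq_along(volumes), function(i) {
    fg <- volumes[[i]][masks[[i]]]
    if (!length(fg)) stop_rfs("empty mask for training volume %d", i)
    q <- strictly_increasing(quantile(fg, ranks / 100, names = FALSE, type = 7))
    (q - q[1]) / (q[length(q)] - q[1]) * (s_max - s_min) + s_min
  }, numeric(length(ranks)))
  values <- strictly_increasing(rowMeans(matrix(mapped, nrow = length(ranks))))
  structure(list(percentile_landmarks = ranks,
                 standard_scale_values = values,
                 standard_range = c(s_min, s_max)),
            class = "nyul_state")
}

#' Apply Nyul histogram standardization to a volume
#'
#' Computes the volume's own foreground landmarks at the trained ranks and
#' maps them piecewise-linearly onto the standard scale values, with linear
#' interpolation between landmarks and linear extrapolation (outer-segment
#' slope) beyond the outermost landmarks; optionally the output can be
#' clipped to the standard range instead. The map is monotone
#' non-decreasing, landmark intensities map exactly to the standard values,
#' and background voxels are set to 0.
#'
#' @param volume 3D numeric array.
#' @param mask logical foreground mask.
#' @param state a [nyul_train()] result.
#' @param clip clip (rather than extrapolate) outside the outer landmarks.
#' @return Standardized array of the same dimensions.
#' @export
nyul_apply <- function(volume, mask, state, clip = FALSE) {
  stopifnot(inherits(state, "nyul_state"))
  if (!identical(dim(volume), dim(mask))) stop_rfs("volume/mask grid mismatch")
  fg <- volume[mask]
  if (!length(fg)) stop_rfs("empty mask")
  if (max(fg) == min(fg))
    stop_rfs("degenerate input: all foreground intensities are equal")
  land <- strictly_increasing(quantile(fg, state$percentile_landmarks / 100,
                                       names = FALSE, type = 7))
  val <- state$standard_scale_values
  seg <- findInterval(fg, land, all.inside = TRUE)
  slope <- diff(val) / diff(land)
  mapped <- val[seg] + (fg - land[seg]) * slope[seg]
  if (clip) mapped <- pmin(pmax(mapped, state$standard_range[1]),
                           state$standard_range[2])
  out <- array(0, dim(volume))
  out[mask] <- mapped
  out
}

#' Serialize / restore a Nyul state as JSON
#'
#' @param state a `nyul_state`.
#' @param path file path.
#' @return `write_nyul_state` returns `path` invisibly; `read_nyul_state`
#'   returns the restored `nyul_state`.
#' @export
write_nyul_state <- function(state, path) {
  jsonlite::write_json(unclass(state), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_nyul_state
#' @export
read_nyul_state <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(percentile_landmarks = as.numeric(x$percentile_landmarks),
                 standard_scale_values = as.numeric(x$standard_scale_values),
                 standard_range = as.numeric(x$standard_range)),
            class = "nyul_state")
}

#' Fit a cohort-level normalizer on training patients
#'
#' Z-score needs no training (it is per-volume); Nyul landmarks are fitted
#' per modality on the supplied patients only. The returned object records
#' which patient ids it was fitted on, so evaluation code can refuse
#' configurations where normalization leaked information from evaluation
#' patients.
#'
#' @param patients list of `phantom_patient` (or any objects with `$volume`
#'   an [mm_volume()] and `$id`).
#' @param method `"zscore"` or `"nyul"`.
#' @param ranks,standard_range passed to [nyul_train()].
#' @return An `mri_normalizer`.
#' @export
fit_normalizer <- function(patients, method = c("zscore", "nyul"),
                           ranks = default_nyul_ranks(),
                           standard_range = c(0, 100)) {
  method <- match.arg(method)
  ids <- vapply(patients, `[[`, "", "id")
  states <- NULL
  if (method == "nyul") {
    states <- lapply(modality_names(), function(m) {
      nyul_train(lapply(patients, function(p) p$volume[[m]]),
                 lapply(patients, function(p) p$volume$mask),
                 ranks = ranks, standard_range = standard_range)
    })
    names(states) <- modality_names()
  }
  structure(list(method = method, states = states, fitted_ids = ids),
            class = "mri_normalizer")
}

#' Apply a fitted normalizer to a multi-modal volume
#'
#' Each modality is normalized independently (per patient); the result is
#' tagged with the normalization method so downstream inference can verify
#' it matches the one a model was trained with.
#'
#' @param normalizer an [fit_normalizer()] result.
#' @param volume an [mm_volume()].
#' @return The normalized `mm_volume`.
#' @export
apply_normalizer <- function(normalizer, volume) {
  stopifnot(inherits(normalizer, "mri_normalizer"), inherits(volume, "mm_volume"))
  out <- volume
  for (m in modality_names()) {
    out[[m]] <- if (normalizer$method == "zscore") {
      zscore_normalize(volume[[m]], volume$mask)
    } else {
      nyul_apply(volume[[m]], volume$mask, normalizer$states[[m]])
    }
  }
  attr(out, "normalization") <- normalizer$method
  out
}
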