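#' Configuration for the synthetic multi-modal phantom generator
#'
#' The generator emulates skull-stripped, co-registered BraTS-style scans:
#' an ellipsoidal "brain" containing nested tumor compartments (an edema
#' shell, a tumor-core ellipsoid whose rim enhances and whose center is
#' necrotic), imaged in four modalities (T1, T1ce, T2, FLAIR) with
#' per-tissue mean contrast, a smooth multiplicative bias field, additive
#' Gaussian noise, and a per-patient affine scanner intensity effect
#' (gain and offset). Ground-truth labels use the BraTS codes
#' 0 (background/healthy), 1 (NCR), 2 (ED) and 4 (ET), so the derived
#' regions always nest: ET within TC within WT.
#'
#' Only the ordering constraints on `contrast_table` are structural: the
#' enhancing tumor must be brighter on T1ce than on T1, and edema (and the
#' other tumor tissues) brighter than healthy brain on FLAIR. The default
#' means are package fixtures chosen to give clearly separable but noisy
#' tissue classes.
#'
#' @param shape integer voxel grid, each dimension at least 16 and at most
#'   the BraTS matrix 240 x 240 x 155.
#' @param n_patients number of patients in a cohort.
#' @param tumor_volume_fraction_range range (in (0,1)) for the whole-tumor
#'   volume as a fraction of brain volume.
#' @param contrast_table 5 x 4 numeric matrix of per-tissue, per-modality
#'   mean intensities; rows `background`, `brain`, `ncr`, `ed`, `et`,
#'   columns `t1`, `t1ce`, `t2`, `flair`.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   intensity units.
#' @param bias_field_amplitude relative amplitude of the smooth
#'   multiplicative bias field (0 disables it).
#' @param scanner_gain_range,scanner_offset_range ranges of the per-patient
#'   multiplicative gain and additive offset emulating scanner differences.
#' @param n_scanners number of scanner tags patients are cycled through.
#' @param spacing voxel spacing in mm.
#' @param seed integer master seed; every patient is a deterministic
#'   function of `(seed, index)`.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64L, 64L, 32L),
                           n_patients = 10L,
                           tumor_volume_fraction_range = c(0.04, 0.12),
                           contrast_table = default_contrast_table(),
                           noise_sd = 4,
                           bias_field_amplitude = 0.1,
                           scanner_gain_range = c(0.8, 1.25),
                           scanner_offset_range = c(-10, 10),
                           n_scanners = 2L,
                           spacing = c(1, 1, 1),
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop_rfs("phantom shape must have 3 dimensions, each >= 16")
  if (any(shape > c(240L, 240L, 155L)))
    stop_rfs("phantom shape may not exceed 240 x 240 x 155")
  fr <- tumor_volume_fraction_range
  if (length(fr) != 2L || any(fr <= 0) || any(fr >= 1) || fr[1] > fr[2])
    stop_rfs("tumor_volume_fraction_range must be an increasing pair in (0,1)")
  if (noise_sd < 0) stop_rfs("noise_sd must be >= 0")
  ct <- contrast_table
  tissues <- c("background", "brain", "ncr", "ed", "et")
  mods <- c("t1", "t1ce", "t2", "flair")
  if (!all(tissues %in% rownames(ct)) || !all(mods %in% colnames(ct)))
    stop_rfs("contrast_table needs rows %s and columns %s",
             paste(tissues, collapse = ", "), paste(mods, collapse = ", "))
  if (ct["et", "t1ce"] <= ct["et", "t1"])
    stop_rfs("contrast_table must encode ET brighter on T1ce than on T1")
  if (ct["ed", "flair"] <= ct["brain", "flair"])
    stop_rfs("contrast_table must encode edema brighter than brain on FLAIR")
  structure(list(shape = shape, n_patients = as.integer(n_patients),
                 tumor_volume_fraction_range = fr,
                 contrast_table = ct[tissues, mods],
                 noise_sd = noise_sd,
                 bias_field_amplitude = bias_field_amplitude,
                 scanner_gain_range = scanner_gain_range,
                 scanner_offset_range = scanner_offset_range,
                 n_scanners = as.integer(n_scanners),
                 spacing = spacing, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Default per-tissue, per-modality mean intensities for phantoms
#'
#' ET is hyper-intense on T1ce relative to T1, and all tumor tissues
#' (most strongly edema) are hyper-intense on FLAIR relative to healthy
#' brain, mirroring the contrast that makes TC visible on T1ce and WT
#' visible on FLAIR in glioma imaging.
#' @return 5 x 4 numeric matrix.
#' @export
default_contrast_table <- function() {
  m <- rbind(background = c(0, 0, 0, 0),
             brain      = c(80, 80, 70, 60),
             ncr        = c(50, 45, 85, 75),
             ed         = c(70, 70, 95, 100),
             et         = c(75, 130, 90, 85))
  colnames(m) <- c("t1", "t1ce", "t2", "flair")
  m
}

# Voxel-center coordinates of an axis-aligned grid.
grid_coords <- function(shape) {
  list(x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3]))
}

# Logical array of voxels inside an axis-aligned ellipsoid.
ellipsoid_mask <- function(shape, center, radii) {
  g <- grid_coords(shape)
  dx2 <- ((g$x - center[1]) / radii[1])^2
  dy2 <- ((g$y - center[2]) / radii[2])^2
  dz2 <- ((g$z - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# Smooth random quadratic bias surface scaled to max |.| = 1.
bias_surface <- function(shape) {
  g <- grid_coords(shape)
  u <- (g$x - mean(g$x)) / (shape[1] / 2)
  v <- (g$y - mean(g$y)) / (shape[2] / 2)
  w <- (g$z - mean(g$z)) / (shape[3] / 2)
  cf <- rnorm(9)
  f <- outer(outer(cf[1] * u + cf[4] * u^2, cf[2] * v + cf[5] * v^2, `+`),
             cf[3] * w + cf[6] * w^2, `+`) +
    outer(outer(u, v, function(a, b) cf[7] * a * b), rep(1, shape[3])) +
    outer(outer(u, rep(1, shape[2])), w, function(a, b) cf[8] * a * b) +
    outer(outer(rep(1, shape[1]), v), w, function(a, b) cf[9] * a * b)
  f / max(abs(f), 1e-12)
}

#' Generate one synthetic phantom patient
#'
#' Deterministic in `(config$seed, index)`: the same pair always yields
#' bit-identical volumes and labels, independent of generation order.
#'
#' @param config a [phantom_config()].
#' @param index 1-based patient index, at most `config$n_patients`.
#' @return A `phantom_patient`: fields `volume` (a `mm_volume` with the four
#'   modality arrays, brain `mask` and `spacing`), `labels` (a
#'   [label_volume()]), `id` and `scanner_id`.
#' @export
generate_patient <- function(config, index) {
  stopifnot(inherits(config, "phantom_config"))
  index <- as.integer(index)
  if (index < 1L || index > config$n_patients)
    stop_rfs("index must be in 1..n_patients (%d)", config$n_patients)
  with_seed(derive_seed(config$seed, index), {
    shape <- config$shape
    brain_center <- shape / 2
    brain_radii <- 0.44 * shape
    brain <- ellipsoid_mask(shape, brain_center, brain_radii)
    brain_vol <- sum(brain)

    frac <- runif(1, config$tumor_volume_fraction_range[1],
                  config$tumor_volume_fraction_range[2])
    target_vol <- frac * brain_vol
    placed <- FALSE
    for (try in 1:25) {
      # tumor shaped like the brain (so the z margin scales with the thinner
      # axis), with a mild random anisotropy jitter of unit volume
      aniso <- runif(3, 0.85, 1.18)
      aniso <- aniso / prod(aniso)^(1 / 3)
      s <- (3 * target_vol / (4 * pi * prod(brain_radii)))^(1 / 3)
      wt_radii <- s * brain_radii * aniso
      margin <- brain_radii * 0.9 - wt_radii
      if (any(margin <= 1)) next
      off <- runif(3, -1, 1) * margin * 0.6
      center <- brain_center + off
      wt <- ellipsoid_mask(shape, center, wt_radii)
      if (all(wt[brain == FALSE] == FALSE)) { placed <- TRUE; break }
    }
    if (!placed)
      stop_rfs(paste0("tumor cannot fit inside the brain at volume fraction ",
                      "%.3f; reduce tumor_volume_fraction_range"), frac)

    tc_radii <- wt_radii * runif(3, 0.55, 0.7)
    ncr_radii <- tc_radii * runif(3, 0.45, 0.6)
    tc <- ellipsoid_mask(shape, center, tc_radii)
    ncr <- ellipsoid_mask(shape, center, ncr_radii)

    labels <- array(0L, shape)
    labels[wt] <- 2L            # edema shell
    labels[tc] <- 4L            # enhancing rim
    labels[ncr] <- 1L           # necrotic core
    labels[!brain] <- 0L

    tissue_idx <- array(1L, shape)          # background
    tissue_idx[brain] <- 2L                 # healthy brain
    tissue_idx[labels == 1L] <- 3L
    tissue_idx[labels == 2L] <- 4L
    tissue_idx[labels == 4L] <- 5L

    bias <- 1 + config$bias_field_amplitude * bias_surface(shape)
    gain <- runif(1, config$scanner_gain_range[1], config$scanner_gain_range[2])
    offset <- runif(1, config$scanner_offset_range[1],
                    config$scanner_offset_range[2])

    mods <- colnames(config$contrast_table)
    vols <- lapply(mods, function(m) {
      clean <- array(config$contrast_table[, m][tissue_idx], shape)
      v <- (clean * bias + rnorm(length(clean), sd = config$noise_sd)) *
        gain + offset
      v[!brain] <- 0
      v
    })
    names(vols) <- mods

    volume <- mm_volume(t1 = vols$t1, t1ce = vols$t1ce, t2 = vols$t2,
                        flair = vols$flair, mask = brain,
                        spacing = config$spacing)
    structure(list(volume = volume,
                   labels = label_volume(labels, config$spacing),
                   id = sprintf("phantom%03d", index),
                   scanner_id = sprintf("scanner%d",
                                        (index - 1L) %% config$n_scanners + 1L),
                   scanner_gain = gain, scanner_offset = offset),
              class = "phantom_patient")
  })
}

#' Generate a cohort of phantom patients
#'
#' @param config a [phantom_config()].
#' @return A `phantom_cohort`: a list with elements `patients` (list of
#'   `phantom_patient`) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$n_patients < 1L) stop_rfs("n_patients must be >= 1")
  patients <- lapply(seq_len(config$n_patients),
                     function(i) generate_patient(config, i))
  names(patients) <- vapply(patients, `[[`, "", "id")
  structure(list(patients = patients, config = config),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom cohort: %d patients, grid %s, %d scanner(s)\n",
              length(x$patients),
              paste(x$config$shape, collapse = "x"),
              length(unique(vapply(x$patients, `[[`, "", "scanner_id")))))
  invisible(x)
}

#' Patient identifiers of a cohort
#' @param cohort a `phantom_cohort` (or list with `$patients`).
#' @return Character vector of patient ids.
#' @export
cohort_ids <- function(cohort) vapply(cohort$patients, `[[`, "", "id")

#' Write a phantom cohort to disk in BraTS-style layout
#'
#' One directory per patient holding one compressed NIfTI file per modality
#' plus the label volume, and a cohort `manifest.csv` with patient id,
#' scanner id and file paths.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory, created if missing.
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$patients, function(p) {
    pdir <- file.path(dir, p$id)
    paths <- write_patient(p, pdir)
    cbind(data.frame(patient_id = p$id, scanner_id = p$scanner_id,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(paths), stringsAsFactors = FALSE))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
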