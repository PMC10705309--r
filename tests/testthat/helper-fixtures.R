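# Shared fixtures: everything is generated in code at test time.

# A small cohort for fast structural tests (16 axial slices, depth-2 nets).
tiny_cohort <- function(n = 6, seed = 11) {
  generate_cohort(phantom_config(shape = c(32, 32, 16), n_patients = n,
                                 seed = seed))
}

tiny_train_config <- function(epochs = 1, seed = 1, augment = FALSE) {
  train_config(epochs = epochs, batch_size = 8, learning_rate = 3e-3,
               seed = seed, augment = augment)
}

tiny_unet <- function(approach, variant = "2d") {
  approach_unet_config(approach, variant, depth = 2L, base_channels = 4L)
}

# Brute-force metric oracles: explicit loops/pairwise distances, no shared
# code with the implementation.
oracle_counts <- function(t, p) {
  tp <- sum(t & p); tn <- sum(!t & !p)
  list(tp = tp, tn = tn, nt = sum(t), np = sum(p), nneg = sum(!t))
}

oracle_dsc <- function(t, p) {
  o <- oracle_counts(t, p)
  if (o$nt + o$np == 0) 1 else 2 * o$tp / (o$nt + o$np)
}

oracle_sensitivity <- function(t, p) {
  o <- oracle_counts(t, p)
  if (o$nt == 0) NA_real_ else o$tp / o$nt
}

oracle_specificity <- function(t, p) {
  o <- oracle_counts(t, p)
  if (o$nneg == 0) NA_real_ else o$tn / o$nneg
}

oracle_hd95 <- function(t, p, spacing = c(1, 1, 1), percentile = 95) {
  if (sum(t) == 0 || sum(p) == 0) return(NA_real_)
  ct <- which(t, arr.ind = TRUE)
  cp <- which(p, arr.ind = TRUE)
  pair_min <- function(a, b) {
    # for each row of a, min distance to rows of b (explicit pairwise)
    vapply(seq_len(nrow(a)), function(i) {
      d2 <- (b[, 1] - a[i, 1])^2 * spacing[1]^2 +
        (b[, 2] - a[i, 2])^2 * spacing[2]^2 +
        (b[, 3] - a[i, 3])^2 * spacing[3]^2
      sqrt(min(d2))
    }, numeric(1))
  }
  max(quantile(pair_min(ct, cp), percentile / 100, names = FALSE, type = 7),
      quantile(pair_min(cp, ct), percentile / 100, names = FALSE, type = 7))
}

random_mask <- function(dim3, density = NULL) {
  if (is.null(density)) density <- runif(1, 0, 0.6)
  array(runif(prod(dim3)) < density, dim3)
}

# A real trained_candidate whose network emits a constant probability:
# the final 1x1 convolution is zeroed and its bias set to logit(p).
constant_candidate <- function(p_const, approach = "binary", region = "tc",
                               normalizer = NULL, variant = "2d") {
  cfg <- tiny_unet(approach, variant)
  net <- build_unet(cfg, seed = 1)
  net$params[["out.W"]][] <- 0
  net$params[["out.b"]][] <- if (cfg$head == "softmax") log(p_const)
                             else stats::qlogis(p_const)
  structure(list(network = net, config = cfg, approach = approach,
                 region = if (approach == "binary") region else NULL,
                 normalization_id = normalizer$method %||% "zscore",
                 normalizer = normalizer %||%
                   structure(list(method = "zscore", states = NULL,
                                  fitted_ids = character()),
                             class = "mri_normalizer"),
                 variant = variant, patch_size = NULL,
                 train_ids = character(),
                 training_log = data.frame(epoch = integer(),
                                           train_loss = numeric(),
                                           val_loss = numeric()),
                 seed = 1L),
            class = "trained_candidate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
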