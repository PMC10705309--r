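#' Training hyperparameters for one candidate network
#'
#' Defaults follow the 2D/2.5D training recipe (100 epochs, batch 16,
#' Adam with learning rate 1e-4); 3D training uses 150 epochs and batch 4.
#' `train_config_3d()` is a convenience wrapper with those defaults.
#'
#' @param epochs number of passes over the training slices (must be >= 1).
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed seed controlling initialization, shuffling and augmentation.
#' @param augment apply random flips/rotation to training slices
#'   (2D/2.5D only; the validation split is never augmented).
#' @param max_angle augmentation rotation range, degrees.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 16L,
                         learning_rate = 1e-4, seed = 1L, augment = TRUE,
                         max_angle = 15) {
  if (epochs < 1L) stop_rfs("epochs must be >= 1")
  if (batch_size < 1L) stop_rfs("batch_size must be >= 1")
  if (learning_rate <= 0) stop_rfs("learning_rate must be > 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 augment = isTRUE(augment), max_angle = max_angle),
            class = "train_config")
}

#' @rdname train_config
#' @export
train_config_3d <- function(epochs = 150L, batch_size = 4L,
                            learning_rate = 1e-4, seed = 1L,
                            augment = FALSE, max_angle = 15) {
  train_config(epochs, batch_size, learning_rate, seed, augment, max_angle)
}

variant_of <- function(unet_config) {
  if (unet_config$dims == 3L) "3d"
  else if (unet_config$in_channels == 12L) "25d" else "2d"
}

# Stack slice samples into (C, P, N) input and (K, P, N) target cubes.
stack_samples <- function(samples) {
  d <- dim(samples[[1]]$image)
  nc <- dim(samples[[1]]$target$channels)[3]
  N <- length(samples)
  x <- array(0, c(d[3], d[1] * d[2], N))
  y <- array(0, c(nc, d[1] * d[2], N))
  for (n in seq_len(N)) {
    x[, , n] <- t(matrix(samples[[n]]$image, ncol = d[3]))
    y[, , n] <- t(matrix(samples[[n]]$target$channels, ncol = nc))
  }
  list(x = x, y = y, sdims = d[1:2])
}

# Loss value and gradient w.r.t. logits for the approach's objective.
head_loss_grad <- function(probs, y, approach) {
  n_entries <- prod(dim(probs)[2:3])
  if (approach == "multi_class") {
    p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
    loss <- -sum(y * log(p)) / n_entries
    dlogits <- (probs - y) / n_entries
  } else {
    nc <- dim(probs)[1]
    p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
    loss <- -sum(y * log(p) + (1 - y) * log(1 - p)) / (n_entries * nc)
    dlogits <- (probs - y) / (n_entries * nc)
  }
  list(loss = loss, dlogits = dlogits)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),  # clones each shape exactly
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

collect_for_variant <- function(patient, variant, approach, region,
                                patch_size = NULL) {
  if (variant == "3d") {
    pt <- extract_3d_patch(patient$volume, patient$labels, patch_size,
                           patient_id = patient$id)
    enc <- encode_target(pt$target, approach, region)
    d <- dim(pt$image)
    list(list(image = pt$image,
              target = list(approach = approach, region = region,
                            channels = enc$channels),
              patient_id = patient$id, slice_index = NA_integer_))
  } else if (variant == "25d") {
    collect_25d(patient$volume, patient$labels, approach, region, patient$id)
  } else {
    collect_2d(patient$volume, patient$labels, approach, region, patient$id)
  }
}

# Stack 3D patch samples into cubes (flattening all spatial axes).
stack_samples_3d <- function(samples) {
  d <- dim(samples[[1]]$image)           # H x W x D x C
  nc <- dim(samples[[1]]$target$channels)[4]
  N <- length(samples)
  P <- prod(d[1:3])
  x <- array(0, c(d[4], P, N))
  y <- array(0, c(nc, P, N))
  for (n in seq_len(N)) {
    x[, , n] <- t(matrix(samples[[n]]$image, ncol = d[4]))
    y[, , n] <- t(matrix(samples[[n]]$target$channels, ncol = nc))
  }
  list(x = x, y = y, sdims = d[1:3])
}

#' Train one candidate network
#'
#' Trains a U-net for one (approach, normalization) cell of the candidate
#' grid on the training split of a cohort, minimizing the approach's loss
#' with Adam. The normalizer (Nyul landmarks, when used) is fitted on the
#' training split only, and the returned model carries it plus the ids it
#' was fitted on, so later evaluation can verify there was no leakage.
#' Per-epoch mean training loss and validation loss are logged.
#'
#' @param cohort a `phantom_cohort` (or list with `$patients`).
#' @param split a [split_patients()] assignment over the cohort ids.
#' @param approach `"multi_class"`, `"multi_label"` or `"binary"`.
#' @param normalization_id `"zscore"` or `"nyul"`.
#' @param unet_config a [unet_config()]; its dims/in_channels select the
#'   2D, 2.5D or 3D variant.
#' @param train_config a [train_config()].
#' @param region target region (required for the binary approach).
#' @param patch_size 3D patch size (3D variant only); defaults to the
#'   full (padded) volume.
#' @return A `trained_candidate`: the fitted network, its normalizer,
#'   identifiers and the per-epoch `training_log` data frame.
#' @export
train_candidate <- function(cohort, split, approach, normalization_id,
                            unet_config, train_config, region = NULL,
                            patch_size = NULL) {
  stopifnot(inherits(split, "split_assignment"),
            inherits(unet_config, "unet_config"),
            inherits(train_config, "train_config"))
  approach <- match.arg(approach, c("multi_class", "multi_label", "binary"))
  normalization_id <- match.arg(normalization_id, c("zscore", "nyul"))
  variant <- variant_of(unet_config)
  if (approach == "binary" && is.null(region))
    stop_rfs("binary approach requires a target region")
  enc_region <- if (approach == "binary") region else NULL

  patients <- cohort$patients
  train_p <- patients[split$train]
  val_p <- patients[split$val]
  if (!length(train_p)) stop_rfs("empty training split")

  normalizer <- fit_normalizer(train_p, normalization_id)
  norm_patient <- function(p) {
    p$volume <- apply_normalizer(normalizer, p$volume)
    p
  }
  if (variant == "3d" && is.null(patch_size)) {
    d <- dim(train_p[[1]]$volume$t1)
    patch_size <- as.integer(ceiling(d / 2^unet_config$depth) * 2^unet_config$depth)
  }
  gather <- function(plist) {
    samples <- unlist(lapply(plist, function(p)
      collect_for_variant(norm_patient(p), variant, approach, enc_region,
                          patch_size)), recursive = FALSE)
    if (variant == "3d") stack_samples_3d(samples) else stack_samples(samples)
  }
  tr <- gather(train_p)
  va <- if (length(val_p)) gather(val_p) else NULL

  net <- build_unet(unet_config, seed = train_config$seed)
  opt <- adam_init(net$params)
  N <- dim(tr$x)[3]
  bs <- min(train_config$batch_size, N)
  log_rows <- vector("list", train_config$epochs)
  do_augment <- train_config$augment && variant != "3d"

  for (epoch in seq_len(train_config$epochs)) {
    ord <- with_seed(derive_seed(train_config$seed, epoch, 1L), sample(N))
    ep_loss <- 0; ep_n <- 0L
    for (start in seq(1L, N, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, N)]
      xb <- tr$x[, , idx, drop = FALSE]
      yb <- tr$y[, , idx, drop = FALSE]
      if (do_augment) {
        for (k in seq_along(idx)) {
          sm <- slice_sample(array(t(xb[, , k]), c(tr$sdims, dim(xb)[1])),
                             array(t(yb[, , k]), c(tr$sdims, dim(yb)[1])),
                             approach, enc_region, "", 0L)
          sm <- augment(sm, derive_seed(train_config$seed, epoch,
                                        1000L + idx[k]),
                        train_config$max_angle)
          xb[, , k] <- t(matrix(sm$image, ncol = dim(xb)[1]))
          yb[, , k] <- t(matrix(sm$target$channels, ncol = dim(yb)[1]))
        }
      }
      fw <- unet_forward(net, xb, tr$sdims, training = TRUE)
      lg <- head_loss_grad(fw$probs, yb, approach)
      if (!is.finite(lg$loss))
        stop_rfs("non-finite training loss at epoch %d; aborting", epoch)
      grads <- unet_backward(net, fw$cache, lg$dlogits)
      step <- adam_step(net$params, grads, opt, train_config$learning_rate)
      net$params <- step$params
      opt <- step$opt
      for (nm in names(fw$bn_updates)) {
        u <- fw$bn_updates[[nm]]
        net$state[[paste0(nm, ".mean")]] <-
          (1 - bn_momentum) * net$state[[paste0(nm, ".mean")]] + bn_momentum * u$mean
        net$state[[paste0(nm, ".var")]] <-
          (1 - bn_momentum) * net$state[[paste0(nm, ".var")]] + bn_momentum * u$var
      }
      ep_loss <- ep_loss + lg$loss * length(idx)
      ep_n <- ep_n + length(idx)
    }
    val_loss <- NA_real_
    if (!is.null(va)) {
      fwv <- unet_forward(net, va$x, va$sdims, training = FALSE)
      val_loss <- head_loss_grad(fwv$probs, va$y, approach)$loss
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch,
                                    train_loss = ep_loss / ep_n,
                                    val_loss = val_loss)
  }

  structure(list(network = net, config = unet_config, approach = approach,
                 region = enc_region, normalization_id = normalization_id,
                 normalizer = normalizer, variant = variant,
                 patch_size = patch_size, train_ids = split$train,
                 training_log = do.call(rbind, log_rows),
                 seed = train_config$seed),
            class = "trained_candidate")
}

#' @export
print.trained_candidate <- function(x, ...) {
  tl <- x$training_log
  cat(sprintf("trained candidate %s/%s (%s): %d epochs, final train loss %.4f\n",
              x$normalization_id, x$approach, x$variant, nrow(tl),
              tl$train_loss[nrow(tl)]))
  invisible(x)
}

candidate_id <- function(model_or_row) {
  paste(model_or_row$normalization_id %||% model_or_row$normalization,
        model_or_row$approach, sep = "/")
}

#' Run a trained candidate over a full volume
#'
#' 2D/2.5D variants run slice-wise (all axial slices batched) and the
#' per-slice probabilities are reassembled into a volume; the 3D variant
#' runs on the brain-centered patch and probabilities are placed back on
#' the original grid (zero elsewhere). The volume must already be
#' normalized with the candidate's own normalization method; a mismatch is
#' an error so differently-normalized inputs cannot be mixed silently.
#'
#' @param model a `trained_candidate`.
#' @param volume an [mm_volume()] tagged by [apply_normalizer()].
#' @return Numeric array `(X, Y, Z, channels)` of probabilities.
#' @export
predict_volume <- function(model, volume) {
  stopifnot(inherits(model, "trained_candidate"), inherits(volume, "mm_volume"))
  tag <- attr(volume, "normalization")
  if (is.null(tag) || !identical(tag, model$normalization_id))
    stop_rfs("volume normalization ('%s') does not match the model's ('%s')",
             tag %||% "none", model$normalization_id)
  d <- dim(volume$t1)
  nc <- model$config$out_channels
  if (model$variant == "3d") {
    ps <- model$patch_size %||%
      as.integer(ceiling(d / 2^model$config$depth) * 2^model$config$depth)
    dummy <- label_volume(array(0L, d), volume$spacing)
    pt <- extract_3d_patch(volume, dummy, ps)
    x <- array(t(matrix(pt$image, ncol = 4L)), c(4L, prod(ps), 1L))
    fw <- unet_forward(model$network, x, ps, training = FALSE)
    probs_patch <- array(aperm(array(fw$probs, c(nc, ps)), c(2, 3, 4, 1)),
                         c(ps, nc))
    out <- array(0, c(d, nc))
    if (model$config$head == "softmax") out[, , , 1] <- 1  # background
    start <- round(pt$center - ps / 2)
    src_lo <- pmax(1L - start, 1L)
    src_hi <- pmin(d - start, ps)
    dst_lo <- start + src_lo
    dst_hi <- start + src_hi
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3], ] <-
      probs_patch[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2],
                  src_lo[3]:src_hi[3], , drop = FALSE]
    return(out)
  }
  nz <- d[3]
  cin <- model$config$in_channels
  x <- array(0, c(cin, d[1] * d[2], nz))
  for (z in seq_len(nz)) {
    if (model$variant == "25d") {
      k <- 0L
      for (m in modality_names()) for (dz in c(-1L, 0L, 1L)) {
        k <- k + 1L
        zs <- z + dz
        x[k, , z] <- if (zs < 1L || zs > nz) 0 else as.numeric(volume[[m]][, , zs])
      }
    } else {
      for (k in seq_along(modality_names()))
        x[k, , z] <- as.numeric(volume[[modality_names()[k]]][, , z])
    }
  }
  fw <- unet_forward(model$network, x, d[1:2], training = FALSE)
  aperm(array(fw$probs, c(nc, d[1], d[2], nz)), c(2, 3, 4, 1))
}

#' Score a candidate on held-out patients
#'
#' For each patient the candidate predicts a probability volume, the
#' target region's probability is extracted, thresholded at `threshold`,
#' and compared to the ground-truth region by Dice; the score is the mean
#' over patients. Patients whose ids the candidate's normalizer was
#' fitted on are refused (normalization leakage guard).
#'
#' @param model a `trained_candidate`.
#' @param patients list of patients (each with `$volume`, `$labels`, `$id`)
#'   disjoint from the training split.
#' @param region region to score (`"et"`, `"tc"`, `"wt"`).
#' @param threshold probability cut for mask decisions.
#' @return A `candidate_score` list: `approach`, `normalization_id`,
#'   `region`, mean `dsc` and the per-patient scores.
#' @export
evaluate_candidate <- function(model, patients, region = c("tc", "et", "wt"),
                               threshold = 0.5) {
  stopifnot(inherits(model, "trained_candidate"))
  region <- match.arg(region)
  if (!length(patients)) stop_rfs("empty patient list")
  ids <- vapply(patients, `[[`, "", "id")
  leaked <- intersect(ids, model$normalizer$fitted_ids)
  if (length(leaked))
    stop_rfs("normalization was fitted on evaluation patient(s): %s",
             paste(leaked, collapse = ", "))
  if (model$approach == "binary" && !identical(model$region, region))
    stop_rfs("binary candidate was trained for region '%s', not '%s'",
             model$region, region)
  per <- vapply(patients, function(p) {
    vol <- apply_normalizer(model$normalizer, p$volume)
    probs <- predict_volume(model, vol)
    pr <- region_probability(probs, model$approach, region)
    truth <- labels_to_regions(p$labels)[[region]]
    dsc(truth, pr >= threshold)
  }, numeric(1))
  structure(list(approach = model$approach,
                 normalization_id = model$normalization_id, region = region,
                 dsc = mean(per), per_patient = setNames(per, ids)),
            class = "candidate_score")
}
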