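grid_candidate_key <- function(approach, normalization) {
  paste(normalization, approach, sep = "/")
}

approach_order <- function() c("multi_class", "multi_label", "binary")
normalization_order <- function() c("zscore", "nyul")

#' Train and score the candidate grid
#'
#' One candidate per (approach x normalization) combination is trained on
#' the cohort's training split and scored by Dice on the internal test
#' split ("the unseen 15%") for each region it can predict; binary
#' candidates are trained for — and scored on — the target region only.
#' The default grid of three approaches by two normalizations yields six
#' candidates.
#'
#' @param cohort a `phantom_cohort` (or compatible list).
#' @param split a [split_patients()] assignment.
#' @param region target region driving binary training and selection.
#' @param approaches subset of `"multi_class"`, `"multi_label"`, `"binary"`.
#' @param normalizations subset of `"zscore"`, `"nyul"`.
#' @param unet_base list of arguments (depth, base_channels) shared by all
#'   candidates.
#' @param train_config a [train_config()].
#' @param variant `"2d"`, `"25d"` or `"3d"`.
#' @param threshold probability cut used when scoring.
#' @return A `candidate_grid`: `scores` (one row per candidate with et/tc/wt
#'   Dice, `NA` where a candidate does not predict a region) and `models`.
#' @export
run_grid <- function(cohort, split, region = "tc",
                     approaches = approach_order(),
                     normalizations = normalization_order(),
                     unet_base = list(depth = 4L, base_channels = 64L),
                     train_config = train_config(),
                     variant = "2d", threshold = 0.5) {
  approaches <- match.arg(approaches, approach_order(), several.ok = TRUE)
  normalizations <- match.arg(normalizations, normalization_order(),
                              several.ok = TRUE)
  if (!length(approaches) || !length(normalizations))
    stop_rfs("need at least one approach and one normalization")
  test_p <- cohort$patients[split$test]
  models <- list()
  rows <- list()
  for (norm in normalizations) {
    for (app in approaches) {
      key <- grid_candidate_key(app, norm)
      cfg <- approach_unet_config(app, variant,
                                  depth = unet_base$depth %||% 4L,
                                  base_channels = unet_base$base_channels %||% 64L)
      model <- tryCatch(
        train_candidate(cohort, split, app, norm, cfg, train_config,
                        region = if (app == "binary") region else NULL),
        error = function(e) stop_rfs("candidate %s failed: %s", key,
                                     conditionMessage(e)))
      models[[key]] <- model
      sc <- c(et = NA_real_, tc = NA_real_, wt = NA_real_)
      regs <- if (app == "binary") region else region_names()
      for (r in regs)
        sc[r] <- evaluate_candidate(model, test_p, r, threshold)$dsc
      rows[[key]] <- data.frame(approach = app, normalization = norm,
                                et = sc["et"], tc = sc["tc"], wt = sc["wt"],
                                stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  structure(list(scores = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 models = models, region = region, split = split),
            class = "candidate_grid")
}

#' Select the top three candidates for a region
#'
#' Orders candidates by descending Dice on the target region; ties are
#' broken by the fixed candidate ordering (approach: multi_class,
#' multi_label, binary; normalization: zscore, nyul) so selection is
#' independent of the order candidates were trained in.
#'
#' @param scores a data frame with columns `approach`, `normalization` and
#'   one Dice column per region (as produced by [run_grid()]), or a
#'   `candidate_grid`.
#' @param region region whose column drives the ranking.
#' @return The three top rows (highest first), with a `dsc` column.
#' @export
select_top3 <- function(scores, region = "tc") {
  if (inherits(scores, "candidate_grid")) scores <- scores$scores
  region <- match.arg(region, region_names())
  s <- scores[!is.na(scores[[region]]), , drop = FALSE]
  if (nrow(s) < 3L)
    stop_rfs("need at least 3 candidates with a %s score, got %d",
             region, nrow(s))
  ord <- order(-s[[region]],
               match(s$approach, approach_order()),
               match(s$normalization, normalization_order()))
  top <- s[ord[1:3], c("approach", "normalization", region)]
  names(top)[3] <- "dsc"
  rownames(top) <- NULL
  top
}

#' Dice-proportional ensemble weights
#'
#' Normalizes the three member scores to sum to one,
#' `w_i = DSC_i / sum_j DSC_j`, so better members vote more strongly;
#' weights are invariant to rescaling all scores. Equal weighting is
#' available for ablation via `equal = TRUE`.
#'
#' @param scores three positive Dice scores (fractions or percentages).
#' @param equal ignore the scores and return (1/3, 1/3, 1/3).
#' @return Three non-negative weights summing to 1.
#' @export
compute_weights <- function(scores, equal = FALSE) {
  if (length(scores) != 3L) stop_rfs("exactly 3 member scores required")
  if (equal) return(rep(1 / 3, 3))
  if (any(scores <= 0))
    stop_rfs("member scores must be > 0 (use equal = TRUE to force equal weights)")
  as.numeric(scores) / sum(scores)
}

#' Ensemble specification for one target region
#'
#' @param region target region.
#' @param members character vector of three distinct candidate ids
#'   (`"normalization/approach"`).
#' @param weights three non-negative weights summing to 1.
#' @param threshold probability cut for the ensembled map.
#' @return An `ensemble_spec`.
#' @export
ensemble_spec <- function(region, members, weights, threshold = 0.5) {
  region <- match.arg(region, region_names())
  if (length(members) != 3L || anyDuplicated(members))
    stop_rfs("members must be 3 distinct candidate ids")
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop_rfs("weights must be 3 non-negative values summing to 1")
  structure(list(region = region, members = as.character(members),
                 weights = as.numeric(weights), threshold = threshold),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("ensemble for %s (threshold %.2f):\n", toupper(x$region),
              x$threshold))
  for (i in 1:3)
    cat(sprintf("  %-22s weight %.5f\n", x$members[i], x$weights[i]))
  invisible(x)
}

#' Serialize / restore an ensemble specification as JSON
#' @param spec an [ensemble_spec()].
#' @param path file path.
#' @export
write_ensemble_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble_spec
#' @export
read_ensemble_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ensemble_spec(x$region, x$members, x$weights, x$threshold)
}

#' Weighted-probability ensemble prediction
#'
#' Each member normalizes the raw volume with its own normalizer, predicts,
#' and contributes its region probability; the ensembled map is the
#' weighted mean, thresholded into a binary region mask.
#'
#' @param spec an [ensemble_spec()].
#' @param models named list of `trained_candidate`s containing
#'   `spec$members`.
#' @param volume a raw (un-normalized) [mm_volume()].
#' @return List: `mask` (logical array) and `probability` (numeric array).
#' @export
ensemble_predict <- function(spec, models, volume) {
  stopifnot(inherits(spec, "ensemble_spec"))
  missing <- setdiff(spec$members, names(models))
  if (length(missing))
    stop_rfs("models missing for member(s): %s", paste(missing, collapse = ", "))
  acc <- NULL
  for (i in seq_along(spec$members)) {
    m <- models[[spec$members[i]]]
    vol <- apply_normalizer(m$normalizer, volume)
    pr <- region_probability(predict_volume(m, vol), m$approach, spec$region)
    acc <- if (is.null(acc)) spec$weights[i] * pr else acc + spec$weights[i] * pr
  }
  list(mask = acc >= spec$threshold, probability = acc)
}

#' Union (OR) combination of region masks
#'
#' The predecessor region-focused selection combiner: the voxelwise union
#' of the member masks, so the result is a superset of every member.
#'
#' @param masks list of binary arrays on a common grid.
#' @return Logical array.
#' @export
union_combine <- function(masks) {
  if (!length(masks)) stop_rfs("no masks given")
  d <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), d)) stop_rfs("mask grid mismatch in union_combine")
  Reduce(`|`, lapply(masks, function(m) m != 0))
}

#' Fit the RFS+ region-focused ensemble on a cohort
#'
#' The end-to-end strategy: split the cohort at patient level (70/15/15),
#' train the candidate grid on the training split, score every candidate
#' on the internal test split, keep the top three for the target region,
#' weight them proportionally to their Dice scores, and evaluate the
#' weighted-probability ensemble (and the union-of-masks combiner) on the
#' internal test patients.
#'
#' @param cohort a `phantom_cohort`, or any list of patients with
#'   `$volume`, `$labels`, `$id`.
#' @param region target region (`"tc"` — the TC/GTV focus — by default).
#' @param approaches,normalizations candidate grid axes.
#' @param unet_base shared architecture size, see [run_grid()].
#' @param train_config a [train_config()].
#' @param variant `"2d"`, `"25d"` or `"3d"`.
#' @param split_seed patient-shuffle seed.
#' @param threshold probability cut.
#' @param equal_weights use equal instead of Dice-proportional weights.
#' @param weight_source compute member weights from the internal test
#'   split scores (default) or refit on the training split scores.
#' @return An object of class `rfsplus`; see [print.rfsplus()],
#'   [summary.rfsplus()], [coef.rfsplus()], [predict.rfsplus()].
#' @export
rfsplus <- function(cohort, region = "tc",
                    approaches = approach_order(),
                    normalizations = normalization_order(),
                    unet_base = list(depth = 4L, base_channels = 64L),
                    train_config = train_config(),
                    variant = "2d", split_seed = 1L, threshold = 0.5,
                    equal_weights = FALSE,
                    weight_source = c("internal_test", "train")) {
  region <- match.arg(region, region_names())
  weight_source <- match.arg(weight_source)
  if (is.null(cohort$patients)) cohort <- list(patients = cohort)
  split <- split_patients(vapply(cohort$patients, `[[`, "", "id"), split_seed)
  grid <- run_grid(cohort, split, region, approaches, normalizations,
                   unet_base, train_config, variant, threshold)
  top <- select_top3(grid$scores, region)
  if (weight_source == "train") {
    train_scores <- vapply(seq_len(3), function(i) {
      key <- grid_candidate_key(top$approach[i], top$normalization[i])
      # score on validation patients (never trained on, never used for
      # selection) as the "training-side" weight source
      evaluate_candidate(grid$models[[key]], cohort$patients[split$val],
                         region, threshold)$dsc
    }, numeric(1))
    w <- compute_weights(train_scores, equal = equal_weights)
  } else {
    w <- compute_weights(top$dsc, equal = equal_weights)
  }
  members <- grid_candidate_key(top$approach, top$normalization)
  spec <- ensemble_spec(region, members, w, threshold)

  test_p <- cohort$patients[split$test]
  spacing <- test_p[[1]]$labels$spacing %||% c(1, 1, 1)
  per_patient <- lapply(test_p, function(p) {
    truth <- labels_to_regions(p$labels)[[region]]
    ens <- ensemble_predict(spec, grid$models, p$volume)
    member_masks <- lapply(spec$members, function(key) {
      m <- grid$models[[key]]
      vol <- apply_normalizer(m$normalizer, p$volume)
      region_probability(predict_volume(m, vol), m$approach, region) >= threshold
    })
    union_mask <- union_combine(member_masks)
    list(ensemble = evaluate_masks(truth, ens$mask, spacing),
         union = evaluate_masks(truth, union_mask, spacing),
         member_dsc = vapply(member_masks, function(mm) dsc(truth, mm),
                             numeric(1)))
  })
  mean_metric <- function(which, field)
    mean(vapply(per_patient, function(pp) pp[[which]][[field]], numeric(1)),
         na.rm = TRUE)
  metrics <- data.frame(
    combiner = c("ensemble", "union"),
    dsc = c(mean_metric("ensemble", "dsc"), mean_metric("union", "dsc")),
    hd95 = c(mean_metric("ensemble", "hd95"), mean_metric("union", "hd95")),
    sensitivity = c(mean_metric("ensemble", "sensitivity"),
                    mean_metric("union", "sensitivity")),
    specificity = c(mean_metric("ensemble", "specificity"),
                    mean_metric("union", "specificity")))
  member_dsc <- rowMeans(vapply(per_patient, `[[`, numeric(3), "member_dsc"))
  names(member_dsc) <- members

  structure(list(region = region, spec = spec, scores = grid$scores,
                 top3 = top, models = grid$models, split = split,
                 metrics = metrics, member_dsc = member_dsc,
                 per_patient = per_patient, threshold = threshold,
                 variant = variant),
            class = "rfsplus")
}

#' @rdname rfsplus
#' @export
rfsplus_run <- rfsplus

#' @export
print.rfsplus <- function(x, ...) {
  cat(sprintf("RFS+ ensemble for %s (%s U-net grid, %d candidates)\n",
              toupper(x$region), x$variant, nrow(x$scores)))
  print(x$spec)
  cat(sprintf("held-out %s Dice: ensemble %.4f, union %.4f, members %s\n",
              toupper(x$region), x$metrics$dsc[1], x$metrics$dsc[2],
              paste(sprintf("%.4f", x$member_dsc), collapse = ", ")))
  invisible(x)
}

#' Summarize an RFS+ fit
#'
#' Prints the full candidate score table (rows = approach x normalization,
#' columns = regions), the selected members with their weights, and the
#' held-out metrics of the ensemble and union combiners.
#'
#' @param object an [rfsplus()] fit.
#' @param ... unused.
#' @export
summary.rfsplus <- function(object, ...) {
  structure(list(region = object$region, scores = object$scores,
                 top3 = object$top3, weights = object$spec$weights,
                 metrics = object$metrics, split = object$split),
            class = "summary.rfsplus")
}

#' @export
print.summary.rfsplus <- function(x, ...) {
  cat(sprintf("RFS+ summary — target region %s\n", toupper(x$region)))
  print(x$split)
  cat("\nCandidate grid (internal-test Dice):\n")
  print(x$scores, digits = 4)
  cat("\nSelected members:\n")
  sel <- x$top3
  sel$weight <- x$weights
  print(sel, digits = 5)
  cat("\nHeld-out metrics:\n")
  print(x$metrics, digits = 4)
  invisible(x)
}

#' @export
coef.rfsplus <- function(object, ...) {
  setNames(object$spec$weights, object$spec$members)
}

#' Predict a region mask for a new patient
#'
#' @param object an [rfsplus()] fit.
#' @param newdata an [mm_volume()] (raw intensities) or a patient list
#'   with `$volume`.
#' @param type `"mask"` for the thresholded ensemble mask, `"prob"` for
#'   the weighted probability map.
#' @param ... unused.
#' @export
predict.rfsplus <- function(object, newdata, type = c("mask", "prob"), ...) {
  type <- match.arg(type)
  vol <- if (inherits(newdata, "mm_volume")) newdata else newdata$volume
  out <- ensemble_predict(object$spec, object$models, vol)
  if (type == "mask") out$mask else out$probability
}

#' Plot a mid-tumor slice of an RFS+ prediction
#'
#' Shows the T1ce slice with the ground-truth (if given) and predicted
#' region boundaries overlaid.
#'
#' @param x an [rfsplus()] fit.
#' @param patient a patient list with `$volume` (and optionally `$labels`).
#' @param slice axial slice index; defaults to the slice with the most
#'   predicted tumor.
#' @param ... passed to [graphics::image()].
#' @export
plot.rfsplus <- function(x, patient, slice = NULL, ...) {
  mask <- predict(x, patient)
  if (is.null(slice)) {
    per_slice <- apply(mask, 3, sum)
    slice <- which.max(per_slice)
  }
  bg <- patient$volume$t1ce[, , slice]
  graphics::image(bg, col = grDevices::gray.colors(64), axes = FALSE,
                  main = sprintf("%s prediction, slice %d", toupper(x$region),
                                 slice), ...)
  add_contour <- function(m, col) {
    if (any(m)) graphics::contour(seq(0, 1, length.out = nrow(m)),
                                  seq(0, 1, length.out = ncol(m)),
                                  m + 0, levels = 0.5, add = TRUE, col = col,
                                  drawlabels = FALSE, lwd = 2)
  }
  if (!is.null(patient$labels))
    add_contour(labels_to_regions(patient$labels)[[x$region]], "green")
  add_contour(mask[, , slice], "red")
  invisible(x)
}
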