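# The six 2D U-net candidates' TC Dice scores (percent) from the published
# approach x normalization comparison, used as a worked selection example.
published_tc_scores <- function() {
  data.frame(
    approach = rep(c("multi_class", "multi_label", "binary"), 2),
    normalization = rep(c("nyul", "zscore"), each = 3),
    et = c(79.44, 83.52, 84.21, 84.99, 82.29, 85.19),
    tc = c(79.53, 88.78, 89.42, 89.71, 87.27, 89.48),
    wt = c(88.98, 92.05, 90.30, 91.65, 92.24, 92.18),
    stringsAsFactors = FALSE)
}

test_that("select_top3 reproduces the published TC selection", {
  top <- select_top3(published_tc_scores(), "tc")
  expect_equal(paste(top$normalization, top$approach, sep = "/"),
               c("zscore/multi_class", "zscore/binary", "nyul/binary"))
  expect_equal(top$dsc, c(89.71, 89.48, 89.42))
})

test_that("selection ties break by the fixed candidate ordering", {
  s <- published_tc_scores()
  s$tc <- 88
  top <- select_top3(s, "tc")
  expect_equal(top$approach, c("multi_class", "multi_class", "multi_label"))
  expect_equal(top$normalization, c("zscore", "nyul", "zscore"))
  expect_error(select_top3(s[1:2, ], "tc"), "at least 3")
  # exactly three candidates are returned sorted
  three <- s[1:3, ]; three$tc <- c(50, 70, 60)
  expect_equal(select_top3(three, "tc")$dsc, c(70, 60, 50))
})

test_that("selection is invariant to candidate training order", {
  s <- published_tc_scores()
  perm <- s[c(4, 2, 6, 1, 5, 3), ]
  expect_equal(select_top3(perm, "tc"), select_top3(s, "tc"))
})

test_that("weights are dice-proportional, normalized and scale-invariant", {
  expect_equal(compute_weights(c(5, 5, 5)), rep(1 / 3, 3))
  w <- compute_weights(c(89.71, 89.48, 89.42))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w, c(0.33398, 0.33312, 0.33290), tolerance = 1e-4)
  expect_equal(compute_weights(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(compute_weights(c(10, 10, 20)), compute_weights(c(1, 1, 2)))
  expect_error(compute_weights(c(0, 1, 1)), "> 0")
  expect_equal(compute_weights(c(0.5, 1, 1), equal = TRUE), rep(1 / 3, 3))
})

test_that("ensemble specs enforce their invariants and round-trip as JSON", {
  expect_error(ensemble_spec("tc", c("a", "a", "b"), rep(1 / 3, 3)),
               "distinct")
  expect_error(ensemble_spec("tc", c("a", "b", "c"), c(0.5, 0.4, 0.2)),
               "summing to 1")
  sp <- ensemble_spec("tc", c("zscore/multi_class", "zscore/binary",
                              "nyul/binary"),
                      compute_weights(c(89.71, 89.48, 89.42)))
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble_spec(sp, path)
  sp2 <- read_ensemble_spec(path)
  expect_equal(sp$weights, sp2$weights, tolerance = 1e-12)
  expect_identical(sp$members, sp2$members)
})

test_that("weighted ensembling reduces to members in degenerate cases", {
  cohort <- tiny_cohort(4, seed = 41)
  vol <- cohort$patients[[4]]$volume
  norm <- structure(list(method = "zscore", states = NULL,
                         fitted_ids = character()),
                    class = "mri_normalizer")
  models <- list(
    "zscore/binary" = constant_candidate(0.9, normalizer = norm),
    "zscore/multi_label" = constant_candidate(0.2, approach = "multi_label",
                                              normalizer = norm),
    "nyul/binary" = constant_candidate(0.2, normalizer = fit_normalizer(
      cohort$patients[1:2], "nyul")))
  members <- names(models)
  # weight 1 on the first member reproduces its thresholded mask exactly
  sp1 <- ensemble_spec("tc", members, c(1, 0, 0))
  out1 <- ensemble_predict(sp1, models, vol)
  expect_true(all(out1$mask))                     # p = 0.9 everywhere
  expect_equal(max(abs(out1$probability - 0.9)), 0, tolerance = 1e-9)
  # identical members agree with any single member
  same <- list("zscore/binary" = models[[1]],
               "m2" = constant_candidate(0.9, normalizer = norm),
               "m3" = constant_candidate(0.9, normalizer = norm))
  spsame <- ensemble_spec("tc", names(same), rep(1 / 3, 3))
  expect_equal(ensemble_predict(spsame, same, vol)$mask, out1$mask)
  # (0.9, 0.2, 0.2) at equal weights averages to 0.4333 -> background
  speq <- ensemble_spec("tc", members, rep(1 / 3, 3))
  outeq <- ensemble_predict(speq, models, vol)
  expect_equal(max(abs(outeq$probability - 1.3 / 3)), 0, tolerance = 1e-6)
  expect_false(any(outeq$mask))
  expect_error(ensemble_predict(sp1, models[1:2], vol), "missing")
})

test_that("union combination is a superset OR of its inputs", {
  d <- c(6, 6, 2)
  set.seed(9)
  a <- random_mask(d, 0.2); b <- random_mask(d, 0.2); c_ <- random_mask(d, 0.2)
  u <- union_combine(list(a, b, c_))
  expect_true(all(u[a])); expect_true(all(u[b])); expect_true(all(u[c_]))
  expect_identical(union_combine(list(a, a, a)), a)
  # disjoint masks add up
  x <- array(FALSE, d); y <- array(FALSE, d); z <- array(FALSE, d)
  x[1] <- TRUE; y[2] <- TRUE; z[3] <- TRUE
  expect_equal(sum(union_combine(list(x, y, z))), 3)
  expect_error(union_combine(list(a, b[, , 1, drop = FALSE])), "mismatch")
})

test_that("thresholded-member ensembles stay inside the union", {
  # when member probabilities are already 0/1 masks and the threshold is
  # positive, the weighted ensemble cannot mark a voxel no member marked
  set.seed(10)
  d <- c(5, 5, 2)
  masks <- lapply(1:3, function(i) random_mask(d, 0.3))
  w <- compute_weights(c(2, 1, 1))
  p <- w[1] * masks[[1]] + w[2] * masks[[2]] + w[3] * masks[[3]]
  ens <- p >= 0.5
  expect_true(all(union_combine(masks)[ens]))
})
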