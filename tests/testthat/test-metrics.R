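test_that("losses match their closed forms", {
  # multi-class CE: certain prediction, uniform prediction, half-confidence
  y4 <- array(c(0, 0, 0, 1), c(1, 1, 4))
  p_sure <- array(c(1e-9, 1e-9, 1e-9, 1), c(1, 1, 4))
  expect_lt(multiclass_cross_entropy(p_sure, y4), 1e-6)
  p_unif <- array(0.25, c(1, 1, 4))
  expect_equal(multiclass_cross_entropy(p_unif, y4), log(4), tolerance = 1e-6)
  p_half <- array(c(0.3, 0.1, 0.1, 0.5), c(1, 1, 4))
  expect_equal(multiclass_cross_entropy(p_half, y4), -log(0.5),
               tolerance = 1e-6)
  expect_error(multiclass_cross_entropy(p_unif,
                                        array(c(1, 1, 0, 0), c(1, 1, 4))),
               "one-hot")
  # binary CE
  expect_equal(binary_cross_entropy(1, 1), 0, tolerance = 1e-6)
  expect_equal(binary_cross_entropy(0.5, 0), -log(0.5), tolerance = 1e-6)
  expect_equal(binary_cross_entropy(0.25, 1), log(4), tolerance = 1e-6)
  # multilabel average of per-region BCEs
  p3 <- array(c(exp(-0.1), exp(-0.2), exp(-0.3)), c(1, 1, 3))
  y3 <- array(1, c(1, 1, 3))
  expect_equal(multilabel_loss(p3, y3), 0.2, tolerance = 1e-6)
  expect_equal(multilabel_loss(y3, y3), 0, tolerance = 1e-6)
  p_one <- array(c(0.5, 1, 1), c(1, 1, 3))
  expect_equal(multilabel_loss(p_one, y3), -log(0.5) / 3, tolerance = 1e-4)
  expect_error(multilabel_loss(array(0.5, c(1, 1, 2)),
                               array(1, c(1, 1, 2))), "3 region")
})

test_that("multilabel loss reduces to binary CE on identical channels", {
  set.seed(8)
  p <- matrix(runif(50), 50, 1)
  y <- matrix(rbinom(50, 1, 0.5), 50, 1)
  p3 <- array(cbind(p, p, p), c(50, 1, 3))
  y3 <- array(cbind(y, y, y), c(50, 1, 3))
  expect_equal(multilabel_loss(p3, y3), binary_cross_entropy(p, y),
               tolerance = 1e-12)
})

test_that("overlap metrics follow their definitions and conventions", {
  d <- c(3, 3, 1)
  empty <- array(FALSE, d)
  expect_equal(dsc(empty, empty), 1)        # both-empty convention
  t1 <- array(FALSE, d); t1[1:4] <- TRUE
  expect_equal(dsc(t1, t1), 1)
  p1 <- array(FALSE, d); p1[3:6] <- TRUE    # |T|=4, |P|=4, overlap 2
  expect_equal(dsc(t1, p1), 0.5)
  expect_equal(sensitivity(t1, t1), 1)
  expect_equal(sensitivity(t1, empty), 0)
  expect_equal(sensitivity(t1, p1), 0.5)
  expect_true(is.na(sensitivity(empty, p1)))
  full <- array(TRUE, d)
  expect_equal(specificity(t1, t1), 1)
  expect_equal(specificity(t1, full), 0)    # nothing predicted negative
  expect_true(is.na(specificity(full, t1)))
  # 4x4 grid: 12 true negatives, 9 of them predicted negative
  t2 <- array(FALSE, c(4, 4, 1)); t2[1:4] <- TRUE
  p2 <- array(FALSE, c(4, 4, 1)); p2[5:7] <- TRUE
  expect_equal(specificity(t2, p2), 0.75)
})

test_that("hd95 handles point, shift and degenerate cases", {
  d <- c(8, 8, 1)
  a <- array(FALSE, d); a[2, 2, 1] <- TRUE
  b <- array(FALSE, d); b[5, 2, 1] <- TRUE       # 3 voxels along one axis
  expect_equal(hd95(a, b), 3)
  expect_equal(hd95(a, a), 0)
  expect_true(is.na(hd95(a, array(FALSE, d))))
  expect_true(is.na(hd95(array(FALSE, d), b)))
  # 20 isolated collinear voxels, each shifted by 1: every directed
  # distance is exactly 1, so any percentile is 1
  t <- array(FALSE, c(64, 4, 1)); t[seq(2, 59, by = 3), 2, 1] <- TRUE
  p <- array(FALSE, c(64, 4, 1)); p[seq(3, 60, by = 3), 2, 1] <- TRUE
  expect_equal(sum(t), 20)
  expect_equal(hd95(t, p), 1)
  # physical spacing scales distances
  expect_equal(hd95(a, b, spacing = c(2, 1, 1)), 6)
})

test_that("metrics agree with brute-force oracles on random mask pairs", {
  set.seed(123)
  n_cases <- 220
  for (case in seq_len(n_cases)) {
    d <- c(sample(2:8, 1), sample(2:8, 1), sample(2:8, 1))
    sp <- if (case %% 4 == 0) runif(3, 0.5, 3) else c(1, 1, 1)
    t <- random_mask(d)
    p <- random_mask(d)
    expect_identical(dsc(t, p), oracle_dsc(t, p))
    expect_identical(sensitivity(t, p), oracle_sensitivity(t, p))
    expect_identical(specificity(t, p), oracle_specificity(t, p))
    h <- hd95(t, p, sp)
    ho <- oracle_hd95(t, p, sp)
    if (is.na(ho)) expect_true(is.na(h)) else expect_equal(h, ho,
                                                           tolerance = 1e-9)
  }
})

test_that("dsc and hd95 are symmetric", {
  set.seed(5)
  for (i in 1:20) {
    d <- c(6, 6, 4)
    t <- random_mask(d, 0.3); p <- random_mask(d, 0.3)
    expect_identical(dsc(t, p), dsc(p, t))
    if (sum(t) && sum(p)) expect_equal(hd95(t, p), hd95(p, t),
                                       tolerance = 1e-12)
  }
})

test_that("the pooled hd95 variant percentiles the pooled distance set", {
  d <- c(8, 8, 2)
  set.seed(6)
  t <- random_mask(d, 0.3); p <- random_mask(d, 0.3)
  pooled <- hd95(t, p, method = "pooled")
  expect_true(pooled <= hd95(t, p, percentile = 100))
})

test_that("metric_table reports one row per patient and region", {
  cohort <- tiny_cohort(2)
  truths <- lapply(cohort$patients, function(p) labels_to_regions(p$labels))
  tab <- metric_table(truths, truths, ids = cohort_ids(cohort))
  expect_equal(nrow(tab), 2 * 3)
  expect_true(all(tab$dsc == 1))
  expect_true(all(tab$hd95 == 0))
})
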