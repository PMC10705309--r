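make_vol <- function(seed = 1, d = c(12, 12, 6)) {
  set.seed(seed)
  list(v = array(rnorm(prod(d), mean = 50, sd = 12), d),
       m = array(runif(prod(d)) < 0.7, d))
}

test_that("z-score gives exact moments and zero background", {
  f <- make_vol(1)
  out <- zscore_normalize(f$v, f$m)
  expect_lt(abs(mean(out[f$m])), 1e-6)
  expect_lt(abs(stats::sd(out[f$m]) - 1), 1e-6)
  expect_true(all(out[!f$m] == 0))
})

test_that("z-score is invariant to positive affine intensity changes", {
  f <- make_vol(2)
  out1 <- zscore_normalize(f$v, f$m)
  out2 <- zscore_normalize(3.7 * f$v + 42, f$m)
  expect_equal(out1, out2, tolerance = 1e-12)
})

test_that("degenerate z-score inputs error", {
  d <- c(8, 8, 4)
  m <- array(TRUE, d)
  expect_error(zscore_normalize(array(5, d), m), "variance")
  m1 <- array(FALSE, d); m1[1] <- TRUE
  expect_error(zscore_normalize(array(rnorm(prod(d)), d), m1), "2 voxels")
})

test_that("nyul training maps a single volume's landmarks onto the range", {
  f <- make_vol(3)
  ranks <- c(1, 25, 50, 75, 99)
  st <- nyul_train(list(f$v), list(f$m), ranks, c(0, 100))
  q <- quantile(f$v[f$m], ranks / 100, names = FALSE, type = 7)
  expected <- (q - q[1]) / (q[length(q)] - q[1]) * 100
  expect_equal(st$standard_scale_values, expected, tolerance = 1e-9)
  # two identical volumes give the same state as one
  st2 <- nyul_train(list(f$v, f$v), list(f$m, f$m), ranks, c(0, 100))
  expect_equal(st2$standard_scale_values, st$standard_scale_values)
  # strictly increasing even with heavily tied input
  tied <- array(rep(c(1, 1, 1, 2), length.out = prod(dim(f$v))), dim(f$v))
  st3 <- nyul_train(list(tied), list(f$m))
  expect_true(all(diff(st3$standard_scale_values) > 0))
})

test_that("nyul application is landmark-exact and monotone", {
  g <- make_vol(5)
  # 101 foreground voxels make every default rank an exact order statistic,
  # so the volume's landmark intensities are actual voxel values
  set.seed(44)
  v <- array(sort(rnorm(101, 60, 15)), c(101, 1, 1))
  m <- array(TRUE, c(101, 1, 1))
  st <- nyul_train(list(g$v, v), list(g$m, m))
  out <- nyul_apply(v, m, st)
  land <- quantile(v[m], st$percentile_landmarks / 100, names = FALSE,
                   type = 7)
  for (k in seq_along(land)) {
    hit <- which(v == land[k])
    expect_gt(length(hit), 0)
    expect_equal(out[hit][1], st$standard_scale_values[k], tolerance = 1e-9)
  }
  # monotone over all voxel pairs, on a generic volume
  f <- make_vol(4)
  st2 <- nyul_train(list(f$v, g$v), list(f$m, g$m))
  o2 <- nyul_apply(f$v, f$m, st2)
  ord <- order(f$v[f$m])
  expect_true(all(diff(o2[f$m][ord]) >= -1e-12))
  expect_true(all(o2[!f$m] == 0))
  expect_error(nyul_apply(array(1, dim(f$v)), f$m, st2), "degenerate")
})

test_that("nyul aligns affinely perturbed scanners at the landmarks", {
  cfg <- phantom_config(shape = c(32, 32, 16), n_patients = 4, seed = 21,
                        scanner_gain_range = c(0.7, 1.4),
                        scanner_offset_range = c(-25, 25))
  cohort <- generate_cohort(cfg)
  base <- cohort$patients[[1]]$volume
  # same patient geometry under two different affine scanner effects
  v1 <- 1.3 * base$flair + 15
  v2 <- 0.8 * base$flair - 5
  st <- nyul_train(list(v1, v2), list(base$mask, base$mask))
  o1 <- nyul_apply(v1, base$mask, st)
  o2 <- nyul_apply(v2, base$mask, st)
  l1 <- quantile(o1[base$mask], st$percentile_landmarks / 100,
                 names = FALSE, type = 7)
  l2 <- quantile(o2[base$mask], st$percentile_landmarks / 100,
                 names = FALSE, type = 7)
  expect_equal(l1, l2, tolerance = 1e-6)
})

test_that("nyul state round-trips through JSON", {
  f <- make_vol(6)
  st <- nyul_train(list(f$v), list(f$m))
  path <- withr::local_tempfile(fileext = ".json")
  write_nyul_state(st, path)
  st2 <- read_nyul_state(path)
  expect_equal(st, st2, tolerance = 1e-12)
})

test_that("normalizers tag volumes and record fitted patients", {
  cohort <- tiny_cohort(4)
  norm <- fit_normalizer(cohort$patients[1:2], "nyul")
  expect_setequal(unname(norm$fitted_ids), unname(cohort_ids(cohort)[1:2]))
  v <- apply_normalizer(norm, cohort$patients[[3]]$volume)
  expect_identical(attr(v, "normalization"), "nyul")
  z <- apply_normalizer(fit_normalizer(cohort$patients[1:2], "zscore"),
                        cohort$patients[[3]]$volume)
  expect_lt(abs(mean(z$t2[z$mask])), 1e-8)
})
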