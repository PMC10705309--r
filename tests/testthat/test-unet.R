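test_that("the default 2D configuration reproduces the canonical widths", {
  cfg <- approach_unet_config("multi_class", "2d")
  w <- rfsplus:::unet_widths(cfg)
  expect_equal(w$enc, c(64, 128, 256, 512))
  expect_equal(w$bottleneck, 1024)
  expect_equal(cfg$head, "softmax")
  expect_equal(cfg$out_channels, 4L)
  cfg25 <- approach_unet_config("multi_label", "25d")
  expect_equal(cfg25$in_channels, 12L)
  expect_equal(cfg25$head, "sigmoid")
  expect_equal(approach_unet_config("binary", "3d")$dims, 3L)
})

test_that("heads give exclusive (softmax) or independent (sigmoid) outputs", {
  cfg <- unet_config(dims = 2, in_channels = 3, out_channels = 4, depth = 2,
                     base_channels = 4, head = "softmax")
  net <- build_unet(cfg, seed = 2)
  x <- array(rnorm(3 * 16 * 16 * 2), c(3, 256, 2))
  fw <- rfsplus:::unet_forward(net, x, c(16, 16))
  expect_equal(dim(fw$probs), c(4L, 256L, 2L))
  sums <- colSums(matrix(fw$probs, nrow = 4))
  expect_lt(max(abs(sums - 1)), 1e-6)
  cfg2 <- unet_config(dims = 2, in_channels = 3, out_channels = 3, depth = 2,
                      base_channels = 4, head = "sigmoid")
  net2 <- build_unet(cfg2, seed = 2)
  fw2 <- rfsplus:::unet_forward(net2, x, c(16, 16))
  expect_true(all(fw2$probs > 0 & fw2$probs < 1))
})

test_that("output grid equals input grid for 2D and 3D variants", {
  cfg3 <- unet_config(dims = 3, in_channels = 4, out_channels = 1, depth = 2,
                      base_channels = 2, head = "sigmoid")
  net3 <- build_unet(cfg3, seed = 3)
  x3 <- array(rnorm(4 * 8 * 8 * 4), c(4, 8 * 8 * 4, 1))
  fw3 <- rfsplus:::unet_forward(net3, x3, c(8, 8, 4))
  expect_equal(dim(fw3$probs), c(1L, 8L * 8L * 4L, 1L))
  # indivisible grids are refused with the constraint named
  expect_error(rfsplus:::unet_forward(net3, x3, c(8, 8, 6)), "divisible")
})

test_that("initialization and inference are deterministic", {
  cfg <- unet_config(dims = 2, in_channels = 4, out_channels = 3, depth = 2,
                     base_channels = 4)
  n1 <- build_unet(cfg, seed = 5)
  n2 <- build_unet(cfg, seed = 5)
  expect_identical(n1$params, n2$params)
  x <- array(rnorm(4 * 256), c(4, 256, 1))
  f1 <- rfsplus:::unet_forward(n1, x, c(16, 16))
  f2 <- rfsplus:::unet_forward(n1, x, c(16, 16))
  expect_identical(f1$probs, f2$probs)
})

test_that("analytic gradients match numeric differentiation", {
  set.seed(31)
  cfg <- unet_config(dims = 2, in_channels = 2, out_channels = 3, depth = 2,
                     base_channels = 3, head = "sigmoid")
  net <- build_unet(cfg, seed = 17)
  H <- 8; W <- 8; N <- 2
  x <- array(rnorm(2 * H * W * N), c(2, H * W, N))
  y <- array(rbinom(3 * H * W * N, 1, 0.4), c(3, H * W, N))
  loss_of <- function(net) {
    fw <- rfsplus:::unet_forward(net, x, c(H, W), training = TRUE)
    rfsplus:::head_loss_grad(fw$probs, y, "multi_label")$loss
  }
  fw <- rfsplus:::unet_forward(net, x, c(H, W), training = TRUE)
  lg <- rfsplus:::head_loss_grad(fw$probs, y, "multi_label")
  grads <- rfsplus:::unet_backward(net, fw$cache, lg$dlogits)
  expect_setequal(names(grads), names(net$params))
  eps <- 1e-5
  for (nm in c("enc1.c1.W", "enc2.n1.g", "bott.c2.W", "dec2.up.W",
               "dec1.c1.W", "out.W", "out.b")) {
    for (t in sample(length(net$params[[nm]]), 2)) {
      np <- net; np$params[[nm]][t] <- np$params[[nm]][t] + eps
      nm2 <- net; nm2$params[[nm]][t] <- nm2$params[[nm]][t] - eps
      num <- (loss_of(np) - loss_of(nm2)) / (2 * eps)
      expect_equal(grads[[nm]][t], num, tolerance = 1e-3)
    }
  }
})

test_that("slice-wise volume inference keeps probabilities coherent", {
  cohort <- tiny_cohort(4)
  norm <- fit_normalizer(cohort$patients[1:2], "zscore")
  vol <- apply_normalizer(norm, cohort$patients[[3]]$volume)
  m <- constant_candidate(0.7)
  pr <- predict_volume(m, vol)
  expect_equal(dim(pr), c(32, 32, 16, 1))
  expect_equal(max(abs(pr - 0.7)), 0, tolerance = 1e-9)
  # inference refuses a normalization mismatch
  expect_error(predict_volume(m, cohort$patients[[3]]$volume),
               "normalization")
  m_nyul <- constant_candidate(0.7, normalizer = fit_normalizer(
    cohort$patients[1:2], "nyul"))
  expect_error(predict_volume(m_nyul, vol), "normalization")
  # a softmax candidate yields per-voxel probabilities summing to 1
  mc <- constant_candidate(c(0.55, 0.2, 0.15, 0.1), approach = "multi_class")
  pr4 <- predict_volume(mc, vol)
  expect_equal(dim(pr4)[4], 4L)
  expect_lt(max(abs(apply(pr4, 1:3, sum) - 1)), 1e-6)
})

test_that("3D candidates predict on the padded patch and restore the grid", {
  cohort <- tiny_cohort(3)
  norm <- fit_normalizer(cohort$patients[1:2], "zscore")
  vol <- apply_normalizer(norm, cohort$patients[[3]]$volume)
  m3 <- constant_candidate(0.6, approach = "binary", variant = "3d")
  pr <- predict_volume(m3, vol)
  expect_equal(dim(pr), c(32, 32, 16, 1))
  expect_true(all(pr >= 0 & pr <= 1))
})
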