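#' U-net architecture configuration
#'
#' Describes one of the 2D / 2.5D / 3D encoder-decoder variants. Each of
#' the `depth` encoder blocks applies (conv 3^d, batch norm, ReLU) twice
#' and then max-pools by 2; feature maps start at `base_channels` and
#' double after each pooling, so the bottleneck holds
#' `base_channels * 2^depth` channels (1024 for the full-width 2D network
#' with base 64 and depth 4). The decoder mirrors the encoder with 2x
#' transposed-convolution upsampling and skip-connection concatenation,
#' and a final 1x1 convolution feeds the head: softmax for the
#' multi-class approach (mutually exclusive channels), sigmoid for the
#' multi-label and binary approaches (independent channels). Convolutions
#' are zero-padded ("same"), so the output grid always equals the input
#' grid.
#'
#' @param dims spatial dimensionality, 2 or 3.
#' @param in_channels input channels: 4 for 2D and 3D (the four
#'   modalities), 12 for 2.5D (3-slice stacks per modality).
#' @param out_channels 4 (multi_class), 3 (multi_label) or 1 (binary).
#' @param depth number of encoder blocks (and poolings).
#' @param base_channels feature maps of the first block.
#' @param head `"softmax"` or `"sigmoid"`.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(dims = 2L, in_channels = 4L, out_channels = 3L,
                        depth = 4L, base_channels = 64L,
                        head = c("sigmoid", "softmax")) {
  head <- match.arg(head)
  if (!dims %in% c(2L, 3L)) stop_rfs("dims must be 2 or 3")
  if (depth < 1L || base_channels < 1L) stop_rfs("depth and base_channels must be positive")
  if (head == "softmax" && out_channels < 2L)
    stop_rfs("softmax head needs at least 2 output channels")
  structure(list(dims = as.integer(dims), in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels), head = head),
            class = "unet_config")
}

#' U-net configuration appropriate for a segmentation approach
#'
#' Maps an approach to head and output channels: multi_class uses a
#' 4-channel softmax (background, NCR, ED, ET), multi_label a 3-channel
#' sigmoid (ET, TC, WT), binary a 1-channel sigmoid.
#'
#' @param approach one of `"multi_class"`, `"multi_label"`, `"binary"`.
#' @param variant `"2d"`, `"25d"` or `"3d"` (sets dims and input channels).
#' @param depth,base_channels as in [unet_config()].
#' @return A `unet_config`.
#' @export
approach_unet_config <- function(approach = c("multi_class", "multi_label",
                                              "binary"),
                                 variant = c("2d", "25d", "3d"),
                                 depth = 4L, base_channels = 64L) {
  approach <- match.arg(approach)
  variant <- match.arg(variant)
  unet_config(dims = if (variant == "3d") 3L else 2L,
              in_channels = if (variant == "25d") 12L else 4L,
              out_channels = switch(approach, multi_class = 4L,
                                    multi_label = 3L, binary = 1L),
              depth = depth, base_channels = base_channels,
              head = if (approach == "multi_class") "softmax" else "sigmoid")
}

kernel_taps <- function(dims) if (dims == 2L) 9L else 27L
up_taps <- function(dims) if (dims == 2L) 4L else 8L

# Encoder/bottleneck/decoder channel widths.
unet_widths <- function(config) {
  ch <- config$base_channels * 2^(seq_len(config$depth) - 1L)
  list(enc = ch, bottleneck = config$base_channels * 2^config$depth)
}

#' Build (initialize) a U-net
#'
#' Weights use He (Kaiming) normal initialization, `sd = sqrt(2 / fan_in)`;
#' batch-norm scales start at 1 with zero shift, and running statistics at
#' (0, 1). Deterministic given `seed`.
#'
#' @param config a [unet_config()].
#' @param seed integer initialization seed.
#' @return An object of class `unet`: `config`, flat parameter list
#'   `params`, and batch-norm running state `state`.
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  K <- kernel_taps(config$dims)
  U <- up_taps(config$dims)
  w <- unet_widths(config)
  params <- list()
  state <- list()
  he <- function(cout, fan) matrix(rnorm(cout * fan, sd = sqrt(2 / fan)), cout, fan)
  add_conv <- function(prefix, cin, cout) {
    params[[paste0(prefix, ".W")]] <<- he(cout, cin * K)
    params[[paste0(prefix, ".b")]] <<- numeric(cout)
  }
  add_bn <- function(prefix, c) {
    params[[paste0(prefix, ".g")]] <<- rep(1, c)
    params[[paste0(prefix, ".b")]] <<- numeric(c)
    state[[paste0(prefix, ".mean")]] <<- numeric(c)
    state[[paste0(prefix, ".var")]] <<- rep(1, c)
  }
  with_seed(as.integer(seed), {
    cin <- config$in_channels
    for (i in seq_len(config$depth)) {
      ci <- w$enc[i]
      add_conv(sprintf("enc%d.c1", i), cin, ci); add_bn(sprintf("enc%d.n1", i), ci)
      add_conv(sprintf("enc%d.c2", i), ci, ci); add_bn(sprintf("enc%d.n2", i), ci)
      cin <- ci
    }
    cb <- w$bottleneck
    add_conv("bott.c1", cin, cb); add_bn("bott.n1", cb)
    add_conv("bott.c2", cb, cb); add_bn("bott.n2", cb)
    for (i in rev(seq_len(config$depth))) {
      ci <- w$enc[i]
      params[[sprintf("dec%d.up.W", i)]] <- he(ci * U, 2L * ci)
      dim(params[[sprintf("dec%d.up.W", i)]]) <- c(ci * U, 2L * ci)
      params[[sprintf("dec%d.up.b", i)]] <- numeric(ci)
      add_conv(sprintf("dec%d.c1", i), 2L * ci, ci); add_bn(sprintf("dec%d.n1", i), ci)
      add_conv(sprintf("dec%d.c2", i), ci, ci); add_bn(sprintf("dec%d.n2", i), ci)
    }
    params[["out.W"]] <- he(config$out_channels, w$enc[1])
    params[["out.b"]] <- numeric(config$out_channels)
  })
  structure(list(config = config, params = params, state = state,
                 seed = as.integer(seed)),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  w <- unet_widths(x$config)
  npar <- sum(vapply(x$params, length, 1L))
  cat(sprintf("%dD U-net: in %d -> widths %s -> bottleneck %d -> out %d (%s head), %s parameters\n",
              x$config$dims, x$config$in_channels,
              paste(w$enc, collapse = ", "), w$bottleneck,
              x$config$out_channels, x$config$head,
              format(npar, big.mark = ",")))
  invisible(x)
}

bn_eps <- 1e-5
bn_momentum <- 0.1

check_spatial <- function(sdims, depth) {
  if (any(sdims %% 2^depth != 0))
    stop_rfs("spatial dims (%s) must be divisible by 2^depth = %d",
             paste(sdims, collapse = "x"), 2^depth)
}

# (conv -> batch norm -> ReLU) with optional cache for backprop.
cbr_forward <- function(params, state, prefix_c, prefix_n, x, sdims,
                        training, cache) {
  y <- .conv_forward(x, params[[paste0(prefix_c, ".W")]],
                     params[[paste0(prefix_c, ".b")]], sdims)
  if (training) {
    bn <- .bn_forward(y, params[[paste0(prefix_n, ".g")]],
                      params[[paste0(prefix_n, ".b")]], bn_eps)
    a <- bn$y
    a[a < 0] <- 0
    if (!is.null(cache)) {
      cache[[prefix_c]] <- list(x = x, y = y, mean = bn$mean, var = bn$var,
                                act = a, sdims = sdims)
    }
    updates <- list(mean = bn$mean, var = bn$var)
  } else {
    a <- .bn_forward_inference(y, params[[paste0(prefix_n, ".g")]],
                               params[[paste0(prefix_n, ".b")]],
                               state[[paste0(prefix_n, ".mean")]],
                               state[[paste0(prefix_n, ".var")]], bn_eps)
    a[a < 0] <- 0
    updates <- NULL
  }
  list(a = a, updates = updates)
}

# Forward pass over a batch cube (C, P, N). Returns logits/probs and, when
# training, the caches needed for the backward pass plus running-stat
# updates.
unet_forward <- function(net, x, sdims, training = FALSE) {
  config <- net$config
  check_spatial(sdims, config$depth)
  if (dim(x)[1] != config$in_channels)
    stop_rfs("input has %d channels, config expects %d", dim(x)[1],
             config$in_channels)
  cache <- if (training) new.env(parent = emptyenv()) else NULL
  p <- net$params; st <- net$state
  upd <- list()
  sd <- as.integer(sdims)
  h <- x
  skips <- vector("list", config$depth)
  pool_idx <- vector("list", config$depth)
  for (i in seq_len(config$depth)) {
    r1 <- cbr_forward(p, st, sprintf("enc%d.c1", i), sprintf("enc%d.n1", i),
                      h, sd, training, cache)
    r2 <- cbr_forward(p, st, sprintf("enc%d.c2", i), sprintf("enc%d.n2", i),
                      r1$a, sd, training, cache)
    if (training) upd[[sprintf("enc%d.n1", i)]] <- r1$updates
    if (training) upd[[sprintf("enc%d.n2", i)]] <- r2$updates
    skips[[i]] <- r2$a
    mp <- .maxpool_forward(r2$a, sd)
    if (training) pool_idx[[i]] <- mp$idx
    h <- mp$y
    sd <- sd %/% 2L
  }
  r1 <- cbr_forward(p, st, "bott.c1", "bott.n1", h, sd, training, cache)
  r2 <- cbr_forward(p, st, "bott.c2", "bott.n2", r1$a, sd, training, cache)
  if (training) { upd[["bott.n1"]] <- r1$updates; upd[["bott.n2"]] <- r2$updates }
  if (training) cache[["bott.in"]] <- h
  h <- r2$a
  up_in <- vector("list", config$depth)
  for (i in rev(seq_len(config$depth))) {
    if (training) up_in[[i]] <- h
    u <- .upconv_forward(h, p[[sprintf("dec%d.up.W", i)]],
                         p[[sprintf("dec%d.up.b", i)]], sd)
    sd <- sd * 2L
    cu <- dim(u)[1]; cs <- dim(skips[[i]])[1]
    hc <- array(0, c(cu + cs, dim(u)[2], dim(u)[3]))
    hc[seq_len(cu), , ] <- u
    hc[cu + seq_len(cs), , ] <- skips[[i]]
    r1 <- cbr_forward(p, st, sprintf("dec%d.c1", i), sprintf("dec%d.n1", i),
                      hc, sd, training, cache)
    r2 <- cbr_forward(p, st, sprintf("dec%d.c2", i), sprintf("dec%d.n2", i),
                      r1$a, sd, training, cache)
    if (training) upd[[sprintf("dec%d.n1", i)]] <- r1$updates
    if (training) upd[[sprintf("dec%d.n2", i)]] <- r2$updates
    h <- r2$a
  }
  # final 1x1 convolution
  C1 <- dim(h)[1]; P <- dim(h)[2]; N <- dim(h)[3]
  hm <- matrix(h, nrow = C1)
  lg <- p[["out.W"]] %*% hm + p[["out.b"]]
  logits <- array(lg, c(config$out_channels, P, N))
  if (training) {
    cache[["out.in"]] <- h
    cache[["skips.dims"]] <- lapply(skips, dim)
    cache[["pool_idx"]] <- pool_idx
    cache[["up_in"]] <- up_in
    cache[["sdims"]] <- as.integer(sdims)
  }
  list(logits = logits, probs = apply_head(logits, config$head),
       cache = cache, bn_updates = if (training) upd else NULL)
}

# Softmax over the channel (first) dimension, or elementwise sigmoid.
apply_head <- function(logits, head) {
  if (head == "sigmoid") return(array(stats::plogis(logits), dim(logits)))
  C <- dim(logits)[1]
  m <- matrix(logits, nrow = C)
  mx <- do.call(pmax, lapply(seq_len(C), function(c) m[c, ]))
  e <- exp(sweep(m, 2, mx))
  array(sweep(e, 2, colSums(e), "/"), dim(logits))
}

# Backward through (conv -> bn -> relu) given upstream grad of the
# activation. Returns grad wrt block input; accumulates parameter grads.
cbr_backward <- function(params, cache, prefix_c, prefix_n, ga, grads) {
  cc <- cache[[prefix_c]]
  ga[cc$act <= 0] <- 0
  bn <- .bn_backward(cc$y, ga, params[[paste0(prefix_n, ".g")]],
                     cc$mean, cc$var, bn_eps)
  grads[[paste0(prefix_n, ".g")]] <- as.numeric(bn$ggamma)
  grads[[paste0(prefix_n, ".b")]] <- as.numeric(bn$gbeta)
  cv <- .conv_backward(cc$x, bn$gx, params[[paste0(prefix_c, ".W")]], cc$sdims)
  grads[[paste0(prefix_c, ".W")]] <- cv$gW
  grads[[paste0(prefix_c, ".b")]] <- as.numeric(cv$gb)
  list(gx = cv$gx, grads = grads)
}

# Full backward pass from d(loss)/d(logits). Returns a flat gradient list
# aligned with net$params.
unet_backward <- function(net, cache, dlogits) {
  config <- net$config
  p <- net$params
  grads <- list()
  h <- cache[["out.in"]]
  C1 <- dim(h)[1]; P <- dim(h)[2]; N <- dim(h)[3]
  dm <- matrix(dlogits, nrow = config$out_channels)
  hm <- matrix(h, nrow = C1)
  grads[["out.W"]] <- dm %*% t(hm)
  grads[["out.b"]] <- rowSums(dm)
  gh <- array(t(p[["out.W"]]) %*% dm, c(C1, P, N))
  # decoder levels, outermost (i = 1) backward first; up_in[[i]] is the
  # output of the next-deeper decoder level (or the bottleneck), so ub$gx
  # seeds the next iteration
  for (i in seq_len(config$depth)) {
    lvl_sd <- cache[[sprintf("dec%d.c1", i)]]$sdims
    r2 <- cbr_backward(p, cache, sprintf("dec%d.c2", i), sprintf("dec%d.n2", i),
                       gh, grads)
    grads <- r2$grads
    r1 <- cbr_backward(p, cache, sprintf("dec%d.c1", i), sprintf("dec%d.n1", i),
                       r2$gx, grads)
    grads <- r1$grads
    ghc <- r1$gx
    cs <- cache[["skips.dims"]][[i]][1]
    cu <- dim(ghc)[1] - cs
    gu <- ghc[seq_len(cu), , , drop = FALSE]
    ub <- .upconv_backward(cache[["up_in"]][[i]], gu,
                           p[[sprintf("dec%d.up.W", i)]], lvl_sd %/% 2L)
    grads[[sprintf("dec%d.up.W", i)]] <- ub$gW
    grads[[sprintf("dec%d.up.b", i)]] <- as.numeric(ub$gb)
    cache[[sprintf("gskip%d", i)]] <- ghc[cu + seq_len(cs), , , drop = FALSE]
    gh <- ub$gx
  }
  # bottleneck
  r2 <- cbr_backward(p, cache, "bott.c2", "bott.n2", gh, grads)
  grads <- r2$grads
  r1 <- cbr_backward(p, cache, "bott.c1", "bott.n1", r2$gx, grads)
  grads <- r1$grads
  gh <- r1$gx
  # encoder levels, deepest first
  for (i in rev(seq_len(config$depth))) {
    sd_i <- cache[[sprintf("enc%d.c1", i)]]$sdims
    P_in <- prod(sd_i)
    gpool <- .maxpool_backward(gh, cache[["pool_idx"]][[i]], P_in)
    ga <- gpool + cache[[sprintf("gskip%d", i)]]
    r2 <- cbr_backward(p, cache, sprintf("enc%d.c2", i), sprintf("enc%d.n2", i),
                       ga, grads)
    grads <- r2$grads
    r1 <- cbr_backward(p, cache, sprintf("enc%d.c1", i), sprintf("enc%d.n1", i),
                       r2$gx, grads)
    grads <- r1$grads
    gh <- r1$gx
  }
  grads
}
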