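test_that("convolution output arithmetic is exact", {
  expect_equal(conv_output_side(256, 7, 2, 3), 128L)
  expect_equal(conv_output_side(17, 1, 1, 0), 17L)
  expect_equal(conv_output_side(64, 3, 2, 1), 32L)
  expect_error(conv_output_side(4, 7, 1, 0), "kernel")
})

test_that("the default topology reproduces the printed shape table", {
  sh <- arcnn_stage_shapes(arcnn_spec())
  expect_equal(nrow(sh), 9)
  expect_equal(sh$stage, c("conv1", "max_pool", "conv2", "conv3", "conv4",
                           "conv5", "GAP", "FC1", "FC2"))
  expect_equal(sh$out_side, c(128L, 64L, 64L, 32L, 16L, 8L, 1L, 1L, 1L))
  expect_equal(sh$out_channels,
               c(64L, 64L, 256L, 512L, 1024L, 2048L, 2048L, 512L, 2L))
  expect_equal(sh$in_side[1], 256L)
  expect_equal(sh$in_channels[1], 1L)

  # five halvings collapse a 32-side input to a single voxel before GAP
  sh32 <- arcnn_stage_shapes(arcnn_spec_scaled(32))
  expect_equal(sh32$out_side[6], 1L)

  expect_error(arcnn_spec(input_side = 100), "divisible by 32")
})

test_that("residual blocks choose the shortcut forced by their shapes", {
  proj <- build_arb(arb_spec(64, 32, 256, cardinality_C = 8))
  expect_identical(proj$shortcut, "projection")
  ident <- build_arb(arb_spec(256, 32, 256, cardinality_C = 8, stride = 1))
  expect_identical(ident$shortcut, "identity")
  strided <- build_arb(arb_spec(256, 64, 256, cardinality_C = 8, stride = 2))
  expect_identical(strided$shortcut, "projection")
  expect_error(arb_spec(64, 30, 256, cardinality_C = 8), "divisible")
})

test_that("grouping with C branches divides the transform weights by C", {
  w <- 64L; C <- 8L
  grouped <- build_arb(arb_spec(w, w, 4 * w, cardinality_C = C))
  ungrouped <- build_arb(arb_spec(w, w, 4 * w, cardinality_C = 1L))
  gw <- prod(grouped$param_shapes$group.w)
  uw <- prod(ungrouped$param_shapes$group.w)
  expect_equal(gw * C, uw)  # k^3 (w/C)(w/C) C vs k^3 w w

  spec_c8 <- arcnn_spec()
  spec_c1 <- arcnn_spec(cardinality = 1L)
  n8 <- sum(vapply(unlist(lapply(1:4, function(s)
    lapply(samdnet:::.stage_blocks(spec_c8, s), build_arb)),
    recursive = FALSE), function(b) b$n_params, numeric(1)))
  n1 <- sum(vapply(unlist(lapply(1:4, function(s)
    lapply(samdnet:::.stage_blocks(spec_c1, s), build_arb)),
    recursive = FALSE), function(b) b$n_params, numeric(1)))
  expect_lt(n8, n1)
})

test_that("a forward pass realizes the analytic shapes", {
  spec <- arcnn_spec_scaled(32)
  m <- build_arcnn(spec, seed = 1)
  set.seed(1)
  x <- array(runif(32^3 * 2), c(32, 32, 32, 1, 2))
  fw <- arcnn_forward(m, x, training = TRUE)
  expect_equal(dim(fw$logits), c(2L, 2L))

  sh <- arcnn_stage_shapes(spec)
  expect_equal(dim(fw$cache$stem_a)[1], sh$out_side[1])
  expect_equal(dim(fw$cache$stem_a)[4], sh$out_channels[1])
  expect_equal(dim(fw$cache$pool$y)[1], sh$out_side[2])
  for (s in 1:4) {
    last <- fw$cache$block_caches[[s]][[spec$stage_repeats[s]]]$sum_pre
    expect_equal(dim(last)[1], sh$out_side[2 + s])
    expect_equal(dim(last)[4], sh$out_channels[2 + s])
  }
  expect_equal(ncol(fw$cache$gap_y), sh$out_channels[7])

  # evaluation mode is deterministic
  l1 <- arcnn_predict(m, x)
  l2 <- arcnn_predict(m, x)
  expect_identical(l1, l2)
})

test_that("global average pooling is a spatially invariant channel mean", {
  x <- array(3.5, c(2, 4, 4, 4, 6))
  y <- global_average_pool(x)
  expect_equal(dim(y), c(2L, 6L))
  expect_true(all(y == 3.5))

  set.seed(2)
  z <- array(rnorm(1 * 3 * 3 * 3 * 5), c(1, 3, 3, 3, 5))
  perm <- sample(27)
  zs <- z
  for (c in 1:5) {
    flat <- as.vector(z[1, , , , c])[perm]
    zs[1, , , , c] <- array(flat, c(3, 3, 3))
  }
  expect_equal(global_average_pool(z), global_average_pool(zs),
               tolerance = 1e-12)
  expect_error(global_average_pool(array(1, c(2, 3, 3))), "batch")
})

test_that("compiled convolution gradients match numeric differentiation", {
  ns <- asNamespace("samdnet")
  set.seed(5)
  x <- array(rnorm(5^3 * 4), c(5, 5, 5, 4))
  w <- array(rnorm(27 * 2 * 6), c(3, 3, 3, 2, 6))
  b <- rnorm(6)
  gy <- array(rnorm(3^3 * 6), c(3, 3, 3, 6))
  loss <- function(x, w, b) sum(ns$conv3d_fwd(x, w, b, 2L, 1L, 2L) * gy)
  bw <- ns$conv3d_bwd(x, w, gy, 2L, 1L, 2L)
  expect_equal(bw$gx, num_grad(function(z) loss(z, w, b), x),
               tolerance = 1e-6)
  expect_equal(bw$gw, num_grad(function(z) loss(x, z, b), w),
               tolerance = 1e-6)
  expect_equal(as.numeric(bw$gb), as.numeric(num_grad(
    function(z) loss(x, w, z), b)), tolerance = 1e-6)

  r <- ns$maxpool3d_fwd(x, 3L, 2L, 1L)
  gyp <- array(rnorm(prod(dim(r$y))), dim(r$y))
  gxp <- ns$maxpool3d_bwd(gyp, r$argmax, dim(x))
  expect_equal(gxp, num_grad(function(z)
    sum(ns$maxpool3d_fwd(z, 3L, 2L, 1L)$y * gyp), x, eps = 1e-6),
    tolerance = 1e-5)
})

test_that("batch normalization gradients match numeric differentiation", {
  ns <- asNamespace("samdnet")
  set.seed(6)
  x5 <- array(rnorm(27 * 2 * 4), c(3, 3, 3, 2, 4))
  gm <- runif(2, 0.5, 1.5); bt <- rnorm(2)
  gy5 <- array(rnorm(27 * 2 * 4), c(3, 3, 3, 2, 4))
  fb <- function(x5, gm, bt) {
    sum(ns$.bn_fwd(x5, gm, bt, c(0, 0), c(1, 1), TRUE)$y * gy5)
  }
  r <- ns$.bn_fwd(x5, gm, bt, c(0, 0), c(1, 1), TRUE)
  bwd <- ns$.bn_bwd(r$cache, gy5)
  expect_equal(bwd$gx, num_grad(function(z) fb(z, gm, bt), x5),
               tolerance = 1e-6)
  expect_equal(as.numeric(bwd$dgamma),
               as.numeric(num_grad(function(z) fb(x5, z, bt), gm)),
               tolerance = 1e-6)
  expect_equal(as.numeric(bwd$dbeta),
               as.numeric(num_grad(function(z) fb(x5, gm, z), bt)),
               tolerance = 1e-6)
})

test_that("whole-model gradients match numeric directional derivatives", {
  set.seed(7)
  m <- build_arcnn(arcnn_spec_scaled(32), seed = 3)
  p <- arcnn_flatten(m$params)
  x <- array(runif(32^3 * 2), c(32, 32, 32, 1, 2))
  y <- c(1L, 2L)
  r <- arcnn_loss_grads(m, x, y)
  lossfn <- function(pv) {
    mm <- samdnet:::.with_flat_params(m, pv)
    samdnet:::.softmax_ce(arcnn_forward(mm, x, training = TRUE)$logits,
                          y)$loss
  }
  set.seed(11)
  idx <- sample(length(p), 12)
  eps <- 1e-4
  for (i in idx) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    nd <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
    # absolute floor guards coordinates whose true gradient is ~0, where
    # central differences are pure roundoff
    expect_lt(abs(r$grads[i] - nd), 1e-6 + 1e-3 * abs(nd))
  }
})

test_that("one training step reaches every stage's weights", {
  set.seed(8)
  m <- build_arcnn(arcnn_spec_scaled(32), seed = 9)
  x <- array(runif(32^3 * 2), c(32, 32, 32, 1, 2))
  y <- c(1L, 2L)
  r <- arcnn_loss_grads(m, x, y)
  p <- arcnn_flatten(m$params)
  p2 <- p - 0.01 * r$grads
  upd <- arcnn_unflatten(p2, m$params)
  conv_names <- grep("\\.w$", names(m$params), value = TRUE)
  for (nm in conv_names) {
    expect_gt(max(abs(upd[[nm]] - m$params[[nm]])), 0)
  }
})

test_that("flatten and unflatten are mutually inverse", {
  m <- build_arcnn(arcnn_spec_scaled(32), seed = 2)
  v <- arcnn_flatten(m$params)
  back <- arcnn_unflatten(v, m$params)
  expect_identical(back, m$params)
  expect_error(arcnn_unflatten(v[-1], m$params))
})

test_that("checkpoints round-trip and predict identically", {
  m <- build_arcnn(arcnn_spec_scaled(32), seed = 4)
  path <- tempfile(fileext = ".rds")
  save_arcnn(m, path)
  m2 <- load_arcnn(path)
  set.seed(4)
  x <- array(runif(32^3), c(32, 32, 32, 1, 1))
  expect_identical(arcnn_predict(m, x), arcnn_predict(m2, x))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(), bad)
  expect_error(load_arcnn(bad), "arcnn_model")
})
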