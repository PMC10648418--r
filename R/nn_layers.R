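# Differentiable layer primitives for the volumetric network. Batched
# activations are 5-d arrays laid out (D, H, W, C, B); convolution and max
# pooling run through compiled kernels per sample, everything else is
# vectorized R. Each primitive has a forward returning (output, cache) and
# a backward consuming (cache, upstream gradient).

.batch_size <- function(x5) dim(x5)[5]

# slice sample i as a 4-d array without dropping singleton dims
.sample4 <- function(x5, i) {
  d <- dim(x5)
  y <- x5[, , , , i, drop = FALSE]
  dim(y) <- d[1:4]
  y
}

.conv_fwd <- function(x5, w, b, stride, pad, groups) {
  B <- .batch_size(x5)
  y1 <- conv3d_fwd(.sample4(x5, 1), w, b, stride, pad, groups)
  yd <- dim(y1)
  y5 <- array(0, c(yd, B))
  y5[, , , , 1] <- y1
  if (B > 1) {
    for (i in 2:B) {
      y5[, , , , i] <- conv3d_fwd(.sample4(x5, i), w, b,
                                  stride, pad, groups)
    }
  }
  y5
}

.conv_bwd <- function(x5, w, gy5, stride, pad, groups) {
  B <- .batch_size(x5)
  gx5 <- array(0, dim(x5))
  gw <- array(0, dim(w))
  gb <- numeric(dim(w)[5])
  for (i in seq_len(B)) {
    r <- conv3d_bwd(.sample4(x5, i), w,
                    .sample4(gy5, i), stride, pad, groups)
    gx5[, , , , i] <- r$gx
    gw <- gw + r$gw
    gb <- gb + r$gb
  }
  list(gx = gx5, gw = gw, gb = gb)
}

.pool_fwd <- function(x5, k = 3L, stride = 2L, pad = 1L) {
  B <- .batch_size(x5)
  r1 <- maxpool3d_fwd(.sample4(x5, 1), k, stride, pad)
  yd <- dim(r1$y)
  y5 <- array(0, c(yd, B))
  am <- vector("list", B)
  y5[, , , , 1] <- r1$y
  am[[1]] <- r1$argmax
  if (B > 1) {
    for (i in 2:B) {
      r <- maxpool3d_fwd(.sample4(x5, i), k, stride, pad)
      y5[, , , , i] <- r$y
      am[[i]] <- r$argmax
    }
  }
  list(y = y5, argmax = am, xdim = dim(x5)[1:4])
}

.pool_bwd <- function(cache, gy5) {
  B <- dim(gy5)[5]
  gx5 <- array(0, c(cache$xdim, B))
  for (i in seq_len(B)) {
    gx5[, , , , i] <- maxpool3d_bwd(.sample4(gy5, i),
                                    cache$argmax[[i]],
                                    as.integer(cache$xdim))
  }
  gx5
}

# reshape (D,H,W,C,B) <-> (D*H*W*B, C) matrices for channelwise statistics
.to_cmat <- function(x5) {
  d <- dim(x5)
  matrix(aperm(x5, c(1, 2, 3, 5, 4)), ncol = d[4])
}
.from_cmat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[3], d[5], d[4])), c(1, 2, 3, 5, 4))
}

.bn_fwd <- function(x5, gamma, beta, run_mean, run_var, training,
                    momentum = 0.1, eps = 1e-5) {
  d <- dim(x5)
  xm <- .to_cmat(x5)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    nb <- nrow(xm)
    run_var <- (1 - momentum) * run_var + momentum * v * nb / max(nb - 1, 1)
  } else {
    mu <- run_mean
    v <- run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xm, 2, mu, "-")
  xhat <- sweep(xhat, 2, invstd, "*")
  ym <- sweep(xhat, 2, gamma, "*")
  ym <- sweep(ym, 2, beta, "+")
  list(y = .from_cmat(ym, d),
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, d = d,
                    training = training),
       run_mean = run_mean, run_var = run_var)
}

.bn_bwd <- function(cache, gy5) {
  d <- cache$d
  gym <- .to_cmat(gy5)
  xhat <- cache$xhat
  n <- nrow(gym)
  dgamma <- colSums(gym * xhat)
  dbeta <- colSums(gym)
  dxhat <- sweep(gym, 2, cache$gamma, "*")
  if (cache$training) {
    # standard batch-norm backward through the batch statistics
    gxm <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(gym), byrow = TRUE) -
                   xhat * matrix(colMeans(dxhat * xhat), n, ncol(gym),
                                 byrow = TRUE),
                 2, cache$invstd, "*")
  } else {
    gxm <- sweep(dxhat, 2, cache$invstd, "*")
  }
  list(gx = .from_cmat(gxm, d), dgamma = dgamma, dbeta = dbeta)
}

.relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}
.relu_bwd <- function(x, gy) {
  gy * (x > 0)
}

.gap_fwd <- function(x5) {
  d <- dim(x5)
  B <- d[5]; C <- d[4]
  y <- matrix(0, B, C)
  for (i in seq_len(B)) {
    y[i, ] <- colMeans(matrix(.sample4(x5, i), ncol = C))
  }
  list(y = y, d = d)
}
.gap_bwd <- function(cache, gy) {
  d <- cache$d
  nvox <- prod(d[1:3])
  gx5 <- array(0, d)
  for (i in seq_len(d[5])) {
    gx5[, , , , i] <- array(rep(gy[i, ] / nvox, each = nvox), d[1:4])
  }
  gx5
}

.fc_fwd <- function(x, w, b) {
  sweep(x %*% w, 2, b, "+")
}
.fc_bwd <- function(x, w, gy) {
  list(gx = gy %*% t(w), gw = crossprod(x, gy), gb = colSums(gy))
}

# Cross-entropy on logits; labels are 1-based class indices.
.softmax_ce <- function(logits, labels) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(logits)
  ll <- -log(pmax(p[cbind(seq_len(n), labels)], 1e-12))
  dlogits <- p
  dlogits[cbind(seq_len(n), labels)] <-
    dlogits[cbind(seq_len(n), labels)] - 1
  list(loss = mean(ll), dlogits = dlogits / n, probs = p)
}

#' Global average pooling
#'
#' Reduces each feature channel to its arithmetic mean over all spatial
#' positions; invariant under any permutation of the spatial grid.
#'
#' @param t A 5-d array of shape `(batch, d, h, w, c)`.
#' @return A `(batch, c)` matrix of channel means.
#' @examples
#' x <- array(3.5, c(2, 4, 4, 4, 6))
#' global_average_pool(x)[1, 1]  # 3.5
#' @export
global_average_pool <- function(t) {
  d <- dim(t)
  if (length(d) != 5) stop("expected a (batch, d, h, w, c) array",
                           call. = FALSE)
  if (any(d[2:4] < 1)) stop("empty spatial extent", call. = FALSE)
  B <- d[1]; C <- d[5]
  y <- matrix(0, B, C)
  for (i in seq_len(B)) {
    xi <- t[i, , , , , drop = FALSE]
    dim(xi) <- d[2:5]
    y[i, ] <- colMeans(matrix(xi, ncol = C))
  }
  y
}
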