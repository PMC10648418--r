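# The ARCNN model: construction, forward pass, reverse-mode gradients and
# flat parameter views. Trainable parameters live in a single named list in
# build order so optimizers can treat the network as one flat vector;
# batch-norm running statistics live in a parallel buffer list.

.he_conv <- function(k, cig, co) {
  array(stats::rnorm(k^3 * cig * co, sd = sqrt(2 / (k^3 * cig))),
        c(k, k, k, cig, co))
}

.block_prefix <- function(stage, block) sprintf("s%db%d", stage, block)

#' Describe an aggregated residual block
#'
#' Expands an [arb_spec()] into its three-stage structure: a 1x1x1 reduce
#' convolution to the bottleneck width, an aggregated 3x3x3 transform with
#' `cardinality_C` branches realized as a grouped convolution, and a 1x1x1
#' expand convolution, each followed by batch normalization; rectified
#' linear activations follow the first two normalizations and the residual
#' addition. The shortcut is the identity when input and output shapes
#' match, otherwise a strided 1x1x1 projection with its own normalization.
#'
#' @param spec An [arb_spec()].
#' @return A list of class `arb_block` with fields `spec`, `shortcut`
#'   (`"identity"` or `"projection"`), `param_shapes` (named list of array
#'   dims) and `n_params`.
#' @examples
#' build_arb(arb_spec(64, 32, 256, cardinality_C = 8))$shortcut
#' @export
build_arb <- function(spec) {
  stopifnot(inherits(spec, "arb_spec"))
  cig <- spec$bottleneck_channels %/% spec$cardinality_C
  shortcut <- if (spec$in_channels == spec$out_channels &&
                  spec$stride == 1L) "identity" else "projection"
  shapes <- list(
    reduce.w = c(1, 1, 1, spec$in_channels, spec$bottleneck_channels),
    reduce.b = spec$bottleneck_channels,
    reduce_bn.gamma = spec$bottleneck_channels,
    reduce_bn.beta = spec$bottleneck_channels,
    group.w = c(spec$kernel, spec$kernel, spec$kernel, cig,
                spec$bottleneck_channels),
    group.b = spec$bottleneck_channels,
    group_bn.gamma = spec$bottleneck_channels,
    group_bn.beta = spec$bottleneck_channels,
    expand.w = c(1, 1, 1, spec$bottleneck_channels, spec$out_channels),
    expand.b = spec$out_channels,
    expand_bn.gamma = spec$out_channels,
    expand_bn.beta = spec$out_channels
  )
  if (shortcut == "projection") {
    shapes$shortcut.w <- c(1, 1, 1, spec$in_channels, spec$out_channels)
    shapes$shortcut.b <- spec$out_channels
    shapes$shortcut_bn.gamma <- spec$out_channels
    shapes$shortcut_bn.beta <- spec$out_channels
  }
  structure(list(spec = spec, shortcut = shortcut, param_shapes = shapes,
                 n_params = sum(vapply(shapes, prod, numeric(1)))),
            class = "arb_block")
}

# initialize parameters/buffers of one block under the given prefix
.init_block <- function(blk, prefix) {
  sp <- blk$spec
  cig <- sp$bottleneck_channels %/% sp$cardinality_C
  params <- list()
  buffers <- list()
  add_conv <- function(name, k, cin, cout) {
    params[[paste0(prefix, ".", name, ".w")]] <<- .he_conv(k, cin, cout)
    params[[paste0(prefix, ".", name, ".b")]] <<- numeric(cout)
  }
  add_bn <- function(name, c) {
    params[[paste0(prefix, ".", name, ".gamma")]] <<- rep(1, c)
    params[[paste0(prefix, ".", name, ".beta")]] <<- numeric(c)
    buffers[[paste0(prefix, ".", name, ".rm")]] <<- numeric(c)
    buffers[[paste0(prefix, ".", name, ".rv")]] <<- rep(1, c)
  }
  add_conv("reduce", 1, sp$in_channels, sp$bottleneck_channels)
  add_bn("reduce_bn", sp$bottleneck_channels)
  add_conv("group", sp$kernel, cig, sp$bottleneck_channels)
  add_bn("group_bn", sp$bottleneck_channels)
  add_conv("expand", 1, sp$bottleneck_channels, sp$out_channels)
  add_bn("expand_bn", sp$out_channels)
  if (blk$shortcut == "projection") {
    add_conv("shortcut", 1, sp$in_channels, sp$out_channels)
    add_bn("shortcut_bn", sp$out_channels)
  }
  list(params = params, buffers = buffers)
}

#' Build a trainable ARCNN
#'
#' Instantiates the staged topology of an [arcnn_spec()] with
#' He-initialized convolution weights, unit batch-norm scales and zero
#' biases. The forward pass on a batch of cubes of side `spec$input_side`
#' yields `(batch, num_classes)` logits. Construction cross-checks the
#' realized stage layout against [arcnn_stage_shapes()].
#'
#' @param spec An [arcnn_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `arcnn_model` with fields `spec`, `params`
#'   (named list of arrays), `buffers` (batch-norm running statistics) and
#'   `blocks` (per-stage [build_arb()] descriptors).
#' @examples
#' m <- build_arcnn(arcnn_spec_scaled(), seed = 1)
#' length(arcnn_flatten(m$params))
#' @export
build_arcnn <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "arcnn_spec"))
  shapes <- arcnn_stage_shapes(spec)
  if (shapes$out_side[6] < 1) stop("input side too small for five halvings",
                                   call. = FALSE)
  set.seed(seed)
  params <- list()
  buffers <- list()

  params[["stem.w"]] <- .he_conv(7, spec$input_channels, spec$conv1_channels)
  params[["stem.b"]] <- numeric(spec$conv1_channels)
  params[["stem_bn.gamma"]] <- rep(1, spec$conv1_channels)
  params[["stem_bn.beta"]] <- numeric(spec$conv1_channels)
  buffers[["stem_bn.rm"]] <- numeric(spec$conv1_channels)
  buffers[["stem_bn.rv"]] <- rep(1, spec$conv1_channels)

  blocks <- vector("list", 4)
  for (s in 1:4) {
    bspecs <- .stage_blocks(spec, s)
    blocks[[s]] <- lapply(bspecs, build_arb)
    for (b in seq_along(bspecs)) {
      ini <- .init_block(blocks[[s]][[b]], .block_prefix(s, b))
      params <- c(params, ini$params)
      buffers <- c(buffers, ini$buffers)
    }
  }

  gap_ch <- spec$stage_channels[4]
  params[["fc1.w"]] <- matrix(stats::rnorm(gap_ch * spec$fc_width,
                                           sd = sqrt(2 / gap_ch)),
                              gap_ch, spec$fc_width)
  params[["fc1.b"]] <- numeric(spec$fc_width)
  params[["fc2.w"]] <- matrix(stats::rnorm(spec$fc_width * spec$num_classes,
                                           sd = sqrt(2 / spec$fc_width)),
                              spec$fc_width, spec$num_classes)
  params[["fc2.b"]] <- numeric(spec$num_classes)

  structure(list(spec = spec, params = params, buffers = buffers,
                 blocks = blocks, shapes = shapes),
            class = "arcnn_model")
}

#' @export
print.arcnn_model <- function(x, ...) {
  cat(sprintf("<arcnn_model> input %d^3, %d trainable parameters\n",
              x$spec$input_side, length(arcnn_flatten(x$params))))
  invisible(x)
}

#' Flatten / restore the parameter list
#'
#' @param params Named list of parameter arrays (as in `model$params`).
#' @return `arcnn_flatten()` returns one numeric vector in build order;
#'   `arcnn_unflatten()` restores the named-list structure of `template`
#'   from such a vector.
#' @export
arcnn_flatten <- function(params) {
  unlist(params, use.names = FALSE)
}

#' @rdname arcnn_flatten
#' @param vec Flat numeric vector from [arcnn_flatten()].
#' @param template Named list giving the target shapes.
#' @export
arcnn_unflatten <- function(vec, template) {
  lens <- vapply(template, length, integer(1))
  stopifnot(length(vec) == sum(lens))
  out <- template
  off <- 0L
  for (i in seq_along(template)) {
    vals <- vec[(off + 1L):(off + lens[i])]
    if (!is.null(dim(template[[i]]))) {
      dim(vals) <- dim(template[[i]])
    }
    out[[i]] <- vals
    off <- off + lens[i]
  }
  out
}

# ---- forward ---------------------------------------------------------------

.bn_apply <- function(x5, P, Bf, prefix, training, updates, caches) {
  r <- .bn_fwd(x5, P[[paste0(prefix, ".gamma")]],
               P[[paste0(prefix, ".beta")]],
               Bf[[paste0(prefix, ".rm")]], Bf[[paste0(prefix, ".rv")]],
               training)
  updates[[paste0(prefix, ".rm")]] <- r$run_mean
  updates[[paste0(prefix, ".rv")]] <- r$run_var
  caches[[prefix]] <- r$cache
  list(y = r$y, updates = updates, caches = caches)
}

.block_forward <- function(model, s, b, x5, training, buf_updates) {
  P <- model$params
  blk <- model$blocks[[s]][[b]]
  sp <- blk$spec
  pre <- .block_prefix(s, b)
  cc <- list(x = x5)
  bn_caches <- list()

  z1 <- .conv_fwd(x5, P[[paste0(pre, ".reduce.w")]],
                  P[[paste0(pre, ".reduce.b")]], 1L, 0L, 1L)
  r <- .bn_apply(z1, P, model$buffers, paste0(pre, ".reduce_bn"), training,
                 buf_updates, bn_caches)
  buf_updates <- r$updates; bn_caches <- r$caches
  cc$a1_pre <- r$y
  a1 <- .relu_fwd(r$y)

  z2 <- .conv_fwd(a1, P[[paste0(pre, ".group.w")]],
                  P[[paste0(pre, ".group.b")]], sp$stride, sp$padding,
                  sp$cardinality_C)
  r <- .bn_apply(z2, P, model$buffers, paste0(pre, ".group_bn"), training,
                 buf_updates, bn_caches)
  buf_updates <- r$updates; bn_caches <- r$caches
  cc$a2_pre <- r$y
  a2 <- .relu_fwd(r$y)

  z3 <- .conv_fwd(a2, P[[paste0(pre, ".expand.w")]],
                  P[[paste0(pre, ".expand.b")]], 1L, 0L, 1L)
  r <- .bn_apply(z3, P, model$buffers, paste0(pre, ".expand_bn"), training,
                 buf_updates, bn_caches)
  buf_updates <- r$updates; bn_caches <- r$caches
  y3 <- r$y

  if (blk$shortcut == "projection") {
    zs <- .conv_fwd(x5, P[[paste0(pre, ".shortcut.w")]],
                    P[[paste0(pre, ".shortcut.b")]], sp$stride, 0L, 1L)
    r <- .bn_apply(zs, P, model$buffers, paste0(pre, ".shortcut_bn"),
                   training, buf_updates, bn_caches)
    buf_updates <- r$updates; bn_caches <- r$caches
    ys <- r$y
  } else {
    ys <- x5
  }

  cc$sum_pre <- y3 + ys
  cc$a1 <- a1
  cc$a2 <- a2
  cc$bn <- bn_caches
  out <- .relu_fwd(cc$sum_pre)
  list(y = out, cache = cc, buf_updates = buf_updates)
}

#' Forward pass of an ARCNN
#'
#' @param model An [build_arcnn()] model.
#' @param x5 Batched input, a `(side, side, side, channels, batch)` array.
#' @param training If `TRUE`, batch statistics are used for normalization
#'   (and running statistics updated in the returned `buffers`); if
#'   `FALSE`, running statistics are used and the pass is deterministic.
#' @return A list with `logits` (`batch x num_classes`), `cache` (forward
#'   intermediates for [arcnn_backward()]; training mode only) and
#'   `buffers` (possibly updated running statistics).
#' @export
arcnn_forward <- function(model, x5, training = FALSE) {
  stopifnot(inherits(model, "arcnn_model"))
  d <- dim(x5)
  if (length(d) == 4L) {
    dim(x5) <- c(d, 1L)
    d <- dim(x5)
  }
  stopifnot(length(d) == 5L, d[1] == model$spec$input_side,
            d[4] == model$spec$input_channels)
  P <- model$params
  buf_updates <- list()
  cache <- list(x = x5)
  bn_caches <- list()

  z <- .conv_fwd(x5, P[["stem.w"]], P[["stem.b"]], 2L, 3L, 1L)
  r <- .bn_apply(z, P, model$buffers, "stem_bn", training, buf_updates,
                 bn_caches)
  buf_updates <- r$updates; bn_caches <- r$caches
  cache$stem_pre <- r$y
  a <- .relu_fwd(r$y)

  pool <- .pool_fwd(a, 3L, 2L, 1L)
  cache$stem_a <- a
  cache$pool <- pool
  h <- pool$y

  cache$stage_in <- vector("list", 4)
  cache$block_caches <- vector("list", 4)
  for (s in 1:4) {
    nb <- length(model$blocks[[s]])
    cache$block_caches[[s]] <- vector("list", nb)
    for (b in seq_len(nb)) {
      r <- .block_forward(model, s, b, h, training, buf_updates)
      buf_updates <- r$buf_updates
      cache$block_caches[[s]][[b]] <- r$cache
      h <- r$y
    }
  }

  gap <- .gap_fwd(h)
  cache$gap <- gap
  f1 <- .fc_fwd(gap$y, P[["fc1.w"]], P[["fc1.b"]])
  cache$f1_pre <- f1
  cache$gap_y <- gap$y
  a1 <- .relu_fwd(f1)
  cache$fc1_a <- a1
  logits <- .fc_fwd(a1, P[["fc2.w"]], P[["fc2.b"]])
  cache$bn <- bn_caches

  buffers <- model$buffers
  for (nm in names(buf_updates)) buffers[[nm]] <- buf_updates[[nm]]
  list(logits = logits, cache = cache, buffers = buffers)
}

# ---- backward --------------------------------------------------------------

.block_backward <- function(model, s, b, cache, gout, grads) {
  P <- model$params
  blk <- model$blocks[[s]][[b]]
  sp <- blk$spec
  pre <- .block_prefix(s, b)
  bnc <- cache$bn

  dsum <- .relu_bwd(cache$sum_pre, gout)

  r <- .bn_bwd(bnc[[paste0(pre, ".expand_bn")]], dsum)
  grads[[paste0(pre, ".expand_bn.gamma")]] <- r$dgamma
  grads[[paste0(pre, ".expand_bn.beta")]] <- r$dbeta
  cb <- .conv_bwd(cache$a2, P[[paste0(pre, ".expand.w")]], r$gx, 1L, 0L, 1L)
  grads[[paste0(pre, ".expand.w")]] <- cb$gw
  grads[[paste0(pre, ".expand.b")]] <- cb$gb

  da2 <- .relu_bwd(cache$a2_pre, cb$gx)
  r <- .bn_bwd(bnc[[paste0(pre, ".group_bn")]], da2)
  grads[[paste0(pre, ".group_bn.gamma")]] <- r$dgamma
  grads[[paste0(pre, ".group_bn.beta")]] <- r$dbeta
  cb <- .conv_bwd(cache$a1, P[[paste0(pre, ".group.w")]], r$gx,
                  sp$stride, sp$padding, sp$cardinality_C)
  grads[[paste0(pre, ".group.w")]] <- cb$gw
  grads[[paste0(pre, ".group.b")]] <- cb$gb

  da1 <- .relu_bwd(cache$a1_pre, cb$gx)
  r <- .bn_bwd(bnc[[paste0(pre, ".reduce_bn")]], da1)
  grads[[paste0(pre, ".reduce_bn.gamma")]] <- r$dgamma
  grads[[paste0(pre, ".reduce_bn.beta")]] <- r$dbeta
  cb <- .conv_bwd(cache$x, P[[paste0(pre, ".reduce.w")]], r$gx, 1L, 0L, 1L)
  grads[[paste0(pre, ".reduce.w")]] <- cb$gw
  grads[[paste0(pre, ".reduce.b")]] <- cb$gb
  dx <- cb$gx

  if (blk$shortcut == "projection") {
    r <- .bn_bwd(bnc[[paste0(pre, ".shortcut_bn")]], dsum)
    grads[[paste0(pre, ".shortcut_bn.gamma")]] <- r$dgamma
    grads[[paste0(pre, ".shortcut_bn.beta")]] <- r$dbeta
    cb <- .conv_bwd(cache$x, P[[paste0(pre, ".shortcut.w")]], r$gx,
                    sp$stride, 0L, 1L)
    grads[[paste0(pre, ".shortcut.w")]] <- cb$gw
    grads[[paste0(pre, ".shortcut.b")]] <- cb$gb
    dx <- dx + cb$gx
  } else {
    dx <- dx + dsum
  }
  list(gx = dx, grads = grads)
}

#' Reverse-mode gradients of an ARCNN
#'
#' @param model The model used in the forward pass.
#' @param cache Forward cache from [arcnn_forward()] with
#'   `training = TRUE`.
#' @param dlogits Upstream gradient at the logits (`batch x num_classes`).
#' @return A named list of gradients matching `model$params`.
#' @export
arcnn_backward <- function(model, cache, dlogits) {
  P <- model$params
  grads <- list()

  fb <- .fc_bwd(cache$fc1_a, P[["fc2.w"]], dlogits)
  grads[["fc2.w"]] <- fb$gw
  grads[["fc2.b"]] <- fb$gb
  da1 <- .relu_bwd(cache$f1_pre, fb$gx)
  fb <- .fc_bwd(cache$gap_y, P[["fc1.w"]], da1)
  grads[["fc1.w"]] <- fb$gw
  grads[["fc1.b"]] <- fb$gb
  gh <- .gap_bwd(cache$gap, fb$gx)

  for (s in 4:1) {
    for (b in length(model$blocks[[s]]):1) {
      r <- .block_backward(model, s, b, cache$block_caches[[s]][[b]], gh,
                           grads)
      gh <- r$gx
      grads <- r$grads
    }
  }

  ga <- .pool_bwd(cache$pool, gh)
  dstem <- .relu_bwd(cache$stem_pre, ga)
  r <- .bn_bwd(cache$bn[["stem_bn"]], dstem)
  grads[["stem_bn.gamma"]] <- r$dgamma
  grads[["stem_bn.beta"]] <- r$dbeta
  cb <- .conv_bwd(cache$x, P[["stem.w"]], r$gx, 2L, 3L, 1L)
  grads[["stem.w"]] <- cb$gw
  grads[["stem.b"]] <- cb$gb

  grads[names(model$params)]
}

#' Minibatch loss and flat gradient
#'
#' Runs a training-mode forward pass, evaluates the cross-entropy loss on
#' the logits, and backpropagates to a flat gradient vector aligned with
#' `arcnn_flatten(model$params)`.
#'
#' @param model An `arcnn_model`.
#' @param x5 Batched input array.
#' @param labels Integer class labels (1-based).
#' @return A list with `loss`, `logits`, `grads` (flat vector) and
#'   `buffers` (updated running statistics).
#' @export
arcnn_loss_grads <- function(model, x5, labels) {
  fw <- arcnn_forward(model, x5, training = TRUE)
  ce <- .softmax_ce(fw$logits, labels)
  g <- arcnn_backward(model, fw$cache, ce$dlogits)
  list(loss = ce$loss, logits = fw$logits, grads = arcnn_flatten(g),
       buffers = fw$buffers)
}

#' Evaluation-mode prediction
#'
#' @param model An `arcnn_model`.
#' @param x5 Batched input array (or a single 4-d volume).
#' @return The `(batch, num_classes)` logit matrix.
#' @export
arcnn_predict <- function(model, x5) {
  arcnn_forward(model, x5, training = FALSE)$logits
}

# replace parameters from a flat vector (optimizer view)
.with_flat_params <- function(model, vec) {
  model$params <- arcnn_unflatten(vec, model$params)
  model
}

#' Save / load a model checkpoint
#'
#' Checkpoints use R's standard serialized form (RDS) and carry the spec,
#' parameters and batch-norm running statistics.
#'
#' @param model An `arcnn_model`.
#' @param path Checkpoint path (conventionally `.rds`).
#' @return `save_arcnn()` returns `path` invisibly; `load_arcnn()` returns
#'   the restored `arcnn_model`.
#' @export
save_arcnn <- function(model, path) {
  if (inherits(model, "arcnn_fit")) model <- model$model
  stopifnot(inherits(model, "arcnn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_arcnn
#' @export
load_arcnn <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "arcnn_model")) {
    stop("checkpoint does not contain an arcnn_model", call. = FALSE)
  }
  model
}
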