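# Bregman geometry: distance-generating functions (mirror maps), Bregman
# divergences, and the mirror-step argmin used by the SAMD iteration.

.ENTROPY_FLOOR <- 1e-12

#' Constraint-set descriptors
#'
#' Helpers describing the feasible set \eqn{\Omega} a mirror map lives on:
#' all of \eqn{R^d}, an axis-aligned box, or the probability simplex.
#'
#' @param lower,upper Numeric vectors of box bounds (recycled to the map
#'   dimension).
#' @return A list descriptor with a `type` field (`"all-space"`, `"box"` or
#'   `"simplex"`), used by [make_mirror_map()].
#' @examples
#' box_domain(0, 10)
#' simplex_domain()
#' @export
box_domain <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper), all(lower < upper))
  structure(list(type = "box", lower = lower, upper = upper),
            class = "samdnet_domain")
}

#' @rdname box_domain
#' @export
simplex_domain <- function() {
  structure(list(type = "simplex"), class = "samdnet_domain")
}

#' @rdname box_domain
#' @export
all_space <- function() {
  structure(list(type = "all-space"), class = "samdnet_domain")
}

.as_domain <- function(domain) {
  if (inherits(domain, "samdnet_domain")) return(domain)
  if (is.character(domain) && length(domain) == 1) {
    return(switch(domain,
      "all-space" = all_space(),
      "simplex"   = simplex_domain(),
      stop("unknown domain string: ", domain, call. = FALSE)
    ))
  }
  if (is.list(domain) && !is.null(domain$type)) {
    if (domain$type == "box") return(box_domain(domain$lower, domain$upper))
    return(.as_domain(domain$type))
  }
  stop("cannot interpret domain descriptor", call. = FALSE)
}

#' Construct a mirror map (distance-generating function)
#'
#' A mirror map is a strongly convex function \eqn{m(\cdot)} whose Bregman
#' divergence defines the geometry of the mirror-descent projection step.
#' Two kinds are supported: the Euclidean map \eqn{m(x) = \tfrac12\|x\|_2^2}
#' (1-strongly convex in the \eqn{\ell_2} norm, gradient the identity) on
#' all of space or a box, and the negative entropy
#' \eqn{m(x) = \sum_i x_i \log x_i} on the probability simplex
#' (1-strongly convex in the \eqn{\ell_1} norm by Pinsker's inequality,
#' gradient \eqn{1 + \log x_i}).
#'
#' @param kind `"euclidean"` or `"negative_entropy"`.
#' @param dimension Positive integer, the ambient dimension.
#' @param domain A descriptor from [box_domain()], [simplex_domain()],
#'   [all_space()], or the strings `"all-space"` / `"simplex"`.
#' @return An object of class `mirror_map` with fields `kind`, `dimension`,
#'   `domain`, `theta_m` (strong-convexity coefficient), `norm` (the
#'   reference norm, `"l2"` or `"l1"`), `value_fn` and `grad_fn`.
#' @examples
#' mm <- make_mirror_map("euclidean", 3, all_space())
#' mm$grad_fn(c(1, 2, 3))
#' @export
make_mirror_map <- function(kind = c("euclidean", "negative_entropy"),
                            dimension, domain = all_space()) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(dimension), length(dimension) == 1, dimension >= 1)
  dimension <- as.integer(dimension)
  domain <- .as_domain(domain)

  if (kind == "negative_entropy" && domain$type != "simplex") {
    stop("negative_entropy requires the probability simplex domain",
         call. = FALSE)
  }
  if (kind == "euclidean" && domain$type == "simplex") {
    stop("euclidean map on the simplex is not supported; ",
         "use negative_entropy or a box domain", call. = FALSE)
  }
  if (domain$type == "box") {
    domain$lower <- rep_len(domain$lower, dimension)
    domain$upper <- rep_len(domain$upper, dimension)
  }

  if (kind == "euclidean") {
    map <- list(
      kind = kind, dimension = dimension, domain = domain,
      theta_m = 1, norm = "l2",
      value_fn = function(x) 0.5 * sum(x^2),
      grad_fn  = function(x) x
    )
  } else {
    map <- list(
      kind = kind, dimension = dimension, domain = domain,
      theta_m = 1, norm = "l1",
      value_fn = function(x) sum(ifelse(x > 0, x * log(x), 0)),
      grad_fn  = function(x) 1 + log(x)
    )
  }
  structure(map, class = "mirror_map")
}

#' @export
print.mirror_map <- function(x, ...) {
  cat(sprintf("<mirror_map> kind=%s dim=%d domain=%s theta_m=%g norm=%s\n",
              x$kind, x$dimension, x$domain$type, x$theta_m, x$norm))
  invisible(x)
}

.ref_norm <- function(map, v) {
  if (map$norm == "l1") sum(abs(v)) else sqrt(sum(v^2))
}

# Pull a point into the interior of the map's domain. For the entropy map,
# coordinates below the floor are additively smoothed then renormalized
# (the gradient diverges on the simplex boundary).
.interior_point <- function(map, x) {
  if (map$kind == "negative_entropy") {
    if (any(x < .ENTROPY_FLOOR)) {
      x <- pmax(x, 0) + .ENTROPY_FLOOR
      x <- x / sum(x)
    }
  }
  x
}

.check_point <- function(map, x, what = "point") {
  if (length(x) != map$dimension) {
    stop(what, " has length ", length(x), ", expected ", map$dimension,
         call. = FALSE)
  }
  if (!all(is.finite(x))) stop(what, " has non-finite entries", call. = FALSE)
  if (map$domain$type == "box") {
    if (any(x < map$domain$lower - 1e-9) || any(x > map$domain$upper + 1e-9)) {
      stop(what, " lies outside the box domain", call. = FALSE)
    }
  }
  if (map$domain$type == "simplex") {
    if (any(x < -1e-9) || abs(sum(x) - 1) > 1e-6) {
      stop(what, " is not on the probability simplex", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Bregman divergence
#'
#' Computes \eqn{B_m(a, b) = m(a) - m(b) - \langle \nabla m(b), a - b\rangle},
#' the gap between \eqn{m(a)} and its first-order expansion around `b`.
#' It generalizes the squared Euclidean distance but is not symmetric and
#' satisfies no triangle inequality. Strong convexity of \eqn{m} gives the
#' lower bound \eqn{B_m(a,b) \ge \tfrac{\theta_m}{2}\|a-b\|^2} in the map's
#' reference norm; the returned `gap` is the slack of that bound.
#'
#' @param map A [make_mirror_map()] object.
#' @param a,b Points in the interior of the map's domain (`b` strictly
#'   interior for the entropy map).
#' @return A list of class `bregman_eval` with fields `value` (the
#'   divergence, nonnegative) and `gap`
#'   (`value - theta_m/2 * ||a-b||^2` under the reference norm).
#' @examples
#' mm <- make_mirror_map("euclidean", 2)
#' bregman_divergence(mm, c(1, 0), c(0, 0))$value  # 0.5
#' @export
bregman_divergence <- function(map, a, b) {
  stopifnot(inherits(map, "mirror_map"))
  a <- .interior_point(map, a)
  b <- .interior_point(map, b)
  .check_point(map, a, "a")
  .check_point(map, b, "b")
  value <- map$value_fn(a) - map$value_fn(b) - sum(map$grad_fn(b) * (a - b))
  gap <- value - map$theta_m / 2 * .ref_norm(map, a - b)^2
  structure(list(value = value, gap = gap), class = "bregman_eval")
}

#' The Eq.-(5)-style mirror-step objective
#'
#' The objective minimized by the mirror step:
#' \eqn{\alpha \langle g, x - x_t\rangle + \beta B_m(x, x_t)}.
#' Exposed so tests and the grid oracle can score candidate points.
#'
#' @inheritParams mirror_argmin
#' @param x Candidate point.
#' @return Scalar objective value.
#' @export
mirror_step_objective <- function(map, x_t, g, alpha, beta, x) {
  alpha * sum(g * (x - x_t)) + beta * bregman_divergence(map, x, x_t)$value
}

#' Mirror step: argmin of the linearized objective plus Bregman term
#'
#' Solves \eqn{x_{t+1} = \arg\min_{x \in \Omega}\{\alpha\langle g, x - x_t
#' \rangle + \beta B_m(x, x_t)\}} in closed form where one exists:
#' Euclidean/all-space gives \eqn{x_t - (\alpha/\beta) g}; Euclidean/box
#' clips that point coordinatewise; negative-entropy/simplex gives the
#' multiplicative-weights update
#' \eqn{x_{t+1,i} \propto x_{t,i} e^{-(\alpha/\beta) g_i}} renormalized.
#' For combinations with no closed form, a dense-grid minimizer is used
#' (dimension at most 3).
#'
#' @param map A [make_mirror_map()] object.
#' @param x_t Current iterate, interior to the domain.
#' @param g Subgradient estimate (finite vector).
#' @param alpha,beta Positive step and deviation-correction factors.
#' @return The minimizing point.
#' @examples
#' mm <- make_mirror_map("euclidean", 2)
#' mirror_argmin(mm, c(0, 0), c(1, -1), alpha = 1, beta = 2)  # (-0.5, 0.5)
#' @export
mirror_argmin <- function(map, x_t, g, alpha, beta) {
  stopifnot(inherits(map, "mirror_map"))
  if (!is.numeric(alpha) || alpha <= 0 || !is.numeric(beta) || beta <= 0) {
    stop("alpha and beta must be positive", call. = FALSE)
  }
  if (!all(is.finite(g))) stop("subgradient g has non-finite entries",
                               call. = FALSE)
  x_t <- .interior_point(map, x_t)
  .check_point(map, x_t, "x_t")
  step <- alpha / beta

  if (map$kind == "euclidean" && map$domain$type == "all-space") {
    return(x_t - step * g)
  }
  if (map$kind == "euclidean" && map$domain$type == "box") {
    return(pmin(pmax(x_t - step * g, map$domain$lower), map$domain$upper))
  }
  if (map$kind == "negative_entropy") {
    lw <- log(x_t) - step * g
    lw <- lw - max(lw)
    w <- exp(lw)
    return(w / sum(w))
  }
  mirror_argmin_grid(map, x_t, g, alpha, beta)$point
}

#' Dense-grid oracle for the mirror step
#'
#' Brute-force minimizer of [mirror_step_objective()] over a dense grid of
#' the domain, used as an independent check of the closed forms (and as the
#' fallback solver when no closed form exists). Only dimensions 1--3 are
#' supported; the per-axis resolution defaults to 1e-4, 2e-3 and 1e-2 of
#' the axis span for dimensions 1, 2 and 3.
#'
#' @inheritParams mirror_argmin
#' @param resolution Optional per-axis relative step.
#' @return A list with `point` (the best grid point) and `value` (its
#'   objective).
#' @export
mirror_argmin_grid <- function(map, x_t, g, alpha, beta, resolution = NULL) {
  stopifnot(inherits(map, "mirror_map"))
  d <- map$dimension
  if (d > 3) stop("grid oracle supports dimension <= 3 only", call. = FALSE)
  if (is.null(resolution)) resolution <- c(1e-4, 2e-3, 1e-2)[d]
  x_t <- .interior_point(map, x_t)
  step <- alpha / beta

  if (map$domain$type == "simplex") {
    eps <- max(resolution / 10, 1e-9)
    ax <- seq(eps, 1 - eps, by = resolution)
    if (d == 2) {
      X <- cbind(ax, 1 - ax)
    } else {
      gr <- expand.grid(x1 = ax, x2 = ax)
      keep <- gr$x1 + gr$x2 < 1 - eps
      gr <- gr[keep, , drop = FALSE]
      X <- cbind(gr$x1, gr$x2, 1 - gr$x1 - gr$x2)
    }
    m_xt <- map$value_fn(x_t)
    gm <- map$grad_fn(x_t)
    mx <- rowSums(X * log(X))
    breg <- mx - m_xt - as.vector((X - rep(x_t, each = nrow(X))) %*% gm)
    lin <- as.vector((X - rep(x_t, each = nrow(X))) %*% g)
    obj <- alpha * lin + beta * breg
    i <- which.min(obj)
    return(list(point = as.numeric(X[i, ]), value = obj[i]))
  }

  # euclidean on a box or all-space: grid a box certain to contain the optimum
  if (map$domain$type == "box") {
    lo <- map$domain$lower
    hi <- map$domain$upper
  } else {
    ctr <- x_t - step * g
    lo <- pmin(x_t, ctr) - 1
    hi <- pmax(x_t, ctr) + 1
  }
  axes <- lapply(seq_len(d), function(i) {
    seq(lo[i], hi[i], by = resolution * (hi[i] - lo[i]))
  })
  gr <- as.matrix(expand.grid(axes))
  diff <- gr - rep(x_t, each = nrow(gr))
  obj <- alpha * as.vector(diff %*% g) + beta * 0.5 * rowSums(diff^2)
  i <- which.min(obj)
  list(point = as.numeric(gr[i, ]), value = obj[i])
}

#' Three-point identity residual
#'
#' The Bregman three-point identity states
#' \eqn{B_m(p,r) - B_m(q,r) = B_m(p,q) + \langle \nabla m(q) - \nabla m(r),
#' p - q\rangle} for any interior triple. This function returns the residual
#' (left side minus right side), which is zero up to rounding; it is the
#' numeric check of the identity the SAMD convergence analysis rests on.
#'
#' @param map A [make_mirror_map()] object.
#' @param p,q,r Interior points.
#' @return Scalar residual (should be ~0).
#' @export
three_point_residual <- function(map, p, q, r) {
  stopifnot(inherits(map, "mirror_map"))
  p <- .interior_point(map, p)
  q <- .interior_point(map, q)
  r <- .interior_point(map, r)
  lhs <- bregman_divergence(map, p, r)$value -
    bregman_divergence(map, q, r)$value
  rhs <- bregman_divergence(map, p, q)$value +
    sum((map$grad_fn(q) - map$grad_fn(r)) * (p - q))
  lhs - rhs
}

# m-argmin over the domain: the Algorithm-1 initial point x0.
.mirror_map_init <- function(map) {
  switch(map$domain$type,
    "all-space" = rep(0, map$dimension),
    "box" = pmin(pmax(rep(0, map$dimension), map$domain$lower),
                 map$domain$upper),
    "simplex" = rep(1 / map$dimension, map$dimension)
  )
}
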