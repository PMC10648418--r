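# SAMD: stochastic unbiased subgradient accelerated mirror descent.
# The iteration couples a decaying step factor alpha_t with a
# bias-correction factor beta_t in the mirror step, estimates subgradients
# without bias at kinks, and returns a weighted average of the iterates.

#' Step factor of the SAMD iteration
#'
#' \eqn{\alpha_t = 1/(t+1)}: the weight on the linearized-objective term of
#' the mirror step, decaying harmonically so that the per-step term of the
#' convergence bound is \eqn{\alpha_t N^2 / (2\theta_m)}.
#'
#' @param t Nonnegative integer iteration counter.
#' @return \eqn{1/(t+1)}.
#' @export
step_factor <- function(t) {
  stopifnot(is.numeric(t), all(t >= 0))
  1 / (t + 1)
}

#' Deviation-correction factor of the SAMD iteration
#'
#' \eqn{\beta_t = 1/(1-\lambda^{t+1})} for \eqn{\lambda \in (0,1)}: starts at
#' \eqn{1/(1-\lambda)} and decreases monotonically toward 1, damping the
#' Bregman term early (momentum-style bias correction) and vanishing in
#' influence as the iterates settle.
#'
#' @param t Nonnegative integer iteration counter.
#' @param lam \eqn{\lambda \in (0,1)}.
#' @return \eqn{1/(1-\lambda^{t+1})}, always in \eqn{(1, 1/(1-\lambda)]}.
#' @export
correction_factor <- function(t, lam) {
  stopifnot(is.numeric(t), all(t >= 0))
  if (!is.numeric(lam) || any(lam <= 0) || any(lam >= 1)) {
    stop("lam must lie in (0, 1)", call. = FALSE)
  }
  1 / (1 - lam^(t + 1))
}

#' SAMD configuration
#'
#' @param lam Deviation-correction rate \eqn{\lambda \in (0,1)}; in practice
#'   chosen by grid search over `lam_grid` (see [select_lambda()]).
#' @param eps Stopping tolerance on \eqn{\|\bar x_{t+1} - \bar x_t\|_2}.
#' @param max_iter Iteration budget \eqn{n}.
#' @param n_subgrad_samples Number of subgradient draws averaged per step
#'   for nondifferentiable objectives.
#' @param seed Integer seed for the subgradient sampling stream.
#' @param lam_grid Candidate \eqn{\lambda} values for grid search.
#' @param beta_one If `TRUE`, force \eqn{\beta_t \equiv 1} (the WOBMD
#'   ablation: mirror descent without the bias-correction factor).
#' @return An object of class `samd_config`.
#' @export
samd_config <- function(lam = 0.5, eps = 1e-6, max_iter = 10000L,
                        n_subgrad_samples = 1L, seed = 1L,
                        lam_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                        beta_one = FALSE) {
  stopifnot(lam > 0, lam < 1, eps > 0, max_iter >= 1, n_subgrad_samples >= 1,
            all(lam_grid > 0), all(lam_grid < 1), is.logical(beta_one))
  structure(list(lam = lam, eps = eps, max_iter = as.integer(max_iter),
                 n_subgrad_samples = as.integer(n_subgrad_samples),
                 seed = as.integer(seed), lam_grid = sort(lam_grid),
                 beta_one = beta_one),
            class = "samd_config")
}

#' Subgradient oracle for a convex objective
#'
#' Wraps an objective \eqn{F}, a sampler drawing one element of the
#' subdifferential \eqn{\partial F(x)} (the gradient where \eqn{F} is
#' differentiable), and the uniform bound \eqn{N} on the expected
#' subgradient norm that the convergence bound uses.
#'
#' @param objective Function `x -> F(x)`.
#' @param subgrad_sampler Function `x -> vector`, one draw from
#'   \eqn{\partial F(x)} (uses the current RNG stream for random draws at
#'   kinks).
#' @param bound_N Positive bound on the Euclidean norm of subgradients over
#'   the feasible set.
#' @param theta_F Strong-convexity coefficient of `F` (0 if unknown).
#' @param differentiable If `TRUE`, the sampler is deterministic and a
#'   single draw is used regardless of `n_subgrad_samples`.
#' @return An object of class `subgradient_oracle`.
#' @export
subgradient_oracle <- function(objective, subgrad_sampler, bound_N,
                               theta_F = 0, differentiable = FALSE) {
  stopifnot(is.function(objective), is.function(subgrad_sampler),
            is.numeric(bound_N), bound_N > 0, theta_F >= 0)
  structure(list(objective = objective, subgrad_sampler = subgrad_sampler,
                 bound_N = bound_N, theta_F = theta_F,
                 differentiable = isTRUE(differentiable)),
            class = "subgradient_oracle")
}

#' Unbiased subgradient estimate
#'
#' For a differentiable objective, returns the gradient (one sampler draw);
#' otherwise returns the mean of `n_samples` independent draws
#' \eqn{f_j(x)} from the subdifferential, an unbiased estimate of
#' \eqn{E[\partial F(x)]}.
#'
#' @param oracle A [subgradient_oracle()].
#' @param x Point at which to estimate.
#' @param n_samples Number of draws for the nondifferentiable case.
#' @return The estimated subgradient vector; its Euclidean norm never
#'   exceeds `bound_N` (up to 1e-9).
#' @export
estimate_subgradient <- function(oracle, x, n_samples = 1L) {
  stopifnot(inherits(oracle, "subgradient_oracle"), n_samples >= 1)
  if (oracle$differentiable) {
    g <- oracle$subgrad_sampler(x)
  } else {
    draws <- vapply(seq_len(n_samples),
                    function(j) as.numeric(oracle$subgrad_sampler(x)),
                    numeric(length(x)))
    g <- if (length(x) == 1L) mean(draws) else rowMeans(draws)
  }
  if (!all(is.finite(g))) stop("subgradient sampler returned non-finite values",
                               call. = FALSE)
  if (sqrt(sum(g^2)) > oracle$bound_N + 1e-9) {
    stop("subgradient estimate exceeds the declared bound N", call. = FALSE)
  }
  g
}

#' Averaging-state update
#'
#' Advances the cumulative weight \eqn{S_t = \sum_{i=0}^{t} 1/\alpha_i}
#' (with \eqn{\alpha_i = 1/(i+1)} this is the triangular number
#' \eqn{(t+1)(t+2)/2}) and returns the next averaging weight
#' \eqn{\gamma_{t+1} = S_t / S_{t+1}}.
#'
#' @param S_t Current cumulative weight (positive).
#' @param t Current iteration counter.
#' @return A list with `S_next` and `gamma_next` \eqn{\in (0,1)}.
#' @export
averaging_state_update <- function(S_t, t) {
  stopifnot(is.numeric(S_t), S_t > 0, t >= 0)
  S_next <- S_t + (t + 2)  # 1 / alpha_{t+1}
  list(S_next = S_next, gamma_next = S_t / S_next)
}

#' Weighted iterate average
#'
#' One step of the running convex combination
#' \eqn{\bar x_{t+1} = \gamma_{t+1}\,\bar x_t + (1-\gamma_{t+1})\,x_{t+1}};
#' unrolled with the [averaging_state_update()] weights this equals
#' \eqn{\sum_i (i+1) x_i / S_t}.
#'
#' @param x_bar Current average.
#' @param x_next New iterate (same length).
#' @param gamma_next Weight in \eqn{[0,1]} on the old average.
#' @return The updated average.
#' @export
weighted_average <- function(x_bar, x_next, gamma_next) {
  if (length(x_bar) != length(x_next)) {
    stop("dimension mismatch in weighted_average", call. = FALSE)
  }
  stopifnot(gamma_next >= 0, gamma_next <= 1)
  gamma_next * x_bar + (1 - gamma_next) * x_next
}

#' Theoretical suboptimality bound
#'
#' The convergence guarantee for the averaged iterate of SAMD on a strongly
#' convex objective: \eqn{F(\bar x_t) - F^* \le N^2 / (2\theta_m (t+1))},
#' an \eqn{O(1/t)} rate.
#'
#' @param N Subgradient-norm bound.
#' @param theta_m Strong-convexity coefficient of the mirror map.
#' @param t Iteration counter.
#' @return The bound value, strictly decreasing in `t`.
#' @export
samd_rate_bound <- function(N, theta_m, t) {
  stopifnot(N > 0, theta_m > 0, all(t >= 0))
  N^2 / (2 * theta_m * (t + 1))
}

#' Minimize a convex objective with SAMD
#'
#' Runs the full SAMD iteration: initialize at the domain's m-minimizer
#' \eqn{x_0 = \arg\min_\Omega m(x)}, then repeat — step factor
#' \eqn{\alpha_t}, correction factor \eqn{\beta_t}, unbiased subgradient
#' estimate \eqn{h(x_t)}, mirror step, cumulative-weight update, weighted
#' average — until \eqn{\|\bar x_{t+1} - \bar x_t\|_2 < \varepsilon} or the
#' iteration budget is reached. The returned solution is the averaged
#' iterate \eqn{\bar x}.
#'
#' @param oracle A [subgradient_oracle()].
#' @param map A [make_mirror_map()] of matching dimension.
#' @param config A [samd_config()].
#' @return An object of class `samd_trace`: a list with `iterates` (a tibble
#'   with columns `t`, `objective` — \eqn{F(\bar x_t)} —, `step_norm`,
#'   `alpha`, `beta`, `gamma`), `solution` (\eqn{x^* = } final \eqn{\bar x}),
#'   `x_last` (the raw final iterate), `stop_reason`
#'   (`"eps_reached"`, `"max_iter"` or `"divergent"`) and `converged`.
#' @examples
#' prob <- convex_problem("quadratic-box")
#' tr <- samd_minimize(prob$oracle, prob$map, samd_config(max_iter = 500))
#' tr$solution
#' @export
samd_minimize <- function(oracle, map, config = samd_config()) {
  stopifnot(inherits(oracle, "subgradient_oracle"),
            inherits(map, "mirror_map"), inherits(config, "samd_config"))
  set.seed(config$seed)
  x <- .mirror_map_init(map)
  xbar <- x
  S <- 1  # S_0 = 1/alpha_0
  n <- config$max_iter
  tt <- integer(n); obj <- numeric(n); stepn <- numeric(n)
  al <- numeric(n); be <- numeric(n); ga <- numeric(n)
  stop_reason <- "max_iter"
  converged <- FALSE
  k <- 0L

  for (t in 0:(n - 1L)) {
    alpha <- step_factor(t)
    beta <- if (config$beta_one) 1 else correction_factor(t, config$lam)
    g <- estimate_subgradient(oracle, x, config$n_subgrad_samples)
    x_next <- mirror_argmin(map, x, g, alpha, beta)
    upd <- averaging_state_update(S, t)
    xbar_next <- weighted_average(xbar, x_next, upd$gamma_next)

    k <- k + 1L
    tt[k] <- t + 1L
    fval <- oracle$objective(xbar_next)
    obj[k] <- fval
    stepn[k] <- sqrt(sum((xbar_next - xbar)^2))
    al[k] <- alpha; be[k] <- beta; ga[k] <- upd$gamma_next

    x <- x_next; xbar <- xbar_next; S <- upd$S_next

    if (!is.finite(fval)) {
      stop_reason <- "divergent"
      warning("objective became non-finite; aborting with diagnostic trace",
              call. = FALSE)
      break
    }
    if (stepn[k] < config$eps) {
      stop_reason <- "eps_reached"
      converged <- TRUE
      break
    }
  }

  structure(list(
    iterates = tibble::tibble(t = tt[1:k], objective = obj[1:k],
                              step_norm = stepn[1:k], alpha = al[1:k],
                              beta = be[1:k], gamma = ga[1:k]),
    solution = xbar, x_last = x,
    stop_reason = stop_reason, converged = converged,
    config = config, map_kind = map$kind
  ), class = "samd_trace")
}

#' @export
print.samd_trace <- function(x, ...) {
  n <- nrow(x$iterates)
  cat(sprintf("<samd_trace> %d iterations, stop: %s\n", n, x$stop_reason))
  cat(sprintf("  final objective F(x_bar) = %.6g\n",
              x$iterates$objective[n]))
  cat("  solution:", format(x$solution, digits = 6), "\n")
  invisible(x)
}

#' Select the correction rate by grid search
#'
#' Runs SAMD for a fixed iteration budget at each candidate \eqn{\lambda}
#' and returns the value attaining the lowest final objective.
#'
#' @param oracle,map,config As in [samd_minimize()]; `config$lam_grid`
#'   supplies the candidates.
#' @param budget Iterations per candidate.
#' @return A list with `lam` (the selected value) and `results` (a tibble of
#'   candidate, final objective).
#' @export
select_lambda <- function(oracle, map, config = samd_config(), budget = 200L) {
  res <- vapply(config$lam_grid, function(l) {
    cfg <- config
    cfg$lam <- l
    cfg$max_iter <- as.integer(budget)
    cfg$eps <- .Machine$double.xmin  # run the full budget
    tr <- samd_minimize(oracle, map, cfg)
    tr$iterates$objective[nrow(tr$iterates)]
  }, numeric(1))
  list(lam = config$lam_grid[which.min(res)],
       results = tibble::tibble(lam = config$lam_grid, final_objective = res))
}

#' Write an optimizer trace as a delimited table
#'
#' @param trace A `samd_trace`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "samd_trace"))
  utils::write.table(trace$iterates, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# ---- network-parameter form ------------------------------------------------

#' Initial state for SAMD network training
#'
#' @param params Flat numeric parameter vector.
#' @return A list of class `samd_state` with counter `t`, cumulative weight
#'   `S`, the running parameter average `x_bar`, and the last
#'   `alpha`/`beta`/`gamma`.
#' @export
samd_state_init <- function(params) {
  structure(list(t = 0L, S = 1, x_bar = params,
                 alpha = NA_real_, beta = NA_real_, gamma = NA_real_),
            class = "samd_state")
}

#' One SAMD update of flat network parameters
#'
#' The Euclidean unconstrained instantiation of the mirror step for network
#' training: \eqn{x_{t+1} = x_t - (\alpha_t/\beta_t)\, \eta\, g} with base
#' learning rate \eqn{\eta}, followed by the cumulative-weight and running-
#' average updates. Evaluation uses the averaged parameters in
#' `state$x_bar`.
#'
#' @param params Flat parameter vector.
#' @param grads Flat minibatch-loss gradient (one subgradient sample).
#' @param state A [samd_state_init()] state.
#' @param config A [samd_config()].
#' @param base_lr Base learning-rate multiplier \eqn{\eta}.
#' @return A list with `params` (updated) and `state` (advanced by one).
#' @export
samd_network_step <- function(params, grads, state, config, base_lr = 0.01) {
  stopifnot(inherits(state, "samd_state"), inherits(config, "samd_config"),
            length(params) == length(grads))
  if (!all(is.finite(grads))) {
    stop("non-finite gradients in samd_network_step", call. = FALSE)
  }
  t <- state$t
  alpha <- step_factor(t)
  beta <- if (config$beta_one) 1 else correction_factor(t, config$lam)
  params_next <- params - (alpha / beta) * base_lr * grads
  upd <- averaging_state_update(state$S, t)
  x_bar <- weighted_average(state$x_bar, params_next, upd$gamma_next)
  state_next <- structure(list(t = t + 1L, S = upd$S_next, x_bar = x_bar,
                               alpha = alpha, beta = beta,
                               gamma = upd$gamma_next),
                          class = "samd_state")
  list(params = params_next, state = state_next)
}

# ---- convex test problems --------------------------------------------------

#' Convex benchmark problems for the optimizer
#'
#' Three canonical problems with known optima, used to exercise the
#' convergence theory directly:
#' \describe{
#'   \item{`"quadratic-box"`}{\eqn{F(x) = (x-2)^2} on the box
#'     \eqn{[0, 10]} (Euclidean map). Differentiable, 2-strongly convex,
#'     subgradient bound \eqn{N = 16}, optimum \eqn{F^* = 0} at \eqn{x=2}.}
#'   \item{`"linear-simplex"`}{\eqn{F(x) = \langle c, x\rangle} with
#'     \eqn{c = (1.0, 0.5, 2.0)} on the 3-simplex (entropy map). Optimum
#'     \eqn{F^* = 0.5} at the vertex of minimal cost.}
#'   \item{`"l1-kink"`}{\eqn{F(x) = |x|} on the line (Euclidean map), with
#'     the subgradient at the kink sampled uniformly from \eqn{[-1, 1]}.
#'     Optimum \eqn{F^* = 0} at \eqn{x = 0}.}
#' }
#'
#' @param name One of `"quadratic-box"`, `"linear-simplex"`, `"l1-kink"`.
#' @return A list with `oracle`, `map`, `f_star`, `x_star` and `name`.
#' @export
convex_problem <- function(name = c("quadratic-box", "linear-simplex",
                                    "l1-kink")) {
  name <- match.arg(name)
  switch(name,
    "quadratic-box" = {
      map <- make_mirror_map("euclidean", 1, box_domain(0, 10))
      oracle <- subgradient_oracle(
        objective = function(x) (x - 2)^2,
        subgrad_sampler = function(x) 2 * (x - 2),
        bound_N = 16, theta_F = 2, differentiable = TRUE
      )
      list(oracle = oracle, map = map, f_star = 0, x_star = 2, name = name)
    },
    "linear-simplex" = {
      cc <- c(1.0, 0.5, 2.0)
      map <- make_mirror_map("negative_entropy", 3, simplex_domain())
      oracle <- subgradient_oracle(
        objective = function(x) sum(cc * x),
        subgrad_sampler = function(x) cc,
        bound_N = sqrt(sum(cc^2)), theta_F = 0, differentiable = TRUE
      )
      list(oracle = oracle, map = map, f_star = 0.5,
           x_star = c(0, 1, 0), name = name)
    },
    "l1-kink" = {
      map <- make_mirror_map("euclidean", 1, all_space())
      oracle <- subgradient_oracle(
        objective = function(x) abs(x),
        subgrad_sampler = function(x) {
          if (x > 0) 1 else if (x < 0) -1 else stats::runif(1, -1, 1)
        },
        bound_N = 1, theta_F = 0, differentiable = FALSE
      )
      list(oracle = oracle, map = map, f_star = 0, x_star = 0, name = name)
    }
  )
}
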