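# Shared test utilities: numeric differentiation, random domain points and
# the separable phantom task used by the end-to-end training checks.

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# random strictly interior simplex point (Dirichlet-like, floored away from
# the boundary so entropy gradients stay well scaled)
r_simplex <- function(d, floor = 1e-3) {
  x <- stats::rgamma(d, shape = 2) + floor
  x / sum(x)
}

r_box <- function(lower, upper, margin = 0.05) {
  span <- upper - lower
  stats::runif(length(lower), lower + margin * span, upper - margin * span)
}

# the strongly separated noiseless phantom task (AD atrophy 0.5) used by
# the training acceptance checks; cube side 32 after preprocessing
separable_cohort <- function(subjects = c(AD = 10, NC = 10),
                             images_per_subject = 3L, seed = 101L) {
  pp <- phantom_params(base_side = 48, noise_sd = 0,
                       atrophy_factor = c(NC = 1.0, sMCI = 0.9,
                                          pMCI = 0.8, AD = 0.5),
                       seed = seed)
  preprocess_cohort(
    generate_cohort(pp, subjects, images_per_subject, seed = seed), 32)
}
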