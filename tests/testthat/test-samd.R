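test_that("step and correction factors follow their closed forms", {
  expect_equal(step_factor(0), 1)
  expect_equal(step_factor(3), 0.25)
  expect_equal(step_factor(9), 0.1)
  expect_error(step_factor(-1))

  expect_equal(correction_factor(0, 0.5), 2)
  expect_equal(correction_factor(1, 0.5), 4 / 3)
  expect_equal(correction_factor(200, 0.5), 1, tolerance = 1e-12)
  expect_error(correction_factor(1, 1.2), "lam")
  expect_error(correction_factor(1, 0), "lam")

  # beta_t in (1, 1/(1-lam)], monotone nonincreasing toward 1 (reaching it
  # only when lam^(t+1) underflows)
  for (lam in c(0.1, 0.5, 0.9)) {
    b <- correction_factor(0:300, lam)
    expect_true(all(b >= 1))
    expect_gt(b[1], 1)
    expect_lte(b[1], 1 / (1 - lam) + 1e-15)
    expect_true(all(diff(b) <= 0))
  }
})

test_that("cumulative weights telescope and averaging weights stay in (0,1)", {
  expect_equal(averaging_state_update(1, 0), list(S_next = 3,
                                                  gamma_next = 1 / 3))
  expect_equal(averaging_state_update(3, 1), list(S_next = 6,
                                                  gamma_next = 0.5))
  expect_equal(averaging_state_update(55, 9), list(S_next = 66,
                                                   gamma_next = 5 / 6))
  S <- 1
  for (t in 0:50) {
    upd <- averaging_state_update(S, t)
    expect_equal(upd$S_next - S, 1 / step_factor(t + 1))  # S_t - S_{t-1}
    expect_gt(upd$gamma_next, 0)
    expect_lt(upd$gamma_next, 1)
    # closed form (t+2)(t+3)/2 for S_{t+1}
    expect_equal(upd$S_next, (t + 2) * (t + 3) / 2)
    S <- upd$S_next
  }
})

test_that("the recursive average equals the explicit (i+1)-weighted sum", {
  expect_identical(weighted_average(c(1, 2), c(9, 9), 1), c(1, 2))
  expect_identical(weighted_average(c(1, 2), c(9, 9), 0), c(9, 9))
  expect_error(weighted_average(1:2, 1:3, 0.5), "dimension")

  set.seed(3)
  xs <- matrix(rnorm(33), nrow = 11)  # iterates x_0..x_10, 3 coords
  xbar <- xs[1, ]
  S <- 1
  for (t in 0:9) {
    upd <- averaging_state_update(S, t)
    xbar <- weighted_average(xbar, xs[t + 2, ], upd$gamma_next)
    S <- upd$S_next
  }
  explicit <- colSums(xs * (1:11)) / sum(1:11)  # S_10 = 66
  expect_equal(xbar, explicit, tolerance = 1e-12)
})

test_that("subgradient estimation is unbiased and bounded", {
  quad <- subgradient_oracle(function(x) x^2, function(x) 2 * x,
                             bound_N = 100, differentiable = TRUE)
  expect_equal(estimate_subgradient(quad, 3), 6)

  kink <- convex_problem("l1-kink")$oracle
  set.seed(4)
  g <- estimate_subgradient(kink, 0, n_samples = 10000)
  expect_lt(abs(g), 0.05)  # 8-sigma Monte-Carlo envelope
  for (i in 1:50) {
    expect_lte(abs(estimate_subgradient(kink, 0)), 1)
  }
  bad <- subgradient_oracle(function(x) x, function(x) NaN, bound_N = 1)
  expect_error(estimate_subgradient(bad, 0), "non-finite")
})

test_that("SAMD solves the box quadratic and respects the rate bound", {
  prob <- convex_problem("quadratic-box")
  tr <- samd_minimize(prob$oracle, prob$map,
                      samd_config(max_iter = 5000, eps = 1e-8))
  expect_lt(abs(tr$solution - 2), 1e-2)
  it <- tr$iterates
  bound <- samd_rate_bound(prob$oracle$bound_N, prob$map$theta_m, it$t)
  expect_true(all(it$objective - prob$f_star <= bound + 1e-12))
})

test_that("SAMD solves the simplex linear program", {
  prob <- convex_problem("linear-simplex")
  tr <- samd_minimize(prob$oracle, prob$map,
                      samd_config(max_iter = 2000, eps = 1e-14))
  # direct vertex enumeration of the LP optimum
  cc <- c(1.0, 0.5, 2.0)
  f_star <- min(cc)
  expect_equal(f_star, prob$f_star)
  expect_lt(prob$oracle$objective(tr$solution) - f_star, 0.05)
})

test_that("a zero subgradient oracle stops at the first convergence check", {
  zero <- subgradient_oracle(function(x) 0, function(x) c(0, 0),
                             bound_N = 1, differentiable = TRUE)
  map <- make_mirror_map("euclidean", 2)
  tr <- samd_minimize(zero, map, samd_config(max_iter = 100))
  expect_identical(tr$stop_reason, "eps_reached")
  expect_equal(nrow(tr$iterates), 1L)
  expect_equal(tr$solution, c(0, 0))  # x* = x_0
})

test_that("identical seeds give bitwise-identical traces", {
  prob <- convex_problem("l1-kink")
  cfg <- samd_config(max_iter = 300, eps = 1e-14, n_subgrad_samples = 3,
                     seed = 42L)
  tr1 <- samd_minimize(prob$oracle, prob$map, cfg)
  tr2 <- samd_minimize(prob$oracle, prob$map, cfg)
  expect_identical(tr1$iterates, tr2$iterates)
  expect_identical(tr1$solution, tr2$solution)
})

test_that("the correction factor is not needed for convergence (ablation)", {
  for (beta_one in c(FALSE, TRUE)) {
    for (name in c("quadratic-box", "linear-simplex")) {
      prob <- convex_problem(name)
      tr <- samd_minimize(prob$oracle, prob$map,
                          samd_config(max_iter = 2000, eps = 1e-14,
                                      beta_one = beta_one))
      gap <- prob$oracle$objective(tr$solution) - prob$f_star
      expect_lt(gap, 0.05)
    }
  }
})

test_that("the network step matches the solver on a deterministic quadratic", {
  expect_equal(
    samd_network_step(0, 1, samd_state_init(0),
                      samd_config(lam = 0.5), base_lr = 1)$params,
    -0.5)
  st <- samd_network_step(c(1, 2), c(0, 0), samd_state_init(c(1, 2)),
                          samd_config(), base_lr = 1)
  expect_identical(st$params, c(1, 2))
  expect_identical(st$state$x_bar, c(1, 2))
  expect_error(samd_network_step(0, NaN, samd_state_init(0), samd_config()),
               "non-finite")

  # unconstrained quadratic: the two code paths implement the same recursion
  map <- make_mirror_map("euclidean", 1, all_space())
  oracle <- subgradient_oracle(function(x) (x - 2)^2,
                               function(x) 2 * (x - 2),
                               bound_N = 1000, differentiable = TRUE)
  cfg <- samd_config(lam = 0.5, eps = 1e-300, max_iter = 100)
  tr <- samd_minimize(oracle, map, cfg)

  p <- 0
  state <- samd_state_init(p)
  objs <- numeric(100)
  for (t in 1:100) {
    g <- 2 * (p - 2)
    st <- samd_network_step(p, g, state, cfg, base_lr = 1)
    p <- st$params
    state <- st$state
    objs[t] <- (state$x_bar - 2)^2
  }
  expect_equal(objs, tr$iterates$objective, tolerance = 1e-10)
  expect_equal(state$x_bar, tr$solution, tolerance = 1e-10)
})

test_that("lambda grid search returns a candidate from the grid", {
  prob <- convex_problem("quadratic-box")
  sel <- select_lambda(prob$oracle, prob$map, samd_config(), budget = 50)
  expect_true(sel$lam %in% samd_config()$lam_grid)
  expect_equal(nrow(sel$results), 5)
  expect_true(all(is.finite(sel$results$final_objective)))
})

test_that("rate-bound values follow the closed form", {
  expect_equal(samd_rate_bound(1, 1, 0), 0.5)
  expect_equal(samd_rate_bound(1, 1, 99), 0.005)
  expect_equal(samd_rate_bound(2, 0.5, 3), 1)
  expect_error(samd_rate_bound(-1, 1, 0))
})

test_that("traces export and tidy into tables", {
  prob <- convex_problem("quadratic-box")
  tr <- samd_minimize(prob$oracle, prob$map, samd_config(max_iter = 20))
  td <- tidy(tr)
  expect_named(td, c("t", "objective", "step_norm", "alpha", "beta",
                     "gamma"))
  gl <- glance(tr)
  expect_equal(gl$iterations, nrow(td))
  f <- tempfile(fileext = ".tsv")
  write_trace(tr, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(td))
  expect_s3_class(autoplot(tr), "ggplot")
})
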