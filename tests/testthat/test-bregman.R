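test_that("mirror maps satisfy their defining identities", {
  mm <- make_mirror_map("euclidean", 3, all_space())
  expect_equal(mm$theta_m, 1)
  x <- c(1.5, -2, 0.25)
  expect_identical(mm$grad_fn(x), x)
  expect_equal(mm$value_fn(x), 0.5 * sum(x^2))

  me <- make_mirror_map("negative_entropy", 4, simplex_domain())
  p <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(me$grad_fn(p), 1 + log(p))
  expect_equal(me$theta_m, 1)
  expect_identical(me$norm, "l1")

  expect_error(make_mirror_map("negative_entropy", 4, all_space()),
               "simplex")
  expect_error(make_mirror_map("hyperbolic", 2), "arg")
})

test_that("Bregman divergence matches its closed forms", {
  mm <- make_mirror_map("euclidean", 2)
  expect_equal(bregman_divergence(mm, c(1, 0), c(0, 0))$value, 0.5)
  expect_equal(bregman_divergence(mm, c(0.3, -1), c(0.3, -1))$value, 0)

  # entropy divergence equals the Kullback-Leibler sum
  me <- make_mirror_map("negative_entropy", 2, simplex_domain())
  a <- c(0.5, 0.5); b <- c(0.25, 0.75)
  kl <- sum(a * log(a / b))
  expect_equal(bregman_divergence(me, a, b)$value, kl, tolerance = 1e-12)
  expect_equal(kl, 0.1438410362, tolerance = 1e-9)
})

test_that("divergence is nonnegative and dominates the strong-convexity bound", {
  set.seed(1)
  mm <- make_mirror_map("euclidean", 3)
  me <- make_mirror_map("negative_entropy", 3, simplex_domain())
  for (i in 1:1000) {
    a <- rnorm(3); b <- rnorm(3)
    ev <- bregman_divergence(mm, a, b)
    expect_gte(ev$value, -1e-12)
    expect_gte(ev$gap, -1e-10)  # value >= theta/2 ||a-b||^2
    p <- r_simplex(3); q <- r_simplex(3)
    ev <- bregman_divergence(me, p, q)
    expect_gte(ev$value, -1e-12)
    expect_gte(ev$gap, -1e-10)  # Pinsker: KL >= 1/2 |p-q|_1^2
  }
})

test_that("mirror step closed forms are exact", {
  mm <- make_mirror_map("euclidean", 2)
  expect_equal(mirror_argmin(mm, c(0, 0), c(1, -1), 1, 2), c(-0.5, 0.5))
  expect_equal(mirror_argmin(mm, c(0.4, -3), c(0, 0), 1, 7), c(0.4, -3))

  mb <- make_mirror_map("euclidean", 1, box_domain(0, 1))
  expect_equal(mirror_argmin(mb, 0.5, 10, 1, 1), 0)

  me <- make_mirror_map("negative_entropy", 2, simplex_domain())
  # weights (0.5 e^{-log 4}, 0.5) = (0.125, 0.5), renormalized
  x1 <- mirror_argmin(me, c(0.5, 0.5), c(log(4), 0), 1, 1)
  expect_equal(x1, c(0.2, 0.8), tolerance = 1e-12)
  g <- mirror_argmin_grid(me, c(0.5, 0.5), c(log(4), 0), 1, 1)
  expect_lte(mirror_step_objective(me, c(0.5, 0.5), c(log(4), 0), 1, 1, x1),
             g$value + 1e-6)

  expect_error(mirror_argmin(mm, c(0, 0), c(1, 1), -1, 1), "positive")
  expect_error(mirror_argmin(mm, c(0, 0), c(1, 1), 1, 0), "positive")
})

test_that("three-point identity residual vanishes on random triples", {
  set.seed(2)
  mm <- make_mirror_map("euclidean", 3)
  me <- make_mirror_map("negative_entropy", 3, simplex_domain())
  expect_lt(abs(three_point_residual(me, c(.2, .3, .5), c(.2, .3, .5),
                                     c(.6, .2, .2))), 1e-12)
  for (i in 1:200) {
    expect_lt(abs(three_point_residual(mm, rnorm(3), rnorm(3), rnorm(3))),
              1e-10)
    expect_lt(abs(three_point_residual(me, r_simplex(3), r_simplex(3),
                                       r_simplex(3))), 1e-10)
  }
})

test_that("boundary points are pulled into the entropy domain", {
  me <- make_mirror_map("negative_entropy", 3, simplex_domain())
  ev <- bregman_divergence(me, c(0, 0.5, 0.5), c(1 / 3, 1 / 3, 1 / 3))
  expect_true(is.finite(ev$value))
  expect_gte(ev$value, 0)
})
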