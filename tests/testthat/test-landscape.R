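test_that("stationary variance of a linear system is D/k, exactly", {
  ou <- make_toy("ou1d", k = 2, g = 1)
  m <- solve_moments(ou, 0.5, D = 0.02)
  expect_equal(unname(m$var), 0.02 / 2)
  # 2-D decoupled linear system: per-coordinate variances D/k_i
  net <- decoupled_linear(g = c(1, 1), k = c(1, 2))
  m2 <- solve_moments(net, c(1, 0.5), D = 0.01)
  expect_equal(unname(m2$var), c(0.01 / 1, 0.01 / 2))
  expect_true(m2$converged)
})

test_that("moment solver refuses unstable fixed points", {
  dw <- make_toy("double_well_1d")
  expect_error(solve_moments(dw, 0, D = 0.01), "not stable")
})

test_that("mean-field toggle variances match Langevin marginals within 15%", {
  net <- toggle()
  as <- toggle_attractors()
  ss <- stable_states(as, full = FALSE)
  m <- solve_moments(net, ss[1, ], D = 0.01)
  ens <- simulate_langevin(net, D = 0.01, n_traj = 60, dt = 0.005, T = 60,
                           seed = 11, x0 = ss[1, , drop = FALSE],
                           burn_in = 0.3)
  emp <- apply(caclandscape:::ensemble_samples(ens), 2, var)
  expect_lt(max(abs(m$var - emp) / emp), 0.15)
})

test_that("a single linear attractor gives a quadratic well at g/k", {
  ou <- make_toy("ou1d", k = 2, g = 1)
  as <- find_attractors(ou, n_starts = 12, seed = 1, t_long = 50)
  ls <- build_landscape(ou, as, D = 0.02)
  # U(x) = -ln N(x; 0.5, D/k): curvature k/(2D) * 2, minimum at 0.5
  comp <- ls$components[[1]]
  expect_equal(unname(comp$mean), 0.5, tolerance = 1e-6)
  x <- seq(0.3, 0.7, by = 0.01)
  U <- -log(dnorm(x, comp$mean, sqrt(comp$var)))
  fit <- lm(U ~ poly(x, 2, raw = TRUE))
  expect_equal(unname(coef(fit)[3]), 1 / (2 * 0.02 / 2), tolerance = 1e-6)
})

test_that("toggle landscape is swap-symmetric with equal-depth minima", {
  net <- toggle()
  as <- toggle_attractors()
  ls <- build_landscape(net, as, D = 0.01, weights = "equal")
  proj <- project_landscape(ls, c("A", "B"), n_grid = 101)
  expect_equal(proj$U, t(proj$U), tolerance = 1e-8)
  mins <- local_minima(proj)
  expect_equal(nrow(mins), 2)
  expect_equal(mins$U[1], mins$U[2], tolerance = 1e-6)
})

test_that("exp(-U) integrates to 1 on the projection grid", {
  net <- toggle()
  as <- toggle_attractors()
  ls <- build_landscape(net, as, D = 0.01, weights = "equal")
  proj <- project_landscape(ls, c("A", "B"), n_grid = 201)
  dx <- diff(proj$x[1:2]); dy <- diff(proj$y[1:2])
  mass <- sum(exp(-proj$U)) * dx * dy
  expect_equal(mass, 1, tolerance = 0.01)
})

test_that("marginal projection of one Gaussian component is that Gaussian", {
  net <- decoupled_linear(g = c(1, 1), k = c(1, 2))
  as <- find_attractors(net, n_starts = 12, seed = 1, t_long = 50)
  ls <- build_landscape(net, as, D = 0.01)
  proj <- project_landscape(ls, c("X1", "X2"), n_grid = 81)
  comp <- ls$components[[1]]
  U_exact <- outer(-log(dnorm(proj$x, comp$mean[1], sqrt(comp$var[1]))),
                   -log(dnorm(proj$y, comp$mean[2], sqrt(comp$var[2]))), "+")
  expect_equal(proj$U, U_exact, tolerance = 1e-8)
})

test_that("minima barely move when D drops tenfold", {
  net <- toggle()
  as <- toggle_attractors()
  loc <- lapply(c(0.01, 0.001), function(D) {
    ls <- build_landscape(net, as, D = D, weights = "equal")
    proj <- project_landscape(ls, c("A", "B"), n_grid = 101,
                              limits = list(c(0, 9), c(0, 9)))
    m <- local_minima(proj)
    m[order(m$x), c("x", "y")]
  })
  cell <- 9 / 100
  expect_lt(max(abs(as.matrix(loc[[1]]) - as.matrix(loc[[2]]))), cell + 1e-9)
})

test_that("PC projection reports the same number of basins as a gene pair", {
  net <- toggle()
  as <- toggle_attractors()
  ls <- build_landscape(net, as, D = 0.01, weights = "equal")
  pj1 <- project_landscape(ls, c("A", "B"), n_grid = 81)
  pj2 <- project_landscape(ls, "pc", n_grid = 81, n_samples = 30000, seed = 3)
  # kernel-density tails are noisy; count basins within 6 log-units of the
  # deepest (the two equal-weight wells sit well inside that band)
  expect_equal(nrow(local_minima(pj1, max_depth = 6)),
               nrow(local_minima(pj2, max_depth = 6)))
})
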