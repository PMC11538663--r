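test_that("a path following the deterministic flow has (near) zero action", {
  net <- toggle()
  vf <- as_vector_field(net)
  # integrate the flow from a perturbed state and use the trajectory itself
  x <- c(7, 0.4)
  P <- matrix(NA_real_, 2001, 2)
  P[1, ] <- x
  dt <- 0.005
  for (i in 2:2001) {
    x <- pmax(x + dt * as.numeric(caclandscape:::vf_f_active(vf, matrix(x, 1))), 0)
    P[i, ] <- x
  }
  expect_lt(path_action(P, net, T = 2000 * dt), 1e-4)
})

test_that("uphill traversal of a gradient field costs 2 * potential gain", {
  dw <- make_toy("double_well_1d")
  V <- dw$facts$V
  # integrate phi-dot = +V'(phi) from a to b, feed the sampled path back in
  a <- -0.95; b <- -0.15
  x <- a; dt <- 0.002; xs <- x
  while (x < b) { x <- x + dt * (x^3 - x); xs <- c(xs, x) }
  S <- path_action(matrix(xs, ncol = 1), dw, T = (length(xs) - 1) * dt)
  expect_equal(S, 2 * (V(xs[length(xs)]) - V(a)), tolerance = 5e-3)
})

test_that("discretized action matches an independent fine-quadrature oracle", {
  net <- toggle()
  as <- toggle_attractors()
  ss <- stable_states(as, full = FALSE)
  P <- caclandscape:::straight_path(ss[1, ], ss[2, ], 200)
  S <- path_action(P, net, T = 20)
  S_oracle <- action_oracle(P, net, T = 20, refine = 50)
  expect_equal(S, S_oracle, tolerance = 1e-4)
})

test_that("degenerate paths are rejected", {
  net <- toggle()
  P <- caclandscape:::straight_path(c(0, 1), c(1, 0), 10)
  expect_error(path_action(P, net, T = 0), "positive")
  expect_error(path_action(P[1:2, ], net, T = 1), "3 points")
})

test_that("double-well MAP action equals twice the barrier height", {
  dw <- make_toy("double_well_1d")
  p <- minimize_action(dw, from = -1, to = 1, N = 200,
                       T_sweep = c(10, 20, 40))
  expect_equal(p$action, dw$facts$map_action, tolerance = 0.02)
  # the path passes through the saddle at 0
  expect_lt(min(abs(p$states)), 1e-2)
  expect_lte(p$action, p$action_straight)
})

test_that("symmetric toggle has equal forward and reverse MAP actions", {
  net <- toggle()
  as <- toggle_attractors()
  ss <- stable_states(as, full = FALSE)
  fwd <- minimize_action(net, ss[1, ], ss[2, ], N = 60, T_sweep = c(10, 20, 40))
  rev <- minimize_action(net, ss[2, ], ss[1, ], N = 60, T_sweep = c(10, 20, 40))
  expect_equal(fwd$action, rev$action, tolerance = 1e-3)
  # minimization property: MAP <= straight line <= perturbed path
  expect_lte(fwd$action, fwd$action_straight + 1e-12)
  set.seed(1)
  P <- fwd$states[, as$active]
  P[2:60, ] <- pmax(P[2:60, ] + matrix(rnorm(59 * 2, sd = 0.1), 59, 2), 0)
  expect_gt(path_action(P, net, T = fwd$T), fwd$action)
})

test_that("MAP action converges under path refinement", {
  dw <- make_toy("double_well_1d")
  p1 <- minimize_action(dw, -1, 1, N = 100, T_sweep = c(20, 40))
  p2 <- minimize_action(dw, -1, 1, N = 200, T_sweep = c(20, 40))
  expect_lt(abs(p1$action - p2$action) / p2$action, 0.005)
})

test_that("action matrix is zero for one attractor, symmetric for the toggle", {
  ou <- make_toy("ou1d", k = 1, g = 1)
  as1 <- find_attractors(ou, n_starts = 10, seed = 1, t_long = 50)
  am1 <- action_matrix(ou, as1)
  expect_equal(unclass(am1), matrix(0, 1, 1, dimnames = list("a1", "a1")),
               ignore_attr = TRUE)
  net <- toggle()
  as2 <- toggle_attractors()
  am2 <- action_matrix(net, as2, N = 60, T_sweep = c(10, 20, 40))
  expect_equal(am2[1, 2], am2[2, 1], tolerance = 1e-3)
  expect_equal(diag(unclass(am2)), c(a1 = 0, a2 = 0))
})

test_that("escape from the shallow well is cheaper than from the deep well", {
  tw <- make_toy("tilted_well", h = 0.15)
  cp <- tw$facts$critical_points
  lo <- min(cp); hi <- max(cp)  # right well is deeper for h > 0
  S_shallow <- minimize_action(tw, lo, hi, N = 150, T_sweep = c(20, 40))$action
  S_deep <- minimize_action(tw, hi, lo, N = 150, T_sweep = c(20, 40))$action
  expect_lt(S_shallow, S_deep)
  # gradient-system identity 2*dV on the tilted potential, both directions
  V <- tw$facts$V; saddle <- cp[2]
  expect_equal(S_shallow, 2 * (V(saddle) - V(lo)), tolerance = 0.03)
  expect_equal(S_deep, 2 * (V(saddle) - V(hi)), tolerance = 0.03)
})

test_that("pseudotime profiles are flat for constant paths and pin endpoints", {
  P <- matrix(rep(c(0.3, 0.8), each = 11), 11, 2,
              dimnames = list(NULL, c("A", "B")))
  prof <- pseudotime_profiles(P)
  expect_true(all(prof$A == 0.3) && all(prof$B == 0.8))
  net <- toggle()
  as <- toggle_attractors()
  ss <- stable_states(as, full = FALSE)
  p <- minimize_action(net, ss[1, ], ss[2, ], N = 40, T_sweep = c(10, 20))
  prof2 <- pseudotime_profiles(p, nodes = c("A", "B"))
  expect_equal(unlist(prof2[1, c("A", "B")]), ss[1, ], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(unlist(prof2[nrow(prof2), c("A", "B")]), ss[2, ],
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(prof2$arclength[c(1, nrow(prof2))], c(0, 1))
})
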