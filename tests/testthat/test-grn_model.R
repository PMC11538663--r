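test_that("shifted Hill factor has the correct limits and symmetry", {
  expect_equal(shifted_hill(0, 1, 2, 4), 1)
  # half-saturation: (1 + lambda)/2 for any lambda, n
  for (lam in c(0.1, 0.5, 2, 7)) for (n in c(1, 2, 4))
    expect_equal(shifted_hill(1, 1, lam, n), (1 + lam) / 2)
  # saturation limit equals lambda
  expect_equal(shifted_hill(1e6, 1, 0.1, 2), 0.1, tolerance = 1e-6)
  # lambda = 1 disables the regulation at every Y
  expect_equal(shifted_hill(c(0, 0.3, 1, 10), 1, 1, 3), rep(1, 4))
})

test_that("shifted Hill rejects invalid domains", {
  expect_error(shifted_hill(-1, 1, 2, 2), "non-negative")
  expect_error(shifted_hill(1, 0, 2, 2), "positive")
  expect_error(shifted_hill(1, 1, 2, 0), "n must be")
})

test_that("shifted Hill is monotone, with direction set by lambda", {
  Y <- seq(0, 5, by = 0.05)
  for (lam in c(0.2, 0.9, 1.5, 4)) {
    h <- shifted_hill(Y, S = 1.2, lambda = lam, n = 3)
    expect_true(all(h >= min(1, lam) - 1e-12 & h <= max(1, lam) + 1e-12))
    if (lam > 1) expect_true(all(diff(h) >= 0))
    if (lam < 1) expect_true(all(diff(h) <= 0))
  }
})

test_that("analytic Hill derivative matches numerical differentiation", {
  eps <- 1e-6
  for (n in c(1, 2, 4)) for (Y in c(0.2, 1, 3)) {
    num <- (shifted_hill(Y + eps, 1.1, 0.3, n) -
              shifted_hill(Y - eps, 1.1, 0.3, n)) / (2 * eps)
    expect_equal(caclandscape:::shifted_hill_deriv(Y, 1.1, 0.3, n), num,
                 tolerance = 1e-6)
  }
  # Y^n is flat at the origin for n >= 2
  expect_identical(caclandscape:::shifted_hill_deriv(0, 1, 2, 3), 0)
  expect_equal(caclandscape:::shifted_hill_deriv(0, 2, 3, 1), (3 - 1) / 2)
})

test_that("unregulated nodes follow g - k x dynamics exactly", {
  net <- decoupled_linear(g = c(1, 1), k = c(1, 2))
  # steady state at g/k has zero rate
  expect_equal(unname(ode_rhs(c(1, 0.5), net)), c(0, 0))
  x <- c(0.3, 1.7)
  expect_equal(unname(ode_rhs(x, net)), c(1, 1) - c(1, 2) * x)
  # diagonal Jacobian entries are -k
  expect_equal(unname(diag(network_jacobian(x, net))), c(-1, -2))
})

test_that("neutral regulations (lambda = 1) reduce rates to g - k x", {
  net <- toggle()
  net$edges$lambda <- c(1, 1)
  x <- c(0.4, 1.3)
  expect_equal(unname(ode_rhs(x, net)),
               net$nodes$g - net$nodes$k * x)
})

test_that("the symmetric toggle state solves the 1-D root equation", {
  net <- toggle()
  xs <- net$facts$symmetric_state
  expect_equal(unname(ode_rhs(c(xs, xs), net)), c(0, 0), tolerance = 1e-6)
})

test_that("analytic network Jacobian matches central finite differences", {
  set.seed(42)
  for (net in list(toggle(), decoupled_linear())) {
    vf <- as_vector_field(net)
    f <- function(x) as.numeric(ode_rhs(x, net))
    for (rep in 1:3) {
      x <- runif(vf$d, 0.05, 2)
      J <- network_jacobian(x, net)
      eps <- 1e-6
      Jfd <- sapply(seq_len(vf$d), function(j) {
        e <- numeric(vf$d); e[j] <- eps
        (f(x + e) - f(x - e)) / (2 * eps)
      })
      expect_lt(max(abs(J - Jfd)) / max(1, max(abs(J))), 1e-6)
    }
  }
})

test_that("input nodes are clamped: zero rates and zero Jacobian rows", {
  net <- network_spec(
    nodes = data.frame(name = c("X", "DRUG"), g = c(1, 0), k = c(1, 1),
                       is_input = c(FALSE, TRUE)),
    edges = data.frame(source = "DRUG", target = "X", lambda = 2, S = 0.5,
                       n = 2, side = "G"),
    inputs = c(DRUG = 0.7))
  r <- ode_rhs(c(0.2, 0.7), net)
  expect_identical(unname(r["DRUG"]), 0)
  expect_true(all(network_jacobian(c(0.2, 0.7), net)["DRUG", ] == 0))
})

test_that("network validation catches structural errors", {
  nodes <- data.frame(name = c("A", "B"), g = 1, k = 1, is_input = FALSE)
  edges <- data.frame(source = "A", target = "C", lambda = 2, S = 1, n = 2,
                      side = "G")
  expect_error(network_spec(nodes, edges), "undeclared")
  edges$target <- "B"; edges$lambda <- -1
  expect_error(network_spec(nodes, edges), "lambda")
  edges$lambda <- 2; edges$n <- 1.5
  expect_error(network_spec(nodes, edges), "integers")
  nodes$k <- c(1, 0)
  expect_error(network_spec(nodes, edges[0, ]), "degradation")
})

test_that("parameter addressing round-trips and interventions scale", {
  net <- toggle()
  fp <- free_parameters(net)
  expect_equal(nrow(fp), 2 * 2 + 3 * 2)  # g,k per node + lambda,S,n per edge
  v <- get_params(net, c("g:A", "lambda:A->B"))
  net2 <- apply_intervention(net, c("g:A" = 2, "lambda:A->B" = 0.5))
  expect_equal(unname(get_params(net2, "g:A")), unname(v["g:A"]) * 2)
  # original untouched; identity multipliers change nothing
  expect_equal(get_params(net), get_params(apply_intervention(net, c("g:A" = 1))))
  expect_error(apply_intervention(net, c("g:NOPE" = 2)), "unknown")
})
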