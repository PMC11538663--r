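test_that("toy factory returns systems with correct analytic facts", {
  expect_error(make_toy("nope"), "unknown toy")
  ou <- make_toy("ou1d", k = 2, g = 0)
  expect_equal(ou$facts$fixed_point, 0)
  expect_equal(ou$facts$stationary_variance(0.04), 0.02)
  dw <- make_toy("double_well_1d")
  expect_equal(dw$facts$minima, c(-1, 1))
  expect_equal(dw$facts$barrier, dw$facts$V(0) - dw$facts$V(-1))
  tog <- make_toy("toggle_switch")
  xs <- tog$facts$symmetric_state
  expect_equal(shifted_hill(xs, tog$facts$S, tog$facts$lambda, tog$facts$n) *
                 tog$facts$g, tog$facts$k * xs, tolerance = 1e-8)
})

test_that("zero-noise generation embeds the state means exactly", {
  states <- rbind(s1 = c(g1 = 1, g2 = 2), s2 = c(g1 = 3, g2 = 0.5))
  ex <- generate_expression(states, c("s1", "s2"), n_per_state = 4,
                            noise_sd = 0, seed = 1)
  expect_equal(unname(ex$matrix[, 1]), unname(states[1, ]))
  expect_equal(max(abs(ex$matrix[, ex$sample_labels == "s2"] - states[2, ])), 0)
})

test_that("generators are seed-deterministic and flag non-positive means", {
  states <- rbind(c(1, 2), c(3, 0.5))
  e1 <- generate_expression(states, n_per_state = 5, noise_sd = 0.3, seed = 7)
  e2 <- generate_expression(states, n_per_state = 5, noise_sd = 0.3, seed = 7)
  expect_identical(e1$matrix, e2$matrix)
  expect_message(generate_expression(rbind(c(0, 1), c(1, 1)), n_per_state = 2,
                                     noise_sd = 0.1, seed = 1), "offsetting")
})

test_that("k-means on four separable states recovers labels (Rand > 0.95)", {
  # four well-separated states over 12 genes
  set.seed(3)
  states <- matrix(exp(rnorm(4 * 12, sd = 1.2)), 4, 12)
  rownames(states) <- c("E", "M", "P2", "A")
  colnames(states) <- paste0("gene", 1:12)
  ex <- generate_expression(states, rownames(states), n_per_state = 20,
                            noise_sd = 0.3, seed = 9)
  km <- kmeans(scale(t(log(ex$matrix))), centers = 4, nstart = 20)
  expect_gt(rand_index(km$cluster, ex$sample_labels), 0.95)
})

test_that("model-data comparison is exact on self-generated data", {
  states <- rbind(E = c(a = 1, b = 2, c = 0.5), M = c(a = 2, b = 0.3, c = 1),
                  A = c(a = 0.2, b = 1, c = 3))
  ex <- generate_expression(states, rownames(states), n_per_state = 3,
                            noise_sd = 0, seed = 1)
  cmp <- compare_states_to_data(states, ex)
  expect_equal(max(abs(cmp$difference)), 0, tolerance = 1e-12)
  expect_equal(unname(diag(cmp$correlation[rownames(states), rownames(states)])),
               rep(1, 3), tolerance = 1e-12)
})

test_that("permuting gene identities destroys the correlation", {
  set.seed(5)
  states <- matrix(exp(rnorm(3 * 30, sd = 1)), 3, 30,
                   dimnames = list(c("E", "M", "A"), paste0("g", 1:30)))
  ex <- generate_expression(states, rownames(states), n_per_state = 10,
                            noise_sd = 0.2, seed = 2)
  cmp <- compare_states_to_data(states, ex)
  perm <- states
  colnames(perm) <- sample(colnames(perm))
  cmp_p <- compare_states_to_data(perm, ex)
  expect_gt(mean(diag(cmp$correlation[c("E", "M", "A"), c("E", "M", "A")])),
            mean(diag(cmp_p$correlation[c("E", "M", "A"), c("E", "M", "A")])) + 0.3)
})

test_that("gene maps bridge model and data naming; empty overlap errors", {
  states <- rbind(E = c(PPARg = 1, Zeb = 2), M = c(PPARg = 0.3, Zeb = 4))
  ex <- generate_expression(states, rownames(states), n_per_state = 3,
                            noise_sd = 0, seed = 1)
  rownames(ex$matrix) <- c("PPARG", "ZEB1")
  expect_error(compare_states_to_data(states, ex), "no genes shared")
  cmp <- compare_states_to_data(states, ex,
                                gene_map = c(PPARg = "PPARG", Zeb = "ZEB1"))
  expect_equal(unname(diag(cmp$correlation)), rep(1, 2), tolerance = 1e-12)
})
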