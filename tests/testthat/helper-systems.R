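# Shared fixtures: all built in code, no stored data.

toggle <- function() make_toy("toggle_switch")

toggle_attractors <- function(net = toggle(), n_starts = 60, seed = 2) {
  find_attractors(net, n_starts = n_starts, seed = seed, t_long = 100)
}

# A two-node decoupled linear network (no regulations): dx_i = g_i - k_i x_i.
decoupled_linear <- function(g = c(1, 1), k = c(1, 2)) {
  network_spec(
    nodes = data.frame(name = c("X1", "X2"), g = g, k = k,
                       is_input = FALSE),
    edges = data.frame(source = character(0), target = character(0),
                       lambda = numeric(0), S = numeric(0), n = numeric(0),
                       side = character(0)))
}

# Independent trapezoid-rule action oracle at very fine resolution:
# deliberately re-implements the quadrature with plain loops and a
# different rule from the package's midpoint scheme.
action_oracle <- function(P, vf, T, refine = 100) {
  vf <- as_vector_field(vf)
  f_active <- caclandscape:::vf_f_active
  P <- as.matrix(P)
  # linear-interpolate the path onto a much finer grid
  N <- nrow(P) - 1
  tt <- seq(0, 1, length.out = N * refine + 1)
  Pf <- apply(P, 2, function(col) stats::approx(seq(0, 1, length.out = N + 1),
                                                col, xout = tt)$y)
  dt <- T / (nrow(Pf) - 1)
  v <- (Pf[-1, , drop = FALSE] - Pf[-nrow(Pf), , drop = FALSE]) / dt
  integrand <- numeric(nrow(Pf))
  for (i in seq_len(nrow(Pf))) {
    vi <- if (i == 1) v[1, ] else if (i == nrow(Pf)) v[nrow(v), ]
          else (v[i - 1, ] + v[i, ]) / 2
    Fi <- as.numeric(f_active(vf, matrix(Pf[i, ], 1)))
    integrand[i] <- 0.5 * sum((vi - Fi)^2)
  }
  sum((integrand[-1] + integrand[-length(integrand)]) / 2) * dt
}

# Plain Rand index by pair counting (independent of any clustering pkg).
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
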