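#' Langevin (Euler-Maruyama) simulation of the stochastic network
#'
#' Simulates the overdamped dynamics `dx = F(x) dt + sqrt(2 D dt) eta`
#' with isotropic Gaussian white noise of diffusion coefficient `D`,
#' serving as the independent stochastic oracle for landscapes and
#' occupancies.  Concentrations are kept non-negative by reflection at 0
#' (for toy potentials on the whole line no reflection is applied).
#' Clamped input coordinates receive no noise and no drift.
#'
#' @param x a `cac_network` or `vector_field`.
#' @param D diffusion coefficient (concentration^2 / time).
#' @param n_traj number of independent trajectories.
#' @param dt Euler-Maruyama time step; halving `dt` should change summary
#'   statistics by well under 2 percent at the default.
#' @param T time horizon per trajectory.
#' @param seed integer seed (bit-reproducible summaries).
#' @param x0 initial states: matrix (rows recycled over trajectories) over
#'   the dynamic coordinates, or `NULL` for Latin-hypercube starts.
#' @param thin store every `thin`-th step (memory control).
#' @param burn_in fraction of the horizon discarded by downstream
#'   estimators (stored in the ensemble).
#' @return a `trajectory_ensemble`: list with `states` (array steps x
#'   trajectories x dynamic coordinates), `times`, `final` (matrix of
#'   final states), `D`, `dt`, `burn_in`, `names`.
#' @export
simulate_langevin <- function(x, D = 0.01, n_traj = 100, dt = 0.01, T = 100,
                              seed = 1, x0 = NULL, thin = 10,
                              burn_in = 0.2) {
  vf <- as_vector_field(x)
  if (D < 0) stop("D must be >= 0")
  na <- length(vf$active)
  set.seed(seed)
  if (is.null(x0)) {
    upper <- vf$range[vf$active]
    lower <- if (vf$nonneg) rep(0, na) else -upper
    X <- lhs::randomLHS(n_traj, na)
    X <- sweep(sweep(X, 2, upper - lower, "*"), 2, lower, "+")
  } else {
    x0 <- as.matrix(x0)
    X <- x0[rep_len(seq_len(nrow(x0)), n_traj), , drop = FALSE]
  }
  n_steps <- ceiling(T / dt)
  keep <- seq(thin, n_steps, by = thin)
  states <- array(NA_real_, c(length(keep), n_traj, na),
                  dimnames = list(NULL, NULL, vf$names[vf$active]))
  sig <- sqrt(2 * D * dt)
  ki <- 1
  for (s in seq_len(n_steps)) {
    R <- vf_f_active(vf, X)
    if (any(!is.finite(R))) stop("numerical blow-up in Langevin step ", s)
    X <- X + R * dt
    if (D > 0) X <- X + matrix(stats::rnorm(n_traj * na, sd = sig), n_traj, na)
    if (vf$nonneg) X <- abs(X)  # reflecting boundary at 0
    if (ki <= length(keep) && s == keep[ki]) {
      states[ki, , ] <- X
      ki <- ki + 1
    }
  }
  structure(list(states = states, times = keep * dt, final = X, D = D,
                 dt = dt, T = T, burn_in = burn_in, seed = seed,
                 names = vf$names[vf$active]),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d trajectories, T = %g, dt = %g, D = %g\n",
              dim(x$states)[2], x$T, x$dt, x$D))
  invisible(x)
}

# Post-burn-in samples pooled over time and trajectories.
ensemble_samples <- function(ens) {
  keep <- ens$times > ens$burn_in * ens$T
  S <- ens$states[keep, , , drop = FALSE]
  M <- matrix(S, prod(dim(S)[1:2]), dim(S)[3])
  colnames(M) <- ens$names
  M
}

#' Basin occupancy from a trajectory ensemble
#'
#' Assigns each post-burn-in sample to the nearest stable attractor in
#' z-scored state space and reports the occupied fractions.  Samples
#' farther than `max_dist` z-units from every attractor are counted as
#' transient and reported separately.
#'
#' @param ens a `trajectory_ensemble`.
#' @param as an `attractor_set` over the same system.
#' @param max_dist transient cutoff (Euclidean distance in z-scored
#'   coordinates); `Inf` disables it.
#' @return data frame with one row per stable attractor (label when
#'   available) plus a `transient` attribute; fractions sum to 1 over
#'   assigned samples.
#' @export
occupancy <- function(ens, as, max_dist = Inf) {
  S <- ensemble_samples(ens)
  A <- stable_states(as, full = FALSE)
  if (!nrow(A)) stop("attractor set has no stable states")
  mu <- colMeans(A); sd0 <- apply(A, 2, stats::sd)
  sd0[!is.finite(sd0) | sd0 < 1e-8] <- 1
  Z  <- sweep(sweep(S, 2, mu), 2, sd0, "/")
  ZA <- sweep(sweep(A, 2, mu), 2, sd0, "/")
  d2 <- sapply(seq_len(nrow(ZA)), function(i)
    rowSums(sweep(Z, 2, ZA[i, ])^2))
  d2 <- matrix(d2, nrow = nrow(Z))
  nearest <- max.col(-d2)
  mind <- sqrt(d2[cbind(seq_len(nrow(d2)), nearest)])
  ok <- mind <= max_dist
  counts <- tabulate(nearest[ok], nbins = nrow(A))
  frac <- counts / max(sum(counts), 1)
  lab <- as$labels[as$stable]
  out <- data.frame(attractor = seq_len(nrow(A)),
                    label = if (all(is.na(lab))) NA_character_ else lab,
                    fraction = frac)
  attr(out, "transient") <- mean(!ok)
  out
}
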