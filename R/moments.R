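#' Self-consistent mean-field Gaussian moments at an attractor
#'
#' Linearizes the dynamics at a stable fixed point and solves the moment
#' equations for the stationary Gaussian approximation.  The mean equals
#' the attractor state; under the mean-field truncation only the diagonal
#' of the covariance is retained, so the stationary variance of
#' coordinate `i` solves `0 = 2 A_ii sigma_i + 2 D`, i.e.
#' `sigma_i = -D / A_ii` with `A` the Jacobian at the attractor.
#'
#' @param x a `cac_network` or `vector_field`.
#' @param attractor state vector of a stable fixed point (full or dynamic
#'   coordinates).
#' @param D diffusion coefficient, `> 0`.
#' @return a `moment_solution`: list with `mean` and `var` (named over
#'   dynamic coordinates) and `converged`.
#' @export
solve_moments <- function(x, attractor, D = 0.01) {
  vf <- as_vector_field(x)
  if (D <= 0) stop("D must be positive")
  xa <- as.numeric(attractor)
  if (length(xa) == vf$d) xa <- xa[vf$active]
  if (length(xa) != length(vf$active))
    stop("attractor length matches neither full nor dynamic coordinates")
  J <- vf_jac_active(vf, xa)
  ev <- eigen(J, only.values = TRUE)$values
  if (max(Re(ev)) >= 0)
    stop("attractor is not stable: variance diverges")
  aii <- diag(J)
  if (any(aii >= 0))
    stop("diagonal Jacobian entries must be negative under the mean-field truncation")
  nm <- vf$names[vf$active]
  structure(list(mean = setNames(xa, nm), var = setNames(-D / aii, nm),
                 D = D, converged = TRUE),
            class = "moment_solution")
}

#' Gaussian-mixture quasi-potential landscape
#'
#' Builds the steady-state probability as a weighted sum over stable
#' attractors of product-form Gaussians (one factor per gene, mean-field
#' approximation) and defines the quasi-potential `U = -ln Pss`.
#'
#' @param x a `cac_network` or `vector_field`.
#' @param as an `attractor_set` with at least one stable state.
#' @param D diffusion coefficient.
#' @param weights `"equal"`, `"occupancy"` (long-run basin occupancy
#'   estimated by Langevin simulation; the default emulated condition for
#'   occupancy statements), or a numeric vector summing to 1.
#' @param occ_args list of arguments forwarded to [simulate_langevin()]
#'   for occupancy weights (`n_traj`, `T`, `dt`, `seed`).
#' @return a `landscape`: list of component means/variances, weights and
#'   labels.
#' @export
build_landscape <- function(x, as, D = 0.01, weights = "equal",
                            occ_args = list()) {
  if (!n_stable(as)) stop("landscape needs at least one stable attractor")
  vf <- as_vector_field(x)
  A <- stable_states(as, full = FALSE)
  comps <- lapply(seq_len(nrow(A)), function(i) solve_moments(vf, A[i, ], D))
  if (is.numeric(weights)) {
    w <- weights / sum(weights)
    if (length(w) != nrow(A)) stop("weights length must match stable attractors")
  } else if (identical(weights, "equal")) {
    w <- rep(1 / nrow(A), nrow(A))
  } else if (identical(weights, "occupancy")) {
    args <- utils::modifyList(
      list(x = vf, D = D, n_traj = 200, dt = 0.01, T = 100, seed = 1), occ_args)
    ens <- do.call(simulate_langevin, args)
    occ <- occupancy(ens, as)
    w <- occ$fraction
    if (all(w == 0)) w <- rep(1 / nrow(A), nrow(A))
    w <- w / sum(w)
  } else stop("unknown weights policy")
  structure(list(components = comps, weights = w,
                 labels = as$labels[as$stable], D = D,
                 names = vf$names[vf$active]),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d Gaussian components over %d genes, D = %g\n",
              length(x$components), length(x$names), x$D))
  cat("weights:", paste(round(x$weights, 3), collapse = ", "), "\n")
  invisible(x)
}

# Mixture density evaluated on arbitrary coordinates (exact marginal of
# the product-form mixture).
mixture_density_2d <- function(ls, coords, X, Y) {
  i <- match(coords, ls$names)
  if (anyNA(i)) stop("unknown coordinate(s): ",
                     paste(coords[is.na(i)], collapse = ", "))
  P <- 0
  for (k in seq_along(ls$components)) {
    c_k <- ls$components[[k]]
    P <- P + ls$weights[k] *
      stats::dnorm(X, c_k$mean[i[1]], sqrt(c_k$var[i[1]])) *
      stats::dnorm(Y, c_k$mean[i[2]], sqrt(c_k$var[i[2]]))
  }
  P
}

#' Project a landscape to two dimensions
#'
#' For a pair of gene coordinates the projection is the analytic 2-D
#' marginal of the Gaussian mixture (exact under the product form).  For
#' a principal-component projection, samples drawn from the mixture are
#' projected onto the basis and smoothed by a 2-D kernel density
#' estimate; `U = -ln` of either density.
#'
#' @param ls a `landscape`.
#' @param coords character pair of gene names, or `"pc"` for principal
#'   components.
#' @param n_grid grid points per axis.
#' @param limits optional list of two length-2 ranges; default spans all
#'   component means +/- 6 standard deviations.
#' @param basis optional `d x 2` projection basis for `coords = "pc"`;
#'   fitted to mixture samples by [stats::prcomp()] when absent.
#' @param n_samples mixture samples for the PC route.
#' @param seed seed for the PC route.
#' @return a `landscape_projection`: list with axis vectors `x`, `y`,
#'   matrix `U`, and `coords`.
#' @export
project_landscape <- function(ls, coords, n_grid = 200, limits = NULL,
                              basis = NULL, n_samples = 20000, seed = 1) {
  if (identical(coords, "pc") || identical(coords, c("PC1", "PC2"))) {
    set.seed(seed)
    ns <- length(ls$components)
    ks <- sample.int(ns, n_samples, replace = TRUE, prob = ls$weights)
    d <- length(ls$names)
    S <- matrix(NA_real_, n_samples, d)
    for (k in seq_len(ns)) {
      idx <- which(ks == k); if (!length(idx)) next
      c_k <- ls$components[[k]]
      S[idx, ] <- matrix(stats::rnorm(length(idx) * d,
                                      mean = rep(c_k$mean, each = length(idx)),
                                      sd = rep(sqrt(c_k$var), each = length(idx))),
                         length(idx), d)
    }
    if (is.null(basis)) {
      pc <- stats::prcomp(S, center = TRUE, scale. = FALSE)
      basis <- pc$rotation[, 1:2]
      P2 <- pc$x[, 1:2]
    } else {
      P2 <- scale(S, center = TRUE, scale = FALSE) %*% basis
    }
    kd <- MASS::kde2d(P2[, 1], P2[, 2], n = n_grid)
    U <- -log(pmax(kd$z, 1e-300))
    return(structure(list(x = kd$x, y = kd$y, U = U, coords = c("PC1", "PC2"),
                          basis = basis), class = "landscape_projection"))
  }
  stopifnot(length(coords) == 2)
  i <- match(coords, ls$names)
  if (anyNA(i)) stop("unknown coordinate(s): ",
                     paste(coords[is.na(i)], collapse = ", "))
  if (is.null(limits)) {
    limits <- lapply(1:2, function(a) {
      mu <- vapply(ls$components, function(c_k) c_k$mean[i[a]], numeric(1))
      sd <- vapply(ls$components, function(c_k) sqrt(c_k$var[i[a]]), numeric(1))
      range(mu - 6 * sd, mu + 6 * sd)
    })
  }
  gx <- seq(limits[[1]][1], limits[[1]][2], length.out = n_grid)
  gy <- seq(limits[[2]][1], limits[[2]][2], length.out = n_grid)
  XY <- expand.grid(x = gx, y = gy)
  P <- mixture_density_2d(ls, coords, XY$x, XY$y)
  U <- matrix(-log(pmax(P, 1e-300)), n_grid, n_grid)
  structure(list(x = gx, y = gy, U = U, coords = coords),
            class = "landscape_projection")
}

#' @export
print.landscape_projection <- function(x, ...) {
  cat(sprintf("<landscape_projection> %s vs %s, %d x %d grid, %d local minima\n",
              x$coords[1], x$coords[2], length(x$x), length(x$y),
              nrow(local_minima(x))))
  invisible(x)
}

#' Long-format table of a projected landscape
#' @param x a `landscape_projection`.
#' @param row.names,optional,... standard [as.data.frame()] arguments (unused).
#' @return data frame with columns named after the two coordinates and `U`.
#' @export
as.data.frame.landscape_projection <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  df <- expand.grid(a = x$x, b = x$y)
  df$U <- as.vector(x$U)
  names(df) <- c(x$coords, "U")
  df
}

#' Local minima of a projected landscape
#'
#' Interior grid cells strictly below all 8 neighbours and within
#' `max_depth` log-units of the global minimum (excludes irrelevant
#' far-field wiggles of the tail).
#'
#' @param proj a `landscape_projection`.
#' @param max_depth relevance cutoff in natural-log units.
#' @return data frame of minima locations and `U` values.
#' @export
local_minima <- function(proj, max_depth = 30) {
  U <- proj$U
  n <- nrow(U); m <- ncol(U)
  out <- NULL
  for (i in 2:(n - 1)) for (j in 2:(m - 1)) {
    w <- U[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (U[i, j] < min(w[-5]) && U[i, j] <= min(U) + max_depth)
      out <- rbind(out, data.frame(x = proj$x[i], y = proj$y[j], U = U[i, j]))
  }
  if (is.null(out)) out <- data.frame(x = numeric(0), y = numeric(0),
                                      U = numeric(0))
  out
}
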