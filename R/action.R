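#' Freidlin-Wentzell action of a discretized path
#'
#' Quadrature of \eqn{S_T[\varphi] = \tfrac12 \int_0^T |\dot\varphi -
#' F(\varphi)|^2 dt} with finite-difference velocities: per segment the
#' velocity is the forward difference and the drift is evaluated at the
#' segment midpoint (midpoint rule).  Zero along any path following the
#' deterministic flow; strictly positive otherwise.
#'
#' @param path matrix of states (rows = `N + 1` path points, columns =
#'   dynamic coordinates), or an `action_path`.
#' @param x a `cac_network` or `vector_field`.
#' @param T total traversal time, `> 0` (uniform time grid).
#' @return the non-negative action value.
#' @export
path_action <- function(path, x, T) {
  vf <- as_vector_field(x)
  P <- path_matrix(path, vf)
  if (inherits(path, "action_path") && missing(T)) T <- path$T
  if (T <= 0) stop("path traversal time T must be positive")
  if (nrow(P) < 3) stop("path needs at least 3 points")
  dt <- T / (nrow(P) - 1)
  seg <- path_residuals(vf, P, dt)
  (dt / 2) * sum(seg$r^2)
}

path_matrix <- function(path, vf) {
  P <- if (inherits(path, "action_path")) path$states else as.matrix(path)
  if (ncol(P) == vf$d) P <- P[, vf$active, drop = FALSE]
  if (ncol(P) != length(vf$active))
    stop("path width matches neither full nor dynamic coordinates")
  P
}

# Segment residuals r_i = (phi_{i+1} - phi_i)/dt - F(midpoint_i) and the
# midpoints themselves.
path_residuals <- function(vf, P, dt) {
  N <- nrow(P) - 1
  V <- (P[-1, , drop = FALSE] - P[-(N + 1), , drop = FALSE]) / dt
  M <- (P[-1, , drop = FALSE] + P[-(N + 1), , drop = FALSE]) / 2
  if (vf$nonneg) M <- pmax(M, 0)
  r <- V - vf_f_active(vf, M)
  list(r = r, M = M, V = V)
}

# Action and analytic gradient w.r.t. the interior points (rows 2..N).
action_and_grad <- function(vf, P, dt) {
  N <- nrow(P) - 1
  sr <- path_residuals(vf, P, dt)
  r <- sr$r; M <- sr$M
  S <- (dt / 2) * sum(r^2)
  Jt_r <- matrix(vapply(seq_len(N), function(i)
    as.numeric(crossprod(vf_jac_active(vf, M[i, ]), r[i, ])),
    numeric(ncol(P))), nrow = N, ncol = ncol(P), byrow = TRUE)
  G <- (r[-N, , drop = FALSE] - r[-1, , drop = FALSE]) -
    (dt / 2) * (Jt_r[-N, , drop = FALSE] + Jt_r[-1, , drop = FALSE])
  list(S = S, G = G)
}

#' Minimum action path between two fixed points
#'
#' Optimizes an endpoint-pinned discretized path by quasi-Newton descent
#' (L-BFGS-B with the analytic action gradient), starting from linear
#' interpolation (optionally routed through an intermediate attractor).
#' Because transitions between attractors favour long traversal times
#' while the action functional fixes `T`, a geometric sweep over `T` is
#' performed and the minimizing horizon retained.
#'
#' @param x a `cac_network` or `vector_field`.
#' @param from,to endpoint states (full or dynamic coordinates).
#' @param N number of path segments (`N + 1` points).
#' @param T_sweep traversal horizons tried.
#' @param via optional intermediate state for the initial path.
#' @param init optional explicit initial path matrix.
#' @param maxit L-BFGS-B iteration cap per horizon.
#' @param reltol stop refinement once the action improves by less than
#'   this relative amount between sweep stages.
#' @return an `action_path`: list with `states` (full coordinates),
#'   `action`, `T`, `converged`, `action_straight` (initialization value).
#' @export
minimize_action <- function(x, from, to, N = 100, T_sweep = c(5, 10, 20, 40, 80),
                            via = NULL, init = NULL, maxit = 400,
                            reltol = 1e-4) {
  vf <- as_vector_field(x)
  a <- endpoint_active(vf, from); b <- endpoint_active(vf, to)
  na <- length(vf$active)
  if (is.null(init)) {
    if (is.null(via)) {
      init <- straight_path(a, b, N)
    } else {
      v <- endpoint_active(vf, via)
      half <- floor(N / 2)
      init <- rbind(straight_path(a, v, half),
                    straight_path(v, b, N - half)[-1, , drop = FALSE])
    }
  } else {
    init <- path_matrix(init, vf)
    if (nrow(init) != N + 1) stop("init path must have N + 1 points")
  }
  best <- NULL
  prev_S <- Inf
  P0 <- init
  for (T in T_sweep) {
    dt <- T / N
    obj <- function(theta) {
      P <- assemble_path(theta, a, b, na)
      action_and_grad(vf, P, dt)$S
    }
    grd <- function(theta) {
      P <- assemble_path(theta, a, b, na)
      as.numeric(t(action_and_grad(vf, P, dt)$G))
    }
    theta0 <- as.numeric(t(P0[2:N, , drop = FALSE]))
    opt <- stats::optim(theta0, obj, grd, method = "L-BFGS-B",
                        lower = if (vf$nonneg) 0 else -Inf,
                        control = list(maxit = maxit))
    P_T <- assemble_path(opt$par, a, b, na)
    cand <- list(P = P_T, S = opt$value, T = T,
                 converged = opt$convergence == 0)
    if (is.null(best) || cand$S < best$S) best <- cand
    P0 <- P_T  # warm-start the next horizon
    # Stop the sweep once longer horizons no longer change the action
    if (abs(prev_S - cand$S) < reltol * max(cand$S, 1e-12)) break
    prev_S <- cand$S
  }
  S_straight <- path_action(straight_path(a, b, N), vf, best$T)
  structure(list(states = vf_embed(vf, best$P), action = best$S, T = best$T,
                 N = N, converged = best$converged,
                 action_straight = S_straight,
                 names = vf$names),
            class = "action_path")
}

endpoint_active <- function(vf, s) {
  s <- as.numeric(s)
  if (length(s) == vf$d) s <- s[vf$active]
  if (length(s) != length(vf$active)) stop("endpoint has wrong dimension")
  s
}

straight_path <- function(a, b, N) {
  s <- seq(0, 1, length.out = N + 1)
  outer(1 - s, a) + outer(s, b)   # (N+1) x d, robust for d = 1
}

assemble_path <- function(theta, a, b, na) {
  rbind(a, matrix(theta, ncol = na, byrow = TRUE), b)
}

#' @export
print.action_path <- function(x, ...) {
  cat(sprintf("<action_path> %d points, T = %g, action = %.6g (straight-line %.6g)%s\n",
              nrow(x$states), x$T, x$action, x$action_straight,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Pairwise minimized transition actions
#'
#' Batch wrapper over [minimize_action()] for every ordered pair of
#' stable attractors.
#'
#' @param x a `cac_network` or `vector_field`.
#' @param as an `attractor_set`.
#' @param ... forwarded to [minimize_action()].
#' @return an `action_matrix`: square matrix `S[i, j]` of minimized
#'   actions i to j (zero diagonal), dimnames from phenotype labels when
#'   available; the optimized paths are attached as the `"paths"`
#'   attribute.
#' @export
action_matrix <- function(x, as, ...) {
  A <- stable_states(as, full = FALSE)
  ns <- nrow(A)
  if (!ns) stop("action matrix needs at least one stable attractor")
  lab <- as$labels[as$stable]
  if (all(is.na(lab))) lab <- paste0("a", seq_len(ns))
  S <- matrix(0, ns, ns, dimnames = list(lab, lab))
  paths <- list()
  if (ns > 1) {
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      if (i == j) next
      p <- minimize_action(x, A[i, ], A[j, ], ...)
      S[i, j] <- p$action
      paths[[paste0(lab[i], "->", lab[j])]] <- p
    }
  }
  structure(S, class = c("action_matrix", "matrix"), paths = paths)
}

#' Expression profiles along a transition path
#'
#' Tabulates gene expression against normalized arc length along a path
#' (the model's pseudotime axis for a cell-state conversion).
#'
#' @param path an `action_path` (or state matrix).
#' @param nodes gene names to report; default all.
#' @return data frame with `arclength` (0 to 1) and one column per gene;
#'   first and last rows equal the endpoint attractor states.
#' @export
pseudotime_profiles <- function(path, nodes = NULL) {
  P <- if (inherits(path, "action_path")) path$states else as.matrix(path)
  if (is.null(colnames(P)) && inherits(path, "action_path"))
    colnames(P) <- path$names
  steps <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  arc <- c(0, cumsum(steps))
  arc <- if (max(arc) > 0) arc / max(arc) else seq(0, 1, length.out = nrow(P))
  df <- data.frame(arclength = arc)
  cols <- nodes %||% colnames(P)
  cbind(df, as.data.frame(P[, cols, drop = FALSE]))
}
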