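#' Find the attractors of a network or vector field
#'
#' Multi-start search for fixed points: Latin-hypercube initial conditions
#' over the attainable box, forward ODE integration to a long horizon,
#' then damped-Newton root polishing with the analytic Jacobian.  Stable
#' points are the attractors; unstable points (saddles) are additionally
#' sought by Newton iteration from midpoints between stable states and
#' from raw starts, and returned flagged.
#'
#' @param x a `cac_network` or `vector_field`.
#' @param n_starts number of Latin-hypercube starts (>= 100 recommended
#'   for the full CAC network).
#' @param seed integer seed controlling the start sample.
#' @param t_long forward-integration horizon before polishing (time units
#'   of the model; default comfortably exceeds the slowest relaxation of
#'   the packaged networks).
#' @param merge_tol relative L-infinity distance below which two fixed
#'   points are merged (the one with smaller residual is kept).
#' @param starts optional matrix of additional warm starts (columns =
#'   dynamic coordinates).
#' @param find_saddles also search for unstable fixed points?
#' @return an `attractor_set`: list with `states` (points x all
#'   coordinates, inputs at their clamped levels), `stable`, `residual`,
#'   `eigenvalues` (list), and `labels` (filled by
#'   [classify_phenotype()]).  Warns and returns zero rows if no start
#'   converges.
#' @export
find_attractors <- function(x, n_starts = 200, seed = 1, t_long = 500,
                            merge_tol = 1e-3, starts = NULL,
                            find_saddles = TRUE) {
  vf <- as_vector_field(x)
  na <- length(vf$active)
  upper <- vf$range[vf$active]
  lower <- if (vf$nonneg) rep(0, na) else -upper
  set.seed(seed)
  S0 <- lhs::randomLHS(n_starts, na)
  S0 <- sweep(sweep(S0, 2, upper - lower, "*"), 2, lower, "+")
  if (!is.null(starts)) S0 <- rbind(S0, as.matrix(starts))

  pts <- list()
  add_point <- function(xa, require_stable = NA) {
    pol <- newton_polish(vf, xa)
    if (!pol$converged) return(invisible(NULL))
    pts[[length(pts) + 1]] <<- pol
    invisible(NULL)
  }
  ends <- integrate_forward_batch(vf, S0, t_long)
  for (i in seq_len(nrow(ends))) {
    if (all(is.finite(ends[i, ]))) add_point(ends[i, ])
  }
  pts <- merge_points(pts, merge_tol)
  stable_states <- do.call(rbind, lapply(Filter(function(p) p$stable, pts),
                                         function(p) p$x))
  if (find_saddles && !is.null(stable_states) && nrow(stable_states) >= 2) {
    ns <- nrow(stable_states)
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns)
      add_point((stable_states[i, ] + stable_states[j, ]) / 2)
    pts <- merge_points(pts, merge_tol)
  }
  if (!length(pts)) warning("no start converged to a fixed point")

  states_a <- do.call(rbind, lapply(pts, function(p) p$x))
  res <- structure(
    list(states = if (length(pts)) vf_embed(vf, states_a)
         else matrix(0, 0, vf$d, dimnames = list(NULL, vf$names)),
         stable = vapply(pts, function(p) p$stable, logical(1)),
         residual = vapply(pts, function(p) p$residual, numeric(1)),
         eigenvalues = lapply(pts, function(p) p$eigenvalues),
         labels = rep(NA_character_, length(pts)),
         active = vf$active, names = vf$names),
    class = "attractor_set")
  # Order: stable first, then by first dynamic coordinate
  ord <- order(!res$stable, res$states[, vf$active[1]])
  reorder_attractors(res, ord)
}

reorder_attractors <- function(as, ord) {
  as$states <- as$states[ord, , drop = FALSE]
  as$stable <- as$stable[ord]
  as$residual <- as$residual[ord]
  as$eigenvalues <- as$eigenvalues[ord]
  as$labels <- as$labels[ord]
  as
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf("<attractor_set> %d fixed points (%d stable)\n",
              length(x$stable), sum(x$stable)))
  if (length(x$stable)) {
    df <- as.data.frame(round(x$states[, x$active, drop = FALSE], 4))
    df$stable <- x$stable
    if (!all(is.na(x$labels))) df$label <- x$labels
    print(df)
  }
  invisible(x)
}

#' Number of stable attractors
#' @param as an `attractor_set`.
#' @return integer count.
#' @export
n_stable <- function(as) sum(as$stable)

#' Stable states as a matrix
#' @param as an `attractor_set`.
#' @param full include clamped input coordinates?
#' @return matrix, one stable state per row.
#' @export
stable_states <- function(as, full = TRUE) {
  M <- as$states[as$stable, , drop = FALSE]
  if (full) M else M[, as$active, drop = FALSE]
}

# Batched fixed-step RK4 over all starts at once (dynamic coordinates).
# Attractor search only needs the basin endpoint, not the transient, so a
# moderate fixed step followed by Newton polishing is accurate and far
# cheaper than per-start adaptive integration.
integrate_forward_batch <- function(vf, X0, t_long, dt = 0.05) {
  X <- as.matrix(X0)
  clamp <- function(M) if (vf$nonneg) pmax(M, 0) else M
  n_steps <- ceiling(t_long / dt)
  for (s in seq_len(n_steps)) {
    k1 <- vf_f_active(vf, X)
    k2 <- vf_f_active(vf, clamp(X + dt / 2 * k1))
    k3 <- vf_f_active(vf, clamp(X + dt / 2 * k2))
    k4 <- vf_f_active(vf, clamp(X + dt * k3))
    X <- clamp(X + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    X[!is.finite(X)] <- NA_real_
  }
  X
}

# Forward integration of the dynamic coordinates; returns final state or
# NULL on failure.
integrate_forward <- function(vf, xa0, t_long) {
  f <- function(t, y, parms) {
    y <- pmax(y, if (vf$nonneg) 0 else -Inf)
    list(as.numeric(vf_f_active(vf, matrix(y, nrow = 1))))
  }
  out <- tryCatch(
    deSolve::ode(y = as.numeric(xa0), times = c(0, t_long / 2, t_long),
                 func = f, parms = NULL, method = "lsoda",
                 rtol = 1e-8, atol = 1e-8),
    warning = function(w) NULL, error = function(e) NULL)
  if (is.null(out) || nrow(out) < 3) return(NULL)
  xa <- as.numeric(out[nrow(out), -1])
  if (any(!is.finite(xa))) return(NULL)
  if (vf$nonneg) xa <- pmax(xa, 0)
  xa
}

# Damped Newton iteration on the dynamic coordinates.
newton_polish <- function(vf, xa, tol = 1e-10, maxit = 60) {
  xa <- as.numeric(xa)
  scale <- pmax(abs(xa), 1)
  fnorm <- function(z) max(abs(vf_f_active(vf, matrix(z, nrow = 1))))
  r <- fnorm(xa)
  for (it in seq_len(maxit)) {
    if (r < tol * max(scale)) break
    J <- vf_jac_active(vf, xa)
    Fv <- as.numeric(vf_f_active(vf, matrix(xa, nrow = 1)))
    step <- tryCatch(solve(J, -Fv), error = function(e) NULL)
    if (is.null(step)) return(list(converged = FALSE))
    lam <- 1
    repeat {
      xn <- xa + lam * step
      if (vf$nonneg) xn <- pmax(xn, 0)
      rn <- fnorm(xn)
      if (is.finite(rn) && (rn < r || lam < 1e-6)) break
      lam <- lam / 2
    }
    if (rn >= r && lam < 1e-6) break
    xa <- xn; r <- rn
  }
  converged <- r < 1e-7 * max(scale)
  if (!converged) return(list(converged = FALSE))
  ev <- eigen(vf_jac_active(vf, xa), only.values = TRUE)$values
  list(converged = TRUE, x = xa, residual = r,
       eigenvalues = ev, stable = max(Re(ev)) < 1e-6)
}

# Relative L-infinity merge of polished points; smaller residual wins.
merge_points <- function(pts, tol) {
  keep <- list()
  for (p in pts) {
    if (is.null(p) || !isTRUE(p$converged)) next
    dup <- FALSE
    for (i in seq_along(keep)) {
      q <- keep[[i]]
      dist <- max(abs(p$x - q$x)) / (1 + max(abs(p$x), abs(q$x)))
      if (dist < tol) {
        dup <- TRUE
        if (p$residual < q$residual) keep[[i]] <- p
        break
      }
    }
    if (!dup) keep[[length(keep) + 1]] <- p
  }
  keep
}
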