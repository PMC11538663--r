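#' Transition-action objective toward the adipose state
#'
#' The landscape-control cost
#' \deqn{\Delta S_A = \sum_{s \in \{M, E, P1, P2\}} (S_{s \to A} - S_{A \to s})}
#' summing forward-minus-reverse minimized transition actions toward the
#' adipose attractor over whichever of the tumor-associated source states
#' exist.  Minimizing it deepens the A basin relative to all sources and
#' so maximizes A-state occupancy.  A source state that has vanished (the
#' desired outcome of control) contributes 0; a missing A state makes the
#' objective undefined.
#'
#' @param x a `cac_network` or `vector_field`.
#' @param as a labelled `attractor_set` (see [classify_phenotype()]).
#' @param sources candidate source labels.
#' @param target target label.
#' @param ... forwarded to [minimize_action()].
#' @return the objective value (0 when no source state remains).
#' @export
delta_S_A <- function(x, as, sources = c("M", "E", "P1", "P2"),
                      target = "A", ...) {
  tgt <- attractor_by_label(as, target)
  if (is.null(tgt)) stop("target state '", target,
                         "' absent: objective undefined")
  total <- 0
  for (s in sources) {
    src <- attractor_by_label(as, s)
    if (is.null(src)) next
    total <- total +
      minimize_action(x, src, tgt, ...)$action -
      minimize_action(x, tgt, src, ...)$action
  }
  total
}

#' Define a landscape-control problem
#'
#' @param factory function mapping a named parameter vector to a
#'   `cac_network` or `vector_field`.
#' @param baseline named numeric vector of baseline parameter values.
#' @param lower,upper bounds; default a multiplicative range
#'   `[base/10, base*10]` (sign-aware for toy parameters that may be
#'   negative or zero, where an absolute band of width 1 is used).
#' @param target_select function mapping an `attractor_set` to the index
#'   of the target stable state (among stable states), or a phenotype
#'   label (string) for labelled networks.
#' @param rules marker rules applied to each iterate's attractors when
#'   `target_select` is a label.
#' @param find_args arguments for [find_attractors()] at each iterate.
#' @param map_args arguments for [minimize_action()] at each iterate.
#' @return a `control_problem`.
#' @export
control_problem <- function(factory, baseline, lower = NULL, upper = NULL,
                            target_select, rules = cac_marker_rules(),
                            find_args = list(n_starts = 40, seed = 1),
                            map_args = list(N = 40, T_sweep = c(10, 20, 40))) {
  stopifnot(is.function(factory), !is.null(names(baseline)))
  if (is.null(lower))
    lower <- ifelse(baseline > 0, baseline / 10, baseline - 0.5)
  if (is.null(upper))
    upper <- ifelse(baseline > 0, baseline * 10, baseline + 0.5)
  if (any(lower > baseline | baseline > upper))
    stop("bounds must contain the baseline")
  structure(list(factory = factory, baseline = baseline,
                 lower = setNames(lower, names(baseline)),
                 upper = setNames(upper, names(baseline)),
                 target_select = target_select, rules = rules,
                 find_args = find_args, map_args = map_args),
            class = "control_problem")
}

# Evaluate the control objective at a parameter vector; target absent ->
# large penalty (the target attractor must persist along the search).
control_objective <- function(problem, theta) {
  sys <- problem$factory(setNames(theta, names(problem$baseline)))
  as <- do.call(find_attractors, c(list(x = sys), problem$find_args))
  if (!n_stable(as)) return(1e6)
  if (is.character(problem$target_select)) {
    as <- classify_phenotype(as, problem$rules)
    tgt_lab <- problem$target_select
    if (is.null(attractor_by_label(as, tgt_lab))) return(1e6)
    return(do.call(delta_S_A,
                   c(list(x = sys, as = as, target = tgt_lab),
                     problem$map_args)))
  }
  ti <- problem$target_select(as)
  if (is.na(ti) || ti < 1) return(1e6)
  A <- stable_states(as, full = FALSE)
  tgt <- A[ti, ]
  total <- 0
  for (i in seq_len(nrow(A))) {
    if (i == ti) next
    total <- total +
      do.call(minimize_action, c(list(x = sys, from = A[i, ], to = tgt),
                                 problem$map_args))$action -
      do.call(minimize_action, c(list(x = sys, from = tgt, to = A[i, ]),
                                 problem$map_args))$action
  }
  total
}

#' Optimize a landscape-control problem
#'
#' Bound-constrained minimization of the transition-action objective by
#' quasi-Newton descent (Brent line search for a single parameter), with
#' several restarts from perturbed initial parameter vectors; the
#' per-parameter sensitivities `(p_opt - p_base)/p_base` are averaged
#' across restarts (multi-start protocol).
#'
#' @param problem a `control_problem`.
#' @param restarts number of optimization restarts (first from the
#'   baseline, the rest from seeded random points inside the bounds).
#' @param seed integer seed.
#' @param budget iteration cap per restart; 0 returns the baseline with
#'   zero sensitivities.
#' @return a `control_result`: list with `par_opt` (best restart),
#'   `objective_baseline`, `objective_opt`, `sensitivity` (averaged over
#'   restarts), and `restarts` (per-restart detail).
#' @export
optimize_control <- function(problem, restarts = 7, seed = 1, budget = 50) {
  base <- problem$baseline
  f0 <- control_objective(problem, base)
  if (f0 >= 1e6) stop("objective undefined at baseline (target state absent)")
  if (budget == 0) {
    return(structure(list(par_opt = base, objective_baseline = f0,
                          objective_opt = f0,
                          sensitivity = setNames(rep(0, length(base)),
                                                 names(base)),
                          restarts = list()),
                     class = "control_result"))
  }
  set.seed(seed)
  runs <- list()
  for (r in seq_len(restarts)) {
    th0 <- if (r == 1) base else
      problem$lower + stats::runif(length(base)) * (problem$upper - problem$lower)
    fn <- function(th) control_objective(problem, th)
    res <- tryCatch({
      if (length(base) == 1) {
        o <- stats::optim(th0, fn, method = "Brent",
                          lower = problem$lower, upper = problem$upper,
                          control = list(maxit = budget))
      } else {
        # box-constrained PORT routine; the inner action minimization
        # already uses L-BFGS-B and the two must not be nested.  An
        # explicit central-difference gradient with a generous step keeps
        # the search robust to the small convergence noise of the inner
        # action minimizations.
        fd_step <- 0.01 * (problem$upper - problem$lower)
        grad <- function(th) {
          vapply(seq_along(th), function(j) {
            e <- numeric(length(th)); e[j] <- fd_step[j]
            hi <- pmin(th + e, problem$upper)
            lo <- pmax(th - e, problem$lower)
            (fn(hi) - fn(lo)) / sum(hi[j] - lo[j])
          }, numeric(1))
        }
        o <- stats::nlminb(th0, fn, gradient = grad, lower = problem$lower,
                           upper = problem$upper,
                           control = list(iter.max = budget,
                                          eval.max = 2 * budget + 5))
        o <- list(par = o$par, value = o$objective, convergence = o$convergence)
      }
      o
    }, error = function(e) {
      warning("restart ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    runs[[length(runs) + 1]] <-
      list(par = setNames(res$par, names(base)), value = res$value,
           start = th0,
           sensitivity = (res$par - base) / ifelse(base != 0, base, 1))
  }
  if (!length(runs)) stop("all restarts failed")
  vals <- vapply(runs, function(x) x$value, numeric(1))
  best <- runs[[which.min(vals)]]
  sens <- Reduce(`+`, lapply(runs, function(x) x$sensitivity)) / length(runs)
  structure(list(par_opt = best$par, objective_baseline = f0,
                 objective_opt = min(best$value, f0),
                 sensitivity = setNames(sens, names(base)),
                 restarts = runs),
            class = "control_result")
}

#' @export
print.control_result <- function(x, ...) {
  cat(sprintf("<control_result> objective %.5g -> %.5g over %d restart(s)\n",
              x$objective_baseline, x$objective_opt, length(x$restarts)))
  invisible(x)
}

#' Rank parameters by control sensitivity
#'
#' Sensitivity of a parameter is its relative change from baseline to the
#' control optimum; a positive sign means increasing the parameter
#' promotes the target state.
#'
#' @param result a `control_result`.
#' @param k how many top parameters to return (truncated to the total).
#' @param druggable optional named logical marking parameters a drug can
#'   plausibly act on (Hill exponents and fold changes are typically
#'   not); carried through to the output for reporting.
#' @return data frame sorted by `|sensitivity|` descending.
#' @export
sensitivity_ranking <- function(result, k = 10, druggable = NULL) {
  s <- result$sensitivity
  ord <- order(abs(s), decreasing = TRUE)
  out <- data.frame(param = names(s)[ord], sensitivity = unname(s[ord]))
  if (!is.null(druggable))
    out$druggable <- unname(druggable[out$param])
  utils::head(out, min(k, nrow(out)))
}

#' Control problem over a network's kinetic parameters
#'
#' Convenience wrapper building a [control_problem()] whose factory edits
#' a `cac_network` by parameter address.  Hill exponents are rounded to
#' integers in 1..6 when applied (cooperativity is not continuous).
#'
#' @param net baseline network.
#' @param params parameter addresses to free; default all of
#'   [free_parameters()].
#' @param bound_factor multiplicative bound half-width.
#' @param target_label phenotype label to promote.
#' @param rules marker rules.
#' @param ... forwarded to [control_problem()].
#' @return a `control_problem`.
#' @export
network_control_problem <- function(net, params = NULL, bound_factor = 10,
                                    target_label = "A",
                                    rules = cac_marker_rules(), ...) {
  fp <- free_parameters(net)
  if (is.null(params)) params <- fp$param
  base <- get_params(net, params)
  is_n <- startsWith(params, "n:")
  lower <- ifelse(is_n, 1, base / bound_factor)
  upper <- ifelse(is_n, 6, base * bound_factor)
  factory <- function(theta) {
    theta[is_n] <- pmin(pmax(round(theta[is_n]), 1), 6)
    set_params(net, theta)
  }
  control_problem(factory, base, lower, upper,
                  target_select = target_label, rules = rules, ...)
}
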