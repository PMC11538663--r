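#' One-parameter bifurcation scan
#'
#' Sweeps a single parameter (typically a drug input level such as
#' TGF-beta) over a grid, locating all fixed points at every grid value.
#' Previously found points are carried along as warm starts so branches
#' are continued cheaply; fresh multi-starts at every grid point guard
#' against newly born branches.  Saddle-node (fold) locations are
#' reported as midpoints of the grid cells where the stable-branch count
#' changes.
#'
#' @param net a `cac_network`.
#' @param param parameter address (see [free_parameters()]), e.g.
#'   `"input:TGFB"`.
#' @param from,to scan range.
#' @param step grid resolution (<= 0.05 for thresholds quoted to one
#'   decimal place).
#' @param n_starts fresh Latin-hypercube starts per grid value.
#' @param seed integer seed.
#' @param rules optional marker rules; when given, stable points are
#'   labelled per grid value.
#' @param ... forwarded to [find_attractors()] (e.g. `t_long`); branch
#'   continuation via warm starts means a shorter horizon than the
#'   default suffices.
#' @return a `bifurcation_diagram`: list with `param`, `grid`,
#'   `attractors` (list of `attractor_set`), `n_stable` (integer per grid
#'   value) and `folds` (parameter values where the stable count
#'   changes).
#' @export
bifurcation_scan <- function(net, param, from, to, step = 0.05,
                             n_starts = 60, seed = 1, rules = NULL, ...) {
  fp <- free_parameters(net)
  if (!param %in% fp$param) stop("unknown parameter: ", param)
  grid <- seq(from, to, by = step)
  sets <- vector("list", length(grid))
  warm <- NULL
  for (g in seq_along(grid)) {
    net_g <- set_params(net, setNames(grid[g], param))
    as_g <- find_attractors(net_g, n_starts = n_starts, seed = seed + g,
                            starts = warm, find_saddles = TRUE, ...)
    if (!is.null(rules) && length(as_g$stable))
      as_g <- classify_phenotype(as_g, rules)
    sets[[g]] <- as_g
    if (length(as_g$stable))
      warm <- as_g$states[, as_g$active, drop = FALSE]
  }
  ns <- vapply(sets, n_stable, integer(1))
  chg <- which(diff(ns) != 0)
  folds <- (grid[chg] + grid[chg + 1]) / 2
  structure(list(param = param, grid = grid, attractors = sets,
                 n_stable = ns, folds = folds),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("<bifurcation_diagram> %s in [%g, %g], %d grid points\n",
              x$param, min(x$grid), max(x$grid), length(x$grid)))
  cat("stable-branch counts:", paste(rle(x$n_stable)$values, collapse = " -> "),
      "\n")
  if (length(x$folds)) cat("folds at:", paste(round(x$folds, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate a bifurcation diagram
#'
#' Long-format table of all fixed points across the scan, suitable for
#' TSV export or plotting one coordinate against the scanned parameter.
#'
#' @param bd a `bifurcation_diagram`.
#' @return data frame with the parameter value, stability flag, label (if
#'   classified) and one column per node coordinate.
#' @export
bifurcation_table <- function(bd) {
  out <- do.call(rbind, lapply(seq_along(bd$grid), function(g) {
    as_g <- bd$attractors[[g]]
    if (!length(as_g$stable)) return(NULL)
    df <- as.data.frame(as_g$states)
    df <- cbind(data.frame(param_value = bd$grid[g], stable = as_g$stable,
                           label = as_g$labels), df)
    df
  }))
  rownames(out) <- NULL
  out
}
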