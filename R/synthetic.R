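#' Generate a synthetic cluster-structured expression matrix
#'
#' Emulates the statistical structure of bulk expression data over a set
#' of cell states: each sample's per-gene expression is the state's
#' attractor mean perturbed by multiplicative log-normal noise
#' (RNA-seq-like dispersion),
#' `x = exp(log(mean) + N(0, noise_sd^2))`.
#' At zero noise the generator embeds the attractor states exactly.
#'
#' @param states matrix of state means (rows = states, columns = genes),
#'   or an `attractor_set` whose stable states are used.
#' @param labels state labels (recycled to rows of `states`); defaults to
#'   the attractor labels.
#' @param n_per_state samples generated per state.
#' @param noise_sd log-scale noise standard deviation, `>= 0`.
#' @param seed integer seed.
#' @param floor non-positive state means are offset to this value before
#'   taking logs (with a message), since log-normal noise needs a
#'   positive location.
#' @return a `synthetic_expression`: list with `matrix` (genes x
#'   samples), `sample_labels`, `states`, `noise_sd`, `seed`.
#' @export
generate_expression <- function(states, labels = NULL, n_per_state = 20,
                                noise_sd = 0.3, seed = 1, floor = 1e-3) {
  if (inherits(states, "attractor_set")) {
    if (is.null(labels)) labels <- states$labels[states$stable]
    states <- stable_states(states, full = FALSE)
  }
  states <- as.matrix(states)
  if (nrow(states) < 2) stop("need at least 2 states")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(labels)) labels <- paste0("state", seq_len(nrow(states)))
  labels <- rep_len(labels, nrow(states))
  if (any(states <= 0)) {
    message("offsetting ", sum(states <= 0),
            " non-positive state mean(s) to ", floor)
    states[states <= 0] <- floor
  }
  set.seed(seed)
  G <- ncol(states)
  cols <- list(); slab <- character(0)
  for (s in seq_len(nrow(states))) {
    mu <- log(states[s, ])
    E <- exp(matrix(mu, G, n_per_state) +
               matrix(stats::rnorm(G * n_per_state, sd = noise_sd), G, n_per_state))
    cols[[s]] <- E
    slab <- c(slab, paste0(labels[s], "_", seq_len(n_per_state)))
  }
  M <- do.call(cbind, cols)
  rownames(M) <- colnames(states)
  colnames(M) <- slab
  structure(list(matrix = M,
                 sample_labels = rep(labels, each = n_per_state),
                 states = states, noise_sd = noise_sd, seed = seed),
            class = "synthetic_expression")
}

#' @export
print.synthetic_expression <- function(x, ...) {
  cat(sprintf("<synthetic_expression> %d genes x %d samples, %d states, noise_sd = %g\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(x$sample_labels)), x$noise_sd))
  invisible(x)
}

# Per-gene z-scoring across columns; constant genes map to 0.
zscore_rows <- function(M) {
  mu <- rowMeans(M)
  sd <- apply(M, 1, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  sweep(sweep(M, 1, mu), 1, sd, "/")
}

#' Compare model states against an expression matrix
#'
#' Both sides are z-scored per gene (model states across states, data
#' across its per-label centroids) after mapping model node names onto
#' data gene symbols; reports a per-gene per-state absolute difference
#' table and the Pearson correlation of every model state with every data
#' centroid.
#'
#' @param states matrix of model states (rows = states, named), or an
#'   `attractor_set`.
#' @param expr a `synthetic_expression`, or a genes x samples matrix.
#' @param sample_labels labels per sample (taken from the
#'   `synthetic_expression` when absent).
#' @param gene_map optional named character vector mapping model node
#'   names to data gene symbols (e.g. `c(PPARG = "PPARG")`).
#' @return list with `difference` (states x genes absolute z-difference
#'   vs the same-label centroid where labels match, else vs the centroid
#'   grid) and `correlation` (model states x data centroids).
#' @export
compare_states_to_data <- function(states, expr, sample_labels = NULL,
                                   gene_map = NULL) {
  state_labels <- NULL
  if (inherits(states, "attractor_set")) {
    state_labels <- states$labels[states$stable]
    states <- stable_states(states, full = FALSE)
  }
  if (inherits(expr, "synthetic_expression")) {
    sample_labels <- sample_labels %||% expr$sample_labels
    expr <- expr$matrix
  }
  states <- as.matrix(states)
  if (is.null(state_labels))
    state_labels <- rownames(states) %||% paste0("state", seq_len(nrow(states)))
  if (is.null(sample_labels)) stop("sample_labels required")
  cn <- colnames(states)
  if (!is.null(gene_map)) cn <- ifelse(cn %in% names(gene_map), gene_map[cn], cn)
  shared <- intersect(cn, rownames(expr))
  if (!length(shared)) stop("no genes shared between model and data")
  Sm <- t(states[, match(shared, cn), drop = FALSE])  # genes x states
  rownames(Sm) <- shared; colnames(Sm) <- state_labels
  centroids <- sapply(split(seq_along(sample_labels), sample_labels),
                      function(j) rowMeans(expr[shared, j, drop = FALSE]))
  Zm <- zscore_rows(Sm)
  Zd <- zscore_rows(centroids)
  corr <- stats::cor(Zm, Zd)
  common_lab <- intersect(colnames(Zm), colnames(Zd))
  diff <- if (length(common_lab))
    t(abs(Zm[, common_lab, drop = FALSE] - Zd[, common_lab, drop = FALSE]))
  else NULL
  list(difference = diff, correlation = corr,
       genes = shared)
}
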