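#' Construct a Hill-regulation gene network specification
#'
#' Defines the ODE model
#' \deqn{\frac{dX}{dt} = g_X \, G - k_X \, K \, X}
#' where `G` and `K` are products of shifted Hill factors
#' ([shifted_hill()]) over the regulations entering the synthesis side
#' (`side = "G"`) or the degradation side (`side = "K"`) of node `X`.
#' Drug nodes (`is_input = TRUE`) are held at fixed levels and have zero
#' dynamics; they may regulate other nodes but are never themselves
#' regulated dynamically.
#'
#' @param nodes data frame with columns `name` (character), `g` (basal
#'   synthesis rate, `>= 0`, concentration/time), `k` (basal degradation
#'   rate, `> 0`, 1/time) and optionally `is_input` (logical, default
#'   `FALSE`).
#' @param edges data frame with columns `source`, `target` (node names),
#'   `lambda` (fold change `> 0`; `> 1` activation, `< 1` inhibition),
#'   `S` (threshold `> 0`), `n` (Hill exponent, integer `>= 1`) and
#'   optionally `side` (`"G"` synthesis or `"K"` degradation, default
#'   `"G"`).
#' @param inputs named numeric vector of levels for the input nodes
#'   (must cover every node with `is_input = TRUE`).
#' @return an object of class `cac_network`.
#' @export
network_spec <- function(nodes, edges, inputs = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(nodes$is_input)) nodes$is_input <- FALSE
  if (nrow(edges) && is.null(edges$side)) edges$side <- "G"
  net <- structure(
    list(nodes = nodes[c("name", "g", "k", "is_input")],
         edges = if (nrow(edges)) edges[c("source", "target", "lambda", "S", "n", "side")]
                 else edges,
         inputs = inputs %||% setNames(numeric(0), character(0))),
    class = "cac_network")
  validate_network(net)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a network specification
#'
#' Checks all structural invariants: declared edge endpoints, positive
#' rates, activation/inhibition consistency of fold changes, input levels
#' supplied for every input node.
#'
#' @param net a `cac_network`.
#' @return `net`, invisibly; stops with an informative error otherwise.
#' @export
validate_network <- function(net) {
  nd <- net$nodes; ed <- net$edges
  if (!nrow(nd)) stop("network has no nodes")
  if (anyDuplicated(nd$name)) stop("duplicated node names")
  if (any(nd$k <= 0)) stop("degradation rates k must be positive: ",
                           paste(nd$name[nd$k <= 0], collapse = ", "))
  if (any(nd$g < 0)) stop("synthesis rates g must be non-negative")
  if (all(nd$is_input)) stop("network needs at least one non-input node")
  if (nrow(ed)) {
    bad <- !(ed$source %in% nd$name) | !(ed$target %in% nd$name)
    if (any(bad)) stop("edges reference undeclared nodes: ",
                       paste(unique(c(ed$source[bad], ed$target[bad])), collapse = ", "))
    if (any(nd$is_input[match(ed$target, nd$name)]))
      stop("input nodes cannot be regulation targets")
    if (any(ed$lambda <= 0)) stop("fold changes lambda must be positive")
    if (any(ed$S <= 0)) stop("thresholds S must be positive")
    if (any(ed$n < 1) || any(ed$n != round(ed$n)))
      stop("Hill exponents n must be integers >= 1")
    if (!all(ed$side %in% c("G", "K"))) stop("edge side must be 'G' or 'K'")
  }
  inp <- nd$name[nd$is_input]
  missing_inp <- setdiff(inp, names(net$inputs))
  if (length(missing_inp)) stop("missing input levels for: ",
                                paste(missing_inp, collapse = ", "))
  if (length(net$inputs) && any(net$inputs < 0)) stop("input levels must be >= 0")
  invisible(net)
}

#' @export
print.cac_network <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("<cac_network> %d nodes (%d dynamic, %d input), %d regulations\n",
              nrow(nd), sum(!nd$is_input), sum(nd$is_input), nrow(x$edges)))
  if (length(x$inputs))
    cat("inputs:", paste(sprintf("%s=%g", names(x$inputs), x$inputs), collapse = ", "), "\n")
  invisible(x)
}

#' Node names of a network
#' @param net a `cac_network`.
#' @param dynamic if `TRUE`, only non-input nodes.
#' @return character vector of node names in model order.
#' @export
node_names <- function(net, dynamic = FALSE) {
  if (dynamic) net$nodes$name[!net$nodes$is_input] else net$nodes$name
}

# Full state vector (all nodes, inputs at their fixed levels) from
# dynamic coordinates, and the reverse projection.
full_state <- function(net, x_dyn) {
  nd <- net$nodes
  x <- setNames(numeric(nrow(nd)), nd$name)
  x[!nd$is_input] <- x_dyn
  if (length(net$inputs)) x[names(net$inputs)] <- net$inputs
  x
}

# Precompile a network into plain index/parameter arrays so the vector
# field and Jacobian avoid repeated name matching in inner loops.
net_compile <- function(net) {
  nd <- net$nodes; ed <- net$edges
  ne <- if (is.null(ed)) 0 else nrow(ed)
  list(d = nrow(nd), names = nd$name, g = nd$g, k = nd$k,
       is_input = nd$is_input, ne = ne,
       si = if (ne) match(ed$source, nd$name) else integer(0),
       ti = if (ne) match(ed$target, nd$name) else integer(0),
       S = ed$S, lam = ed$lambda, n = ed$n,
       isG = if (ne) ed$side == "G" else logical(0))
}

# Fast vectorized rates on a states-by-nodes matrix for a compiled network.
net_rates <- function(cn, X) {
  m <- nrow(X)
  G <- matrix(1, m, cn$d); K <- matrix(1, m, cn$d)
  for (e in seq_len(cn$ne)) {
    u <- (X[, cn$si[e]] / cn$S[e])^cn$n[e]
    h <- 1 + (cn$lam[e] - 1) * u / (1 + u)
    if (cn$isG[e]) G[, cn$ti[e]] <- G[, cn$ti[e]] * h
    else K[, cn$ti[e]] <- K[, cn$ti[e]] * h
  }
  R <- sweep(G, 2, cn$g, "*") - sweep(K, 2, cn$k, "*") * X
  R[, cn$is_input] <- 0
  R
}

# Fast analytic Jacobian at one state for a compiled network.
net_jac <- function(cn, x) {
  d <- cn$d
  H <- numeric(cn$ne); Hd <- numeric(cn$ne)
  for (e in seq_len(cn$ne)) {
    H[e]  <- shifted_hill(x[cn$si[e]], cn$S[e], cn$lam[e], cn$n[e])
    Hd[e] <- shifted_hill_deriv(x[cn$si[e]], cn$S[e], cn$lam[e], cn$n[e])
  }
  Gp <- rep(1, d); Kp <- rep(1, d)
  for (e in seq_len(cn$ne)) {
    if (cn$isG[e]) Gp[cn$ti[e]] <- Gp[cn$ti[e]] * H[e]
    else Kp[cn$ti[e]] <- Kp[cn$ti[e]] * H[e]
  }
  A <- matrix(0, d, d, dimnames = list(cn$names, cn$names))
  diag(A) <- -cn$k * Kp
  for (e in seq_len(cn$ne)) {
    i <- cn$ti[e]; j <- cn$si[e]
    partial <- if (H[e] != 0) Hd[e] / H[e] else 0
    if (cn$isG[e]) A[i, j] <- A[i, j] + cn$g[i] * Gp[i] * partial
    else A[i, j] <- A[i, j] - cn$k[i] * x[i] * Kp[i] * partial
  }
  A[cn$is_input, ] <- 0
  A
}

#' Deterministic vector field of the network ODE
#'
#' Evaluates `dX/dt = g_X G - k_X K X` for every node; input nodes get
#' rate 0.
#'
#' @param state named (or model-ordered) numeric vector over all nodes,
#'   or a matrix with one state per row.
#' @param net a `cac_network`.
#' @return rate vector (or matrix) matching `state`.
#' @export
ode_rhs <- function(state, net) {
  cn <- net_compile(net)
  one_row <- is.null(dim(state))
  X <- if (one_row) matrix(state, nrow = 1) else as.matrix(state)
  if (ncol(X) != cn$d) stop("state length must equal node count")
  if (any(X < 0)) stop("state entries must be non-negative")
  R <- net_rates(cn, X)
  if (one_row) setNames(drop(R), cn$names) else R
}

#' Analytic Jacobian of the network vector field
#'
#' Matrix `A` with `A[i, j] = dF_i/dx_j` evaluated at `state`; rows for
#' input nodes are zero.  Used for stability spectra, moment equations and
#' minimum-action gradients.
#'
#' @inheritParams ode_rhs
#' @return a `d x d` matrix (d = node count) with dimnames.
#' @export
network_jacobian <- function(state, net) {
  cn <- net_compile(net)
  x <- as.numeric(state)
  if (length(x) != cn$d) stop("state length must equal node count")
  net_jac(cn, x)
}

# ---- parameter addressing -------------------------------------------------
# Parameters are addressed by strings:
#   "g:NODE", "k:NODE", "input:NODE",
#   "lambda:SRC->TGT", "S:SRC->TGT", "n:SRC->TGT"
edge_key <- function(edges) paste0(edges$source, "->", edges$target)

#' Enumerate the free parameters of a network
#'
#' The landscape-control search space: basal synthesis and degradation
#' rates of every dynamic node, fold change / threshold / Hill exponent of
#' every regulation, and the drug input levels.  Hill exponents `n` and
#' fold changes `lambda` are flagged non-druggable (hard to target
#' pharmacologically) but remain in the search space.
#'
#' @param net a `cac_network`.
#' @return data frame with columns `param`, `value`, `druggable`.
#' @export
free_parameters <- function(net) {
  nd <- net$nodes; ed <- net$edges
  dyn <- nd[!nd$is_input, ]
  out <- data.frame(param = character(0), value = numeric(0),
                    druggable = logical(0), stringsAsFactors = FALSE)
  add <- function(param, value, druggable)
    rbind(out, data.frame(param = param, value = value, druggable = druggable))
  out <- add(paste0("g:", dyn$name), dyn$g, TRUE)
  out <- add(paste0("k:", dyn$name), dyn$k, TRUE)
  if (nrow(ed)) {
    ek <- edge_key(ed)
    out <- add(paste0("lambda:", ek), ed$lambda, FALSE)
    out <- add(paste0("S:", ek), ed$S, TRUE)
    out <- add(paste0("n:", ek), ed$n, FALSE)
  }
  if (length(net$inputs))
    out <- add(paste0("input:", names(net$inputs)), unname(net$inputs), TRUE)
  rownames(out) <- NULL
  out
}

#' Read network parameters by address
#' @param net a `cac_network`.
#' @param params character vector of parameter addresses (see
#'   [free_parameters()]); `NULL` means all free parameters.
#' @return named numeric vector.
#' @export
get_params <- function(net, params = NULL) {
  fp <- free_parameters(net)
  if (is.null(params)) params <- fp$param
  idx <- match(params, fp$param)
  if (anyNA(idx)) stop("unknown parameter(s): ",
                       paste(params[is.na(idx)], collapse = ", "))
  setNames(fp$value[idx], params)
}

#' Set network parameters by address
#' @param net a `cac_network`.
#' @param values named numeric vector, names as in [free_parameters()].
#' @return a new `cac_network`; the original is untouched.
#' @export
set_params <- function(net, values) {
  stopifnot(!is.null(names(values)))
  nd <- net$nodes; ed <- net$edges
  ek <- if (nrow(ed)) edge_key(ed) else character(0)
  for (nm in names(values)) {
    v <- unname(values[[nm]])
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed parameter address: ", nm)
    kind <- parts[1]; who <- parts[2]
    if (kind %in% c("g", "k")) {
      i <- match(who, nd$name)
      if (is.na(i)) stop("unknown node in parameter: ", nm)
      nd[[kind]][i] <- v
    } else if (kind == "input") {
      if (!who %in% names(net$inputs)) stop("unknown input in parameter: ", nm)
      net$inputs[[who]] <- v
    } else if (kind %in% c("lambda", "S", "n")) {
      e <- match(who, ek)
      if (is.na(e)) stop("unknown edge in parameter: ", nm)
      ed[[kind]][e] <- v
    } else stop("unknown parameter kind: ", kind)
  }
  net$nodes <- nd; net$edges <- ed
  validate_network(net)
  net
}

#' Apply a multiplicative intervention to named parameters
#'
#' Models drug perturbations as fold changes of kinetic parameters or
#' input levels, e.g. a 500x dose of a ZEB1 activator multiplies
#' `"g:ZEB1"` by 500.
#'
#' @param net a `cac_network`.
#' @param multipliers named numeric vector of positive factors, names as
#'   in [free_parameters()].
#' @return a new `cac_network` with scaled parameters.
#' @export
apply_intervention <- function(net, multipliers) {
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  base <- get_params(net, names(multipliers))
  set_params(net, base * multipliers)
}
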