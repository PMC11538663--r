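#' Generic vector-field object
#'
#' Light container unifying Hill networks and analytic toy systems so the
#' attractor search, Langevin simulator, moment solver and minimum-action
#' optimizer all operate on the same interface.
#'
#' @param fun function taking a states-by-coordinates matrix and returning
#'   the matrix of rates (same shape).
#' @param jac function taking one state vector and returning the `d x d`
#'   Jacobian.
#' @param d state dimension.
#' @param names coordinate names.
#' @param active integer indices of the dynamical coordinates (the rest
#'   are clamped inputs).
#' @param fixed named values of the clamped coordinates.
#' @param nonneg are coordinates constrained to be non-negative
#'   (concentrations)?  Toy potentials may live on the whole line.
#' @param range per-coordinate upper bound of the multi-start sampling box.
#' @param facts optional list of analytic facts (fixed points, barriers,
#'   stationary variances) for oracle tests.
#' @return an object of class `vector_field`.
#' @export
vector_field <- function(fun, jac, d, names = paste0("x", seq_len(d)),
                         active = seq_len(d), fixed = NULL, nonneg = TRUE,
                         range = rep(1, d), facts = NULL) {
  structure(list(fun = fun, jac = jac, d = d, names = names,
                 active = active, fixed = fixed, nonneg = nonneg,
                 range = range, facts = facts),
            class = "vector_field")
}

#' Coerce to a vector field
#' @param x a `cac_network` or `vector_field`.
#' @param ... unused.
#' @return a `vector_field`.
#' @export
as_vector_field <- function(x, ...) UseMethod("as_vector_field")

#' @export
as_vector_field.vector_field <- function(x, ...) x

#' @export
as_vector_field.cac_network <- function(x, ...) {
  net <- x
  nd <- net$nodes
  d <- nrow(nd)
  active <- which(!nd$is_input)
  fixed <- if (length(net$inputs)) net$inputs else NULL
  # Sampling box: [0, 2 g/k] per dynamic coordinate (max unregulated level
  # times the largest fold amplification is unknowable; 2 g/k covers the
  # attainable range for lambda-bounded regulation in practice).
  gmax <- ifelse(nd$k > 0, nd$g / nd$k, 1)
  amp <- rep(1, d)
  if (nrow(net$edges)) {
    ag <- tapply(pmax(net$edges$lambda, 1), match(net$edges$target, nd$name),
                 prod)
    amp[as.integer(names(ag))] <- as.numeric(ag)
  }
  rng <- 2 * pmax(gmax * pmin(amp, 10), 1e-3)
  fx <- setNames(numeric(d), nd$name)
  if (length(net$inputs)) fx[names(net$inputs)] <- net$inputs
  cn <- net_compile(net)
  vector_field(
    fun = function(X) net_rates(cn, X),
    jac = function(x) net_jac(cn, x),
    d = d, names = nd$name, active = active,
    fixed = fixed, nonneg = TRUE, range = rng)
}

# Embed dynamic coordinates into a full state row-matrix with clamped
# inputs filled in.
vf_embed <- function(vf, Xa) {
  if (is.null(dim(Xa))) Xa <- matrix(Xa, nrow = 1)
  X <- matrix(0, nrow(Xa), vf$d, dimnames = list(NULL, vf$names))
  X[, vf$active] <- Xa
  if (!is.null(vf$fixed))
    X[, names(vf$fixed)] <- matrix(vf$fixed, nrow(Xa), length(vf$fixed),
                                   byrow = TRUE)
  X
}

# Rates restricted to active coordinates, for active-coordinate states.
vf_f_active <- function(vf, Xa) {
  R <- vf$fun(vf_embed(vf, Xa))
  R[, vf$active, drop = FALSE]
}

# Active-block Jacobian at an active-coordinate state vector.
vf_jac_active <- function(vf, xa) {
  J <- vf$jac(drop(vf_embed(vf, xa)))
  J[vf$active, vf$active, drop = FALSE]
}
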