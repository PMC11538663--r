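#' Toy systems with closed-form properties
#'
#' Small dynamical systems whose fixed points, barrier heights and
#' stationary variances are known analytically; they anchor the oracle
#' tests of every analysis stage.
#'
#' * `"ou1d"`: linear relaxation `F = g - k x` (Ornstein-Uhlenbeck under
#'   noise); fixed point `g/k`, stationary variance `D/k`.
#' * `"double_well_1d"`: gradient field of `V(x) = x^4/4 - x^2/2`
#'   (`F = x - x^3`); minima at -1 and +1, saddle at 0, barrier 0.25.
#' * `"tilted_well"`: `V(x) = x^4/4 - x^2/2 - h x` (`F = x - x^3 + h`);
#'   the tilt `h` deepens the right well for `h > 0`.
#' * `"toggle_switch"`: symmetric two-gene mutual-inhibition network
#'   (shifted-Hill inhibition both ways), the canonical bistable circuit;
#'   returned as a [network_spec()].  The default parameterization puts
#'   expression levels well above the noise scale of the stochastic
#'   analyses (barrier action much larger than typical diffusion
#'   coefficients), i.e. inside the small-noise regime the mean-field
#'   Gaussian approximation assumes.
#'
#' @param name one of `"ou1d"`, `"double_well_1d"`, `"tilted_well"`,
#'   `"toggle_switch"`.
#' @param k,g rate constants for `"ou1d"`.
#' @param h tilt for `"tilted_well"`.
#' @param lambda,S,n,g_tog,k_tog toggle-switch Hill parameters.
#' @return a `vector_field` (1-D toys) or `cac_network`
#'   (`"toggle_switch"`), each carrying a `facts` list (fixed points,
#'   `V`, barrier, variance formulas) for test assertions.
#' @export
make_toy <- function(name, k = 2, g = 0, h = 0.15,
                     lambda = 0.1, S = 3.2, n = 4, g_tog = 8, k_tog = 1) {
  switch(
    name,
    ou1d = {
      vector_field(
        fun = function(X) matrix(g - k * X[, 1], ncol = 1),
        jac = function(x) matrix(-k, 1, 1),
        d = 1, names = "x", nonneg = FALSE, range = 2 * max(abs(g / k), 1),
        facts = list(fixed_point = g / k,
                     stationary_variance = function(D) D / k, k = k, g = g))
    },
    double_well_1d = {
      V <- function(x) x^4 / 4 - x^2 / 2
      vector_field(
        fun = function(X) matrix(X[, 1] - X[, 1]^3, ncol = 1),
        jac = function(x) matrix(1 - 3 * x[1]^2, 1, 1),
        d = 1, names = "x", nonneg = FALSE, range = 2,
        facts = list(V = V, minima = c(-1, 1), saddle = 0, barrier = 0.25,
                     map_action = 0.5))  # 2 * [V(0) - V(-1)]
    },
    tilted_well = {
      V <- function(x) x^4 / 4 - x^2 / 2 - h * x
      rts <- sort(Re(polyroot(c(h, 1, 0, -1))[abs(Im(polyroot(c(h, 1, 0, -1)))) < 1e-8]))
      vector_field(
        fun = function(X) matrix(X[, 1] - X[, 1]^3 + h, ncol = 1),
        jac = function(x) matrix(1 - 3 * x[1]^2, 1, 1),
        d = 1, names = "x", nonneg = FALSE, range = 2,
        facts = list(V = V, h = h,
                     critical_points = rts,
                     # For |h| < 2/(3 sqrt 3) the wells sit near -1 and +1
                     deep_well = if (h > 0) max(rts) else min(rts)))
    },
    toggle_switch = {
      nodes <- data.frame(name = c("A", "B"), g = g_tog, k = k_tog,
                          is_input = FALSE)
      edges <- data.frame(source = c("A", "B"), target = c("B", "A"),
                          lambda = lambda, S = S, n = n, side = "G")
      net <- network_spec(nodes, edges)
      # Symmetric fixed point solves g * Hs(x) - k x = 0 in 1-D.
      froot <- function(x) g_tog * shifted_hill(x, S, lambda, n) - k_tog * x
      xs <- stats::uniroot(froot, c(1e-9, g_tog / k_tog + 1), tol = 1e-12)$root
      net$facts <- list(symmetric_state = xs, lambda = lambda, S = S, n = n,
                        g = g_tog, k = k_tog)
      net
    },
    stop("unknown toy system: ", name))
}
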