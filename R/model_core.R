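#' Propensities and stoichiometry of the burst model
#'
#' Assembles the four reaction channels. For burst size `r` the
#' propensity vector is `c(k1, k2*x, k3*x^2/r, k4*x^3)` and the
#' stoichiometric vector is `c(+1, -1, +r, -1)`; their inner product is
#' the deterministic drift `A(x)` for every state, so the rate equation
#' is independent of `r` by construction. The polynomial rate forms are
#' used as given (not combinatorial falling factorials).
#'
#' @param params A [schlogl_params()] object.
#' @return An object of class `reaction_system`: list with
#'   * `propensities`: function of a state vector `x`, returning an
#'     `length(x) x 4` matrix of channel rates;
#'   * `S`: integer stoichiometric vector `c(1, -1, r, -1)`.
#' @examples
#' sys <- build_system(schlogl_params(3e6, 77518, 601, r = 25))
#' sys$S
#' sys$propensities(43)
#' @export
build_system <- function(params) {
  params <- as_schlogl_params(params)
  k1 <- params$k1; k2 <- params$k2; k3 <- params$k3; k4 <- params$k4
  r <- params$r
  structure(
    list(
      propensities = function(x) {
        stopifnot(all(x >= 0))
        cbind(nu1 = rep(k1, length(x)), nu2 = k2 * x,
              nu3 = k3 * x^2 / r, nu4 = k4 * x^3)
      },
      S = c(1L, -1L, as.integer(r), -1L),
      params = params
    ),
    class = "reaction_system"
  )
}

#' @export
print.reaction_system <- function(x, ...) {
  cat("<reaction_system>  S = [", paste(x$S, collapse = ", "),
      "]  nu = [k1, k2 x, k3 x^2/r, k4 x^3]\n")
  invisible(x)
}

#' Deterministic drift A(x)
#'
#' `A(x) = k1 - k2 x + k3 x^2 - k4 x^3`, the right-hand side of the
#' rate equation. Identical for every burst size `r`.
#'
#' @param params A [schlogl_params()] object.
#' @param x Non-negative state value(s).
#' @return `A(x)`, vectorised over `x`.
#' @export
drift <- function(params, x) {
  params <- as_schlogl_params(params)
  stopifnot(all(x >= 0))
  params$k1 - params$k2 * x + params$k3 * x^2 - params$k4 * x^3
}

drift_dx <- function(params, x) {
  -params$k2 + 2 * params$k3 * x - 3 * params$k4 * x^2
}

#' Cusp discriminant of the deterministic cubic
#'
#' In reduced rates (`ki/k4`) the condition that the stationary cubic
#' `A(x) = 0` has three real roots is `Delta > 0`, with
#' `Delta = -27 k1^2 + 18 k1 k2 k3 - 4 k1 k3^3 - 4 k2^3 + k2^2 k3^2`.
#' Its sign classifies the deterministic regime: `Delta > 0` bistable,
#' `Delta < 0` monostable, `Delta = 0` the saddle-node boundary.
#'
#' @param params A [schlogl_params()] object (rates are reduced by `k4`
#'   internally).
#' @return The discriminant, a single number.
#' @export
discriminant <- function(params) {
  k <- reduced_params(as_schlogl_params(params))
  -27 * k$k1^2 + 18 * k$k1 * k$k2 * k$k3 - 4 * k$k1 * k$k3^3 -
    4 * k$k2^3 + k$k2^2 * k$k3^2
}

#' Fixed points of the deterministic rate equation
#'
#' Solves `A(x) = 0` in closed form (trigonometric/Cardano, with Newton
#' polish), keeps the roots in the physical domain `x >= 0`, labels
#' stability from the sign of `A'(x)` and attaches the cusp
#' discriminant. Roots closer than 1e-6 (relative) are merged and
#' reported once as a saddle-node (marginal) root.
#'
#' @param params A [schlogl_params()] object.
#' @return A tibble of class `fixed_point_set` with columns `root`
#'   (sorted), `stability` (`"stable"`, `"unstable"` or `"marginal"`)
#'   and `multiplicity`; attributes `discriminant` and `params`.
#' @examples
#' fixed_points(schlogl_params(3e6, 77518, 601))
#' @export
fixed_points <- function(params) {
  params <- as_schlogl_params(params)
  sol <- cubic_roots_real(params$k1, -params$k2, params$k3, -params$k4)
  keep <- sol$roots >= -1e-9 * max(1, abs(sol$roots))
  roots <- pmax(sol$roots[keep], 0)
  mult <- sol$multiplicity[keep]
  ap <- drift_dx(params, roots)
  scale <- params$k2 + 2 * params$k3 * abs(roots) + 3 * params$k4 * roots^2
  stability <- ifelse(mult > 1L | abs(ap) <= 1e-8 * pmax(scale, 1), "marginal",
                      ifelse(ap < 0, "stable", "unstable"))
  out <- tibble::tibble(root = roots, stability = stability,
                        multiplicity = mult)
  structure(out,
            discriminant = discriminant(params),
            params = params,
            class = c("fixed_point_set", class(out)))
}
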