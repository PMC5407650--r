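#' Diffusion function B(x) of the Fokker-Planck approximation
#'
#' Second Kramers-Moyal coefficient of the burst model,
#' `B(x) = k1 + k2 x + r k3 x^2 + k4 x^3`. Only the autocatalytic term
#' feels the burst size: each firing is `r` times rarer but jumps `r`
#' molecules, so its second-moment contribution grows linearly in `r`.
#' For `r = 1`, `B` equals the plain sum of the four propensities.
#'
#' @inheritParams drift
#' @return `B(x)`, vectorised over `x`.
#' @export
diffusion <- function(params, x) {
  params <- as_schlogl_params(params)
  stopifnot(all(x >= 0))
  params$k1 + params$k2 * x + params$r * params$k3 * x^2 + params$k4 * x^3
}

diffusion_dx <- function(params, x) {
  params$k2 + 2 * params$r * params$k3 * x + 3 * params$k4 * x^2
}

#' Extremum function alpha(x) = A(x) - B'(x)/2
#'
#' The stationary density satisfies `d log Ps / dx = 2 alpha(x) / B(x)`,
#' so the interior maxima and minima of the stationary law are exactly
#' the roots of `alpha`. Unlike the drift, `alpha` depends on the burst
#' size through `B'`, which is how bursts move, create and destroy
#' stationary modes without touching the deterministic fixed points.
#'
#' @inheritParams drift
#' @return `alpha(x)`, vectorised over `x`.
#' @export
alpha_fun <- function(params, x) {
  params <- as_schlogl_params(params)
  drift(params, x) - 0.5 * diffusion_dx(params, x)
}

# alpha is itself a cubic; ascending coefficients (c0, c1, c2, c3)
alpha_cubic_coefs <- function(params) {
  c(params$k1 - params$k2 / 2,
    -(params$k2 + params$r * params$k3),
    params$k3 - 1.5 * params$k4,
    -params$k4)
}

# default upper bound of the analysis window: twice the largest
# deterministic root plus 10 r, generous for every mode of this family
default_x_max <- function(params) {
  fp <- fixed_points(params)
  2 * max(fp$root, 1) + 10 * params$r
}

#' Locate the extrema of the stationary density
#'
#' Finds all roots of `alpha(x) = A(x) - B'(x)/2` in `(0, x_max]` by a
#' unit-step sign scan with bisection refinement, and classifies each
#' crossing: a negative-going crossing of `alpha` is a maximum of the
#' stationary density, a positive-going one a minimum. Tangential
#' (double) roots -- the signature of a saddle-node of the stationary
#' law, where a maximum/minimum pair merges -- are detected at the
#' critical points of `alpha` and reported separately, not as two
#' extrema. When `alpha(0) < 0` the density is falling at the origin
#' and a boundary maximum at `x = 0` is reported (flagged).
#'
#' @param params A [schlogl_params()] object with `k1 > 0`.
#' @param x_max Upper end of the scan window; defaults to twice the
#'   largest deterministic root plus `10 r`.
#' @param scan_step Step of the bracketing scan, in molecules.
#' @param tol Absolute bisection tolerance for root location.
#' @param merge_tol Relative tolerance (against the scan-wide scale of
#'   `alpha`) under which a tangential critical point is reported as a
#'   merged extremum pair.
#' @return A tibble of class `extrema_report` with columns `location`,
#'   `type` (`"maximum"`/`"minimum"`) and `boundary` (logical);
#'   attributes `n_maxima`, `merged_pairs` (tibble of bifurcation
#'   points), `boundary_mode`, `params`, `x_max`. Locations are
#'   continuous; round to the nearest integer for molecule counts.
#' @examples
#' find_extrema(schlogl_params(3e6, 77518, 601, r = 25))
#' @export
find_extrema <- function(params, x_max = NULL, scan_step = 1,
                         tol = 1e-9, merge_tol = 1e-6) {
  params <- as_schlogl_params(params)
  require_nonabsorbing(params)
  if (is.null(x_max)) x_max <- default_x_max(params)
  xs <- seq(0, x_max, by = scan_step)
  if (xs[length(xs)] < x_max) xs <- c(xs, x_max)
  av <- alpha_fun(params, xs)
  a_scale <- max(abs(av))

  loc <- type <- numeric(0)
  sgn <- sign(av)
  for (i in seq_len(length(xs) - 1)) {
    if (sgn[i] == 0) next  # exact grid zero handled as crossing below
    if (sgn[i] * av[i + 1] < 0 || (av[i + 1] == 0 && i + 1 == length(xs))) {
      root <- stats::uniroot(function(x) alpha_fun(params, x),
                             lower = xs[i], upper = xs[i + 1],
                             tol = tol)$root
      loc <- c(loc, root)
      type <- c(type, if (av[i] > 0) "maximum" else "minimum")
    }
  }

  # tangential double roots at critical points of alpha (quadratic)
  co <- alpha_cubic_coefs(params)
  disc_q <- (2 * co[3])^2 - 4 * (3 * co[4]) * co[2]
  merged <- numeric(0)
  if (disc_q > 0) {
    crit <- (-2 * co[3] + c(-1, 1) * sqrt(disc_q)) / (2 * 3 * co[4])
    crit <- crit[crit > 0 & crit <= x_max]
    for (xc in crit) {
      near_root <- length(loc) > 0 && min(abs(loc - xc)) < scan_step
      if (!near_root && abs(alpha_fun(params, xc)) < merge_tol * a_scale) {
        merged <- c(merged, xc)
      }
    }
  }

  boundary_mode <- FALSE
  if (av[1] < 0) {
    # density decreasing away from the origin: boundary maximum at 0
    loc <- c(0, loc); type <- c("maximum", type)
    boundary_mode <- length(loc) == 1L
  }
  bnd <- loc == 0
  ord <- order(loc)
  out <- tibble::tibble(location = loc[ord], type = type[ord],
                        boundary = bnd[ord])
  structure(out,
            n_maxima = sum(out$type == "maximum"),
            merged_pairs = tibble::tibble(location = merged),
            boundary_mode = boundary_mode,
            params = params, x_max = x_max,
            class = c("extrema_report", class(out)))
}

#' Stationary density of the Fokker-Planck equation
#'
#' Computes `Ps(x) = N / B(x) * exp(integral_0^x 2 A / B dx')` on a
#' uniform grid. The exponent is accumulated by per-interval Simpson
#' quadrature (midpoints included), everything is kept in log-space
#' until the final normalisation (trapezoid rule on the grid), and the
#' zero-flux (reflecting) boundary at `x = 0` fixes the lower
#' integration limit. Works for every burst size; for `r = 1` the
#' closed-form partial-fraction solution is available as an independent
#' route via `method = "closed_form"`.
#'
#' @inheritParams find_extrema
#' @param x_max Upper end of the grid. When omitted, defaults to twice
#'   the largest deterministic root plus `10 r` and is doubled
#'   automatically until the tail criterion passes. When supplied
#'   explicitly, a violated tail criterion is an error asking for a
#'   larger window.
#' @param grid_step Grid spacing in molecules; must be `<= 0.1` so that
#'   grid extrema resolve integer modes.
#' @param method `"quadrature"` (any `r`) or `"closed_form"`
#'   (`r = 1` only, distinct roots required).
#' @param tail_tol Maximum stationary mass allowed in the top 1% of the
#'   grid (truncation criterion).
#' @return A tibble of class `stationary_density` with columns `x`,
#'   `log_density`, `density`; attributes `params`, `method`,
#'   `log_norm` (log of the normalisation constant applied),
#'   `tail_mass`, `grid_step`, `x_max`.
#' @examples
#' d <- stationary_density(schlogl_params(3e6, 77518, 601, r = 25))
#' glance(d)
#' @export
stationary_density <- function(params, x_max = NULL, grid_step = 0.1,
                               method = c("quadrature", "closed_form"),
                               tail_tol = 1e-9) {
  params <- as_schlogl_params(params)
  require_nonabsorbing(params)
  method <- match.arg(method)
  if (grid_step > 0.1) stop("`grid_step` must be <= 0.1 molecules", call. = FALSE)
  auto <- is.null(x_max)
  if (auto) x_max <- default_x_max(params)
  for (attempt in 1:8) {
    grid <- seq(0, x_max, by = grid_step)
    ld <- if (method == "quadrature") {
      log_density_quadrature(params, grid, grid_step)
    } else {
      log_density_closed_form(params, grid)
    }
    m <- max(ld)
    dens <- exp(ld - m)
    z <- sum((dens[-1] + dens[-length(dens)]) / 2) * grid_step
    log_norm <- m + log(z)
    ld <- ld - log_norm
    dens <- exp(ld)
    tail_idx <- grid >= 0.99 * x_max
    tail_mass <- sum((dens[tail_idx][-1] + utils::head(dens[tail_idx], -1)) / 2) *
      grid_step
    if (tail_mass <= tail_tol) break
    if (!auto) {
      stop("stationary mass ", format(tail_mass), " beyond 0.99*x_max exceeds ",
           format(tail_tol), "; enlarge `x_max`", call. = FALSE)
    }
    x_max <- 2 * x_max
    if (attempt == 8) stop("tail criterion not met after repeated doubling of x_max",
                           call. = FALSE)
  }
  out <- tibble::tibble(x = grid, log_density = ld, density = dens)
  structure(out,
            params = params, method = method, log_norm = log_norm,
            tail_mass = tail_mass, grid_step = grid_step, x_max = x_max,
            class = c("stationary_density", class(out)))
}

log_density_quadrature <- function(params, grid, h) {
  f <- function(x) 2 * drift(params, x) / diffusion(params, x)
  n <- length(grid)
  mid <- grid[-1] - h / 2
  inc <- h / 6 * (f(grid[-n]) + 4 * f(mid) + f(grid[-1]))
  c(0, cumsum(inc)) - log(diffusion(params, grid))
}

# all three roots of A (complex allowed): closed-form real roots plus
# complex-conjugate pair from quadratic deflation when only one is real
roots_of_drift_complex <- function(params) {
  sol <- cubic_roots_real(params$k1, -params$k2, params$k3, -params$k4)
  if (any(sol$multiplicity > 1L)) {
    stop("repeated roots of A(x) (Delta = 0): the partial-fraction ",
         "closed form is invalid; use method = \"quadrature\"", call. = FALSE)
  }
  if (length(sol$roots) == 3L) return(as.complex(sol$roots))
  # monic cubic x^3 + a x^2 + b x + c = A / (-k4)
  a <- -params$k3 / params$k4
  b <- params$k2 / params$k4
  x1 <- sol$roots[1]
  B <- a + x1
  C <- b + x1 * B
  disc <- as.complex(B^2 - 4 * C)
  c(as.complex(x1), (-B + sqrt(disc)) / 2, (-B - sqrt(disc)) / 2)
}

# r = 1 only: log Ps up to a constant, via the partial-fraction
# decomposition of 2A/B. With A = -k4 (x-x1)(x-x2)(x-x3) and
# B = k4 (x+x1)(x+x2)(x+x3),
#   2A/B = -2 + sum_i c_i / (x + x_i),
#   c_i  = 4 x_i (x_i+x_j)(x_i+x_k) / ((x_j-x_i)(x_k-x_i)),
# so log Ps = const - 2x + sum_i (c_i - 1) log(x + x_i); complex root
# pairs carry conjugate residues and the sum is real.
log_density_closed_form <- function(params, grid) {
  if (params$r != 1L) {
    stop("closed-form stationary density is only valid for r = 1",
         call. = FALSE)
  }
  z <- roots_of_drift_complex(params)
  resid <- function(i) {
    j <- setdiff(1:3, i)
    4 * z[i] * (z[i] + z[j[1]]) * (z[i] + z[j[2]]) /
      ((z[j[1]] - z[i]) * (z[j[2]] - z[i]))
  }
  ld <- -2 * grid
  for (i in 1:3) ld <- ld + (resid(i) - 1) * log(grid + z[i])
  max_im <- max(abs(Im(ld)))
  if (max_im > 1e-6 * max(1, max(abs(Re(ld))))) {
    stop("closed-form evaluation lost realness (imaginary residue ",
         format(max_im), ")", call. = FALSE)
  }
  Re(ld)
}

#' Closed-form stationary density for the classical model (r = 1)
#'
#' Evaluates the exact partial-fraction solution of the stationary
#' Fokker-Planck equation on a supplied grid and normalises it there.
#' Refuses degenerate (repeated-root, `Delta = 0`) parameter sets, for
#' which the decomposition is invalid -- use quadrature instead.
#'
#' @param params A [schlogl_params()] object with `r = 1` and `k1 > 0`.
#' @param grid Increasing non-negative grid (spacing `<= 0.1`).
#' @return A `stationary_density` tibble (see [stationary_density()]).
#' @export
closed_form_r1 <- function(params, grid) {
  params <- as_schlogl_params(params)
  require_nonabsorbing(params)
  h <- unique(round(diff(grid), 12))
  if (length(h) != 1L) stop("`grid` must be uniform", call. = FALSE)
  stationary_density(params, x_max = max(grid), grid_step = h,
                     method = "closed_form")
}

#' Discretise a continuous stationary density onto integer states
#'
#' Evaluates the density at integer molecule numbers and renormalises,
#' giving a probability vector directly comparable (e.g. by
#' [tv_distance()]) with a master-equation or simulation distribution.
#'
#' @param density A [stationary_density()] result.
#' @param states Integer states to evaluate on; defaults to
#'   `0:floor(x_max)`.
#' @return A tibble with columns `x` (integer) and `p`.
#' @export
discretize_density <- function(density, states = NULL) {
  stopifnot(inherits(density, "stationary_density"))
  if (is.null(states)) states <- 0:floor(max(density$x))
  p <- stats::approx(density$x, density$density, xout = states)$y
  p[is.na(p)] <- 0
  tibble::tibble(x = as.integer(states), p = p / sum(p))
}
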