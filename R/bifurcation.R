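#' Count the stable states of the stationary law
#'
#' Classifies a parameter set as monostable, bistable, or sitting on a
#' bifurcation point, by counting maxima of the stationary distribution
#' (phenomenological definition: a qualitative change of the stationary
#' law's shape, detected when two extrema merge). Three sources are
#' available: the Fokker-Planck extrema (`"fpe"`), the modes of the
#' exact truncated master-equation distribution (`"cme"`), and the
#' deterministic fixed-point count from the discriminant
#' (`"deterministic"`, which by construction ignores `r`).
#'
#' @param params A [schlogl_params()] object.
#' @param source Which stationary description to count on.
#' @param x_max Analysis window (defaults as in [find_extrema()] /
#'   [stationary_distribution()]).
#' @return A one-row tibble: `source`, `n_maxima`, `label`
#'   (`"monostable"`, `"bistable"` or `"bifurcation_point"`).
#' @examples
#' count_maxima(schlogl_params(3e6, 77518, 601, r = 25), "fpe")
#' @export
count_maxima <- function(params, source = c("fpe", "cme", "deterministic"),
                         x_max = NULL) {
  params <- as_schlogl_params(params)
  source <- match.arg(source)
  if (source == "fpe") {
    ex <- find_extrema(params, x_max = x_max)
    n <- attr(ex, "n_maxima")
    bif <- nrow(attr(ex, "merged_pairs")) > 0
  } else if (source == "cme") {
    d <- stationary_distribution(params, x_max = x_max)
    n <- length(distribution_mode(d))
    bif <- FALSE
  } else {
    fp <- fixed_points(params)
    n <- sum(fp$stability == "stable")
    bif <- any(fp$stability == "marginal")
    if (bif) n <- n + sum(fp$stability == "marginal")
  }
  label <- if (bif) "bifurcation_point" else if (n >= 2) "bistable" else "monostable"
  tibble::tibble(source = source, n_maxima = as.integer(n), label = label)
}

n_maxima_at <- function(k1, k2, k3, r, source, x_max = NULL) {
  count_maxima(schlogl_params(k1, k2, k3, k4 = 1, r = r),
               source = source, x_max = x_max)$n_maxima
}

#' Phase diagram of stationary stability over parameter sweeps
#'
#' Labels every point of a 1- or 2-dimensional grid in reduced rate
#' space (`k4 = 1`), for each requested burst size, by its number of
#' stationary maxima, and extracts the bifurcation boundaries along the
#' first axis by bisection between grid points with differing counts
#' (grid-independent boundary curves).
#'
#' @param axes Named list of one or two numeric grids; names among
#'   `"k1"`, `"k2"`, `"k3"`. The first axis is the sweep direction used
#'   for boundary refinement.
#' @param fixed Named numeric vector giving the remaining reduced
#'   rate(s).
#' @param r Integer vector of burst sizes.
#' @param source Stationary description to count on (see
#'   [count_maxima()]).
#' @param refine Refine boundaries by bisection (relative tolerance
#'   `1e-4` on the axis value).
#' @param x_max Optional analysis window passed through.
#' @return A tibble of class `phase_diagram`: grid columns (axis
#'   names), `r`, `n_maxima`, `label`; attributes `axes` (axis names),
#'   `fixed`, `source`, and `boundaries` -- a tibble with the refined
#'   crossing location on axis 1, the axis-2 value (`NA` when absent),
#'   `r`, and the maxima counts on either side.
#' @examples
#' scan_phase_diagram(list(k3 = seq(660, 740, by = 20)),
#'                    fixed = c(k1 = 8e6, k2 = 1.33e5),
#'                    r = 1, source = "deterministic")
#' @export
scan_phase_diagram <- function(axes, fixed = NULL, r = 1L,
                               source = c("fpe", "deterministic", "cme"),
                               refine = TRUE, x_max = NULL) {
  source <- match.arg(source)
  stopifnot(is.list(axes), length(axes) %in% 1:2,
            all(names(axes) %in% c("k1", "k2", "k3")))
  need <- setdiff(c("k1", "k2", "k3"), names(axes))
  if (!all(need %in% names(fixed))) {
    stop("`fixed` must supply: ", paste(need, collapse = ", "), call. = FALSE)
  }
  ax1 <- names(axes)[1]
  ax2 <- if (length(axes) == 2) names(axes)[2] else NULL

  grid <- tidyr::expand_grid(!!!axes, r = as.integer(r))
  kval <- function(row, name) {
    if (name %in% names(row)) row[[name]] else unname(fixed[[name]])
  }
  grid$n_maxima <- purrr::pmap_int(grid, function(...) {
    row <- list(...)
    n_maxima_at(kval(row, "k1"), kval(row, "k2"), kval(row, "k3"),
                row$r, source, x_max)
  })
  grid$label <- ifelse(grid$n_maxima >= 2, "bistable", "monostable")

  boundaries <- tibble::tibble(value = numeric(0), axis2 = numeric(0),
                               r = integer(0), n_lower = integer(0),
                               n_upper = integer(0))
  split_cols <- c(if (!is.null(ax2)) ax2, "r")
  groups <- dplyr::group_split(dplyr::group_by(
    grid, dplyr::across(dplyr::all_of(split_cols))))
  for (g in groups) {
    g <- dplyr::arrange(g, .data[[ax1]])
    v <- g[[ax1]]; n <- g$n_maxima
    for (i in seq_len(nrow(g) - 1)) {
      if (n[i] != n[i + 1]) {
        lo <- v[i]; hi <- v[i + 1]
        if (refine) {
          fval <- function(val) {
            kk <- stats::setNames(as.list(c(fixed)), names(fixed))
            kk[[ax1]] <- val
            if (!is.null(ax2)) kk[[ax2]] <- g[[ax2]][1]
            n_maxima_at(kk$k1, kk$k2, kk$k3, g$r[1], source, x_max)
          }
          while (hi - lo > 1e-4 * max(abs(hi), abs(lo), 1)) {
            mid <- (lo + hi) / 2
            if (fval(mid) == n[i]) lo <- mid else hi <- mid
          }
        }
        boundaries <- dplyr::bind_rows(boundaries, tibble::tibble(
          value = (lo + hi) / 2,
          axis2 = if (is.null(ax2)) NA_real_ else g[[ax2]][1],
          r = g$r[1], n_lower = n[i], n_upper = n[i + 1]))
      }
    }
  }
  structure(grid,
            axes = names(axes), fixed = fixed, source = source,
            boundaries = boundaries,
            class = c("phase_diagram", class(grid)))
}

#' Analytic shift of stationary extrema with burst size
#'
#' On the extremum manifold `alpha(x; k, r) = 0`, the implicit function
#' theorem gives the rate at which an extremum's location on a chosen
#' parameter axis moves as the burst size grows:
#' `dk/dr = (d2B/dxdr) / (2 dA/dk - d2B/dkdx)` (the drift `A` does not
#' depend on `r`). In reduced rates the three axes give
#' `dk1/dr = k3 x`, `dk2/dr = -2 k3 x / (2x + 1)` (tending to the
#' constant `-k3` for large `x`, which is why successive burst-size
#' curves are equidistant on the `k2` axis), and
#' `dk3/dr = k3 / (x - r)` (a pole at `x = r`; vanishing for large
#' `x`). The general composite and the simplified closed forms are both
#' returned, along with an optional finite-difference cross-check that
#' re-solves `alpha = 0` for the parameter at `r` and `r + dr`.
#'
#' @param params A [schlogl_params()] object (reduced internally).
#' @param which Parameter axis: `"k1"`, `"k2"` or `"k3"`.
#' @param x Extremum location (the formula is exact on the manifold
#'   `alpha(x) = 0`; it can be evaluated at any `x` for analysis).
#' @param r Burst size at which to evaluate; defaults to `params$r`.
#' @param finite_diff Also compute the finite-difference slope.
#' @param dr Burst-size step for the finite difference.
#' @return A one-row tibble of class `shift_report`: `parameter`, `x`,
#'   `r`, `analytic` (general composite), `simplified` (closed form),
#'   `finite_difference`, `rel_error`. At the `k3` pole `x == r` the
#'   shift is undefined and returned as `NA` with a warning.
#' @examples
#' shift_derivative(schlogl_params(9e6, 1.5e5, 720), "k1", x = 100)
#' @export
shift_derivative <- function(params, which = c("k1", "k2", "k3"), x,
                             r = NULL, finite_diff = TRUE, dr = 1) {
  params <- as_schlogl_params(params)
  which <- match.arg(which)
  k <- reduced_params(params)
  if (is.null(r)) r <- k$r
  stopifnot(length(x) == 1L, x >= 0)

  # general composite: dk/dr = (d2B/dxdr) / (2 dA/dk - d2B/dkdx)
  d2B_dxdr <- 2 * k$k3 * x
  dA_dk <- switch(which, k1 = 1, k2 = -x, k3 = x^2)
  d2B_dkdx <- switch(which, k1 = 0, k2 = 1, k3 = 2 * r * x)
  denom <- 2 * dA_dk - d2B_dkdx
  if (abs(denom) < .Machine$double.eps * max(1, abs(d2B_dxdr))) {
    warning("shift undefined at x = ", x, " (pole of the ", which,
            " shift; for k3 this is x = r)")
    analytic <- NA_real_
  } else {
    analytic <- d2B_dxdr / denom
  }
  simplified <- switch(which,
                       k1 = k$k3 * x,
                       k2 = -2 * k$k3 * x / (2 * x + 1),
                       k3 = if (x == r) NA_real_ else k$k3 / (x - r))

  fd <- rel <- NA_real_
  if (finite_diff && is.finite(analytic)) {
    # alpha is linear in each reduced rate: solve alpha(x; k, r) = 0
    # for the chosen rate at r and r + dr and difference the solutions
    solve_k <- function(rr) {
      kk <- k
      kk[[which]] <- 0
      base <- (kk$k1 - kk$k2 * x + kk$k3 * x^2 - x^3) -
        0.5 * (kk$k2 + 2 * rr * kk$k3 * x + 3 * x^2)
      coef <- switch(which, k1 = 1, k2 = -(x + 0.5), k3 = x^2 - rr * x)
      -base / coef
    }
    fd <- (solve_k(r + dr) - solve_k(r)) / dr
    # reference the analytic form at the manifold-consistent rate: for
    # the k3 axis the shift depends on k3 itself, which off-manifold
    # differs from the supplied value
    ref <- if (which == "k3") solve_k(r) / (x - r) else analytic
    rel <- abs(fd - ref) / abs(ref)
  }
  out <- tibble::tibble(parameter = which, x = x, r = r,
                        analytic = analytic, simplified = simplified,
                        finite_difference = fd, rel_error = rel)
  structure(out, class = c("shift_report", class(out)))
}

# count distinct positive real roots of alpha for a real-valued burst
# size (used to bisect transition points in r)
alpha_root_count <- function(params, r_real) {
  co <- c(params$k1 - params$k2 / 2,
          -(params$k2 + r_real * params$k3),
          params$k3 - 1.5 * params$k4,
          -params$k4)
  sol <- cubic_roots_real(co[1], co[2], co[3], co[4])
  sum(sol$roots > 0 & sol$multiplicity == 1L)
}

#' Track stationary extrema across burst sizes
#'
#' Runs [find_extrema()] for every burst size in `r_range`, recording
#' all extrema, and detects the burst sizes at which the number of
#' maxima changes -- the noise-induced (or noise-destroyed) saddle-node
#' of the stationary law. Each transition is refined by bisection in a
#' continuous burst-size variable to the point `r*` where an extremum
#' pair is born or merges, and the degenerate location `x*` is
#' reported. The deterministic fixed points are unaffected throughout
#' (the drift does not depend on `r`).
#'
#' @param params A [schlogl_params()] object (its own `r` is ignored).
#' @param r_range Integer vector of burst sizes, each `>= 1`.
#' @param x_max Optional window passed to [find_extrema()].
#' @param refine Refine transition points in continuous `r`.
#' @return A tibble of class `extrema_track` with columns `r`,
#'   `location`, `type`, `boundary`; attributes `transitions` (tibble:
#'   `r_lower`, `r_upper`, `n_lower`, `n_upper`, `r_star`, `x_star`)
#'   and `params`.
#' @examples
#' tr <- track_extrema_vs_r(schlogl_params(3e6, 77518, 601), 1:25)
#' attr(tr, "transitions")
#' @export
track_extrema_vs_r <- function(params, r_range, x_max = NULL,
                               refine = TRUE) {
  params <- as_schlogl_params(params)
  r_range <- sort(unique(as.integer(r_range)))
  stopifnot(all(r_range >= 1L))
  per_r <- purrr::map(r_range, function(r) {
    p <- schlogl_params(params$k1, params$k2, params$k3, params$k4, r)
    ex <- find_extrema(p, x_max = x_max)
    tibble::tibble(r = r, location = ex$location, type = ex$type,
                   boundary = ex$boundary,
                   n_maxima = attr(ex, "n_maxima"))
  })
  tab <- dplyr::bind_rows(per_r)
  nmax <- vapply(per_r, function(d) if (nrow(d)) d$n_maxima[1] else 0L,
                 integer(1))

  transitions <- tibble::tibble(r_lower = integer(0), r_upper = integer(0),
                                n_lower = integer(0), n_upper = integer(0),
                                r_star = numeric(0), x_star = numeric(0))
  for (i in seq_len(length(r_range) - 1)) {
    if (nmax[i] != nmax[i + 1]) {
      r_star <- x_star <- NA_real_
      if (refine) {
        lo <- r_range[i]; hi <- r_range[i + 1]
        n_lo <- alpha_root_count(params, lo)
        while (hi - lo > 1e-9 * max(1, hi)) {
          mid <- (lo + hi) / 2
          if (alpha_root_count(params, mid) == n_lo) lo <- mid else hi <- mid
        }
        r_star <- (lo + hi) / 2
        # degenerate location: critical point of alpha nearest zero
        co <- c(params$k1 - params$k2 / 2,
                -(params$k2 + r_star * params$k3),
                params$k3 - 1.5 * params$k4,
                -params$k4)
        disc_q <- (2 * co[3])^2 - 4 * (3 * co[4]) * co[2]
        if (disc_q >= 0) {
          crit <- (-2 * co[3] + c(-1, 1) * sqrt(disc_q)) / (6 * co[4])
          crit <- crit[crit > 0]
          aval <- abs(((co[4] * crit + co[3]) * crit + co[2]) * crit + co[1])
          if (length(crit)) x_star <- crit[which.min(aval)]
        }
      }
      transitions <- dplyr::bind_rows(transitions, tibble::tibble(
        r_lower = r_range[i], r_upper = r_range[i + 1],
        n_lower = nmax[i], n_upper = nmax[i + 1],
        r_star = r_star, x_star = x_star))
    }
  }
  out <- dplyr::select(tab, -"n_maxima")
  structure(out, transitions = transitions, params = params,
            class = c("extrema_track", class(out)))
}
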