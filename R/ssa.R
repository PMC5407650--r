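#' Exact stochastic simulation of the burst model
#'
#' Direct-method Gillespie simulation: exponential waiting times with
#' the total propensity `a0(x) = k1 + k2 x + k3 x^2 / r + k4 x^3`, the
#' firing channel drawn proportionally to the propensities, and the
#' state updated by the channel's stoichiometry (`+1`, `-1`, `+r`,
#' `-1`). No leaping or hybrid approximation is used; the sample paths
#' are statistically exact realisations of the master equation.
#'
#' Time-weighted occupancy (after burn-in) is accumulated during the
#' run regardless of length; the first `max_store` events are also
#' recorded as an explicit trajectory. A run is reproducible bit-exactly
#' from `(params, x0, seed)`: the simulator draws from R's RNG stream.
#'
#' @param params A [schlogl_params()] object with `k1 > 0`.
#' @param t_max Simulated time horizon (time is in `1/rate` units; the
#'   model carries no physical time scale).
#' @param x0 Initial molecule count; defaults to the nearest integer to
#'   the largest stable deterministic fixed point.
#' @param seed Optional integer; when supplied, `set.seed(seed)` is
#'   called so the trajectory is reproducible.
#' @param burn_in Fraction of `t_max` discarded before occupancy
#'   accumulation (transient removal), in `[0, 1)`.
#' @param max_store Maximum number of events kept as an explicit
#'   trajectory (the occupancy histogram is exact regardless).
#' @return An object of class `ssa_trajectory`: list with `events`
#'   (tibble `t`, `x`; piecewise-constant, right-continuous),
#'   `occupancy` (tibble `x`, `weight` of post-burn-in holding time),
#'   `params`, `x0`, `seed`, `t_max`, `burn_in`, `n_events`,
#'   `truncated` (whether `events` is a prefix of the run).
#' @examples
#' p <- schlogl_params(500, 150, 10, r = 2)
#' traj <- simulate_schlogl(p, t_max = 5, seed = 1)
#' occupancy_histogram(traj)
#' @export
simulate_schlogl <- function(params, t_max, x0 = NULL, seed = NULL,
                             burn_in = 0.1, max_store = 1e6) {
  params <- as_schlogl_params(params)
  require_nonabsorbing(params)
  stopifnot(t_max > 0, burn_in >= 0, burn_in < 1)
  if (is.null(x0)) {
    fp <- fixed_points(params)
    stable <- fp$root[fp$stability != "unstable"]
    x0 <- round(max(stable, 0))
  }
  stopifnot(x0 >= 0, x0 == round(x0))
  if (!is.null(seed)) set.seed(seed)
  res <- ssa_run_cpp(params$k1, params$k2, params$k3, params$k4, params$r,
                     as.double(x0), t_max, burn_in * t_max,
                     as.integer(max_store))
  occ <- tibble::tibble(x = seq_along(res$occ_weight) - 1L,
                        weight = res$occ_weight)
  occ <- occ[occ$weight > 0, ]
  structure(
    list(events = tibble::tibble(t = res$t, x = res$x),
         occupancy = occ,
         params = params, x0 = as.integer(x0), seed = seed,
         t_max = t_max, burn_in = burn_in,
         n_events = res$n_events, t_end = res$t_end,
         truncated = res$truncated || max_store <= 0),
    class = "ssa_trajectory"
  )
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat("<ssa_trajectory>  ", format(x$n_events, big.mark = ","),
      " events over t = [0, ", format(x$t_max), "], x0 = ", x$x0,
      if (!is.null(x$seed)) paste0(", seed = ", x$seed) else "",
      if (x$truncated) "  (event list truncated; occupancy exact)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Time-weighted occupancy histogram of a trajectory
#'
#' Weights every visited state by its total holding time after burn-in,
#' the stationary estimator behind simulated stationary distributions.
#' For a fully stored trajectory the histogram is recomputed from the
#' event list at any requested burn-in; for a run whose event list was
#' truncated, the exact occupancy accumulated during simulation (at the
#' simulation's own burn-in) is returned.
#'
#' @param traj A [simulate_schlogl()] result.
#' @param burn_in Fraction of `t_max` to discard; defaults to the
#'   trajectory's simulation-time value.
#' @return A tibble of class `occupancy_histogram` with columns `x`,
#'   `weight`, `p` (normalised); attributes `total_time`, `burn_in`,
#'   `params`, `seed`.
#' @export
occupancy_histogram <- function(traj, burn_in = NULL) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  if (is.null(burn_in)) burn_in <- traj$burn_in
  stopifnot(burn_in >= 0, burn_in < 1)
  t0 <- burn_in * traj$t_max
  if (traj$truncated) {
    if (burn_in != traj$burn_in) {
      stop("event list was truncated at max_store; the occupancy is only ",
           "available at the simulation burn-in (", traj$burn_in, ")",
           call. = FALSE)
    }
    agg <- traj$occupancy
  } else {
    ev <- traj$events
    start <- ev$t
    end <- c(ev$t[-1], traj$t_max)
    w <- pmax(pmin(end, traj$t_max) - pmax(start, t0), 0)
    keep <- w > 0
    agg <- tibble::tibble(x = ev$x[keep], weight = w[keep]) |>
      dplyr::group_by(x) |>
      dplyr::summarise(weight = sum(weight), .groups = "drop")
  }
  total <- sum(agg$weight)
  if (total <= 0) stop("no post-burn-in simulated time", call. = FALSE)
  out <- dplyr::arrange(agg, x)
  out$p <- out$weight / total
  structure(out,
            total_time = total, burn_in = burn_in,
            params = traj$params, seed = traj$seed,
            class = c("occupancy_histogram", class(out)))
}
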