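#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and summarise fitted stationary objects
#'
#' `tidy()` returns the per-component table (roots, extrema, boundary
#' crossings); `glance()` returns a one-row summary. Available for
#' [fixed_points()], [find_extrema()], [stationary_density()],
#' [stationary_distribution()], [scan_phase_diagram()] and
#' [track_extrema_vs_r()] results.
#'
#' @param x The fitted object.
#' @param ... Unused.
#' @name burstbif_tidiers
NULL

#' @rdname burstbif_tidiers
#' @export
tidy.fixed_point_set <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("root", "stability", "multiplicity")])
}

#' @rdname burstbif_tidiers
#' @export
glance.fixed_point_set <- function(x, ...) {
  tibble::tibble(n_roots = nrow(x),
                 n_stable = sum(x$stability == "stable"),
                 discriminant = attr(x, "discriminant"),
                 bistable = sum(x$stability == "stable") >= 2)
}

#' @rdname burstbif_tidiers
#' @export
tidy.extrema_report <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("location", "type", "boundary")])
}

#' @rdname burstbif_tidiers
#' @export
glance.extrema_report <- function(x, ...) {
  tibble::tibble(n_maxima = attr(x, "n_maxima"),
                 n_minima = sum(x$type == "minimum"),
                 n_merged = nrow(attr(x, "merged_pairs")),
                 boundary_mode = attr(x, "boundary_mode"),
                 x_max = attr(x, "x_max"))
}

#' @rdname burstbif_tidiers
#' @export
glance.stationary_density <- function(x, ...) {
  d <- x$density
  n <- length(d)
  i <- 2:(n - 1)
  tibble::tibble(method = attr(x, "method"),
                 n_grid = n,
                 grid_step = attr(x, "grid_step"),
                 x_max = attr(x, "x_max"),
                 tail_mass = attr(x, "tail_mass"),
                 n_maxima = sum(d[i] > d[i - 1] & d[i] >= d[i + 1]))
}

#' @rdname burstbif_tidiers
#' @export
glance.cme_distribution <- function(x, ...) {
  modes <- distribution_mode(x)
  tibble::tibble(method = attr(x, "method"),
                 x_max = attr(x, "x_max"),
                 tail_mass = attr(x, "tail_mass"),
                 n_modes = length(modes),
                 mode_lower = if (length(modes)) min(modes) else NA_integer_,
                 mode_upper = if (length(modes)) max(modes) else NA_integer_)
}

#' @rdname burstbif_tidiers
#' @export
tidy.phase_diagram <- function(x, ...) attr(x, "boundaries")

#' @rdname burstbif_tidiers
#' @export
glance.phase_diagram <- function(x, ...) {
  tibble::tibble(source = attr(x, "source"),
                 n_points = nrow(x),
                 n_boundaries = nrow(attr(x, "boundaries")),
                 n_bistable = sum(x$n_maxima >= 2))
}

#' @rdname burstbif_tidiers
#' @export
tidy.extrema_track <- function(x, ...) attr(x, "transitions")
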