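#' Parameter set for the (burst-modified) Schlogl model
#'
#' The Schlogl scheme is the minimal one-species mass-action system with
#' bistability: production from the reservoir at rate `k1`, linear decay
#' `k2*x`, autocatalysis `2X -> 3X` at `k3*x^2`, and the back reaction
#' `3X -> 2X` at `k4*x^3`. The burst modification replaces the
#' autocatalytic step by `2X -> (2+r)X` firing at rate `k3*x^2/r`, so a
#' single firing produces `r` molecules `r` times less often: the
#' deterministic rate equation is unchanged while the intrinsic noise
#' grows with `r`. `r = 1` recovers the unmodified model.
#'
#' @param k1 Production rate (molecules per unit time). `k1 = 0` is
#'   allowed for deterministic analysis only; the stochastic modules
#'   reject it because the empty state becomes absorbing.
#' @param k2 Linear decay rate (per molecule per unit time), `> 0`.
#' @param k3 Autocatalytic rate constant, `> 0`.
#' @param k4 Cubic back-reaction rate constant, `> 0`. Defaults to 1,
#'   the natural choice when reduced rates (k-tilde, i.e. `ki/k4`) are
#'   supplied directly.
#' @param r Burst size, a positive integer. `r = 1` is the classical
#'   model.
#'
#' @return An object of class `schlogl_params`: a named list with
#'   elements `k1`, `k2`, `k3`, `k4` (doubles) and `r` (integer).
#' @examples
#' p <- schlogl_params(k1 = 3e6, k2 = 77518, k3 = 601, r = 25)
#' p
#' reduced_params(p)
#' @export
schlogl_params <- function(k1, k2, k3, k4 = 1, r = 1) {
  for (nm in c("k1", "k2", "k3", "k4")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (k1 < 0) stop("`k1` must be >= 0", call. = FALSE)
  for (nm in c("k2", "k3", "k4")) {
    if (get(nm) <= 0) stop("`", nm, "` must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) ||
      abs(r - round(r)) > 1e-8 || r < 1) {
    stop("burst size `r` must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(k1 = as.double(k1), k2 = as.double(k2), k3 = as.double(k3),
         k4 = as.double(k4), r = as.integer(round(r))),
    class = "schlogl_params"
  )
}

#' @export
print.schlogl_params <- function(x, ...) {
  cat("<schlogl_params>  k1 =", format(x$k1), " k2 =", format(x$k2),
      " k3 =", format(x$k3), " k4 =", format(x$k4), " r =", x$r, "\n")
  invisible(x)
}

#' Reduced (k-tilde) rates
#'
#' Divides the rate constants by `k4`, the reduction under which the
#' deterministic cubic becomes monic and the cusp discriminant takes its
#' standard three-parameter form.
#'
#' @param params A [schlogl_params()] object.
#' @return A named list with `k1`, `k2`, `k3` (each `ki/k4`) and `r`.
#' @export
reduced_params <- function(params) {
  stopifnot(inherits(params, "schlogl_params"))
  list(k1 = params$k1 / params$k4, k2 = params$k2 / params$k4,
       k3 = params$k3 / params$k4, r = params$r)
}

# stochastic modules need k1 > 0: x = 0 is absorbing otherwise
require_nonabsorbing <- function(params) {
  if (params$k1 <= 0) {
    stop("k1 must be > 0 for stochastic analysis: with k1 = 0 the empty ",
         "state is absorbing and no unique stationary law exists",
         call. = FALSE)
  }
  invisible(params)
}

as_schlogl_params <- function(x) {
  if (inherits(x, "schlogl_params")) return(x)
  if (is.list(x) && all(c("k1", "k2", "k3") %in% names(x))) {
    return(schlogl_params(x$k1, x$k2, x$k3,
                          k4 = x$k4 %||% 1, r = x$r %||% 1))
  }
  stop("cannot interpret `params`; supply a schlogl_params object",
       call. = FALSE)
}
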