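#' Truncated master-equation generator
#'
#' Builds the sparse generator of the jump process on the truncated
#' state space `0..x_max`. Out of state `x` the channels are: `+1` at
#' rate `k1`, `-1` at `k2 x + k4 x^3`, and `+r` at `k3 x^2 / r` (the
#' polynomial rate forms of the model, not combinatorial factors).
#' Burst jumps that would overshoot the truncation are redirected to
#' `x_max`, so probability is conserved exactly; the bias is negligible
#' whenever the stationary tail criterion holds.
#'
#' @param params A [schlogl_params()] object with `k1 > 0` (with
#'   `k1 = 0` the empty state is absorbing and no unique stationary law
#'   exists).
#' @param x_max Truncation bound (integer, at least `10 r`).
#' @return An object of class `cme_space`: list with `states`
#'   (`0:x_max`), `Q` (sparse generator, rows = origin states, row sums
#'   zero), `params`, `x_max`.
#' @examples
#' sp <- build_generator(schlogl_params(3e6, 77518, 601, r = 25), 1000)
#' @export
build_generator <- function(params, x_max) {
  params <- as_schlogl_params(params)
  require_nonabsorbing(params)
  x_max <- as.integer(x_max)
  if (x_max < 10L * params$r) {
    stop("`x_max` must be at least 10 * r (= ", 10L * params$r, ")",
         call. = FALSE)
  }
  k1 <- params$k1; k2 <- params$k2; k3 <- params$k3; k4 <- params$k4
  r <- params$r
  x <- 0:x_max

  from <- integer(0); to <- integer(0); rate <- numeric(0)
  # birth +1 (suppressed at the truncation boundary)
  i <- 0:(x_max - 1L)
  from <- c(from, i); to <- c(to, i + 1L); rate <- c(rate, rep(k1, length(i)))
  # death -1
  i <- 1:x_max
  from <- c(from, i); to <- c(to, i - 1L)
  rate <- c(rate, k2 * i + k4 * as.double(i)^3)
  # burst +r, overshoot redirected to x_max
  i <- 1:x_max
  tgt <- pmin(i + r, x_max)
  keep <- tgt != i
  from <- c(from, i[keep]); to <- c(to, tgt[keep])
  rate <- c(rate, k3 * as.double(i[keep])^2 / r)

  n <- x_max + 1L
  Q <- Matrix::sparseMatrix(i = from + 1L, j = to + 1L, x = rate,
                            dims = c(n, n))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  structure(list(states = x, Q = Q, params = params, x_max = x_max),
            class = "cme_space")
}

#' @export
print.cme_space <- function(x, ...) {
  cat("<cme_space>  states 0..", x$x_max, ", ",
      length(x$Q@x), " transition entries\n", sep = "")
  invisible(x)
}

#' Exact stationary distribution of the truncated master equation
#'
#' Solves `t(Q) p = 0`, `sum(p) = 1` as a sparse linear system (one
#' balance equation replaced by the normalisation); the chain is
#' irreducible on the truncated space for `k1 > 0`, so the solution is
#' unique. A deterministic linear solve is used rather than an
#' eigen-decomposition.
#'
#' @param space A [build_generator()] result, or a [schlogl_params()]
#'   object (the generator is then built internally).
#' @param x_max Truncation bound, used only when `space` is a parameter
#'   set. When omitted, starts from twice the largest deterministic
#'   root plus `10 r` and doubles until the tail criterion passes.
#' @param tail_tol Maximum stationary mass allowed on the top 1% of
#'   states; a violation is a truncation error asking for a larger
#'   `x_max`.
#' @return A tibble of class `cme_distribution` with columns `x`
#'   (integer states) and `p`; attributes `params`, `x_max`,
#'   `tail_mass`.
#' @examples
#' d <- stationary_distribution(schlogl_params(3e6, 77518, 601, r = 25), 1000)
#' distribution_mode(d)
#' @export
stationary_distribution <- function(space, x_max = NULL, tail_tol = 1e-9) {
  if (inherits(space, "schlogl_params") || !inherits(space, "cme_space")) {
    params <- as_schlogl_params(space)
    if (is.null(x_max)) {
      x_max <- max(ceiling(default_x_max(params)), 10L * params$r)
      for (attempt in 1:6) {
        res <- tryCatch(
          stationary_distribution(build_generator(params, x_max),
                                  tail_tol = tail_tol),
          error = function(e) {
            if (grepl("enlarge", conditionMessage(e))) NULL else stop(e)
          })
        if (!is.null(res)) return(res)
        x_max <- 2L * x_max
      }
      stop("tail criterion not met after repeated doubling of x_max",
           call. = FALSE)
    }
    space <- build_generator(params, x_max)
  }
  n <- space$x_max + 1L
  M <- Matrix::t(space$Q)
  M[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  p <- as.numeric(Matrix::solve(M, b))
  if (min(p) < -1e-10) {
    warning("stationary solve produced negative probabilities as low as ",
            format(min(p)), "; clamped to zero")
  }
  p[p < 0] <- 0
  p <- p / sum(p)
  top <- ceiling(0.01 * n)
  tail_mass <- sum(p[(n - top + 1L):n])
  if (tail_mass > tail_tol) {
    stop("stationary mass ", format(tail_mass), " on the top 1% of states ",
         "exceeds ", format(tail_tol), "; enlarge `x_max` (currently ",
         space$x_max, ")", call. = FALSE)
  }
  out <- tibble::tibble(x = space$states, p = p)
  structure(out, params = space$params, x_max = space$x_max,
            tail_mass = tail_mass, method = "nullspace",
            class = c("cme_distribution", class(out)))
}

#' Stationary law of the classical (r = 1) model by detailed balance
#'
#' For `r = 1` the process is a nearest-neighbour birth-death chain and
#' detailed balance gives the stationary law in closed form through the
#' recurrence `p(x+1)/p(x) = T(x+1|x) / T(x-1|x+1)` with
#' `T(x+1|x) = k1 + k3 x^2` and `T(x-1|x) = k2 x + k4 x^3`. Evaluated
#' in log-space and normalised. This is the independent oracle for the
#' nullspace solve.
#'
#' @param params A [schlogl_params()] object with `r = 1`, `k1 > 0`.
#' @param x_max Largest state of the support.
#' @return A `cme_distribution` tibble (see
#'   [stationary_distribution()]).
#' @export
birth_death_stationary <- function(params, x_max) {
  params <- as_schlogl_params(params)
  require_nonabsorbing(params)
  if (params$r != 1L) {
    stop("detailed balance requires r = 1 (nearest-neighbour chain)",
         call. = FALSE)
  }
  x_max <- as.integer(x_max)
  x <- 0:x_max
  up <- params$k1 + params$k3 * as.double(0:(x_max - 1L))^2
  dn <- params$k2 * as.double(1:x_max) + params$k4 * as.double(1:x_max)^3
  lp <- cumsum(c(0, log(up) - log(dn)))
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  top <- ceiling(0.01 * (x_max + 1L))
  out <- tibble::tibble(x = x, p = p)
  structure(out, params = params, x_max = x_max,
            tail_mass = sum(p[(x_max + 2L - top):(x_max + 1L)]),
            method = "recurrence",
            class = c("cme_distribution", class(out)))
}

#' Modes of a discrete stationary distribution
#'
#' Interior local maxima (`p(x) > p(x-1)` and `p(x) >= p(x+1)`; ties
#' broken toward the smaller state and flagged). A monotone decreasing
#' distribution has its mode at the boundary state 0, returned flagged
#' via the `boundary_mode` attribute.
#'
#' @param dist A `cme_distribution` (or any tibble with columns `x`,
#'   `p`).
#' @return Integer vector of modal states, with attributes `ties` and
#'   `boundary_mode` (logicals).
#' @export
distribution_mode <- function(dist) {
  p <- dist$p; x <- dist$x
  n <- length(p)
  stopifnot(n >= 3)
  i <- 2:(n - 1)
  is_mode <- p[i] > p[i - 1] & p[i] >= p[i + 1]
  modes <- x[i][is_mode]
  ties <- any(p[i][is_mode] == p[i + 1][is_mode])
  boundary <- FALSE
  if (length(modes) == 0L && p[1] > p[2]) {
    modes <- x[1]
    boundary <- TRUE
  }
  structure(as.integer(modes), ties = ties, boundary_mode = boundary)
}
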