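#' @importFrom rlang %||%
NULL

#' Total variation distance between two probability vectors
#'
#' Half the L1 distance. Inputs may be bare numeric vectors of equal
#' length or two distribution tibbles with columns `x` and `p` (states
#' are aligned by `x`; states absent from one distribution contribute
#' their full mass).
#'
#' @param p,q Probability vectors, or tibbles/data frames with columns
#'   `x` and `p`.
#' @return A single number in `[0, 1]`.
#' @export
tv_distance <- function(p, q) {
  if (is.data.frame(p) && is.data.frame(q)) {
    states <- sort(union(p$x, q$x))
    pv <- qv <- numeric(length(states))
    pv[match(p$x, states)] <- p$p
    qv[match(q$x, states)] <- q$p
    return(0.5 * sum(abs(pv - qv)))
  }
  stopifnot(is.numeric(p), is.numeric(q), length(p) == length(q))
  0.5 * sum(abs(p - q))
}

# Real roots of c3 x^3 + c2 x^2 + c1 x + c0 (c3 != 0) by the
# trigonometric (three real roots) / Cardano (one real root) closed
# form, each root polished by a few Newton steps against the original
# coefficients. Roots closer than `merge_tol` (relative) are merged and
# returned once, with the multiplicity recorded.
#
# Returns a list: roots (sorted), multiplicity (same length), delta
# (discriminant of the monic depressed cubic, same sign convention as
# the cubic discriminant).
cubic_roots_real <- function(c0, c1, c2, c3, merge_tol = 1e-6) {
  stopifnot(c3 != 0)
  a <- c2 / c3; b <- c1 / c3; cc <- c0 / c3
  p <- b - a^2 / 3
  q <- 2 * a^3 / 27 - a * b / 3 + cc
  delta <- -4 * p^3 - 27 * q^2
  shift <- -a / 3
  scale <- max(1, abs(p))^1.5 + abs(q)
  if (abs(delta) < 1e-12 * scale^2 && abs(p) < 1e-10 * max(1, abs(q))^(2 / 3)) {
    t_roots <- c(0, 0, 0)                      # triple root
  } else if (delta > 0) {
    # three distinct real roots (trigonometric form)
    m <- 2 * sqrt(-p / 3)
    arg <- 3 * q / (2 * p) * sqrt(-3 / p)
    arg <- max(-1, min(1, arg))
    th <- acos(arg) / 3
    t_roots <- m * cos(th - 2 * pi * (0:2) / 3)
  } else if (delta < -1e-12 * scale^2) {
    # one real root (Cardano)
    s <- sqrt(q^2 / 4 + p^3 / 27)
    cbrt <- function(z) sign(z) * abs(z)^(1 / 3)
    t_roots <- cbrt(-q / 2 + s) + cbrt(-q / 2 - s)
  } else {
    # double + simple root (saddle-node boundary)
    t_roots <- c(3 * q / p, -3 * q / (2 * p), -3 * q / (2 * p))
  }
  x <- sort(t_roots + shift)
  # Newton polish on the original cubic
  f <- function(x) ((c3 * x + c2) * x + c1) * x + c0
  fp <- function(x) (3 * c3 * x + 2 * c2) * x + c1
  for (i in seq_along(x)) {
    for (it in 1:4) {
      d <- fp(x[i])
      if (abs(d) < .Machine$double.eps * max(1, abs(x[i]))) break
      step <- f(x[i]) / d
      x[i] <- x[i] - step
      if (abs(step) < 1e-14 * max(1, abs(x[i]))) break
    }
  }
  x <- sort(x)
  # merge near-equal roots (relative tolerance)
  roots <- x[1]; mult <- 1L
  for (i in seq_along(x)[-1]) {
    if (abs(x[i] - roots[length(roots)]) <=
        merge_tol * max(1, abs(x[i]), abs(roots[length(roots)]))) {
      mult[length(mult)] <- mult[length(mult)] + 1L
      roots[length(roots)] <- (roots[length(roots)] * (mult[length(mult)] - 1L) +
                                 x[i]) / mult[length(mult)]
    } else {
      roots <- c(roots, x[i]); mult <- c(mult, 1L)
    }
  }
  list(roots = roots, multiplicity = mult, delta = delta)
}

# format doubles so they survive a text round trip exactly
format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}
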