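# shared fixtures and generators for the test suite

fig6_params <- function(r = 1) schlogl_params(3e6, 77518, 601, k4 = 1, r = r)
fig3_params <- function(r = 1) schlogl_params(9e6, 1.5e5, 720, k4 = 1, r = r)
fig2_params <- function(k3, r = 1) schlogl_params(8e6, 1.33e5, k3, k4 = 1, r = r)

# random reduced-rate draws on a scale where modes sit below ~200
# molecules, so truncated master-equation solves stay cheap; half the
# draws are built from three explicit positive roots (deterministically
# bistable), half drawn freely (mostly monostable)
rand_params <- function(n, seed, r = 1L) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    if (stats::runif(1) < 0.5) {
      rts <- sort(stats::runif(3, 4, 120))
      if (min(diff(rts)) < 2) next
      p <- schlogl_params(prod(rts),
                          rts[1] * rts[2] + rts[1] * rts[3] + rts[2] * rts[3],
                          sum(rts), k4 = 1, r = r)
    } else {
      k3 <- stats::runif(1, 20, 90)
      k2 <- stats::runif(1, 0.1, 0.4) * k3^2
      k1 <- stats::runif(1, 0.02, 0.2) * k2 * k3
      p <- schlogl_params(k1, k2, k3, k4 = 1, r = r)
    }
    if (max(fixed_points(p)$root) > 150) next
    i <- i + 1L
    out[[i]] <- p
  }
  out
}

# independent root counter for the deterministic cubic (Jenkins-Traub)
count_real_positive_roots <- function(params, tol = 1e-7) {
  z <- polyroot(c(params$k1, -params$k2, params$k3, -params$k4))
  re <- Re(z[abs(Im(z)) < tol * pmax(1, Mod(z))])
  sum(re > 0)
}
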