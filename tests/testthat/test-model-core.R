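test_that("reaction system carries the burst propensities and stoichiometry", {
  p <- fig6_params(r = 25)
  sys <- build_system(p)
  expect_identical(sys$S, c(1L, -1L, 25L, -1L))
  expect_equal(unname(sys$propensities(0)[1, ]), c(3e6, 0, 0, 0))
  # burst channel fires r times less often: k3 * 43^2 / 25
  expect_equal(unname(sys$propensities(43)[1, 3]), 44449.96)

  sys1 <- build_system(fig6_params(r = 1))
  expect_identical(sys1$S, c(1L, -1L, 1L, -1L))
  x <- c(0, 1, 43, 400)
  expect_equal(unname(sys1$propensities(x)),
               cbind(rep(3e6, 4), 77518 * x, 601 * x^2, x^3))
})

test_that("S . nu equals the drift for every burst size", {
  x <- seq(0, 600, by = 7.5)
  for (r in c(1L, 2L, 7L, 25L, 50L)) {
    p <- fig6_params(r = r)
    sys <- build_system(p)
    expect_equal(as.vector(sys$propensities(x) %*% sys$S), drift(p, x))
  }
})

test_that("drift is the rate-equation cubic and independent of r", {
  p <- fig6_params()
  expect_equal(drift(p, 0), 3e6)
  expect_equal(drift(p, 43), 698468)  # direct polynomial evaluation
  x <- seq(0, 800, by = 3)
  expect_identical(drift(fig6_params(r = 25), x), drift(p, x))
  expect_identical(drift(fig6_params(r = 50), x), drift(p, x))
})

test_that("parameter validation rejects bad rates and burst sizes", {
  expect_error(schlogl_params(1, -1, 1), "k2")
  expect_error(schlogl_params(1, 1, 1, r = 0), "r")
  expect_error(schlogl_params(1, 1, 1, r = 2.5), "r")
  expect_error(build_system(schlogl_params(1, 1, 1, r = -3)), "r")
  # k1 = 0 is fine deterministically, rejected by stochastic modules
  p0 <- schlogl_params(0, 1, 2, 1)
  expect_s3_class(p0, "schlogl_params")
  expect_error(stationary_density(p0), "absorbing")
  expect_error(build_generator(p0, 100), "absorbing")
  expect_error(simulate_schlogl(p0, t_max = 1), "absorbing")
})

test_that("fixed points handle the factorable boundary cubic", {
  # A = -x (x - 1)^2: root at 0 and a saddle-node double root at 1
  fp <- fixed_points(schlogl_params(0, 1, 2, 1))
  expect_equal(fp$root, c(0, 1), tolerance = 1e-8)
  expect_equal(fp$multiplicity, c(1L, 2L))
  expect_equal(fp$stability[2], "marginal")
  expect_equal(attr(fp, "discriminant"), 0)
})

test_that("the single fixed point of the bistable-to-be set lies in (440, 441)", {
  fp <- fixed_points(fig6_params())
  expect_equal(nrow(fp), 1L)
  expect_gt(fp$root, 440)
  expect_lt(fp$root, 441)
  expect_equal(fp$stability, "stable")
  expect_lt(attr(fp, "discriminant"), 0)
})

test_that("discriminant reduces algebraically when k1 = 0", {
  # Delta |_{k1=0} = k2^2 (k3^2 - 4 k2); with k2 = 1, k3 = 2 it vanishes
  expect_equal(discriminant(schlogl_params(0, 1, 2, 1)), 0)
  # and scales out of k4: reduced rates are used
  expect_equal(discriminant(schlogl_params(0, 2, 4, 2)), 0)
})

test_that("sign of the discriminant matches brute-force root counting", {
  for (p in rand_params(200, seed = 42)) {
    d <- discriminant(p)
    n <- count_real_positive_roots(p)
    if (d > 0) expect_identical(n, 3L) else expect_identical(n, 1L)
    expect_identical(nrow(fixed_points(p)), n)
  }
})

test_that("stability labels alternate stable/unstable/stable for three roots", {
  found <- 0L
  for (p in rand_params(60, seed = 7)) {
    fp <- fixed_points(p)
    if (nrow(fp) == 3L) {
      found <- found + 1L
      expect_identical(fp$stability, c("stable", "unstable", "stable"))
    }
  }
  expect_gt(found, 5L)
})

test_that("closed-form cubic roots agree with the independent solver", {
  for (p in rand_params(50, seed = 11)) {
    z <- polyroot(c(p$k1, -p$k2, p$k3, -p$k4))
    re <- sort(Re(z[abs(Im(z)) < 1e-7 * Mod(z)]))
    fp <- fixed_points(p)
    expect_equal(fp$root, re, tolerance = 1e-6)
  }
})
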