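test_that("diffusion carries the burst factor and reduces to the propensity sum at r = 1", {
  p25 <- fig6_params(r = 25)
  expect_equal(diffusion(p25, 0), 3e6)
  # 3e6 + 77518*43 + 25*601*43^2 + 43^3
  expect_equal(diffusion(p25, 43), 34194006)
  p1 <- fig6_params(r = 1)
  x <- seq(0, 500, by = 11)
  expect_equal(diffusion(p1, x),
               as.vector(build_system(p1)$propensities(x) %*% c(1, 1, 1, 1)))
})

test_that("alpha brackets the lower stationary maximum of the bursty set", {
  p <- fig6_params(r = 25)
  expect_equal(alpha_fun(p, 0), 3e6 - 77518 / 2)
  expect_equal(alpha_fun(p, 43), 10860.5)
  expect_equal(alpha_fun(p, 44), -35203)
})

test_that("stationary density normalises and meets the tail criterion", {
  for (p in list(fig6_params(r = 25), fig3_params(r = 1))) {
    d <- stationary_density(p)
    h <- attr(d, "grid_step")
    integral <- sum((d$density[-1] + d$density[-nrow(d)]) / 2) * h
    expect_equal(integral, 1, tolerance = 1e-6)
    expect_true(all(is.finite(d$log_density)))
    expect_true(all(d$density >= 0))
    expect_lt(attr(d, "tail_mass"), 1e-9)
  }
  expect_error(stationary_density(fig6_params(r = 25), x_max = 500),
               "enlarge")
  expect_error(stationary_density(fig6_params(), grid_step = 0.5),
               "grid_step")
})

test_that("quadrature matches the closed form for r = 1 across random parameter sets", {
  sets <- c(list(fig3_params(), fig2_params(680), fig2_params(720),
                 fig6_params()),
            rand_params(8, seed = 3))
  for (p in sets) {
    if (discriminant(p) == 0) next  # closed form undefined at the boundary
    q <- stationary_density(p, method = "quadrature")
    cf <- stationary_density(p, x_max = attr(q, "x_max"),
                             method = "closed_form")
    expect_lt(max(abs(q$density - cf$density)), 1e-6)
    expect_true(all(cf$density > 0))
  }
})

test_that("closed form refuses degenerate (repeated-root) rate sets", {
  # A = -(x - 1)^2 (x - 3): saddle-node double root, Delta = 0
  expect_error(stationary_density(schlogl_params(3, 7, 5, 1),
                                  method = "closed_form"),
               "quadrature")
})

test_that("log-density slope identity d log Ps/dx = 2 alpha / B holds", {
  for (p in list(fig6_params(r = 25), fig3_params(r = 1), fig3_params(r = 10))) {
    d <- stationary_density(p)
    h <- attr(d, "grid_step")
    x <- d$x
    mid <- (x[-1] + x[-length(x)]) / 2
    slope_fd <- diff(d$log_density) / h
    slope_an <- 2 * alpha_fun(p, mid) / diffusion(p, mid)
    # central differences on the uniform grid are O(h^2) accurate
    expect_lt(max(abs(slope_fd - slope_an) / pmax(1, abs(slope_an))), h^2)
  }
})

test_that("extrema classification matches the grid argmax of the density", {
  for (p in list(fig6_params(r = 25), fig6_params(r = 1),
                 fig3_params(r = 1), fig3_params(r = 10))) {
    ex <- find_extrema(p)
    d <- stationary_density(p, x_max = attr(ex, "x_max"))
    h <- attr(d, "grid_step")
    dens <- d$density
    i <- 2:(length(dens) - 1)
    grid_max <- d$x[i][dens[i] > dens[i - 1] & dens[i] >= dens[i + 1]]
    loc_max <- ex$location[ex$type == "maximum" & !ex$boundary]
    expect_equal(length(loc_max), length(grid_max))
    expect_lt(max(abs(sort(loc_max) - sort(grid_max))), h + 1e-9)
  }
})

test_that("the bursty stationary law is bimodal where the plain one is unimodal", {
  ex25 <- find_extrema(fig6_params(r = 25))
  expect_identical(attr(ex25, "n_maxima"), 2L)
  ex1 <- find_extrema(fig6_params(r = 1))
  expect_identical(attr(ex1, "n_maxima"), 1L)
  # maxima and minima interleave
  expect_identical(ex25$type, c("maximum", "minimum", "maximum"))
})

test_that("extrema converge to the deterministic stable roots as rates scale up", {
  # scaling k3 -> c k3, k2 -> c^2 k2, k1 -> c^3 k1 scales the roots by c
  # while the B'/2 correction stays relatively O(1/c)
  base <- list(k1 = 9e6, k2 = 1.5e5, k3 = 720)  # strongly bistable
  rel_dev <- function(c) {
    p <- schlogl_params(base$k1 * c^3, base$k2 * c^2, base$k3 * c, 1, r = 1)
    fp <- fixed_points(p)
    stable <- fp$root[fp$stability == "stable"]
    ex <- find_extrema(p)
    mx <- ex$location[ex$type == "maximum"]
    max(vapply(mx, function(m) min(abs(m - stable) / stable), 0))
  }
  d1 <- rel_dev(1); d10 <- rel_dev(10); d100 <- rel_dev(100)
  expect_lt(d10, d1 / 5)
  expect_lt(d100, d10 / 5)
})

test_that("a falling density at the origin is reported as a boundary mode", {
  # k2 > 2 k1 makes alpha(0) < 0; choose rates with no interior extrema
  p <- schlogl_params(1, 10, 1, 1)
  ex <- find_extrema(p)
  expect_true(attr(ex, "boundary_mode"))
  expect_identical(attr(ex, "n_maxima"), 1L)
  expect_equal(ex$location[1], 0)
})

test_that("discretised density agrees with its own grid modes", {
  d <- stationary_density(fig6_params(r = 25))
  disc <- discretize_density(d)
  expect_equal(sum(disc$p), 1)
  m <- distribution_mode(disc)
  expect_identical(length(m), 2L)
})
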