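test_that("maxima counting agrees across sources on the canonical bursty set", {
  expect_identical(count_maxima(fig6_params(r = 1), "fpe")$n_maxima, 1L)
  expect_identical(count_maxima(fig6_params(r = 25), "fpe")$n_maxima, 2L)
  expect_identical(count_maxima(fig6_params(r = 25), "fpe")$label, "bistable")
  expect_identical(count_maxima(fig6_params(r = 25), "cme")$n_maxima, 2L)
  # the deterministic description never sees the burst size
  for (r in c(1L, 25L)) {
    cm <- count_maxima(fig6_params(r = r), "deterministic")
    expect_identical(cm$n_maxima, 1L)
    expect_identical(cm$label, "monostable")
  }
})

test_that("burst size alone induces and then destroys bistability", {
  tr <- track_extrema_vs_r(fig6_params(), r_range = c(1:30, seq(35, 60, 5)))
  trans <- tidy(tr)
  expect_identical(nrow(trans), 2L)
  # induced in (1, 25], destroyed again at larger r
  expect_identical(trans$n_lower[1], 1L)
  expect_identical(trans$n_upper[1], 2L)
  expect_true(trans$r_upper[1] <= 25)
  expect_identical(trans$n_upper[2], 1L)
  # refined transition: the merging extremum pair collapses to x_star
  p_star <- trans$r_star[2]
  expect_true(is.finite(p_star))
  lo <- dplyr::filter(tr, r == trans$r_lower[2])
  expect_lt(min(abs(lo$location[lo$type == "minimum"] - trans$x_star[2])),
            50)
})

test_that("deterministic fixed points are constant along the burst-size track", {
  roots <- vapply(c(1L, 10L, 25L, 40L),
                  function(r) fixed_points(fig6_params(r = r))$root[1], 0)
  expect_identical(max(roots) - min(roots), 0)
})

test_that("phase-diagram boundaries shift equidistantly in k2 with burst size", {
  # sweep k2 at fixed k1 = 5.33e6, k3 = 800: the bistable-to-monostable
  # boundary per burst size moves by dk2/dr ~ -k3 per unit r, so the
  # five boundaries are (near-)equidistant
  fixed <- c(k1 = 5.33e6, k3 = 800)
  rs <- c(1L, 11L, 21L, 31L, 41L)
  pd <- scan_phase_diagram(list(k2 = seq(1.35e5, 1.8e5, length.out = 19)),
                           fixed = fixed, r = rs, source = "fpe")
  b <- dplyr::arrange(tidy(pd), r)
  expect_identical(nrow(b), length(rs))
  expect_true(all(b$n_lower == 2L & b$n_upper == 1L))
  gaps <- diff(b$value)
  expect_true(all(gaps < 0))  # larger bursts close the window earlier
  spread <- (max(gaps) - min(gaps)) / abs(mean(gaps))
  expect_lt(spread, 0.05)
  # spacing per unit burst size is close to the analytic constant -k3
  expect_equal(mean(gaps) / 10, -800, tolerance = 0.05)
})

test_that("boundary location is resolution-stable", {
  fixed <- c(k1 = 5.33e6, k3 = 800)
  coarse <- scan_phase_diagram(list(k2 = seq(1.35e5, 1.8e5, length.out = 10)),
                               fixed = fixed, r = 1L, source = "fpe")
  fine <- scan_phase_diagram(list(k2 = seq(1.35e5, 1.8e5, length.out = 19)),
                             fixed = fixed, r = 1L, source = "fpe")
  vb_c <- tidy(coarse)$value
  vb_f <- tidy(fine)$value
  expect_identical(length(vb_c), length(vb_f))
  cell <- 4.5e4 / 9
  expect_true(all(abs(sort(vb_c) - sort(vb_f)) < cell))
})

test_that("the deterministic scan shows the two saddle-node branches of the cusp", {
  # 2-D slice at k3 = 720: every k2 line inside the tongue crosses both
  # saddle-node branches, and the tongue narrows towards the cusp tip
  # at k2 = k3^2 / 3
  pd <- scan_phase_diagram(
    list(k1 = seq(2e6, 1.45e7, length.out = 51),
         k2 = seq(1.4e5, 1.7e5, length.out = 7)),
    fixed = c(k3 = 720), r = 1L, source = "deterministic")
  b <- tidy(pd)
  per_k2 <- dplyr::count(b, axis2)
  crossed <- dplyr::filter(per_k2, n == 2)$axis2
  expect_gt(length(crossed), 4)
  widths <- vapply(sort(crossed), function(k2v) {
    vv <- sort(dplyr::filter(b, axis2 == k2v)$value)
    vv[2] - vv[1]
  }, 0)
  expect_true(all(diff(widths) < 0))
  expect_lt(max(crossed), 720^2 / 3)
})

test_that("shift formulas reproduce their closed forms to machine precision", {
  set.seed(2)
  for (i in 1:50) {
    k3 <- runif(1, 100, 1000)
    x <- runif(1, 5, 500)
    r <- sample(1:40, 1)
    p <- schlogl_params(9e6, 1.5e5, k3, 1, r = r)
    s1 <- shift_derivative(p, "k1", x = x, r = r, finite_diff = FALSE)
    expect_equal(s1$analytic, k3 * x, tolerance = 1e-14)
    expect_equal(s1$analytic, s1$simplified, tolerance = 1e-14)
    s2 <- shift_derivative(p, "k2", x = x, r = r, finite_diff = FALSE)
    expect_equal(s2$analytic, -2 * k3 * x / (2 * x + 1), tolerance = 1e-14)
    if (abs(x - r) > 1e-6) {
      s3 <- shift_derivative(p, "k3", x = x, r = r, finite_diff = FALSE)
      expect_equal(s3$analytic, k3 / (x - r), tolerance = 1e-14)
      expect_equal(s3$analytic, s3$simplified, tolerance = 1e-14)
    }
  }
})

test_that("the k2 shift tends to the constant -k3 for large x", {
  p <- fig3_params()
  s <- shift_derivative(p, "k2", x = 400, finite_diff = FALSE)
  expect_equal(s$analytic, -720, tolerance = 2e-3)
  expect_lt(abs(shift_derivative(p, "k2", x = 4000,
                                 finite_diff = FALSE)$analytic + 720),
            abs(s$analytic + 720))
})

test_that("finite-difference tracking of real extrema matches the analytic shift", {
  # upper stationary maximum of the bursty canonical set: x >> 1
  p <- fig6_params(r = 25)
  ex <- find_extrema(p)
  x_up <- max(ex$location[ex$type == "maximum"])
  for (w in c("k1", "k2", "k3")) {
    s <- shift_derivative(p, w, x = x_up, r = 25)
    expect_lt(s$rel_error, 0.01)
  }
})

test_that("the k3 shift is undefined on its pole x = r", {
  expect_warning(s <- shift_derivative(fig3_params(r = 25), "k3", x = 25,
                                       r = 25, finite_diff = FALSE))
  expect_true(is.na(s$analytic))
})
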