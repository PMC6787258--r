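# The elastica geometry: elliptic parameter routes, profile coordinates,
# tangent angle, curvature fields.

test_that("series elliptic parameter matches its four printed terms and limits", {
  # 0.1 - 0.1^2/8 - 0.1^3/32 - 11*0.1^4/1024, frozen by hand arithmetic
  expect_equal(elliptic_parameter_series(0.1), 0.0987176758, tolerance = 1e-9)
  expect_lt(elliptic_parameter_series(1e-6), 1.1e-6)  # m -> 0 as gamma -> 0
  expect_error(elliptic_parameter_series(0.25), "series")
  expect_error(elliptic_parameter_series(0), "series|\\(0, 0.2\\]")
})

test_that("exact inversion solves the width-ratio relation and agrees with the series", {
  m <- elliptic_parameter_exact(0.9)
  expect_equal(elliptic_width_ratio(m), 0.9, tolerance = 1e-10)
  # independent bisection oracle on the same complete-elliptic relation
  expect_equal(m, bisect_m_for_ratio(0.9), tolerance = 1e-9)
  # the truncated series lands within 1e-5 of the exact root at gamma = 0.1
  expect_equal(elliptic_parameter_series(0.1), m, tolerance = 1e-5)
  expect_error(elliptic_parameter_exact(1.2), "\\(0, 1\\)")
})

test_that("round trip exact inversion recovers m across the parameter range", {
  for (m in c(0.01, 0.05, 0.098718, 0.2)) {
    expect_equal(elliptic_parameter_exact(elliptic_width_ratio(m)), m,
                 tolerance = 1e-9)
  }
})

test_that("profile endpoints, peak and monotonicity follow the elastica", {
  bp <- default_profile()
  p <- profile_xz(bp, c(0, bp$L / 2, bp$L))
  expect_equal(p$x[1], 0, tolerance = 1e-6 * bp$L)
  expect_equal(p$z[1], 0, tolerance = 1e-6 * bp$L)
  expect_equal(p$x[3], bp$Lx, tolerance = 1e-6 * bp$L)
  expect_equal(p$z[3], 0, tolerance = 1e-6 * bp$L)
  # peak height 4 * lam * sqrt(m): cn at the half-period argument is -1
  expect_equal(p$z[2], 4 * bp$lam * sqrt(bp$m), tolerance = 1e-9)
  s <- seq(0, bp$L, length.out = 500)
  pp <- profile_xz(bp, s)
  expect_true(all(diff(pp$x) > 0))
  expect_true(all(pp$z > -1e-9))
  expect_error(profile_xz(bp, -1), "wrap")
})

test_that("x(L) equals the numeric integral of cos(psi) over the period", {
  bp <- default_profile()
  xL <- stats::integrate(function(s) cos(tangent_angle(bp, s)), 0, bp$L,
                         rel.tol = 1e-10)$value
  expect_equal(profile_xz(bp, bp$L)$x, xL, tolerance = 1e-8)
})

test_that("arc length integrates back to L and the profile is symmetric", {
  bp <- default_profile()
  s <- seq(0, bp$L, length.out = 20001)
  p <- profile_xz(bp, s)
  arclen <- sum(sqrt(diff(p$x)^2 + diff(p$z)^2))
  expect_equal(arclen, bp$L, tolerance = 1e-4 * bp$L)
  sa <- seq(0.05, 0.45, by = 0.05) * bp$L
  expect_equal(profile_xz(bp, sa)$z, profile_xz(bp, bp$L - sa)$z,
               tolerance = 1e-9)
  expect_equal(local_curvature(bp, sa), local_curvature(bp, bp$L - sa),
               tolerance = 1e-9)
})

test_that("tangent angle hits its quarter-period value and differentiates to the curvature", {
  bp <- default_profile()
  expect_equal(tangent_angle(bp, 0), 0)
  # sn(K) = 1, so psi(L/4) = 2 asin(sqrt(m))
  expect_equal(tangent_angle(bp, bp$L / 4), 2 * asin(sqrt(bp$m)),
               tolerance = 1e-12)
  expect_equal(tangent_angle(bp, bp$L / 4), 0.6394, tolerance = 5e-4)
  s <- seq(1e-3, bp$L - 1e-3, length.out = 1000)
  h <- 1e-5
  dpsi <- (tangent_angle(bp, s + h) - tangent_angle(bp, s - h)) / (2 * h)
  expect_equal(abs(dpsi), local_curvature(bp, s), tolerance = 1e-6)
})

test_that("curvature vanishes at the inflection, peaks at the crest, and closes the loop", {
  bp <- default_profile()
  expect_equal(local_curvature(bp, bp$L / 4), 0, tolerance = 1e-9)
  expect_equal(local_curvature(bp, bp$L / 2), 2 * sqrt(bp$m) / bp$lam,
               tolerance = 1e-12)
  # signed curvature integrates to zero over a full period (closed psi loop)
  s <- seq(0, bp$L, length.out = 40001)
  sgn <- sign(pracma::ellipj(s / bp$lam, bp$m)$sn)
  signed <- local_curvature(bp, s) * sgn
  # trapezoid error at the inflection kinks limits this to ~1e-4
  expect_lt(abs(sum((signed[-1] + signed[-length(s)]) / 2 * diff(s))), 1e-3)
  # the same closure, exactly: psi returns to zero after one period
  expect_equal(tangent_angle(bp, bp$L), 0, tolerance = 1e-10)
})

test_that("flat limit: curvature scale vanishes and the profile straightens", {
  for (g in c(0.01, 0.001)) {
    bp <- buckle_profile(L = 37.8, gamma = g)
    s <- seq(0, bp$L, length.out = 200)
    expect_lt(max(local_curvature(bp, s)) * bp$L, 13 * sqrt(g))
    expect_lt(max(profile_xz(bp, s)$z), 2.4 * bp$L * sqrt(g))
  }
  bp1 <- buckle_profile(L = 37.8, gamma = 1e-4)
  p <- profile_xz(bp1, seq(0, bp1$L, length.out = 50))
  expect_equal(p$x, p$s, tolerance = 1e-3 * bp1$L)
  expect_lt(max(p$z) / bp1$L, 0.01)
})

test_that("oriented curvature follows the cos^2 law with an infinite-radius sentinel", {
  bp <- default_profile()
  oc90 <- oriented_curvature(bp, bp$L / 2, 90)
  expect_equal(oc90$C, 0)
  expect_identical(oc90$R, Inf)
  oc0 <- oriented_curvature(bp, bp$L / 2, 0)
  expect_equal(oc0$C, 2 * sqrt(bp$m) / bp$lam, tolerance = 1e-12)
  oc45 <- oriented_curvature(bp, bp$L / 3, 45)
  expect_equal(oc45$C, local_curvature(bp, bp$L / 3) / 2, tolerance = 1e-12)
  expect_equal(oc45$R, 1 / oc45$C)
  expect_error(oriented_curvature(bp, 1, 120), "90")
})

test_that("profile construction validates its inputs", {
  expect_error(buckle_profile(L = -1, gamma = 0.1), "> 0")
  expect_error(buckle_profile(L = 30), "exactly one")
  expect_error(buckle_profile(L = 30, gamma = 0.1, lx_over_l = 0.9),
               "exactly one")
  bp <- buckle_profile(L = 30, lx_over_l = 0.9)
  expect_equal(bp$gamma, 0.1, tolerance = 1e-12)
})
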