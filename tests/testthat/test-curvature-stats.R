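# Occupancy maps and Boltzmann-inversion free-energy profiles.

test_that("occupancy histogram puts identical placements in one bin and matches the analytic map", {
  bp <- default_profile()
  pl <- tibble::tibble(s_norm = rep(0.513, 77), theta = rep(42.2, 77))
  lm_ <- occupancy_map(pl, bp)
  expect_equal(sum(lm_$occupancy), 77)
  expect_equal(max(lm_$occupancy), 77)
  # companion curvature map equals oriented_curvature at the bin centres
  s_mid <- (lm_$s_edges[-1] + lm_$s_edges[-51]) / 2
  t_mid <- (lm_$theta_edges[-1] + lm_$theta_edges[-46]) / 2
  oc <- oriented_curvature(bp, rep(s_mid * bp$L, 45), rep(t_mid, each = 50))
  expect_equal(as.vector(lm_$C_map), oc$C, tolerance = 1e-12)
  expect_error(occupancy_map(pl[0, ], bp), "at least one")
})

test_that("uniform placements fill the occupancy map multinomially", {
  bp <- default_profile()
  set.seed(11)
  n <- 9e4
  pl <- tibble::tibble(s_norm = runif(n), theta = runif(n, 0, 90))
  lm_ <- occupancy_map(pl, bp, s_bins = 10L, theta_bins = 9L)
  expect_equal(sum(lm_$occupancy), n)
  p <- 1 / 90
  sd_bin <- sqrt(n * p * (1 - p))
  expect_lt(max(abs(lm_$occupancy - n * p)), 4.5 * sd_bin)
})

test_that("the density-of-states correction makes a uniform ensemble flat", {
  bp <- default_profile()
  set.seed(12)
  n <- 1e5
  pl <- tibble::tibble(s_norm = runif(n), theta = runif(n, 0, 90))
  fe <- free_energy_profile(pl, bp)
  pop <- !is.na(fe$F) & fe$count >= 25
  expect_gt(sum(pop), 15)
  counting_err <- 1 / sqrt(fe$count[pop])
  expect_true(all(abs(fe$F[pop]) <= 3 * counting_err))
  # without the correction the same ensemble is NOT flat
  fe_raw <- free_energy_profile(pl, bp, correct_dos = FALSE)
  expect_gt(max(abs(fe_raw$F[!is.na(fe_raw$F)])), 1)
})

test_that("a step binding energy is recovered at its imposed depth", {
  bp <- default_profile()
  set.seed(13)
  # direct independent sampler (rejection, not the package MC): the oracle
  n <- 2e5
  u0 <- 1.5
  window <- c(17, 33)
  s <- runif(n, 0, bp$L)
  th <- runif(n, 0, 90)
  oc <- oriented_curvature(bp, s, th)
  w <- ifelse(oc$R >= window[1] & oc$R <= window[2], exp(u0), 1)
  keep <- runif(n) < w / exp(u0)
  pl <- tibble::tibble(s_norm = s[keep] / bp$L, theta = th[keep])
  fe <- free_energy_profile(pl, bp)
  inside <- which(fe$R_lo >= window[1] & fe$R_hi <= window[2] & !is.na(fe$F))
  outside <- which((fe$R_hi < window[1] | fe$R_lo > window[2]) & !is.na(fe$F) &
                     fe$count > 50)
  expect_gt(length(inside), 2)
  ref_var <- 1 / fe$count[attr(fe, "reference_bin")]
  err_in <- sqrt(1 / fe$count[inside] + ref_var)
  expect_true(all(abs(fe$F[inside] + u0) <= 3.5 * err_in))
  err_out <- sqrt(1 / fe$count[outside] + ref_var)
  expect_true(all(abs(fe$F[outside]) <= 3.5 * err_out))
})

test_that("free energies are invariant to count scaling and reference choice shifts only the offset", {
  bp <- default_profile()
  set.seed(14)
  n <- 2e4
  pl <- tibble::tibble(s_norm = runif(n), theta = runif(n, 0, 90))
  fe1 <- free_energy_profile(pl, bp)
  fe2 <- free_energy_profile(dplyr::bind_rows(pl, pl), bp)
  pop <- !is.na(fe1$F) & !is.na(fe2$F)
  expect_equal(fe1$F[pop], fe2$F[pop], tolerance = 1e-9)
  # differences between populated bins do not depend on the reference offset
  edges <- default_R_edges(12, 12, 150)
  fe3 <- free_energy_profile(pl, bp, R_edges = edges)
  i <- which(!is.na(fe3$F))[1:2]
  shifted <- fe3$F - fe3$F[i[1]]
  expect_equal(shifted[i[2]] - shifted[i[1]], fe3$F[i[2]] - fe3$F[i[1]],
               tolerance = 1e-12)
  expect_equal(fe3$F[attr(fe3, "reference_bin")], 0)
})

test_that("binding free energy interpolates the profile and rejects empty bins", {
  bp <- default_profile()
  set.seed(15)
  n <- 5e4
  pl <- tibble::tibble(s_norm = runif(n), theta = runif(n, 0, 90))
  fe <- free_energy_profile(pl, bp)
  expect_lt(abs(binding_free_energy(fe, 25)), 0.15)  # flat ensemble -> ~0
  # reference bin reads zero by construction
  ref <- attr(fe, "reference_bin")
  if (is.finite(fe$R_mid[ref])) {
    expect_lt(abs(binding_free_energy(fe, fe$R_mid[ref])), 0.1)
  }
  expect_error(binding_free_energy(fe, 5), "unpopulated|coverage")
  expect_error(binding_free_energy(fe, -2), "positive")
})

test_that("empty bins are reported as NA, never zero", {
  bp <- default_profile()
  # all placements at one (s, theta): a single populated radius bin
  pl <- tibble::tibble(s_norm = rep(0.5, 200), theta = rep(60, 200))
  expect_warning(fe <- free_energy_profile(pl[1:50, ], bp), "noisy")
  fe <- free_energy_profile(pl, bp)
  expect_true(any(is.na(fe$F)))
  expect_false(any(fe$F[fe$count == 0] == 0, na.rm = TRUE))
  # placements whose curvature exceeds the binned range are a hard error,
  # not a silently empty profile (the peak at theta = 0 has R = 9.33 nm,
  # below the default 10 nm edge)
  sharp <- tibble::tibble(s_norm = rep(0.5, 200), theta = rep(0, 200))
  expect_error(free_energy_profile(sharp, bp), "outside")
})
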