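# Circle fitting, membrane radius series, RMSD/RMSF, protein curvature.

test_that("circle fit is exact on a circumcircle and on noiseless arcs", {
  fit <- fit_circle(cbind(c(0, 1, 0), c(1, 0, -1)))
  expect_equal(fit$center, c(0, 0), tolerance = 1e-12)
  expect_equal(fit$radius, 1, tolerance = 1e-12)
  expect_lt(fit$rms_residual, 1e-9)
  # any 3 non-collinear points fit exactly
  set.seed(21)
  for (i in 1:10) {
    pts <- matrix(rnorm(6, sd = 5), 3, 2)
    f <- tryCatch(fit_circle(pts), error = function(e) NULL)
    if (!is.null(f)) expect_lt(f$rms_residual, 1e-9)
  }
  # 200 noiseless points on a 30-degree arc of radius 100
  phi <- seq(pi / 2 - pi / 12, pi / 2 + pi / 12, length.out = 200)
  f100 <- fit_circle(cbind(100 * cos(phi), 100 * sin(phi)))
  expect_equal(f100$radius, 100, tolerance = 1e-9)
  expect_error(fit_circle(cbind(1:10, 2 * (1:10) + 3)), "collinear")
})

test_that("noisy arc radius is recovered within its Monte-Carlo spread", {
  radii <- sapply(1:50, function(sd) {
    set.seed(sd)
    phi <- seq(pi / 2 - pi / 12, pi / 2 + pi / 12, length.out = 200)
    pts <- cbind(100 * cos(phi), 100 * sin(phi)) +
      matrix(rnorm(400, 0, 0.3), ncol = 2)
    fit_circle(pts)$radius
  })
  # geometric-fit spread at this noise and arc span is about 2 nm (1 sd)
  expect_lt(abs(mean(radii) - 100), 1)
  expect_lt(sd(radii), 3)
  expect_lt(max(abs(radii - 100)), 8)
})

test_that("membrane radius series recovers bent-sheet radii and flags flat sheets", {
  for (R in c(60, 100)) {
    fr <- make_bent_sheet(R, noise_sigma = 0.3, seed = R)
    out <- membrane_radius_series(list(fr))
    expect_equal(out$flag, "ok")
    expect_lt(abs(out$radius - R) / R, 0.02)
  }
  flat <- make_bent_sheet(Inf, noise_sigma = 0.1, seed = 3)
  out <- membrane_radius_series(list(flat))
  expect_identical(out$radius, Inf)
  expect_equal(out$flag, "flat")
})

test_that("a ramped bending trajectory yields a monotone radius series", {
  radii_true <- seq(150, 60, length.out = 12)
  frames <- lapply(seq_along(radii_true), function(i) {
    make_bent_sheet(radii_true[i], noise_sigma = 0.2, seed = 100 + i,
                    time = i)
  })
  out <- membrane_radius_series(frames)
  expect_true(all(out$flag == "ok"))
  expect_lt(max(abs(out$radius - radii_true) / radii_true), 0.02)
  expect_true(all(diff(out$radius) < 0))
})

test_that("rmsd obeys identity, rigid-motion invariance and the hand-computed toy value", {
  set.seed(22)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd(a, a), 0, tolerance = 1e-12)
  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- a %*% t(Rz) + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  expect_lt(rmsd(moved, a, superpose = TRUE), 1e-9)
  expect_gt(rmsd(moved, a, superpose = FALSE), 1)
  # 4-point toy: two points displaced +1 nm in z, no superposition
  ref <- cbind(c(0, 1, 2, 3), 0, 0)
  tgt <- ref; tgt[3:4, 3] <- 1
  expect_equal(rmsd(tgt, ref, superpose = FALSE), sqrt(2 / 4),
               tolerance = 1e-12)
  expect_equal(rmsd(tgt, ref, superpose = FALSE),
               rmsd(ref, tgt, superpose = FALSE), tolerance = 1e-12)
  expect_error(rmsd(a[1:5, ], a), "identical dimensions")
})

test_that("rmsd without superposition satisfies a triangle-like bound", {
  set.seed(23)
  a <- matrix(rnorm(24), 8, 3)
  b <- a + matrix(rnorm(24, sd = 0.4), 8, 3)
  c2 <- b + matrix(rnorm(24, sd = 0.4), 8, 3)
  expect_lte(rmsd(a, c2, superpose = FALSE),
             rmsd(a, b, superpose = FALSE) + rmsd(b, c2, superpose = FALSE) + 1e-12)
})

test_that("superposed rmsd agrees with the bio3d reference implementation", {
  skip_if_not_installed("bio3d")
  set.seed(24)
  a <- matrix(rnorm(36), 12, 3)
  b <- a + matrix(rnorm(36, sd = 0.5), 12, 3)
  ours <- rmsd(b, a, superpose = TRUE)
  theirs <- bio3d::rmsd(as.vector(t(a)) * 10, as.vector(t(b)) * 10,
                        fit = TRUE) / 10
  expect_lt(abs(ours - theirs), 1e-4)  # bio3d rounds to 3 decimals (Angstrom)
})

test_that("rmsf is zero for static or rigidly tumbling ensembles", {
  set.seed(25)
  base <- matrix(rnorm(30, sd = 3), 10, 3)
  static <- replicate(8, base, simplify = FALSE)
  expect_true(all(rmsf(static)$rmsf < 1e-12))
  tumbled <- lapply(1:8, function(i) {
    th <- i / 3
    Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    base %*% t(Rz) + matrix(rnorm(3), 10, 3, byrow = TRUE)
  })
  expect_true(all(rmsf(tumbled)$rmsf < 1e-9))
  expect_error(rmsf(static[1]), "at least 2")
})

test_that("rmsf of one jittered site among anchors recovers sigma * sqrt(3)", {
  set.seed(26)
  sigma <- 0.25
  n_frames <- 1e4
  # anchors must span 3D: a collinear scaffold leaves a free rotation that
  # soaks up the jittered site's fluctuation
  base <- matrix(rnorm(60 * 3, sd = 4), 60, 3)
  frames <- lapply(seq_len(n_frames), function(i) {
    m <- base
    m[15, ] <- m[15, ] + rnorm(3, 0, sigma)
    m
  })
  out <- rmsf(frames)
  expect_lt(abs(out$rmsf[15] - sigma * sqrt(3)) / (sigma * sqrt(3)), 0.05)
  expect_true(all(out$rmsf[-15] < 0.05 * sigma * sqrt(3)))
})

test_that("protein curvature recovers arc radii and flags straight rods", {
  for (R in c(25, 50)) {
    ens <- make_conformer_ensemble(1, base_radius = R, seed = R)
    expect_lt(abs(protein_curvature(ens$frames[[1]]) - R) / R, 0.02)
  }
  rod <- straight_rod_frame(20)
  co <- rod$coords; co[, 3] <- 10   # exactly straight
  expect_identical(protein_curvature(co), Inf)
})

test_that("a flexing conformer ensemble spans its imposed radius range", {
  ens <- make_conformer_ensemble(400, base_radius = 37, radius_sigma = 0.2,
                                 jitter_sigma = 0, seed = 27)
  fitted <- vapply(ens$frames, protein_curvature, numeric(1))
  expect_equal(fitted, ens$truth$radius, tolerance = 1e-6)
  expect_lt(quantile(fitted, 0.1), 30)
  expect_gt(quantile(fitted, 0.9), 45)
  # free-energy-style histogram over the fitted radii has its mode near the
  # imposed median
  h <- hist(log(fitted), breaks = 15, plot = FALSE)
  expect_lt(abs(exp(h$mids[which.max(h$counts)]) - 37) / 37, 0.25)
})
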