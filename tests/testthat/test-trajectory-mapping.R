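# Mapping snapshots onto the buckle: alignment, arc position, orientation.

test_that("alignment recovers a known rigid shift on a noiseless sheet", {
  cfg <- quiet_cfg(noise_sigma = 0)
  bp <- cfg$profile
  bin_w <- bp$Lx / 50
  fr0 <- make_buckled_sheet(cfg)
  al0 <- align_to_profile(fr0, bp)
  expect_lt(abs(al0$shift), bin_w)

  fr <- make_buckled_sheet(cfg, shift_x = 7.3)
  al <- align_to_profile(fr, bp)
  expect_lt(abs(al$shift + 7.3), bin_w)

  # a full-period shift is a no-op modulo L_x
  frL <- make_buckled_sheet(cfg, shift_x = bp$Lx)
  alL <- align_to_profile(frL, bp)
  expect_lt(abs(alL$shift), bin_w)
})

test_that("alignment refuses frames with the wrong box or too little coverage", {
  cfg <- quiet_cfg(noise_sigma = 0)
  fr <- make_buckled_sheet(cfg)
  bad <- labeled_frame(fr$coords, fr$role, c(fr$box[1] * 1.2, fr$box[2:3]))
  expect_error(align_to_profile(bad, cfg$profile), "5%")
  narrow <- which(fr$coords[, 1] %% fr$box[1] < 3)   # a thin x-slab only
  few <- labeled_frame(fr$coords[narrow, ], fr$role[narrow], fr$box)
  expect_error(align_to_profile(few, cfg$profile), "bins")
})

test_that("arc position and orientation recover generator ground truth", {
  cfg <- quiet_cfg(noise_sigma = 0)
  bp <- cfg$profile
  for (tgt in list(c(0.50, 0), c(0.50, 90), c(0.25, 30), c(0.70, 60))) {
    fr <- place_protein(cfg, tgt[1], tgt[2])
    al <- align_to_profile(fr, bp)
    expect_lt(abs(protein_arclength(al$frame, bp) - tgt[1]), 0.01)
    expect_lt(abs(protein_orientation(al$frame) - tgt[2]), 1)
  }
  # inflection point carries (near) zero curvature
  fr <- place_protein(cfg, 0.25, 0)
  al <- align_to_profile(fr, bp)
  s <- protein_arclength(al$frame, bp)
  expect_lt(local_curvature(bp, s * bp$L), 0.02 * 2 * sqrt(bp$m) / bp$lam)
})

test_that("the centre of mass at the analytic peak maps to mid-arc", {
  cfg <- quiet_cfg(noise_sigma = 0)
  bp <- cfg$profile
  fr <- make_buckled_sheet(cfg)
  pro <- cbind(bp$Lx / 2 + seq(-2, 2, length.out = 5), 7.5, 10)
  fr2 <- labeled_frame(rbind(fr$coords, pro),
                       c(fr$role, rep("protein_backbone", 5)), fr$box)
  expect_equal(protein_arclength(fr2, bp), 0.5, tolerance = 1e-3)
})

test_that("orientation is the folded in-plane angle of the first principal axis", {
  expect_lt(abs(protein_orientation(straight_rod_frame(0))), 0.2)
  expect_lt(abs(protein_orientation(straight_rod_frame(90)) - 90), 0.2)
  rod30 <- straight_rod_frame(30)
  rod210 <- straight_rod_frame(210)    # same axis, flipped sign
  expect_lt(abs(protein_orientation(rod30) - 30), 0.2)
  expect_equal(protein_orientation(rod210), protein_orientation(rod30),
               tolerance = 1e-9)
  # reflection y -> -y leaves the folded angle unchanged
  refl <- straight_rod_frame(30)
  co <- refl$coords; co[, 2] <- 50 - co[, 2]
  refl2 <- labeled_frame(co, refl$role, refl$box)
  expect_equal(protein_orientation(refl2), protein_orientation(rod30),
               tolerance = 1e-9)
})

test_that("orientation errors on degenerate bead clouds", {
  # isotropic 4-point cloud: top two eigenvalues tie
  co <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)) + 25
  fr <- labeled_frame(co, rep("protein_backbone", 4), c(50, 50, 50))
  expect_error(protein_orientation(fr), "[Dd]egenerate")
  fr2 <- labeled_frame(co[1:2, ], rep("protein_backbone", 2), c(50, 50, 50))
  expect_error(protein_orientation(fr2), "at least 3")
})

test_that("mapping a trajectory is invariant to rigid x-translation", {
  cfg <- quiet_cfg(noise_sigma = 0)
  bp <- cfg$profile
  fr <- place_protein(cfg, 0.4, 25)
  m1 <- map_trajectory(fr, bp)
  co <- fr$coords
  co[, 1] <- (co[, 1] + 11.17) %% bp$Lx
  m2 <- map_trajectory(labeled_frame(co, fr$role, fr$box), bp)
  expect_lt(abs(m2$s_norm - m1$s_norm), 0.011)
  expect_lt(abs(m2$theta - m1$theta), 1)
  expect_false(isTRUE(all.equal(m2$shift, m1$shift)))
})

test_that("trajectory mapping composes per-frame results and reports curvature", {
  cfg <- quiet_cfg(noise_sigma = 0.3, seed = 7)
  bp <- cfg$profile
  truth <- tibble::tibble(sample = 1:60,
                          s_norm = rep(c(0.5, 0.35, 0.6), 20),
                          theta = rep(c(45, 10, 80), 20))
  frames <- render_trajectory(cfg, truth)
  mt <- map_trajectory(frames, bp)
  expect_equal(nrow(mt), 60)
  expect_lt(max(abs((mt$s_norm - truth$s_norm + 0.5) %% 1 - 0.5)), 0.012)
  expect_lt(max(abs(mt$theta - truth$theta)), 4)
  oc <- oriented_curvature(bp, mt$s_norm * bp$L, mt$theta)
  expect_equal(mt$C, oc$C, tolerance = 1e-12)
  # single frame maps to a single row
  expect_equal(nrow(map_trajectory(frames[[1]], bp)), 1)
})

test_that("unmappable frames are skipped with a warning, many failures abort", {
  cfg <- quiet_cfg(noise_sigma = 0)
  bp <- cfg$profile
  good <- place_protein(cfg, 0.5, 45)
  membrane_only <- make_buckled_sheet(cfg)
  frames <- c(rep(list(good), 9), list(membrane_only))
  expect_warning(mt <- map_trajectory(frames, bp), "skipped")
  expect_equal(nrow(mt), 9)
  expect_error(
    suppressWarnings(map_trajectory(c(list(good), rep(list(membrane_only), 9)), bp)),
    "20%")
})
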