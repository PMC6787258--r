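# Ground-truth generators: buckled bead sheets, banana-protein placements,
# Boltzmann (s, theta) ensembles, cylindrically bent / flat sheets, and
# protein conformer ensembles. Every generator is a pure function of
# (configuration, seed).

#' Generator configuration
#'
#' Bundles the geometry and sampling parameters shared by the synthetic-data
#' generators. Defaults emulate a coarse-grained buckled-bilayer system at 10%
#' lateral compression: one buckle period of arc length `L = 37.8` nm
#' (`L_x` about 34 nm; the period is an assumption, as it is set by the
#' simulation box), a 15 nm deep sheet, 0.8 nm head-bead spacing, two leaflets
#' offset 2 nm either side of the midsurface, 0.3 nm thermal positional noise,
#' and a banana-shaped protein of arc radius 25 nm and chord length 15 nm.
#'
#' @param seed Integer seed; every generator is deterministic given the
#'   config and seed.
#' @param gamma Compression ratio in (0, 0.2).
#' @param L Arc length of one buckle period, nm.
#' @param Ly Sheet depth along y, nm.
#' @param lipid_spacing Head-bead grid spacing, nm.
#' @param leaflet_offset Half bilayer thickness: leaflet offset from the
#'   midsurface along the local normal, nm.
#' @param noise_sigma Isotropic Gaussian positional noise, nm.
#' @param protein_arc_radius Radius of the circular arc forming the banana
#'   protein, nm.
#' @param protein_length Chord length of the protein arc, nm.
#' @param n_protein_beads Number of backbone beads along the arc.
#' @param energy_model List describing the curvature-dependent binding energy
#'   used by [sample_boltzmann_trajectory()]: `model` (`"step"` or
#'   `"harmonic"`), `preferred_R` (nm), `well_depth` (kBT, depth of the
#'   favourable well relative to a flat membrane) and, for the step model,
#'   `window` (nm, the radius band over which binding is favourable).
#' @param n_frames Number of retained Monte-Carlo frames.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             gamma = 0.1,
                             L = 37.8,
                             Ly = 15,
                             lipid_spacing = 0.8,
                             leaflet_offset = 2.0,
                             noise_sigma = 0.3,
                             protein_arc_radius = 25,
                             protein_length = 15,
                             n_protein_beads = 21L,
                             energy_model = list(model = "step",
                                                 preferred_R = 25,
                                                 well_depth = 2,
                                                 window = c(17, 33)),
                             n_frames = 100L) {
  lens <- c(L = L, Ly = Ly, lipid_spacing = lipid_spacing,
            leaflet_offset = leaflet_offset, protein_arc_radius = protein_arc_radius,
            protein_length = protein_length)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    rlang::abort("All generator lengths must be positive and finite.")
  }
  if (noise_sigma < 0) rlang::abort("`noise_sigma` must be >= 0.")
  if (gamma <= 0 || gamma >= 0.2) rlang::abort("`gamma` must lie in (0, 0.2).")
  if (n_frames < 1) rlang::abort("`n_frames` must be >= 1.")
  if (protein_length > L / 2) {
    rlang::abort("Protein chord length must not exceed half the buckle period.")
  }
  cfg <- list(seed = as.integer(seed), gamma = gamma, L = L, Ly = Ly,
              lipid_spacing = lipid_spacing, leaflet_offset = leaflet_offset,
              noise_sigma = noise_sigma,
              protein_arc_radius = protein_arc_radius,
              protein_length = protein_length,
              n_protein_beads = as.integer(n_protein_beads),
              energy_model = energy_model,
              n_frames = as.integer(n_frames))
  cfg$profile <- buckle_profile(L, gamma = gamma)
  cfg$cache <- new.env(parent = emptyenv())
  class(cfg) <- "generator_config"
  cfg
}

# noiseless head-bead scaffold of the buckled sheet: positions, one row per
# bead, two leaflets offset along the local normal (-sin psi, 0, cos psi);
# identical across frames for a given config, so cached
buckled_sheet_scaffold <- function(cfg) {
  if (!is.null(cfg$cache$scaffold)) return(cfg$cache$scaffold)
  bp <- cfg$profile
  s <- seq(0, bp$L - cfg$lipid_spacing / 2, by = cfg$lipid_spacing)
  y <- seq(0, cfg$Ly - cfg$lipid_spacing / 2, by = cfg$lipid_spacing)
  prof <- profile_xz(bp, s)
  psi <- tangent_angle(bp, s)
  nx <- -sin(psi)
  nz <- cos(psi)
  one_leaflet <- function(sign) {
    cbind(x = rep(prof$x + sign * cfg$leaflet_offset * nx, times = length(y)),
          y = rep(y, each = length(s)),
          z = rep(prof$z + sign * cfg$leaflet_offset * nz, times = length(y)))
  }
  out <- rbind(one_leaflet(+1), one_leaflet(-1))
  cfg$cache$scaffold <- out
  out
}

#' Synthetic buckled bilayer sheet
#'
#' Lays membrane head beads on the analytic buckle ([profile_xz()]) on an
#' `(s, y)` grid, offsets two leaflets by `leaflet_offset` along the local
#' surface normal, and adds isotropic Gaussian positional noise. The returned
#' frame is in the canonical aligned position (peak at `x = L_x/2`) shifted
#' by `shift_x`.
#'
#' @param cfg A [generator_config()].
#' @param shift_x Rigid x-translation applied to the sheet, nm (ground truth
#'   for alignment tests).
#' @param seed Optional seed overriding `cfg$seed`.
#' @param time Time stamp, ps.
#' @return A [labeled_frame()] with `membrane_head` beads and box
#'   `(L_x, Ly, 4 * peak height + 4 * leaflet offset)`.
#' @export
make_buckled_sheet <- function(cfg, shift_x = 0, seed = cfg$seed, time = 0) {
  stopifnot(inherits(cfg, "generator_config"))
  coords <- buckled_sheet_scaffold(cfg)
  if (!is.null(seed)) set.seed(seed)
  if (cfg$noise_sigma > 0) {
    coords <- coords + matrix(stats::rnorm(length(coords), 0, cfg$noise_sigma),
                              ncol = 3)
  }
  bp <- cfg$profile
  coords[, 1] <- wrap_into(coords[, 1] + shift_x, bp$Lx)
  box <- c(bp$Lx, cfg$Ly, 4 * (4 * bp$lam * sqrt(bp$m)) + 4 * cfg$leaflet_offset)
  labeled_frame(coords, rep("membrane_head", nrow(coords)), box, time = time)
}

# protein arc bead chain in local coordinates: long axis u, bow towards +w
protein_arc_local <- function(radius, chord, n_beads) {
  alpha <- asin(pmin(chord / 2 / radius, 1))
  phi <- seq(-alpha, alpha, length.out = n_beads)
  cbind(u = radius * sin(phi), w = radius * (1 - cos(phi)))
}

#' Place a banana-shaped protein on the buckled sheet
#'
#' Builds a circular-arc backbone bead chain (radius `protein_arc_radius`,
#' chord `protein_length`, `n_protein_beads` beads), lays it tangent to the
#' membrane surface at arc position `s_norm * L`, rotated so that the
#' xy-projection of its long axis makes the angle `theta` with the buckling
#' direction, bowing away from the surface with a small standoff. The chain is
#' then translated along x so that its centre of mass projects exactly onto
#' the target arc position: ground truth is defined in terms of the centre of
#' mass, which is what the mapping stage measures.
#'
#' @param cfg A [generator_config()].
#' @param s_norm Target normalized arc position in `[0, 1)`.
#' @param theta Target in-plane orientation, degrees in `[0, 90]`.
#' @param frame Optional existing sheet frame to add the protein to; by
#'   default a fresh [make_buckled_sheet()] is generated.
#' @param standoff Gap between the membrane surface and the lowest protein
#'   bead, nm.
#' @param seed Optional seed overriding `cfg$seed` (used for the sheet and
#'   the protein-bead noise).
#' @param time Time stamp, ps.
#' @return A [labeled_frame()] with both `membrane_head` and
#'   `protein_backbone` beads.
#' @export
place_protein <- function(cfg, s_norm, theta, frame = NULL, standoff = 0.5,
                          seed = cfg$seed, time = 0) {
  stopifnot(inherits(cfg, "generator_config"))
  if (s_norm < 0 || s_norm >= 1) rlang::abort("`s_norm` must lie in [0, 1).")
  if (theta < 0 || theta > 90) rlang::abort("`theta` must lie in [0, 90].")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(frame)) frame <- make_buckled_sheet(cfg, seed = NULL, time = time)
  bp <- cfg$profile
  s0 <- s_norm * bp$L
  base <- profile_xz(bp, s0)
  psi <- tangent_angle(bp, s0)
  tangent <- c(cos(psi), 0, sin(psi))
  normal <- c(-sin(psi), 0, cos(psi))
  yhat <- c(0, 1, 0)
  # choose the surface angle so that the xy-PROJECTED axis angle equals theta
  th <- theta * pi / 180
  thp <- if (theta >= 90) pi / 2 else atan(tan(th) * cos(psi))
  axis <- cos(thp) * tangent + sin(thp) * yhat
  local <- protein_arc_local(cfg$protein_arc_radius, cfg$protein_length,
                             cfg$n_protein_beads)
  pts <- outer(local[, "u"], axis) + outer(local[, "w"] + standoff, normal)
  pts <- sweep(pts, 2, c(base$x, cfg$Ly / 2, base$z), "+")
  if (cfg$noise_sigma > 0) {
    pts <- pts + matrix(stats::rnorm(length(pts), 0, cfg$noise_sigma), ncol = 3)
  }
  # centre-of-mass convention: shift along x so the COM maps back to s0
  pts[, 1] <- pts[, 1] + (base$x - mean(pts[, 1]))
  pts[, 1] <- wrap_into(pts[, 1], bp$Lx)
  labeled_frame(rbind(frame$coords, pts),
                c(frame$role, rep("protein_backbone", nrow(pts))),
                frame$box, time = time,
                name = c(frame$name, rep("BB", nrow(pts))))
}

# curvature-dependent binding energy, kBT, as a function of C (1/nm)
binding_energy_fun <- function(energy_model) {
  em <- energy_model
  if (identical(em$model, "step")) {
    lo <- min(em$window); hi <- max(em$window)
    function(C) {
      R <- ifelse(C < C_FLOOR, Inf, 1 / C)
      ifelse(R >= lo & R <= hi, -em$well_depth, 0)
    }
  } else if (identical(em$model, "harmonic")) {
    C0 <- 1 / em$preferred_R
    function(C) em$well_depth * ((C - C0) / C0)^2 - em$well_depth
  } else {
    rlang::abort("`energy_model$model` must be \"step\" or \"harmonic\".")
  }
}

#' Metropolis Monte-Carlo ensemble of protein placements on the buckle
#'
#' Samples `(s, theta)` from the Boltzmann distribution
#' \eqn{p \propto \exp(-U(C(s,\theta)))} (uniform base measure on
#' `[0, L) x [0, 90]`) with the curvature-dependent binding energy of
#' `cfg$energy_model`, in kBT units. Proposals are Gaussian (`s` wrapped
#' periodically, `theta` reflected at the boundaries, both symmetric, so the
#' chain is exact); the chain is thinned 10x. If the acceptance rate leaves
#' `[0.1, 0.9]` during burn-in, proposal widths are auto-tuned towards 30-50%
#' acceptance and a warning is raised.
#'
#' @param cfg A [generator_config()]; `cfg$n_frames` samples are returned.
#' @param render If `TRUE` also renders each retained sample as a full
#'   coordinate frame via [make_buckled_sheet()] + [place_protein()]
#'   (memory-heavy; prefer [render_trajectory()] in chunks for large runs).
#' @param proposal_s,proposal_theta Proposal standard deviations (nm fraction
#'   of `L`, and degrees).
#' @return A list with `truth` (tibble: `sample`, `s_norm`, `theta`, `C`,
#'   `R`, `U`), `acceptance_rate`, and `frames` (list of [labeled_frame()] or
#'   `NULL`).
#' @export
sample_boltzmann_trajectory <- function(cfg, render = FALSE,
                                        proposal_s = 0.02, proposal_theta = 5) {
  stopifnot(inherits(cfg, "generator_config"))
  bp <- cfg$profile
  U <- binding_energy_fun(cfg$energy_model)
  # fast C(s) lookup: linear interpolation on a fine grid (the sampler takes
  # millions of scalar curvature evaluations; interpolation error ~1e-8 1/nm)
  if (is.null(bp$cache$C_interp)) {
    sg <- seq(0, bp$L, length.out = 8193L)
    bp$cache$C_interp <- stats::approxfun(sg, local_curvature(bp, sg),
                                          rule = 2)
  }
  C_of <- bp$cache$C_interp
  Ufun <- function(s, th) U(C_of(s) * cospi(th / 180)^2)
  set.seed(cfg$seed)
  n_keep <- cfg$n_frames
  thin <- 10L
  ds <- proposal_s * bp$L
  dth <- proposal_theta

  # short burn-in with acceptance monitoring / auto-tuning
  s <- stats::runif(1, 0, bp$L)
  th <- stats::runif(1, 0, 90)
  u <- Ufun(s, th)
  for (tune in 1:3) {
    acc <- 0L
    n_burn <- 500L
    for (i in seq_len(n_burn)) {
      sp <- wrap_into(s + stats::rnorm(1, 0, ds), bp$L)
      tp <- reflect_into(th + stats::rnorm(1, 0, dth), 0, 90)
      up <- Ufun(sp, tp)
      if (stats::runif(1) < exp(u - up)) {
        s <- sp; th <- tp; u <- up; acc <- acc + 1L
      }
    }
    rate <- acc / n_burn
    if (rate >= 0.1 && rate <= 0.9) break
    rlang::warn(sprintf(
      "MC acceptance rate %.2f outside [0.1, 0.9]; auto-tuning proposal widths.",
      rate))
    scale <- if (rate < 0.1) 0.3 else 3
    ds <- ds * scale
    dth <- min(dth * scale, 45)
  }

  n_steps <- n_keep * thin
  keep_s <- numeric(n_keep)
  keep_t <- numeric(n_keep)
  prop_s <- stats::rnorm(n_steps, 0, ds)
  prop_t <- stats::rnorm(n_steps, 0, dth)
  log_u <- log(stats::runif(n_steps))
  acc <- 0L
  for (i in seq_len(n_steps)) {
    sp <- wrap_into(s + prop_s[i], bp$L)
    tp <- reflect_into(th + prop_t[i], 0, 90)
    up <- Ufun(sp, tp)
    if (log_u[i] < u - up) {
      s <- sp; th <- tp; u <- up; acc <- acc + 1L
    }
    if (i %% thin == 0L) {
      j <- i %/% thin
      keep_s[j] <- s
      keep_t[j] <- th
    }
  }
  oc <- oriented_curvature(bp, keep_s, keep_t)
  truth <- tibble::tibble(sample = seq_len(n_keep),
                          s_norm = keep_s / bp$L, theta = keep_t,
                          C = oc$C, R = oc$R, U = Ufun(keep_s, keep_t))
  frames <- if (render) render_trajectory(cfg, truth) else NULL
  list(truth = truth, acceptance_rate = acc / n_steps, frames = frames)
}

reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Render sampled placements as coordinate frames
#'
#' Deterministically renders rows of a ground-truth placement table (from
#' [sample_boltzmann_trajectory()]) as full bead frames: fresh noisy sheet,
#' protein placed at the sampled `(s_norm, theta)`, and a random rigid
#' x-shift of the whole frame (exercising the alignment stage). Each frame's
#' noise is seeded from `cfg$seed` and the row index, so rendering in chunks
#' is reproducible.
#'
#' @param cfg A [generator_config()].
#' @param truth Tibble with columns `sample`, `s_norm`, `theta`.
#' @param rows Which rows to render (default all).
#' @param random_shift Apply a per-frame uniform rigid x-shift (default TRUE).
#' @return List of [labeled_frame()] objects.
#' @export
render_trajectory <- function(cfg, truth, rows = seq_len(nrow(truth)),
                              random_shift = TRUE) {
  bp <- cfg$profile
  lapply(rows, function(i) {
    set.seed((cfg$seed + 7919L * (truth$sample[i] %% 262144L)) %% .Machine$integer.max)
    fr <- place_protein(cfg, truth$s_norm[i], truth$theta[i], seed = NULL,
                        time = truth$sample[i])
    if (random_shift) {
      dx <- stats::runif(1, 0, bp$Lx)
      coords <- fr$coords
      coords[, 1] <- wrap_into(coords[, 1] + dx, bp$Lx)
      fr <- labeled_frame(coords, fr$role, fr$box, fr$time, fr$name)
    }
    fr
  })
}

#' Cylindrically bent (or flat) bilayer sheet
#'
#' Builds an open-edged sheet bent into a cylindrical arc of known radius for
#' circle-fit testing: the innermost (concave-side) leaflet beads lie on an
#' arc of exactly `radius`, the outer leaflet `2 * leaflet_offset` further
#' out, with the cylinder axis along y and the cap centred in x. With
#' `radius = Inf` a flat sheet is produced.
#'
#' @param radius Radius of the innermost-leaflet arc, nm (`Inf` for flat).
#' @param arc_span Angular span of the arc, degrees.
#' @param Ly Sheet depth along y, nm.
#' @param spacing Bead spacing, nm.
#' @param noise_sigma Isotropic Gaussian noise, nm.
#' @param seed Integer seed.
#' @param leaflet_offset Half bilayer thickness, nm.
#' @param time Time stamp, ps.
#' @return A [labeled_frame()]; the true radius is stored in
#'   `attr(, "true_radius")`.
#' @export
make_bent_sheet <- function(radius, arc_span = 30, Ly = 15, spacing = 0.8,
                            noise_sigma = 0, seed = 1L, leaflet_offset = 2.0,
                            time = 0) {
  if (!(radius > 0)) rlang::abort("`radius` must be > 0 (use Inf for flat).")
  set.seed(seed)
  y <- seq(0, Ly - spacing / 2, by = spacing)
  if (is.finite(radius)) {
    half <- arc_span / 2 * pi / 180
    radii <- c(inner = radius, outer = radius + 2 * leaflet_offset)
    arcs <- lapply(radii, function(r) {
      phi <- seq(pi / 2 - half, pi / 2 + half, by = spacing / r)
      cbind(x = r * cos(phi), z = r * sin(phi))
    })
    xz <- do.call(rbind, arcs)
    xz[, "z"] <- xz[, "z"] - radius * cos(half)   # lowest inner bead near z=0
    width <- 2 * (radius + 2 * leaflet_offset) * sin(half)
  } else {
    half_w <- 40
    xs <- seq(-half_w, half_w, by = spacing)
    xz <- rbind(cbind(x = xs, z = 0), cbind(x = xs, z = 2 * leaflet_offset))
    width <- 2 * half_w
  }
  coords <- cbind(rep(xz[, "x"], times = length(y)),
                  rep(y, each = nrow(xz)),
                  rep(xz[, "z"], times = length(y)))
  if (noise_sigma > 0) {
    coords <- coords + matrix(stats::rnorm(length(coords), 0, noise_sigma),
                              ncol = 3)
  }
  box_x <- width * 1.2 + 2
  coords[, 1] <- coords[, 1] + box_x / 2
  zr <- range(coords[, 3])
  coords[, 3] <- coords[, 3] - zr[1] + 1
  fr <- labeled_frame(coords, rep("membrane_head", nrow(coords)),
                      box = c(box_x, Ly, diff(zr) + 2 + 2), time = time)
  attr(fr, "true_radius") <- radius
  fr
}

#' Banana-protein conformer ensemble
#'
#' Generates protein-only frames in which the backbone is a circular arc
#' whose radius varies log-normally around `base_radius` from frame to frame,
#' with optional per-bead Gaussian jitter: a stand-in for the conformational
#' flexing (straightening) of a banana-shaped dimer, used to exercise RMSD,
#' RMSF and protein-curvature metrics against known truth.
#'
#' @param n_frames Number of frames.
#' @param base_radius Median arc radius, nm.
#' @param radius_sigma Log-scale standard deviation of the per-frame radius
#'   (0 = fixed radius).
#' @param jitter_sigma Per-bead isotropic Gaussian jitter, nm.
#' @param seed Integer seed.
#' @param n_beads Backbone beads per frame.
#' @param chord Arc chord length, nm.
#' @return A list with `frames` (list of [labeled_frame()]) and `truth`
#'   (tibble: `frame`, `radius`).
#' @export
make_conformer_ensemble <- function(n_frames, base_radius, radius_sigma = 0,
                                    jitter_sigma = 0, seed = 1L,
                                    n_beads = 21L, chord = 15) {
  set.seed(seed)
  radii <- base_radius * exp(stats::rnorm(n_frames, 0, radius_sigma))
  frames <- lapply(seq_len(n_frames), function(i) {
    loc <- protein_arc_local(radii[i], chord, n_beads)
    pts <- cbind(loc[, "u"], 0, loc[, "w"])
    if (jitter_sigma > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), 0, jitter_sigma), ncol = 3)
    }
    pts <- sweep(pts, 2, c(50, 50, 50), "+")
    labeled_frame(pts, rep("protein_backbone", n_beads),
                  box = c(100, 100, 100), time = i)
  })
  list(frames = frames, truth = tibble::tibble(frame = seq_len(n_frames),
                                               radius = radii))
}
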