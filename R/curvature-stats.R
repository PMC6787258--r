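# From (s_norm, theta) ensembles to occupancy maps, the analytic curvature
# map, the Boltzmann-inversion free-energy profile along the radius of
# curvature, and the curvature-dependent binding free energy.

#' Default radius-of-curvature bin edges
#'
#' Log-spaced bin edges between 10 and 200 nm plus an overflow bin collecting
#' everything flatter (including the infinite-radius sentinel produced at
#' orientations near 90 degrees).
#'
#' @param n Number of finite bins (default 24).
#' @param lo,hi Finite range, nm.
#' @return Numeric vector of `n + 2` edges, the last being `Inf`.
#' @export
default_R_edges <- function(n = 24, lo = 10, hi = 200) {
  c(exp(seq(log(lo), log(hi), length.out = n + 1)), Inf)
}

#' Occupancy and analytic curvature map over position and orientation
#'
#' Bins protein placements into a 2D histogram over the normalized arc
#' position `s_norm` in `[0, 1)` and the orientation `theta` in `[0, 90]`
#' degrees, and evaluates the analytic radius of curvature `R(s, theta)`
#' ([oriented_curvature()]) at the bin centres: the two companion panels of a
#' curvature-sensing analysis (where does the protein sit, and what curvature
#' does each location offer).
#'
#' @param placements Tibble with columns `s_norm` and `theta`, e.g. from
#'   [map_trajectory()] or [sample_boltzmann_trajectory()].
#' @param profile The [buckle_profile()].
#' @param s_bins,theta_bins Bin counts (defaults 50 x 45).
#' @return A `curvature_landscape` object: list with `s_edges`, `theta_edges`,
#'   `occupancy` (s_bins x theta_bins counts), `C_map` and `R_map` (analytic
#'   curvature and radius at bin centres), `n` (placements binned) and
#'   `profile`.
#' @export
occupancy_map <- function(placements, profile, s_bins = 50L, theta_bins = 45L) {
  if (!all(c("s_norm", "theta") %in% names(placements))) {
    rlang::abort("`placements` needs columns `s_norm` and `theta`.")
  }
  n <- nrow(placements)
  if (n < 1L) rlang::abort("Need at least one placement.")
  if (any(placements$s_norm < 0 | placements$s_norm >= 1)) {
    rlang::abort("`s_norm` must lie in [0, 1).")
  }
  if (any(placements$theta < 0 | placements$theta > 90)) {
    rlang::abort("`theta` must lie in [0, 90].")
  }
  s_edges <- seq(0, 1, length.out = s_bins + 1L)
  t_edges <- seq(0, 90, length.out = theta_bins + 1L)
  si <- pmin(findInterval(placements$s_norm, s_edges), s_bins)
  ti <- pmin(findInterval(placements$theta, t_edges,
                          rightmost.closed = TRUE), theta_bins)
  occ <- matrix(tabulate((ti - 1L) * s_bins + si, s_bins * theta_bins),
                nrow = s_bins)
  s_mid <- (s_edges[-1] + s_edges[-length(s_edges)]) / 2
  t_mid <- (t_edges[-1] + t_edges[-length(t_edges)]) / 2
  oc <- oriented_curvature(profile,
                           rep(s_mid * profile$L, times = theta_bins),
                           rep(t_mid, each = s_bins))
  structure(
    list(s_edges = s_edges, theta_edges = t_edges, occupancy = occ,
         C_map = matrix(oc$C, nrow = s_bins),
         R_map = matrix(oc$R, nrow = s_bins),
         n = n, profile = profile),
    class = "curvature_landscape"
  )
}

#' @export
print.curvature_landscape <- function(x, ...) {
  mode_idx <- arrayInd(which.max(x$occupancy), dim(x$occupancy))
  s_mid <- (x$s_edges[-1] + x$s_edges[-length(x$s_edges)]) / 2
  t_mid <- (x$theta_edges[-1] + x$theta_edges[-length(x$theta_edges)]) / 2
  cat(sprintf(
    "<curvature_landscape> %d placements in %d x %d (s_norm x theta) bins\n",
    x$n, nrow(x$occupancy), ncol(x$occupancy)))
  cat(sprintf("  mode bin: s_norm = %.3f, theta = %.1f deg (R = %.3g nm)\n",
              s_mid[mode_idx[1]], t_mid[mode_idx[2]],
              x$R_map[mode_idx[1], mode_idx[2]]))
  invisible(x)
}

#' @export
tidy.curvature_landscape <- function(x, ...) {
  s_mid <- (x$s_edges[-1] + x$s_edges[-length(x$s_edges)]) / 2
  t_mid <- (x$theta_edges[-1] + x$theta_edges[-length(x$theta_edges)]) / 2
  tibble::tibble(
    s_norm = rep(s_mid, times = length(t_mid)),
    theta = rep(t_mid, each = length(s_mid)),
    count = as.vector(x$occupancy),
    C = as.vector(x$C_map),
    R = as.vector(x$R_map)
  )
}

# geometric density of states: histogram of R(s, theta) over a fine uniform
# grid on [0, L) x [0, 90]; cached on the profile per (edges, grid) signature
geometric_R_density <- function(profile, R_edges, n_s = 2000L, n_theta = 900L) {
  key <- paste0("dos_", paste(signif(R_edges, 10), collapse = "_"),
                "_", n_s, "x", n_theta)
  if (!is.null(profile$cache[[key]])) return(profile$cache[[key]])
  s <- (seq_len(n_s) - 0.5) / n_s * profile$L
  th <- (seq_len(n_theta) - 0.5) / n_theta * 90
  Cs <- local_curvature(profile, s)
  C <- outer(Cs, cospi(th / 180)^2)
  R <- ifelse(C < C_FLOOR, Inf, 1 / C)
  counts <- bin_R(as.vector(R), R_edges)
  dens <- counts / sum(counts)
  profile$cache[[key]] <- dens
  dens
}

# histogram over R edges; Inf lands in the overflow bin; values outside the
# covered range are dropped (returned attribute reports how many)
bin_R <- function(R, R_edges) {
  nb <- length(R_edges) - 1L
  idx <- findInterval(R, R_edges, rightmost.closed = TRUE)
  keep <- idx >= 1L & idx <= nb
  counts <- tabulate(idx[keep], nb)
  attr(counts, "n_dropped") <- sum(!keep)
  counts
}

#' Free-energy profile along the radius of curvature
#'
#' Boltzmann inversion of the placement histogram over the local radius of
#' curvature `R(s, theta)`:
#' \deqn{F(R) = -\ln\frac{P_{obs}(R)}{P_{geom}(R)} \quad [k_BT]}
#' where \eqn{P_{geom}} is the geometric density of states — the distribution
#' of `R(s, theta)` under the uniform measure on `[0, L) x [0, 90]`,
#' evaluated on a fine 2000 x 900 grid. Dividing by \eqn{P_{geom}} removes
#' the surface area available at each curvature, so that a non-interacting
#' (uniform) ensemble gives a flat profile; `correct_dos = FALSE` gives the
#' raw inversion instead. The profile is shifted so that the flattest
#' (largest-R) populated bin — the stand-in for a flat membrane — is zero.
#' Unpopulated bins are reported as `NA`, never 0.
#'
#' @param placements Tibble with columns `s_norm` and `theta`, or a
#'   precomputed `R` column (used directly if present).
#' @param profile The [buckle_profile()].
#' @param R_edges Radius bin edges, nm (default [default_R_edges()]; the last
#'   edge may be `Inf` for an overflow bin).
#' @param correct_dos Apply the density-of-states correction (default TRUE).
#' @return A tibble of class `fe_profile` with columns `R_lo`, `R_hi`,
#'   `R_mid` (geometric mean of finite edges), `count`, `p_obs`, `p_geom`,
#'   `F` (kBT, `NA` where unpopulated). Attributes: `reference_bin`, `n`,
#'   `n_dropped`.
#' @export
free_energy_profile <- function(placements, profile,
                                R_edges = default_R_edges(),
                                correct_dos = TRUE) {
  if (is.unsorted(R_edges, strictly = TRUE)) {
    rlang::abort("`R_edges` must be strictly increasing.")
  }
  if ("R" %in% names(placements)) {
    R <- placements$R
  } else {
    oc <- oriented_curvature(profile, placements$s_norm * profile$L,
                             placements$theta)
    R <- oc$R
  }
  n <- length(R)
  if (n < 100L) {
    rlang::warn(sprintf(
      "Only %d placements; free-energy estimates will be noisy (>= 100 recommended).",
      n))
  }
  counts <- bin_R(R, R_edges)
  if (sum(counts) == 0L) {
    rlang::abort(paste0(
      "No placements fall inside the radius bins; the sampled curvatures lie ",
      "outside [", signif(R_edges[1], 4), ", ",
      signif(R_edges[length(R_edges)], 4), "] nm."))
  }
  p_obs <- counts / sum(counts)
  p_geom <- geometric_R_density(profile, R_edges)
  Fv <- ifelse(counts > 0,
               -log(ifelse(p_obs > 0, p_obs, NA) /
                      if (correct_dos) p_geom else 1),
               NA_real_)
  ref <- max(which(counts > 0))
  Fv <- Fv - Fv[ref]
  nb <- length(R_edges) - 1L
  R_lo <- R_edges[-length(R_edges)]
  R_hi <- R_edges[-1]
  R_mid <- ifelse(is.finite(R_hi), sqrt(R_lo * R_hi), Inf)
  out <- tibble::tibble(R_lo = R_lo, R_hi = R_hi, R_mid = R_mid,
                        count = as.integer(counts), p_obs = p_obs,
                        p_geom = p_geom, F = Fv)
  class(out) <- c("fe_profile", class(out))
  attr(out, "reference_bin") <- ref
  attr(out, "n") <- n
  attr(out, "n_dropped") <- attr(counts, "n_dropped")
  attr(out, "correct_dos") <- correct_dos
  out
}

#' @export
glance.fe_profile <- function(x, ...) {
  pop <- !is.na(x$F)
  imin <- which.min(x$F)
  tibble::tibble(
    n = attr(x, "n"),
    n_bins = nrow(x),
    n_populated = sum(pop),
    F_min = x$F[imin],
    R_at_min = x$R_mid[imin],
    reference_R_lo = x$R_lo[attr(x, "reference_bin")]
  )
}

#' Curvature-dependent binding free energy at a chosen radius
#'
#' Reads the free-energy profile at `R = R_bind` by linear interpolation (in
#' log R) between the centres of the populated bins, giving the binding free
#' energy at that curvature relative to the flat-membrane reference of the
#' profile. Negative values mean binding at that curvature is favourable.
#'
#' @param fe An `fe_profile` from [free_energy_profile()].
#' @param R_bind Radius of curvature, nm.
#' @return `delta_G` in kBT.
#' @export
binding_free_energy <- function(fe, R_bind) {
  if (!inherits(fe, "fe_profile")) rlang::abort("`fe` must be an fe_profile.")
  if (!is.finite(R_bind) || R_bind <= 0) {
    rlang::abort("`R_bind` must be a positive finite radius in nm.")
  }
  bin <- findInterval(R_bind, c(fe$R_lo, fe$R_hi[nrow(fe)]),
                      rightmost.closed = TRUE)
  pop <- which(!is.na(fe$F))
  if (bin < 1L || bin > nrow(fe) || is.na(fe$F[bin])) {
    rng <- range(c(fe$R_lo[pop], fe$R_hi[pop][is.finite(fe$R_hi[pop])]))
    rlang::abort(sprintf(
      "R_bind = %.3g nm falls in an unpopulated bin; populated coverage is %.3g-%.3g nm.",
      R_bind, rng[1], rng[2]))
  }
  fin <- pop[is.finite(fe$R_mid[pop])]
  if (length(fin) < 2L) return(fe$F[bin])
  stats::approx(log(fe$R_mid[fin]), fe$F[fin], xout = log(R_bind),
                rule = 2)$y
}
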