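# Mapping of simulation snapshots onto the analytic buckle: x-alignment of
# the membrane peak, arc-length position of the protein centre of mass, and
# in-plane orientation of the protein's first principal axis.

wrap_into <- function(x, period) x - period * floor(x / period)

# mean z per x-bin over membrane head beads, 3-bin circular moving average
binned_membrane_z <- function(xw, z, Lx, n_bins) {
  bin <- pmin(floor(xw / (Lx / n_bins)), n_bins - 1L) + 1L
  zsum <- rep(NA_real_, n_bins)
  cnt <- tabulate(bin, n_bins)
  zs <- rowsum(z, bin)
  zsum[as.integer(rownames(zs))] <- zs[, 1]
  zmean <- zsum / ifelse(cnt > 0, cnt, NA)
  occupied <- which(cnt > 0)
  sm <- (zmean[c(n_bins, 1:(n_bins - 1))] + zmean +
           zmean[c(2:n_bins, 1)]) / 3
  list(zmean = zmean, smooth = sm, occupied = occupied, count = cnt)
}

# analytic template: bin-mean midsurface height of the centred profile
# (peak at L_x/2), cached on the profile object per bin count
profile_z_template <- function(profile, n_bins) {
  key <- paste0("z_template_", n_bins)
  if (!is.null(profile$cache[[key]])) return(profile$cache[[key]])
  s <- seq(0, profile$L, length.out = 8192L)
  p <- profile_xz(profile, s)
  b <- binned_membrane_z(wrap_into(p$x, profile$Lx), p$z, profile$Lx, n_bins)
  profile$cache[[key]] <- b$zmean
  b$zmean
}

#' Align a snapshot to the analytic buckle profile
#'
#' Translates a frame along x (with periodic wrapping) so that the membrane's
#' peak coincides with the analytic buckle peak at `s = L/2`
#' (i.e. `x = L_x/2`), and subtracts a z offset so that the lowest membrane
#' bin sits at `z = 0`. The mean head-bead height per x-bin (bin width
#' `L_x/n_bins`, 3-bin circular moving average) is matched against the
#' analytic profile by circular cross-correlation over whole-bin shifts, with
#' parabolic sub-bin refinement of the correlation peak. Correlating the whole
#' binned profile, rather than taking the mode of the bin means directly, is
#' robust to the local dip in mean height that the two leaflets' unequal
#' projected bead densities produce right at the buckle crest.
#'
#' @param frame A [labeled_frame()] containing membrane head beads.
#' @param profile The [buckle_profile()] the snapshot should follow.
#' @param n_bins Number of x-bins for peak detection (default 50).
#' @return A list with `frame` (the aligned [labeled_frame()], x wrapped into
#'   `[0, L_x)`) and `shift` (the applied x-offset in nm, in `(-L_x/2, L_x/2]`).
#' @export
align_to_profile <- function(frame, profile, n_bins = 50L) {
  stopifnot(inherits(frame, "labeled_frame"), inherits(profile, "buckle_profile"))
  Lx <- profile$Lx
  if (abs(frame$box[1] - Lx) > 0.05 * Lx) {
    rlang::abort(sprintf(
      "Frame box x-length (%.4g nm) differs from profile L_x (%.4g nm) by more than 5%%.",
      frame$box[1], Lx))
  }
  mem <- frame$role == "membrane_head"
  if (sum(mem) < 3L) rlang::abort("Need at least 3 membrane_head beads.")
  xw <- wrap_into(frame$coords[mem, 1], Lx)
  z <- frame$coords[mem, 3]
  b <- binned_membrane_z(xw, z, Lx, n_bins)
  if (length(b$occupied) < 10L) {
    rlang::abort("Fewer than 10 occupied x-bins; cannot locate membrane peak.")
  }
  n <- as.integer(n_bins)
  obs <- b$smooth
  obs[!is.finite(obs)] <- mean(obs, na.rm = TRUE)
  obs <- obs - mean(obs)
  tpl <- profile_z_template(profile, n)
  tpl <- tpl - mean(tpl)
  # score(k): template shifted left by k bins vs observed profile
  score <- vapply(0:(n - 1L), function(k) {
    sum(obs * tpl[((seq_len(n) - 1L + k) %% n) + 1L])
  }, numeric(1))
  k_best <- which.max(score) - 1L
  # flag ambiguous secondary correlation maxima away from the main peak
  prv <- score[c(n, 1:(n - 1))]
  nxt <- score[c(2:n, 1)]
  locmax <- setdiff(which(score >= prv & score >= nxt), k_best + 1L)
  locmax <- locmax[pmin(abs(locmax - 1L - k_best),
                        n - abs(locmax - 1L - k_best)) > 2L]
  if (length(locmax) &&
      max(score[locmax]) > score[k_best + 1L] - 1e-3 * abs(score[k_best + 1L])) {
    rlang::warn("Ambiguous membrane peak: near-equal profile matches; using the stronger one.")
  }
  ym <- score[((k_best - 1L) %% n) + 1L]
  y0 <- score[k_best + 1L]
  yp <- score[((k_best + 1L) %% n) + 1L]
  denom <- ym - 2 * y0 + yp
  delta <- if (abs(denom) > 1e-12) {
    pmin(pmax(0.5 * (ym - yp) / denom, -0.5), 0.5)
  } else 0
  shift <- (k_best + delta) * Lx / n
  shift <- shift - Lx * round(shift / Lx)
  z0 <- min(b$zmean, na.rm = TRUE)
  coords <- frame$coords
  coords[, 1] <- wrap_into(coords[, 1] + shift, Lx)
  coords[, 3] <- coords[, 3] - z0
  list(frame = labeled_frame(coords, frame$role, frame$box, frame$time, frame$name),
       shift = shift)
}

# unwrap the protein chain through periodic boundaries (x and y):
# consecutive backbone beads are close, so each bead is unwrapped by the
# minimum image relative to its predecessor (robust even when the whole
# chain spans more than half the box)
unwrap_protein <- function(frame) {
  pro <- frame$role == "protein_backbone"
  if (sum(pro) < 3L) rlang::abort("Need at least 3 protein_backbone beads.")
  p <- frame$coords[pro, , drop = FALSE]
  for (k in 1:2) {
    step <- diff(p[, k])
    step <- step - frame$box[k] * round(step / frame$box[k])
    p[, k] <- p[1, k] + c(0, cumsum(step))
  }
  p
}

# unweighted mean of backbone-bead positions (CG backbone beads are
# near-uniform in mass, and no topology masses are required)
protein_com <- function(frame) colMeans(unwrap_protein(frame))

#' Arc-length position of the protein on the buckle
#'
#' Computes the protein-backbone centre of mass (unweighted mean with
#' minimum-image unwrapping around the first bead) and inverts the monotone
#' map `x(s)` to find the arc position whose horizontal coordinate matches the
#' centre of mass, returning the normalized arc length `s/L` in `[0, 1)`.
#'
#' @param frame An aligned [labeled_frame()] (see [align_to_profile()]).
#' @param profile The [buckle_profile()].
#' @return `s_norm`, dimensionless in `[0, 1)`.
#' @export
protein_arclength <- function(frame, profile) {
  com <- protein_com(frame)
  x_com <- wrap_into(com[1], profile$Lx)
  # x(s) is strictly increasing for m < 1/2; linear interpolation on the
  # precomputed 4097-point table is accurate to << 1e-6 * L
  s <- stats::approx(profile$x_grid, profile$s_grid, xout = x_com,
                     rule = 2, ties = "ordered")$y
  unname(s / profile$L) %% 1
}

#' In-plane orientation angle of the protein
#'
#' The first principal axis is the eigenvector with the largest eigenvalue of
#' the 3 x 3 positional covariance of the protein backbone beads. Its
#' projection onto the x-y plane is compared with the buckling direction (x),
#' and the angle is folded into `[0, 90]` degrees: a principal axis has no
#' sign, and the buckle's curvature response depends only on
#' \eqn{\cos^2\theta}, so directions related by axis flip or y-reflection are
#' equivalent.
#'
#' @param frame A [labeled_frame()] with at least 3 non-collinear
#'   protein-backbone beads.
#' @return `theta` in degrees, in `[0, 90]`.
#' @export
protein_orientation <- function(frame) {
  p <- unwrap_protein(frame)
  ev <- eigen(stats::cov(p), symmetric = TRUE)
  if ((ev$values[1] - ev$values[2]) <= 1e-9 * max(ev$values[1], 1e-300)) {
    rlang::abort("Degenerate covariance: first principal axis is not unique.")
  }
  v <- ev$vectors[, 1]
  if (abs(v[1]) < 1e-15 && abs(v[2]) < 1e-15) {
    rlang::abort("First principal axis is vertical; in-plane orientation undefined.")
  }
  atan2(abs(v[2]), abs(v[1])) * 180 / pi
}

map_one_frame <- function(frame, profile, n_bins) {
  al <- align_to_profile(frame, profile, n_bins)
  s_norm <- protein_arclength(al$frame, profile)
  theta <- protein_orientation(al$frame)
  C <- local_curvature(profile, s_norm * profile$L) * cospi(theta / 180)^2
  c(time = frame$time, s_norm = s_norm, theta = theta,
    C = C, R = if (C < C_FLOOR) Inf else 1 / C, shift = al$shift)
}

#' Map a trajectory of snapshots onto the buckle
#'
#' Runs [align_to_profile()], [protein_arclength()] and
#' [protein_orientation()] on every frame and attaches the local curvature
#' and radius of curvature felt by the protein ([oriented_curvature()]).
#' Frames whose mapping fails are skipped with a warning; if more than 20% of
#' frames fail the whole mapping errors out.
#'
#' @param frames A list of [labeled_frame()] objects (or a single frame).
#' @param profile The [buckle_profile()].
#' @param n_bins x-bins used for peak alignment (default 50).
#' @return A tibble with one row per mapped frame: `frame`, `time`, `s_norm`,
#'   `theta` (degrees), `C` (1/nm), `R` (nm), `shift` (nm).
#' @export
map_trajectory <- function(frames, profile, n_bins = 50L) {
  if (inherits(frames, "labeled_frame")) frames <- list(frames)
  if (!length(frames)) rlang::abort("`frames` must contain at least one frame.")
  res <- matrix(NA_real_, nrow = length(frames), ncol = 6)
  failed <- character(0)
  for (i in seq_along(frames)) {
    out <- tryCatch(map_one_frame(frames[[i]], profile, n_bins),
                    error = function(e) conditionMessage(e))
    if (is.character(out)) {
      failed <- c(failed, sprintf("frame %d: %s", i, out))
    } else {
      res[i, ] <- out
    }
  }
  if (length(failed)) {
    rlang::warn(c("Some frames could not be mapped and were skipped:",
                  utils::head(failed, 5)))
    if (length(failed) > 0.2 * length(frames)) {
      rlang::abort(sprintf("%d of %d frames failed to map (> 20%%).",
                           length(failed), length(frames)))
    }
  }
  ok <- !is.na(res[, 2])
  tibble::tibble(frame = which(ok), time = res[ok, 1], s_norm = res[ok, 2],
                 theta = res[ok, 3], C = res[ok, 4], R = res[ok, 5],
                 shift = res[ok, 6])
}
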