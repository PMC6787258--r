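# Shared fixtures built in code: a default buckle profile and small
# generator configurations used across the unit tests.

default_profile <- function() buckle_profile(L = 37.8, gamma = 0.1)

quiet_cfg <- function(...) {
  args <- list(...)
  do.call(generator_config, args)
}

# straight bead rod in the x-y plane at a given in-plane angle (degrees),
# placed well inside the box to avoid wrapping
straight_rod_frame <- function(angle_deg, n = 11, length = 8, box = c(50, 50, 50)) {
  t <- seq(-length / 2, length / 2, length.out = n)
  a <- angle_deg * pi / 180
  coords <- cbind(25 + t * cos(a), 25 + t * sin(a), 10 + 0.01 * t^2)
  labeled_frame(coords, rep("protein_backbone", n), box)
}

# independent brute-force oracle for the width-ratio inversion: bisection on
# 2E[m]/K[m] - 1 using pracma directly (no curvsense internals)
bisect_m_for_ratio <- function(target, tol = 1e-12) {
  f <- function(m) {
    ke <- pracma::ellipke(m)
    2 * ke$e / ke$k - 1 - target
  }
  lo <- 1e-12; hi <- 1 - 1e-12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

wrap_into_test <- function(x, period) x - period * floor(x / period)

# 3x3 boxcar smoothing of an occupancy matrix (s periodic, theta clamped),
# used to take stable modes of sampled histograms
smooth_occupancy <- function(M) {
  Mp <- rbind(M[nrow(M), ], M, M[1, ])
  Mp <- cbind(Mp[, 1], Mp, Mp[, ncol(Mp)])
  out <- matrix(0, nrow(M), ncol(M))
  for (di in 0:2) for (dj in 0:2) {
    out <- out + Mp[seq_len(nrow(M)) + di, seq_len(ncol(M)) + dj]
  }
  out / 9
}
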