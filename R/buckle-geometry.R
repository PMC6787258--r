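# Euler-elastica geometry of a laterally buckled bilayer.
#
# Convention note: throughout this file `m` is the elliptic PARAMETER (the
# square of the elliptic modulus), the same convention used by
# pracma::ellipke() / pracma::ellipj() and scipy.special.

#' Elliptic parameter from the compression ratio (series expansion)
#'
#' Four-term series giving the elliptic parameter `m` (modulus squared) of the
#' buckled-membrane elastica from the lateral compression ratio
#' \eqn{\gamma = (L - L_x)/L}:
#' \deqn{m = \gamma - \gamma^2/8 - \gamma^3/32 - 11\gamma^4/1024}
#' The series is truncated exactly at these four terms; it is accurate to a few
#' parts in 1e7 at \eqn{\gamma = 0.1} and is only intended for the weakly
#' compressed regime. [elliptic_parameter_exact()] inverts the defining
#' complete-elliptic-integral relation without truncation error and is what
#' [buckle_profile()] uses by default.
#'
#' @param gamma Compression ratio, dimensionless, in (0, 0.2] (the range where
#'   the truncated series is trustworthy).
#' @return The elliptic parameter `m`, dimensionless.
#' @seealso [elliptic_parameter_exact()], [buckle_profile()]
#' @export
#' @examples
#' elliptic_parameter_series(0.1)
elliptic_parameter_series <- function(gamma) {
  if (!is.numeric(gamma) || any(!is.finite(gamma))) {
    rlang::abort("`gamma` must be finite numeric.")
  }
  if (any(gamma <= 0 | gamma > 0.2)) {
    rlang::abort(paste0(
      "`gamma` must lie in (0, 0.2]: the four-term series for the elliptic ",
      "parameter is only valid for weak compression. Use ",
      "elliptic_parameter_exact() outside this range."
    ))
  }
  gamma - gamma^2 / 8 - gamma^3 / 32 - 11 * gamma^4 / 1024
}

#' Projected-to-arc length ratio implied by an elliptic parameter
#'
#' Evaluates \eqn{L_x/L = 2E[m]/K[m] - 1}, the relation between the projected
#' box length and the total arc length of one buckle period, where `K` and `E`
#' are the complete elliptic integrals of the first and second kind in the
#' parameter convention.
#'
#' @param m Elliptic parameter in (0, 1).
#' @return \eqn{L_x/L}, dimensionless.
#' @export
elliptic_width_ratio <- function(m) {
  if (any(m <= 0 | m >= 1)) rlang::abort("`m` must lie in (0, 1).")
  vapply(m, function(mi) {
    ke <- pracma::ellipke(mi)
    2 * ke$e / ke$k - 1
  }, numeric(1))
}

#' Elliptic parameter from the projected-to-arc length ratio (exact inversion)
#'
#' Solves \eqn{L_x/L = 2E[m]/K[m] - 1} for the elliptic parameter `m` by
#' bracketed root finding on \eqn{m \in (10^{-12}, 1 - 10^{-12})}. The residual
#' of the returned root is below 1e-10. This is the default route used by
#' [buckle_profile()]; the truncated series of [elliptic_parameter_series()]
#' is retained as a cross-check.
#'
#' @param lx_over_l Ratio \eqn{L_x/L} in (0, 1).
#' @return The elliptic parameter `m`.
#' @export
#' @examples
#' m <- elliptic_parameter_exact(0.9)
#' elliptic_width_ratio(m)  # 0.9 to ~1e-12
elliptic_parameter_exact <- function(lx_over_l) {
  if (!is.numeric(lx_over_l) || length(lx_over_l) != 1L ||
      !is.finite(lx_over_l) || lx_over_l <= 0 || lx_over_l >= 1) {
    rlang::abort("`lx_over_l` must be a single number in (0, 1).")
  }
  f <- function(m) elliptic_width_ratio(m) - lx_over_l
  lo <- 1e-12
  hi <- 1 - 1e-12
  # 2E/K - 1 decreases monotonically from 1 (m -> 0) to -1 (m -> 1)
  if (f(lo) < 0 || f(hi) > 0) {
    rlang::abort("No sign change in bracket; cannot invert width ratio.")
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  if (abs(f(root)) > 1e-10) {
    rlang::abort("Root finding did not reach the 1e-10 residual tolerance.")
  }
  root
}

# Jacobi epsilon function eps(u | m) = E(am(u|m) | m) = \int_0^u dn^2(w|m) dw.
# Reduced to [0, K] by the quarter-period symmetries
#   eps(u + 2K) = eps(u) + 2E,   eps(2K - u) = 2E - eps(u),
# then integrated with fixed-node Gauss-Legendre quadrature; dn^2 is analytic
# so 48 nodes reach ~1e-14 absolute accuracy.
.gl_cache <- new.env(parent = emptyenv())

gl_nodes_01 <- function(n = 48L) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  }
  .gl_cache[[key]]
}

jacobi_epsilon <- function(u, m) {
  ke <- pracma::ellipke(m)
  K <- ke$k
  E <- ke$e
  n2 <- floor(u / (2 * K) + 1e-15)
  r <- u - 2 * K * n2
  flip <- r > K
  r0 <- ifelse(flip, 2 * K - r, r)

  gl <- gl_nodes_01(48L)
  # nodes scaled per evaluation point: w = r0 * t, t in (0,1)
  tt <- gl$x
  ww <- gl$w
  W <- outer(r0, tt)                       # n x 48 evaluation points
  dn <- pracma::ellipj(as.vector(W), m)$dn
  dn2 <- matrix(dn^2, nrow = length(r0))
  eps0 <- r0 * as.vector(dn2 %*% ww)
  eps0 <- ifelse(flip, 2 * E - eps0, eps0)
  2 * E * n2 + eps0
}

#' Buckled-membrane profile
#'
#' Constructs the analytic Euler-elastica profile of one period of a laterally
#' buckled bilayer midsurface. The shape, parametrized by arc length `s`, is
#' \deqn{x(s) = 2\lambda E[\mathrm{am}(s/\lambda, m), m] - s, \qquad
#'       z(s) = 2\lambda\sqrt{m}\,(1 - \mathrm{cn}(s/\lambda, m))}
#' with the elliptic parameter `m` fixed by the compression ratio
#' \eqn{\gamma = (L - L_x)/L} through \eqn{L_x/L = 2E[m]/K[m] - 1}, and the
#' characteristic length \eqn{\lambda = L/4K[m]}.
#'
#' Exactly one of `gamma` or `lx_over_l` must be given. By default `m` is
#' obtained by exact inversion of the width-ratio relation
#' ([elliptic_parameter_exact()]); `method = "series"` instead uses the
#' four-term expansion of [elliptic_parameter_series()].
#'
#' @param L Total arc length of one buckle period, nm. The buckle period is
#'   not a universal constant: it is set by the simulation box, so it must be
#'   supplied explicitly.
#' @param gamma Compression ratio \eqn{(L - L_x)/L}, dimensionless.
#' @param lx_over_l Alternative input: the ratio \eqn{L_x/L} directly.
#' @param method How to compute `m`: `"exact"` (default) or `"series"`.
#' @return An object of class `buckle_profile`: a list with fields `gamma`,
#'   `L`, `Lx`, `m`, `lam` (the characteristic length, nm), `K`, `E`, plus a
#'   precomputed monotone `x(s)` table used to invert arc positions.
#' @export
#' @examples
#' bp <- buckle_profile(L = 37.8, gamma = 0.1)
#' bp
#' profile_xz(bp, seq(0, bp$L, length.out = 5))
buckle_profile <- function(L, gamma = NULL, lx_over_l = NULL,
                           method = c("exact", "series")) {
  method <- match.arg(method)
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0) {
    rlang::abort("`L` (arc length of one buckle period, nm) must be > 0.")
  }
  if (is.null(gamma) == is.null(lx_over_l)) {
    rlang::abort("Supply exactly one of `gamma` or `lx_over_l`.")
  }
  if (is.null(gamma)) gamma <- 1 - lx_over_l
  if (gamma <= 0 || gamma >= 1) rlang::abort("`gamma` must lie in (0, 1).")
  m <- if (method == "series") {
    elliptic_parameter_series(gamma)
  } else {
    elliptic_parameter_exact(1 - gamma)
  }
  ke <- pracma::ellipke(m)
  lam <- L / (4 * ke$k)
  obj <- structure(
    list(
      gamma = gamma, L = L, Lx = (1 - gamma) * L,
      m = m, lam = lam, K = ke$k, E = ke$e, method = method,
      cache = new.env(parent = emptyenv())
    ),
    class = "buckle_profile"
  )
  # monotone inversion table for x(s); x'(s) = 1 - 2 m sn^2 > 0 for m < 1/2
  sg <- seq(0, L, length.out = 4097L)
  obj$s_grid <- sg
  obj$x_grid <- profile_xz(obj, sg)$x
  obj
}

#' @export
print.buckle_profile <- function(x, ...) {
  cat("<buckle_profile>\n")
  cat(sprintf("  gamma  = %.6g   (L_x/L = %.6g)\n", x$gamma, 1 - x$gamma))
  cat(sprintf("  L      = %.6g nm   L_x = %.6g nm\n", x$L, x$Lx))
  cat(sprintf("  m      = %.8g   (elliptic parameter, %s)\n", x$m, x$method))
  cat(sprintf("  lambda = %.6g nm   peak height = %.6g nm\n",
              x$lam, 4 * x$lam * sqrt(x$m)))
  cat(sprintf("  max curvature 2*sqrt(m)/lambda = %.6g 1/nm (R_min = %.4g nm)\n",
              2 * sqrt(x$m) / x$lam, x$lam / (2 * sqrt(x$m))))
  invisible(x)
}

check_s_domain <- function(profile, s) {
  if (any(s < -1e-9 * profile$L | s > profile$L * (1 + 1e-9))) {
    rlang::abort(paste0(
      "`s` must lie in [0, L]; wrap arc positions periodically before ",
      "calling the geometry functions."
    ))
  }
  pmin(pmax(s, 0), profile$L)
}

#' Evaluate the buckle profile x(s), z(s)
#'
#' @param profile A [buckle_profile()].
#' @param s Arc length positions, nm, in `[0, L]` (callers wrap periodically).
#' @return A tibble with columns `s`, `x`, `z` (nm).
#' @export
profile_xz <- function(profile, s) {
  s <- check_s_domain(profile, s)
  u <- s / profile$lam
  eps <- jacobi_epsilon(u, profile$m)
  cn <- pracma::ellipj(u, profile$m)$cn
  tibble::tibble(
    s = s,
    x = 2 * profile$lam * eps - s,
    z = 2 * profile$lam * sqrt(profile$m) * (1 - cn)
  )
}

#' Tangent angle of the buckle profile
#'
#' \eqn{\psi(s) = 2\arcsin\{\sqrt{m}\,\mathrm{sn}(s/\lambda, m)\}}: the signed
#' angle between the local membrane tangent and the buckling (x) direction.
#'
#' @inheritParams profile_xz
#' @return Tangent angle in radians (signed; negative past the half-period).
#' @export
tangent_angle <- function(profile, s) {
  s <- check_s_domain(profile, s)
  sn <- pracma::ellipj(s / profile$lam, profile$m)$sn
  2 * asin(sqrt(profile$m) * sn)
}

#' Local curvature of the buckle along the buckling direction
#'
#' \eqn{C(s) = d\psi/ds = \sqrt{2(\cos\psi - (1 - 2m))}/\lambda}. The radicand
#' equals \eqn{4 m\,\mathrm{cn}^2(s/\lambda)} analytically, so it is
#' non-negative; tiny negative values from round-off are clamped to zero.
#'
#' @inheritParams profile_xz
#' @return Curvature \eqn{C(s) \ge 0} in 1/nm. Maximal at the buckle peak
#'   `s = L/2`, where \eqn{C = 2\sqrt{m}/\lambda}; zero at the inflection
#'   points `s = L/4` and `s = 3L/4`.
#' @export
local_curvature <- function(profile, s) {
  s <- check_s_domain(profile, s)
  psi <- tangent_angle(profile, s)
  rad <- 2 * (cos(psi) - (1 - 2 * profile$m))
  if (any(rad < -1e-12)) {
    rlang::abort("Curvature radicand below round-off tolerance; invalid profile.")
  }
  sqrt(pmax(rad, 0)) / profile$lam
}

#' Curvature floor below which the radius of curvature is reported as infinite
#'
#' Curvatures below 1e-6 1/nm (radius above 1000 km on a nanometre-scale
#' membrane) are physically flat; reporting `R = Inf` avoids overflow at
#' protein orientations near 90 degrees.
#' @keywords internal
C_FLOOR <- 1e-6

#' Curvature felt by a tilted protein on the buckle
#'
#' The buckle has principal curvatures \eqn{c_1 = C(s)} (along x) and
#' \eqn{c_2 = 0} (along y), so a protein whose long axis makes an in-plane
#' angle \eqn{\theta} with the buckling direction experiences, by Euler's
#' curvature formula,
#' \deqn{C(s, \theta) = c_1\cos^2\theta + c_2\sin^2\theta = C(s)\cos^2\theta.}
#'
#' @inheritParams profile_xz
#' @param theta In-plane orientation angle(s) in degrees, in `[0, 90]`.
#' @return A tibble with columns `C` (1/nm) and `R` (nm); `R = Inf` whenever
#'   `C` falls below the `1e-6` 1/nm curvature floor (e.g. at `theta = 90`).
#' @export
oriented_curvature <- function(profile, s, theta) {
  if (any(theta < -1e-9 | theta > 90 + 1e-9)) {
    rlang::abort("`theta` must lie in [0, 90] degrees.")
  }
  n <- max(length(s), length(theta))
  s <- rep_len(s, n)
  theta <- rep_len(theta, n)
  C <- local_curvature(profile, s) * cospi(theta / 180)^2
  tibble::tibble(C = C, R = ifelse(C < C_FLOOR, Inf, 1 / C))
}
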