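# Angle conventions
# -----------------
# All user-facing angles are in degrees in the "arena frame": 0 deg points
# East (toward the low-value zone) and angles increase CLOCKWISE, so that
# North = 270, NE = 315, South = 90, NW = 225 and the high-value zone sits
# at 180 (due West). The conversion to the standard counterclockwise math
# convention is a sign flip: theta_math = -theta_arena (mod 360).

deg2rad <- function(d) d * pi / 180

rad2deg <- function(r) r * 180 / pi

wrap360 <- function(a) a %% 360

# signed angular difference a - b mapped into (-180, 180]
signed180 <- function(a) {
  d <- (a + 180) %% 360 - 180
  ifelse(d == -180, 180, d)
}

signed_diff <- function(a, b) signed180(a - b)

# unit vector (Cartesian, meters) pointing along an arena-frame angle
unit_from_arena <- function(a) {
  r <- deg2rad(a)
  cbind(cos(r), -sin(r))
}

arena_angle_from_xy <- function(x, y) wrap360(-rad2deg(atan2(y, x)))

#' Smallest absolute angular difference between two directions
#'
#' Returns the unsigned circular deviation between two angles, i.e. the
#' smallest rotation (in either sense) taking one onto the other. Used for
#' the deviation of departing and perimeter-crossing directions from the
#' high-value zone centre.
#'
#' @param a,b angles in degrees (any real values; vectors recycle).
#' @return deviation in degrees, in `[0, 180]`.
#' @examples
#' circular_deviation(350, 10)  # 20
#' circular_deviation(225, 180) # 45
#' @export
circular_deviation <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Draw angles from a von Mises distribution
#'
#' Samples angles (degrees) from a von Mises distribution with mean
#' direction `mu` and concentration `kappa`, using the Best-Fisher
#' rejection algorithm. `kappa = 0` gives the circular uniform
#' distribution; very large (or infinite) `kappa` collapses to the point
#' mass at `mu`.
#'
#' @param n number of draws.
#' @param mu mean direction in degrees.
#' @param kappa concentration parameter, `>= 0`.
#' @return numeric vector of angles in `[0, 360)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa) || kappa > 1e6) return(rep(wrap360(mu), n))
  if (kappa < 1e-8) return(runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
    out <- c(out, theta)
  }
  wrap360(mu + rad2deg(out[seq_len(n)]))
}
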