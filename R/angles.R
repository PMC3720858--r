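#' Wrap an angle into (-180, 180]
#'
#' All angular arithmetic in the package goes through this convention:
#' degrees everywhere, half-open wrap with +180 included (so the trans
#' peptide omega is representable as exactly 180).
#'
#' @param angle Numeric vector of angles in degrees. `NA` values pass
#'   through unchanged (they mark undefined terminal dihedrals).
#' @return Angles congruent to the input mod 360, each in (-180, 180].
#' @examples
#' wrap_angle(190)   # -170
#' wrap_angle(-180)  # 180
#' wrap_angle(360)   # 0
#' @export
wrap_angle <- function(angle) {
  if (!is.numeric(angle)) stop("'angle' must be numeric")
  ok <- is.na(angle) | is.finite(angle)
  if (!all(ok)) stop("non-finite angle")
  w <- angle - 360 * floor(angle / 360)   # [0, 360)
  w[!is.na(w) & w > 180] <- w[!is.na(w) & w > 180] - 360
  w[!is.na(w) & w == -180] <- 180
  w
}

#' Signed shortest angular difference a - b in degrees, wrapped
#' @noRd
angle_diff <- function(a, b) wrap_angle(a - b)

#' Circular mean of angles in degrees (NA removed); NA if all NA
#' @noRd
circular_mean <- function(theta) {
  theta <- theta[!is.na(theta)]
  if (length(theta) == 0L) return(NA_real_)
  r <- theta * pi / 180
  wrap_angle(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize near-zero vector")
  v / n
}

#' Torsion angle (degrees, IUPAC sign) defined by four points
#' @noRd
torsion4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    stop("collinear atoms: torsion undefined")
  }
  m1 <- cross3(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(rad2deg(atan2(-y, x)))
}

#' Rodrigues rotation of row-matrix `pts` about unit axis through `origin`
#' @noRd
rotate_points <- function(pts, origin, axis, theta_deg) {
  th <- deg2rad(theta_deg)
  k <- unitv(axis)
  p <- sweep(pts, 2L, origin)
  kx <- k[2L] * p[, 3L] - k[3L] * p[, 2L]
  ky <- k[3L] * p[, 1L] - k[1L] * p[, 3L]
  kz <- k[1L] * p[, 2L] - k[2L] * p[, 1L]
  kd <- p[, 1L] * k[1L] + p[, 2L] * k[2L] + p[, 3L] * k[3L]
  ct <- cos(th); st <- sin(th)
  out <- cbind(
    p[, 1L] * ct + kx * st + k[1L] * kd * (1 - ct),
    p[, 2L] * ct + ky * st + k[2L] * kd * (1 - ct),
    p[, 3L] * ct + kz * st + k[3L] * kd * (1 - ct)
  )
  sweep(out, 2L, origin, "+")
}
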