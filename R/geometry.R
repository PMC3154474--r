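# Small 3D geometry helpers shared across the package. All angles in the
# user-facing API are degrees; internal helpers take radians where noted.

DEG <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @keywords internal
#' @noRd
clamp1 <- function(x) pmin(1, pmax(-1, x))

# Angle between two vectors, degrees in [0, 180].
vec_angle <- function(a, b) {
  acos(clamp1(sum(a * b) / (vnorm(a) * vnorm(b)))) * DEG
}

# Signed angle (degrees) from a to b about axis n (right-hand rule).
signed_angle <- function(a, b, n) {
  atan2(sum(cross3(a, b) * n), sum(a * b)) * DEG
}

# Rodrigues rotation matrix about unit axis u by angle theta (radians).
rot_about <- function(u, theta) {
  u <- unitv(u)
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, u[3], -u[2],
                 -u[3], 0, u[1],
                 u[2], -u[1], 0), 3, 3)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

# Rotation about the z axis (radians); used heavily by the mid-frame math.
rot_z <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, st, 0, -st, ct, 0, 0, 0, 1), 3, 3)
}

# 180 degree flip about the frame's own x axis: maps a complementary base
# frame into the same orientation family as its Watson partner.
flip_x <- function() diag(c(1, -1, -1))

is_rotation <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && det(R) > 0
}
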