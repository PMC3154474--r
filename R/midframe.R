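# Mid-frame (CEHS-style) decomposition of the relative placement of two
# orthonormal base/pair frames, and its exact inverse. This is the single
# convention used for both intra-base-pair parameters
# (shear, stretch, stagger, buckle, propeller, opening) and base-pair-step
# parameters (shift, slide, rise, tilt, roll, twist); only the naming of the
# six numbers differs between the two uses.
#
# Forward: both frames are rotated by half the bending angle (the angle
# between their z axes) about the common hinge axis so their z axes
# coincide; twist is the residual rotation about that shared z, the
# mid-frame bisects the two rotated frames, the bend is decomposed into
# roll/tilt (or buckle-type/propeller-type) components by the phase angle
# between the hinge and the mid-frame y axis, and the translation is the
# origin displacement expressed in mid-frame coordinates.
#
# The inverse (`midframe_compose`) reconstructs frame 2 from frame 1 and the
# six parameters exactly; round-tripping is validated to <= 1e-9 in the
# tests and underpins the synthetic duplex builder.

# Returns list(par = c(d1, d2, d3, a1, a2, a3), mid = list(R, origin)).
# Translations in Angstrom, angles in degrees. a1/a2 are the tilt-like and
# roll-like components, a3 the twist-like component.
midframe_params <- function(R1, o1, R2, o2) {
  z1 <- R1[, 3]; z2 <- R2[, 3]
  cz <- clamp1(sum(z1 * z2))
  if (cz < 0) {
    stop("frame z axes are anti-aligned; check strand orientation/flip")
  }
  cr <- cross3(z1, z2)
  ncr <- vnorm(cr)
  if (ncr > 1e-9) {
    hinge <- cr / ncr
    gamma <- atan2(ncr, cz)
    R1p <- rot_about(hinge, +gamma / 2) %*% R1
    R2p <- rot_about(hinge, -gamma / 2) %*% R2
  } else {
    hinge <- NULL
    R1p <- R1; R2p <- R2
  }
  zm <- unitv(R1p[, 3] + R2p[, 3])
  twist <- signed_angle(R1p[, 1], R2p[, 1], zm)
  xm <- unitv(R1p[, 1] + R2p[, 1])
  ym <- cross3(zm, xm)
  Rm <- cbind(xm, ym, zm)
  if (!is.null(hinge)) {
    phi <- signed_angle(hinge, ym, zm) / DEG
    roll <- gamma * cos(phi) * DEG
    tilt <- gamma * sin(phi) * DEG
  } else {
    roll <- 0; tilt <- 0
  }
  tr <- drop(crossprod(Rm, o2 - o1))
  list(par = c(tr[1], tr[2], tr[3], tilt, roll, twist),
       mid = list(R = Rm, origin = (o1 + o2) / 2))
}

# Exact inverse: place frame 2 relative to frame 1 using the six
# parameters c(d1, d2, d3, tilt_like, roll_like, twist_like).
midframe_compose <- function(R1, o1, par) {
  tr <- par[1:3]
  tilt <- par[4] / DEG; roll <- par[5] / DEG; twist <- par[6] / DEG
  gamma <- sqrt(roll^2 + tilt^2)
  phi <- if (gamma > 0) atan2(tilt, roll) else 0
  hm <- c(sin(phi), cos(phi), 0)   # hinge in mid-frame coordinates
  half_bend <- if (gamma > 0) rot_about(hm, gamma / 2) else diag(3)
  Rm <- R1 %*% rot_z(twist / 2) %*% half_bend
  R2 <- Rm %*% half_bend %*% rot_z(twist / 2)
  o2 <- o1 + drop(Rm %*% tr)
  list(R = R2, origin = o2, mid = list(R = Rm, origin = o1 + drop(Rm %*% tr) / 2))
}

# Place the two frames of a pair symmetrically about a given mid-frame.
# Inverse of the mid-frame construction at the pair level: frame 1 is the
# flipped complementary-base frame, frame 2 the Watson-strand base frame.
midframe_split <- function(Rm, om, par) {
  tr <- par[1:3]
  tilt <- par[4] / DEG; roll <- par[5] / DEG; twist <- par[6] / DEG
  gamma <- sqrt(roll^2 + tilt^2)
  phi <- if (gamma > 0) atan2(tilt, roll) else 0
  hm <- c(sin(phi), cos(phi), 0)
  half_bend <- if (gamma > 0) rot_about(hm, gamma / 2) else diag(3)
  half_bend_inv <- if (gamma > 0) rot_about(hm, -gamma / 2) else diag(3)
  R1 <- Rm %*% half_bend_inv %*% rot_z(-twist / 2)
  R2 <- Rm %*% half_bend %*% rot_z(twist / 2)
  shift <- drop(Rm %*% tr) / 2
  list(frame1 = list(R = R1, origin = om - shift),
       frame2 = list(R = R2, origin = om + shift))
}
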