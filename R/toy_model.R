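# Reduced planar-limbed 3D test model: a trunk/pelvis segment with 6 global
# DoFs and two 3-DoF legs (hip yaw, hip pitch, knee pitch) ending in point
# feet that carry three contact points each. Small enough for minutes-scale
# collocation solves, rich enough to show the kinematic-chain error
# accumulation that distinguishes marker from coordinate tracking.

#' Build the reduced test model
#'
#' A 12-DoF model: pelvis/trunk root (3 translations + yaw/obliquity/tilt
#' rotations, vertical-axis rotation first) and two legs with hip yaw, hip
#' pitch and knee pitch. The trunk, head and arms are lumped into the root
#' segment. Each shank ends in a point foot with four contact points (toe and
#' heel pairs) so a planted foot resists pitch, roll and twist even when the
#' load concentrates forward, and standing still requires no joint torque. A
#' wide hip-yaw range lets the model pivot about the vertical axis with
#' planted feet. Four optional
#' mono-articular hip muscles (flexor/extensor per side) with polynomial
#' muscle-tendon lengths act alongside torque actuators on all six leg DoFs.
#'
#' @param n_mus 0 or 4 muscles.
#' @param body_mass total mass is scaled to this value (kg).
#' @param body_height stature used only for unit scalings (m).
#' @param rigid_tendon use the rigid-tendon debugging variant of the muscles.
#' @return an `msk_model`.
#' @export
toy_model <- function(n_mus = 4, body_mass = 76, body_height = 1.75,
                      rigid_tendon = FALSE) {
  stopifnot(n_mus %in% c(0, 4))
  hipy <- -0.10; hipz <- 0.12; lthigh <- 0.45; lshank <- 0.45; footdrop <- 0.48
  dof <- list(
    name = c("pelvis_tx", "pelvis_ty", "pelvis_tz",
             "pelvis_rot", "pelvis_obl", "pelvis_tilt",
             "hip_yaw_r", "hip_pitch_r", "knee_pitch_r",
             "hip_yaw_l", "hip_pitch_l", "knee_pitch_l"),
    parent = c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 6L, 10L, 11L),
    jtype = c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    axis = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(0, 1, 0), c(1, 0, 0), c(0, 0, 1),
                 c(0, 1, 0), c(0, 0, 1), c(0, 0, 1),
                 c(0, 1, 0), c(0, 0, 1), c(0, 0, 1)),
    trans = rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                  c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                  c(0, hipy, hipz), c(0, 0, 0), c(0, -lthigh, 0),
                  c(0, hipy, -hipz), c(0, 0, 0), c(0, -lthigh, 0)))
  msc <- body_mass / 76  # mass scale
  cyl_inertia <- function(m, r, l) {
    ix <- m * (3 * r^2 + l^2) / 12
    c(ix, 0, 0, 0, m * r^2 / 2, 0, 0, 0, ix)
  }
  body <- list(
    name = c("trunk", "thigh_r", "shank_r", "thigh_l", "shank_l"),
    dof = c(6L, 8L, 9L, 11L, 12L),
    mass = msc * c(50, 8, 5, 8, 5),
    com = rbind(c(0, 0.25, 0), c(0, -0.20, 0), c(0, -0.25, 0),
                c(0, -0.20, 0), c(0, -0.25, 0)),
    inertia = rbind(msc * cyl_inertia(50, 0.18, 0.80),
                    msc * cyl_inertia(8, 0.06, 0.45),
                    msc * cyl_inertia(5, 0.05, 0.50),
                    msc * cyl_inertia(8, 0.06, 0.45),
                    msc * cyl_inertia(5, 0.05, 0.50)))
  markers <- list(
    name = c("SACR", "LASI", "RASI", "STRN",
             "RTHI", "RKNE", "LTHI", "LKNE",
             "RANK", "RTOE", "RHEE", "LANK", "LTOE", "LHEE"),
    dof = c(6L, 6L, 6L, 6L, 8L, 8L, 11L, 11L, 9L, 9L, 9L, 12L, 12L, 12L),
    # lateral wand/epicondyle/malleolus offsets give the transverse-plane
    # observability a real marker set has
    local = rbind(c(-0.12, 0.05, 0), c(0.10, 0.03, -0.12), c(0.10, 0.03, 0.12),
                  c(0.10, 0.35, 0),
                  c(0.06, -0.25, 0.08), c(0.02, -0.44, 0.08),
                  c(0.06, -0.25, -0.08), c(0.02, -0.44, -0.08),
                  c(0.00, -0.42, 0.08), c(0.13, -0.47, 0.04), c(-0.10, -0.47, 0.00),
                  c(0.00, -0.42, -0.08), c(0.13, -0.47, -0.04), c(-0.10, -0.47, 0.00)))
  # four contact points per foot (toe pair + heel pair), fore-aft symmetric:
  # a collinear point pair loses all torsional grip as soon as the load
  # concentrates on one point, and a fore-aft asymmetric set would demand
  # joint torque to stand still
  cp <- rbind(c(0.12, -footdrop, 0.05), c(0.12, -footdrop, -0.05),
              c(-0.12, -footdrop, 0.05), c(-0.12, -footdrop, -0.05))
  contacts <- list(
    dof = c(rep(9L, 4), rep(12L, 4)),
    foot = c(rep(0L, 4), rep(1L, 4)),
    local = rbind(cp, cp),
    k = 3e5, expn = 1.5, cdamp = 1.0, mu = 1.2, vs = 0.02, eps = 1e-4,
    offset = 0)
  if (n_mus == 4) {
    poly1 <- function(d, sgn) {  # lmt = 0.25 + sgn*(0.05 q + 0.005 q^2)
      expo <- matrix(0L, 3, 12); expo[2, d] <- 1L; expo[3, d] <- 2L
      list(coef = c(0.25, sgn * 0.05, sgn * 0.005), expo = expo)
    }
    muscles <- list(
      name = c("hip_ext_r", "hip_flex_r", "hip_ext_l", "hip_flex_l"),
      fmax = rep(1500, 4), lmopt = rep(0.10, 4), ltslack = rep(0.15, 4),
      vmax = rep(10, 4), tact = rep(0.010, 4), tdeact = rep(0.040, 4),
      w = rep(150, 4), kt = rep(12, 4), rigid = rep(as.integer(rigid_tendon), 4),
      poly = list(poly1(8, +1), poly1(8, -1), poly1(11, +1), poly1(11, -1)))
  } else {
    muscles <- list(name = character(0), fmax = numeric(0), lmopt = numeric(0),
                    ltslack = numeric(0), vmax = numeric(0), tact = numeric(0),
                    tdeact = numeric(0), w = numeric(0), kt = numeric(0),
                    rigid = integer(0), poly = list())
  }
  deg <- pi / 180
  passive <- list(
    qlo = c(rep(-Inf, 3), rep(-2 * pi, 3),
            -125 * deg, -40 * deg, -130 * deg, -125 * deg, -40 * deg, -130 * deg),
    qhi = c(rep(Inf, 3), rep(2 * pi, 3),
            125 * deg, 100 * deg, 15 * deg, 125 * deg, 100 * deg, 15 * deg),
    k = c(rep(0, 6), rep(2, 6)),
    b = c(rep(0, 6), rep(12, 6)),
    d = c(rep(0, 6), rep(0.5, 6)))
  margin <- 10 * deg
  ranges <- rbind(c(-3, 3), c(0.3, 1.6), c(-3, 3),
                  c(-2 * pi, 2 * pi), c(-pi, pi), c(-pi, pi),
                  cbind(passive$qlo[7:12] - margin, passive$qhi[7:12] + margin))
  msk_model(dof = dof, body = body, markers = markers, contacts = contacts,
            muscles = muscles, tor = 7:12, tor_gain = rep(300, 6),
            passive = passive, ranges = ranges,
            body_mass = body_mass, body_height = body_height,
            name = sprintf("toy12-%dmus", n_mus))
}
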