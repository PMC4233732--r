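# Mandible pose: generalized coordinates and the rigid transform they induce.
#
# Six generalized coordinates: sagittal angle (deg, positive = opening),
# frontal angle (deg, positive = roll of the chin toward the working/right
# side about the anteroposterior axis through the balancing/left condyle),
# yaw angle (deg, standard rotation about +z through the condylar midpoint;
# negative yaw retracts the working condyle), and a 3-vector translation (mm).
# The transform is applied as: sagittal, then frontal, then yaw, then
# translation. The closed midline pose is the identity.

#' Mandible pose
#'
#' @param sagittal Sagittal (lateral-view) gape angle in degrees; positive
#'   opens the jaw.
#' @param frontal Frontal-view roll angle in degrees; positive moves the chin
#'   toward the working (right) side. The rotation axis is the
#'   anteroposterior axis through the balancing (left) condyle, so the
#'   balancing condyle is stationary under frontal rotation.
#' @param yaw Rotation about the vertical axis through the condylar midpoint,
#'   degrees. Equivalent to differential anteroposterior condylar
#'   translation.
#' @param translation Rigid translation of the mandible, mm (3-vector).
#' @param velocity,acceleration Optional first and second time derivatives of
#'   the six generalized coordinates `(sagittal, frontal, yaw, tx, ty, tz)`
#'   in deg/s, mm/s and deg/s^2, mm/s^2; used only by the dynamic residual.
#' @return An object of class `jaw_pose`.
#' @export
jaw_pose <- function(sagittal = 0, frontal = 0, yaw = 0,
                     translation = c(0, 0, 0),
                     velocity = rep(0, 6), acceleration = rep(0, 6)) {
  stopifnot(length(translation) == 3, length(velocity) == 6,
            length(acceleration) == 6)
  structure(list(
    sagittal = sagittal, frontal = frontal, yaw = yaw,
    translation = as.numeric(translation),
    velocity = as.numeric(velocity),
    acceleration = as.numeric(acceleration)
  ), class = "jaw_pose")
}

#' @export
print.jaw_pose <- function(x, ...) {
  cat(sprintf(
    "<jaw_pose> sagittal %.3f deg, frontal %.3f deg, yaw %.3f deg, t = (%.3f, %.3f, %.3f) mm\n",
    x$sagittal, x$frontal, x$yaw,
    x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

pose_coords <- function(pose) {
  c(pose$sagittal, pose$frontal, pose$yaw, pose$translation)
}

pose_from_coords <- function(q, velocity = rep(0, 6),
                             acceleration = rep(0, 6)) {
  jaw_pose(q[1], q[2], q[3], q[4:6], velocity, acceleration)
}

rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' Rigid transform of a mandible pose
#'
#' Composes the pose's generalized coordinates into the rigid transform
#' mapping mandible body-frame points (closed midline pose) to the cranium
#' (world) frame: a sagittal rotation about the transverse axis through both
#' condyles, a frontal rotation about the anteroposterior axis through the
#' balancing-side condyle (so that the working condyle displaces while the
#' balancing condyle stays put), a yaw about the vertical axis through the
#' condylar midpoint, then a translation.
#'
#' @param pose A [jaw_pose()].
#' @param model A model built by [build_jaw_model()] (supplies the condyle
#'   positions that anchor the rotation axes).
#' @return A list with rotation matrix `R` and offset `t`; apply with
#'   [transform_points()].
#' @export
pose_transform <- function(pose, model) {
  d2r <- pi / 180
  cl <- model$condyle_left # axis anchor for frontal rotation
  # sagittal: +y axis through condylar axis (z = 0 plane through origin)
  R1 <- rot_y(pose$sagittal * d2r)
  # frontal: rotation about +x through the left condyle; positive pose
  # angle tips the chin toward the right (-y), i.e. Rx(-frontal)
  R2 <- rot_x(-pose$frontal * d2r)
  # yaw about +z through the condylar midpoint (origin)
  R3 <- rot_z(pose$yaw * d2r)
  R <- R3 %*% R2 %*% R1
  # p' = t + R3 (R2 (R1 p - cl) + cl)
  t0 <- R3 %*% (cl - R2 %*% cl)
  list(R = R, t = as.numeric(t0) + pose$translation)
}

#' Apply a rigid transform to points
#'
#' @param transform A transform from [pose_transform()].
#' @param points A 3-vector or an n x 3 matrix of points (mm).
#' @return Transformed points with the same shape.
#' @export
transform_points <- function(transform, points) {
  if (is.matrix(points)) {
    sweep(points %*% t(transform$R), 2, -transform$t)
  } else {
    as.numeric(transform$R %*% points + transform$t)
  }
}

# World position of a single body-frame point under a pose.
body_point_world <- function(model, pose, p) {
  transform_points(pose_transform(pose, model), p)
}

# Jacobian d p_world / d q (3 x 6) of a body-frame point, by central
# differences on the generalized coordinates (angles in degrees, mm).
point_jacobian <- function(model, pose, p, h = 1e-4) {
  q0 <- pose_coords(pose)
  J <- matrix(0, 3, 6)
  for (k in seq_len(6)) {
    qp <- q0; qp[k] <- qp[k] + h
    qm <- q0; qm[k] <- qm[k] - h
    pp <- body_point_world(model, pose_from_coords(qp), p)
    pm <- body_point_world(model, pose_from_coords(qm), p)
    J[, k] <- (pp - pm) / (2 * h)
  }
  J
}
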