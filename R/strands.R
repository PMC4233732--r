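# Hill-type muscle strands: path geometry, tension law, and the wrench each
# strand exerts on the mandible.

#' Passive tension law
#'
#' Strands resist elongation with a small passive tension that rises
#' exponentially with strain and saturates at `cap_fraction` of the strand's
#' maximum force (default 0.1%). The law is zero at and below zero strain,
#' strictly increasing up to `strain_at_cap`, and constant beyond.
#'
#' @param cap_fraction Saturation level as a fraction of maximum force,
#'   in (0, 0.01]; default 0.001.
#' @param shape Exponential shape coefficient (dimensionless, default 5).
#' @param strain_at_cap Strain at which the cap is reached (default 0.5).
#' @return An object of class `passive_law`.
#' @export
passive_law <- function(cap_fraction = 0.001, shape = 5, strain_at_cap = 0.5) {
  stopifnot(cap_fraction > 0, cap_fraction <= 0.01, shape > 0,
            strain_at_cap > 0)
  structure(list(cap_fraction = cap_fraction, shape = shape,
                 strain_at_cap = strain_at_cap), class = "passive_law")
}

#' Passive strand tension at a given strain
#'
#' @param strain Engineering strain `(length - rest_length) / rest_length`;
#'   negative (slack) strain gives zero tension.
#' @param max_force Strand (or muscle) maximum force, N.
#' @param law A [passive_law()].
#' @return Passive tension in N. Vectorised over `strain`.
#' @export
passive_tension <- function(strain, max_force, law = passive_law()) {
  cap <- law$cap_fraction * max_force
  scale <- expm1(law$shape * law$strain_at_cap)
  out <- cap * expm1(law$shape * pmin(pmax(strain, 0), law$strain_at_cap)) / scale
  out[strain >= law$strain_at_cap] <- cap
  out[strain <= 0] <- 0
  out
}

#' Hill-type strand tension
#'
#' The strand force model uses three parameters: maximum force, activation
#' factor and passive tension. Tension = activation x maximum force share +
#' passive. There is no force-length or force-velocity scaling.
#'
#' @param activation Activation in `[0, 1]`.
#' @param max_force_share Strand maximum force, N.
#' @param passive Passive tension, N (default 0).
#' @return Tension in N.
#' @export
strand_tension <- function(activation, max_force_share, passive = 0) {
  if (any(activation < -1e-12) || any(activation > 1 + 1e-12)) {
    stop("activation must lie in [0, 1]", call. = FALSE)
  }
  pmin(pmax(activation, 0), 1) * max_force_share + passive
}

# World-frame strand path under a pose: mandible-frame points are
# transformed, cranium-frame points are fixed.
strand_path_world <- function(strand, pose, model) {
  tr <- pose_transform(pose, model)
  path <- strand$path
  mand <- strand$frames == "mandible"
  if (any(mand)) {
    path[mand, ] <- transform_points(tr, path[mand, , drop = FALSE])
  }
  path
}

#' Strand path length under a pose
#'
#' Sum of Euclidean segment lengths of the strand polyline after
#' transforming its mandible-frame points by the pose.
#'
#' @param strand A strand from `model$strands`.
#' @param pose A [jaw_pose()].
#' @param model The model the strand belongs to.
#' @return Length in mm.
#' @export
strand_path_length <- function(strand, pose, model) {
  polyline_length(strand_path_world(strand, pose, model))
}

strand_strain <- function(strand, pose, model) {
  (strand_path_length(strand, pose, model) - strand$rest_length) /
    strand$rest_length
}

strand_passive <- function(strand, pose, model, law = passive_law()) {
  passive_tension(strand_strain(strand, pose, model),
                  strand$max_force_share, law)
}

#' Wrench a strand exerts on the mandible
#'
#' Tension acts along the strand path. At every mandible-frame path point
#' the strand pulls toward its neighbouring path points; the insertion (last
#' point) is pulled toward the adjacent via/origin point. Cranium-frame
#' points load the fixed cranium and contribute nothing to the mandible
#' wrench. The wrench (force N, moment N mm) is taken about `ref` (default:
#' the world position of the mandible reference point).
#'
#' @param strand A strand.
#' @param pose A [jaw_pose()].
#' @param tension Strand tension, N (>= 0).
#' @param model The model.
#' @param ref Moment reference point (world, mm).
#' @return A 6-vector `(Fx, Fy, Fz, Mx, My, Mz)`.
#' @export
strand_wrench <- function(strand, pose, tension, model,
                          ref = pose_transform(pose, model)$t) {
  stopifnot(tension >= 0)
  if (tension == 0) return(rep(0, 6))
  path <- strand_path_world(strand, pose, model)
  n <- nrow(path)
  w <- rep(0, 6)
  for (j in which(strand$frames == "mandible")) {
    f <- c(0, 0, 0)
    for (adj in c(j - 1, j + 1)) {
      if (adj < 1 || adj > n) next
      seg <- path[adj, ] - path[j, ]
      len <- sqrt(sum(seg^2))
      if (len < 1e-9) {
        stop("degenerate zero-length strand segment at ", strand$muscle,
             call. = FALSE)
      }
      f <- f + tension * seg / len
    }
    w <- w + point_wrench(f, path[j, ], ref)
  }
  w
}

# Generalized force of a strand on the six pose coordinates per unit
# tension; by the principle of virtual work this equals minus the gradient
# of path length with respect to the coordinates (the moment arms).
strand_moment_arms <- function(strand, pose, model, h = 1e-4) {
  path <- strand_path_world(strand, pose, model)
  n <- nrow(path)
  Q <- rep(0, 6)
  for (j in which(strand$frames == "mandible")) {
    f <- c(0, 0, 0)
    for (adj in c(j - 1, j + 1)) {
      if (adj < 1 || adj > n) next
      seg <- path[adj, ] - path[j, ]
      f <- f + seg / sqrt(sum(seg^2))
    }
    J <- point_jacobian(model, pose, strand$path[j, ], h = h)
    Q <- Q + as.numeric(f %*% J)
  }
  Q
}
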