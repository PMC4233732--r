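# Rigid mandible: mass properties, mesh-derived inertia, TMJ admissibility
# and the six degree-of-freedom equilibrium residual.

#' Rigid mandible body
#'
#' @param mass Mass in grams (> 0).
#' @param com Centre of mass, mm, in the mandible body frame.
#' @param inertia 3x3 symmetric positive-definite inertia tensor about the
#'   centre of mass, g mm^2, body frame. Principal moments must satisfy the
#'   triangle inequalities.
#' @return An object of class `mandible_body`.
#' @export
mandible_body <- function(mass, com, inertia) {
  stopifnot(mass > 0, length(com) == 3, all(dim(inertia) == c(3, 3)))
  if (max(abs(inertia - t(inertia))) > 1e-6 * max(abs(inertia))) {
    stop("inertia tensor must be symmetric", call. = FALSE)
  }
  ev <- eigen((inertia + t(inertia)) / 2, symmetric = TRUE)$values
  if (any(ev <= 0)) stop("inertia tensor must be positive definite", call. = FALSE)
  p <- sort(ev)
  if (p[1] + p[2] < p[3] * (1 - 1e-9)) {
    stop("principal moments violate the triangle inequality", call. = FALSE)
  }
  structure(list(mass = mass, com = as.numeric(com), inertia = inertia),
            class = "mandible_body")
}

#' Default ellipsoidal mandible approximation
#'
#' A solid ellipsoid of tissue density 1.05 g cm^-3 standing in for the
#' mandible when no surface mesh is supplied: semi-axes 30 x 10 x 8 mm
#' (mass ~10.6 g), centre of mass anterior and ventral to the condylar
#' midpoint.
#'
#' @param semi_axes Ellipsoid semi-axes (mm).
#' @param com Centre of mass, mm.
#' @param density Tissue density, g cm^-3.
#' @return A [mandible_body()].
#' @export
default_mandible_body <- function(semi_axes = c(30, 10, 8),
                                  com = c(25, 0, -12),
                                  density = 1.05) {
  a <- semi_axes[1]; b <- semi_axes[2]; c3 <- semi_axes[3]
  mass <- density * 1e-3 * 4 / 3 * pi * a * b * c3
  inertia <- diag(mass / 5 * c(b^2 + c3^2, a^2 + c3^2, a^2 + b^2))
  mandible_body(mass, com, inertia)
}

# ---- surface meshes -------------------------------------------------------

#' Read a triangle surface mesh (ASCII STL or OBJ)
#'
#' Minimal reader for the two plain-text mesh formats used for mandible
#' inertia computation. OBJ polygon faces are fan-triangulated; STL vertices
#' are merged exactly.
#'
#' @param path Path to a `.stl` (ASCII) or `.obj` file.
#' @return A list with `vertices` (n x 3, mm) and `faces` (m x 3 indices).
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "obj") {
    vl <- grep("^v\\s", lines, value = TRUE)
    fl <- grep("^f\\s", lines, value = TRUE)
    vertices <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                                      function(x) as.numeric(x[1:3])))
    faces <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
      function(x) {
        idx <- as.integer(sub("/.*", "", x))
        if (length(idx) < 3) stop("degenerate OBJ face", call. = FALSE)
        cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])
      }))
  } else if (ext == "stl") {
    vl <- grep("vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                    function(x) as.numeric(x[2:4])))
    if (nrow(coords) %% 3 != 0) stop("malformed ASCII STL", call. = FALSE)
    key <- apply(coords, 1, paste, collapse = ",")
    uk <- unique(key)
    vertices <- coords[match(uk, key), , drop = FALSE]
    faces <- matrix(match(key, uk), ncol = 3, byrow = TRUE)
  } else {
    stop("unsupported mesh format: ", ext, call. = FALSE)
  }
  list(vertices = vertices, faces = faces)
}

mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  fwd <- paste(e[, 1], e[, 2])
  rev <- paste(e[, 2], e[, 1])
  !any(duplicated(fwd)) && all(fwd %in% rev)
}

#' Mass properties of a watertight mesh
#'
#' Computes volume, centre of mass and the inertia tensor of a closed
#' triangle mesh by exact tetrahedral decomposition against the origin
#' (divergence theorem), then scales by density. Mesh coordinates are in mm;
#' outward-facing, consistently wound normals are required.
#'
#' @param mesh A mesh list (`vertices`, `faces`) or a path readable by
#'   [read_mesh()].
#' @param density Density in g cm^-3 (default 1.05, standard tissue).
#' @return A list with `mass` (g), `com` (mm), `inertia` (g mm^2 about the
#'   centre of mass) and `volume` (mm^3).
#' @export
inertia_from_mesh <- function(mesh, density = 1.05) {
  if (is.character(mesh)) mesh <- read_mesh(mesh)
  if (!mesh_is_watertight(mesh)) {
    stop("mesh is not watertight (open or inconsistently wound edges)",
         call. = FALSE)
  }
  V <- mesh$vertices
  Ftri <- mesh$faces
  vol <- 0
  first <- c(0, 0, 0)
  S <- matrix(0, 3, 3)
  for (i in seq_len(nrow(Ftri))) {
    A <- V[Ftri[i, 1], ]; B <- V[Ftri[i, 2], ]; C <- V[Ftri[i, 3], ]
    v6 <- det(cbind(A, B, C))
    v <- v6 / 6
    vol <- vol + v
    first <- first + v * (A + B + C) / 4
    s <- A + B + C
    S <- S + v / 20 * (tcrossprod(A) + tcrossprod(B) + tcrossprod(C) +
                         tcrossprod(s))
  }
  if (vol < 0) { # inward winding: flip sign convention
    vol <- -vol; first <- -first; S <- -S
  }
  rho <- density * 1e-3 # g mm^-3
  mass <- rho * vol
  com <- first / vol
  S <- rho * S
  inertia_origin <- diag(sum(diag(S)), 3) - S
  # parallel axis shift to the centre of mass
  inertia_com <- inertia_origin -
    mass * (diag(sum(com^2), 3) - tcrossprod(com))
  list(mass = mass, com = as.numeric(com),
       inertia = (inertia_com + t(inertia_com)) / 2, volume = vol)
}

# ---- TMJ admissibility ----------------------------------------------------

#' Admissibility of a temporomandibular joint reaction
#'
#' The TMJ is a unilateral point contact: the reaction on the mandible must
#' be compressive along the fossa contact normal, with tangential (frictional)
#' components bounded by `mu * normal`. The default `mu = 0` gives a
#' frictionless contact whose reaction lies along the normal. Inadmissible
#' candidates are projected onto the cone by clipping: a tensile normal
#' component is zeroed, and the tangential component is scaled down to the
#' friction bound at the retained normal load.
#'
#' @param candidate Candidate reaction force on the mandible, N (3-vector).
#' @param normal Unit fossa contact normal (direction of admissible push on
#'   the condyle).
#' @param mu Joint friction coefficient (default 0).
#' @return A list with `admissible` (logical) and `projection` (the nearest
#'   admissible reaction).
#' @export
admissible_joint_reaction <- function(candidate, normal, mu = 0) {
  n_hat <- normal / sqrt(sum(normal^2))
  fn <- sum(candidate * n_hat)
  ft_vec <- candidate - fn * n_hat
  ft <- sqrt(sum(ft_vec^2))
  tol <- 1e-9 * max(1, sqrt(sum(candidate^2)))
  admissible <- fn >= -tol && ft <= mu * max(fn, 0) + tol
  if (admissible) {
    return(list(admissible = TRUE, projection = candidate))
  }
  # clip: tensile normal components vanish; tangential components are
  # scaled down to the friction bound at the (retained) normal load
  fn_new <- max(fn, 0)
  ft_max <- mu * fn_new
  proj <- if (ft > 1e-12) {
    fn_new * n_hat + min(ft, ft_max) * ft_vec / ft
  } else {
    fn_new * n_hat
  }
  list(admissible = FALSE, projection = proj)
}

# ---- equilibrium residual -------------------------------------------------

skew_part <- function(M) (M - t(M)) / 2
vee <- function(W) c(W[3, 2], W[1, 3], W[2, 1])

# Inertial wrench (force N, moment N mm about the world reference point),
# from finite differences of the pose trajectory implied by the pose's
# velocity/acceleration coordinates.
inertial_wrench <- function(model, pose, ref, h = 1e-5) {
  q0 <- pose_coords(pose)
  qd <- pose$velocity
  qdd <- pose$acceleration
  if (all(qd == 0) && all(qdd == 0)) return(rep(0, 6))
  at <- function(t) {
    pose_transform(pose_from_coords(q0 + qd * t + 0.5 * qdd * t^2), model)
  }
  Tm <- at(-h); T0 <- at(0); Tp <- at(h)
  com <- model$mandible$com
  p_m <- transform_points(Tm, com)
  p_0 <- transform_points(T0, com)
  p_p <- transform_points(Tp, com)
  a_com <- (p_p - 2 * p_0 + p_m) / h^2          # mm s^-2
  Rdot <- (Tp$R - Tm$R) / (2 * h)
  Rddot <- (Tp$R - 2 * T0$R + Tm$R) / h^2
  omega <- vee(skew_part(Rdot %*% t(T0$R)))      # rad s^-1
  alpha <- vee(skew_part(Rddot %*% t(T0$R)))     # rad s^-2
  m <- model$mandible$mass
  Iw <- T0$R %*% model$mandible$inertia %*% t(T0$R)
  f <- m * a_com * 1e-6                          # N
  m_com <- (Iw %*% alpha + cross3(omega, Iw %*% omega)) * 1e-6 # N mm
  r <- p_0 - ref
  c(f, as.numeric(m_com) + cross3(r, f))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

point_wrench <- function(force, point, ref) {
  c(force, cross3(point - ref, force))
}

gravity_wrench <- function(model, pose, ref) {
  tr <- pose_transform(pose, model)
  com_w <- transform_points(tr, model$mandible$com)
  fg <- c(0, 0, -model$mandible$mass * 1e-3 * model$gravity) # N
  point_wrench(fg, com_w, ref)
}

joint_wrenches <- function(model, pose, joint_reactions, ref) {
  tr <- pose_transform(pose, model)
  w <- rep(0, 6)
  for (side in c("right", "left")) {
    f <- joint_reactions[[side]]
    if (is.null(f)) next
    cond <- if (side == "right") model$condyle_right else model$condyle_left
    w <- w + point_wrench(f, transform_points(tr, cond), ref)
  }
  w
}

#' Six degree-of-freedom mandible equilibrium residual
#'
#' Sums every wrench acting on the mandible about the world position of the
#' body reference point (the condylar midpoint): muscle strand wrenches at
#' the given activations (with passive tension), joint reactions, the food
#' bolus force at its bite point, gravity, and (in dynamic mode) minus the
#' inertial wrench. The residual is the 6-vector (net force N, net moment
#' N mm); it vanishes at a consistent static (or dynamic) state, and is
#' affine in the activations at a fixed pose.
#'
#' @param model A [build_jaw_model()] model.
#' @param pose A [jaw_pose()].
#' @param activations Numeric vector of per-strand activations in `[0, 1]`,
#'   in `model$strands` order.
#' @param joint_reactions List with 3-vector reactions `right` and `left`
#'   (N, on the mandible), or `NULL` for none.
#' @param bolus_force Force on the lower bolus plate (N), or `NULL`.
#' @param bolus_site Bite point name (see `model$bite_points`) where the
#'   bolus force acts.
#' @param gravity_on Include gravity (default `TRUE`).
#' @param dynamic Include inertial terms driven by the pose's velocity and
#'   acceleration coordinates (default `FALSE`: quasi-static).
#' @param law Passive tension law, default [passive_law()].
#' @param passive_on Include passive strand tension (default `TRUE`).
#' @return Residual 6-vector `(Fx, Fy, Fz, Mx, My, Mz)` in N and N mm.
#' @export
equilibrium_residual <- function(model, pose, activations,
                                 joint_reactions = NULL,
                                 bolus_force = NULL, bolus_site = "incisor",
                                 gravity_on = TRUE, dynamic = FALSE,
                                 law = passive_law(), passive_on = TRUE) {
  stopifnot(length(activations) == length(model$strands))
  tr <- pose_transform(pose, model)
  ref <- tr$t
  w <- rep(0, 6)
  for (i in seq_along(model$strands)) {
    st <- model$strands[[i]]
    tension <- strand_tension(
      activations[i], st$max_force_share,
      if (passive_on) strand_passive(st, pose, model, law) else 0)
    if (tension > 0) w <- w + strand_wrench(st, pose, tension, model, ref)
  }
  if (!is.null(joint_reactions)) {
    w <- w + joint_wrenches(model, pose, joint_reactions, ref)
  }
  if (!is.null(bolus_force)) {
    p <- transform_points(tr, model$bite_points[[bolus_site]])
    w <- w + point_wrench(bolus_force, p, ref)
  }
  if (gravity_on) w <- w + gravity_wrench(model, pose, ref)
  if (dynamic) w <- w - inertial_wrench(model, pose, ref)
  w
}
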