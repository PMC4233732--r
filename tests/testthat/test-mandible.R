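test_that("mesh mass properties: cube, scaling laws, sphere closed form", {
  cube <- cube_mesh(10, shift = c(2, 3, 4))
  p <- inertia_from_mesh(cube, density = 1.05)
  expect_equal(p$volume, 1000, tolerance = 1e-9)
  expect_equal(p$mass, 1.05, tolerance = 1e-9)
  expect_equal(p$com, c(7, 8, 9), tolerance = 1e-9)
  expect_equal(p$inertia, diag(1.05 * 100 / 6, 3), tolerance = 1e-9)

  big <- cube_mesh(10)
  big$vertices <- big$vertices * 2
  p1 <- inertia_from_mesh(cube_mesh(10), density = 1.05)
  p2 <- inertia_from_mesh(big, density = 1.05)
  expect_equal(p2$mass, 8 * p1$mass, tolerance = 1e-9)
  expect_equal(p2$inertia, 32 * p1$inertia, tolerance = 1e-9)

  sph <- uv_sphere_mesh(r = 5)
  ps <- inertia_from_mesh(sph, density = 1.05)
  exact_mass <- 1.05e-3 * 4 / 3 * pi * 125
  exact_I <- 0.4 * exact_mass * 25
  expect_lt(abs(ps$inertia[1, 1] - exact_I) / exact_I, 0.01)
  expect_lt(abs(ps$inertia[3, 3] - exact_I) / exact_I, 0.01)
})

test_that("non-watertight meshes are rejected", {
  cube <- cube_mesh(10)
  cube$faces <- cube$faces[-1, ]
  expect_error(inertia_from_mesh(cube), "watertight")
})

test_that("ASCII STL and OBJ readers reproduce the cube", {
  cube <- cube_mesh(10, shift = c(1, 1, 1))
  obj <- withr::local_tempfile(fileext = ".obj")
  writeLines(c(
    apply(cube$vertices, 1, function(v) sprintf("v %g %g %g", v[1], v[2], v[3])),
    apply(cube$faces, 1, function(f) sprintf("f %d %d %d", f[1], f[2], f[3]))
  ), obj)
  p_obj <- inertia_from_mesh(obj, density = 1.05)
  expect_equal(p_obj$mass, 1.05, tolerance = 1e-9)
  expect_equal(p_obj$com, c(6, 6, 6), tolerance = 1e-9)

  stl <- withr::local_tempfile(fileext = ".stl")
  lines <- c("solid cube")
  for (i in seq_len(nrow(cube$faces))) {
    tri <- cube$vertices[cube$faces[i, ], ]
    lines <- c(lines, "facet normal 0 0 0", "outer loop",
               apply(tri, 1, function(v)
                 sprintf("vertex %g %g %g", v[1], v[2], v[3])),
               "endloop", "endfacet")
  }
  writeLines(c(lines, "endsolid cube"), stl)
  p_stl <- inertia_from_mesh(stl, density = 1.05)
  expect_equal(p_stl$mass, 1.05, tolerance = 1e-9)
  expect_equal(p_stl$inertia, p_obj$inertia, tolerance = 1e-9)
})

test_that("mandible body validates its inertia tensor", {
  expect_error(mandible_body(10, c(0, 0, 0), diag(c(-1, 2, 3))), "positive")
  asym <- diag(3); asym[1, 2] <- 1
  expect_error(mandible_body(10, c(0, 0, 0), asym), "symmetric")
  expect_error(mandible_body(10, c(0, 0, 0), diag(c(1, 1, 3))), "triangle")
  body <- default_mandible_body()
  expect_gt(body$mass, 5); expect_lt(body$mass, 20)
})

test_that("joint reaction admissibility and cone clipping", {
  n <- c(0, 0, -1)
  tens <- admissible_joint_reaction(c(0, 0, 2), n)
  expect_false(tens$admissible)
  expect_equal(tens$projection, c(0, 0, 0))
  comp <- admissible_joint_reaction(c(0, 0, -5), n)
  expect_true(comp$admissible)
  expect_equal(comp$projection, c(0, 0, -5))
  mixed <- admissible_joint_reaction(c(5, 0, -10), n, mu = 0.3)
  expect_false(mixed$admissible)
  expect_equal(mixed$projection, c(3, 0, -10), tolerance = 1e-12)
  slip <- admissible_joint_reaction(c(2, 0, -10), n, mu = 0.3)
  expect_true(slip$admissible)
})

test_that("pose transform geometry: identity, sagittal drop, frontal axis", {
  model <- default_model()
  tr0 <- pose_transform(jaw_pose(), model)
  expect_equal(tr0$R, diag(3), tolerance = 1e-12)
  expect_equal(tr0$t, c(0, 0, 0), tolerance = 1e-12)

  p_inc <- model$bite_points$incisor
  drop <- incisal_gape_mm(jaw_pose(12), model)
  exact <- p_inc[1] * sin(12 * pi / 180) + p_inc[3] * (1 - cos(12 * pi / 180))
  expect_equal(drop, exact, tolerance = 1e-9)
  expect_lt(abs(drop - p_inc[1] * sin(12 * pi / 180)) / drop, 0.03)

  tr <- pose_transform(jaw_pose(0, 4), model)
  bal <- transform_points(tr, model$condyle_left)
  expect_lt(sqrt(sum((bal - model$condyle_left)^2)), 0.1)
  mol <- transform_points(tr, model$bite_points$molar_right)
  expect_gt(abs(mol[2] - model$bite_points$molar_right[2]), 0.5)
})

test_that("equilibrium residual: empty scene, gravity statics, linearity", {
  model <- default_model()
  pose <- jaw_pose(6, 2)
  zero <- equilibrium_residual(model, pose, rep(0, 150), gravity_on = FALSE,
                               passive_on = FALSE)
  expect_equal(zero, rep(0, 6), tolerance = 1e-12)

  grav <- equilibrium_residual(model, jaw_pose(), rep(0, 150),
                               passive_on = FALSE)
  mg <- model$mandible$mass * 1e-3 * model$gravity
  expect_equal(grav[1:3], c(0, 0, -mg), tolerance = 1e-12)
  expect_equal(grav[4:6],
               masticate:::cross3(model$mandible$com, c(0, 0, -mg)),
               tolerance = 1e-12)

  # affine in activations: superposition of the activation-dependent part
  set.seed(1)
  a1 <- stats::runif(150, 0, 0.5); a2 <- stats::runif(150, 0, 0.5)
  r0 <- equilibrium_residual(model, pose, rep(0, 150))
  r1 <- equilibrium_residual(model, pose, a1)
  r2 <- equilibrium_residual(model, pose, a2)
  r12 <- equilibrium_residual(model, pose, a1 + a2)
  expect_equal(r12 - r0, (r1 - r0) + (r2 - r0), tolerance = 1e-8)
})

test_that("quasi-static and dynamic residuals agree at zero rates", {
  model <- default_model()
  pose <- jaw_pose(5, 1)
  a <- rep(0.1, 150)
  expect_equal(
    equilibrium_residual(model, pose, a, dynamic = TRUE),
    equilibrium_residual(model, pose, a, dynamic = FALSE),
    tolerance = 1e-10)
  # non-zero rates change the dynamic residual but not the static one
  pose2 <- jaw_pose(5, 1, velocity = c(200, 0, 0, 0, 0, 0),
                    acceleration = c(4000, 0, 0, 0, 0, 0))
  dyn <- equilibrium_residual(model, pose2, a, dynamic = TRUE)
  stat <- equilibrium_residual(model, pose2, a, dynamic = FALSE)
  expect_false(isTRUE(all.equal(dyn, stat, tolerance = 1e-12)))
})

test_that("opposing bolus plate forces cancel as a scene wrench", {
  model <- default_model()
  pose <- jaw_pose(2)
  f <- c(3, -2, -10)
  base <- equilibrium_residual(model, pose, rep(0, 150),
                               gravity_on = FALSE, passive_on = FALSE)
  lower <- equilibrium_residual(model, pose, rep(0, 150), bolus_force = f,
                                bolus_site = "molar_right",
                                gravity_on = FALSE, passive_on = FALSE)
  upper <- equilibrium_residual(model, pose, rep(0, 150), bolus_force = -f,
                                bolus_site = "molar_right",
                                gravity_on = FALSE, passive_on = FALSE)
  expect_equal((lower - base) + (upper - base), rep(0, 6), tolerance = 1e-12)
})
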