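# The QP core is exercised directly on small recruitment problems (rows =
# balance equations, columns = unit-force strand directions), then through
# solve_step on the full model.

qp <- masticate:::solve_recruitment_qp

test_that("single strand collinear with the demand activates linearly", {
  # one strand of 10 N capacity along +z, demand 5 N
  A <- matrix(c(0, 1), 2, 1) * 10
  sol <- qp(A, c(0, 5), n_act = 1)
  expect_equal(sol$x, 0.5, tolerance = 1e-9)
})

test_that("identical parallel strands share the load equally", {
  A <- matrix(c(0, 10, 0, 10), 2, 2)
  sol <- qp(A, c(0, 5), n_act = 2)
  expect_equal(sol$x, c(0.25, 0.25), tolerance = 1e-9)
})

test_that("grid-search oracle matches the QP objective on planar toys", {
  # exhaustive search over the activation grid, vectorised; feasible points
  # are those meeting the planar (2-DOF) balance exactly
  grid_oracle <- function(A, d, step = 0.01) {
    vals <- seq(0, 1, by = step)
    G <- as.matrix(do.call(expand.grid, rep(list(vals), ncol(A))))
    R <- G %*% t(A)
    feas <- rowSums(abs(sweep(R, 2, d)) > 1e-9) == 0
    min(rowSums(G[feas, , drop = FALSE]^2))
  }
  cases <- list(
    # two orthogonal strands, separable demands on a 2-DOF planar mandible
    list(A = rbind(c(10, 0), c(0, 10)), d = c(2, 5)),
    # redundant pair shares half the load, third strand independent
    list(A = rbind(c(10, 10, 0), c(0, 0, 10)), d = c(5, 4)),
    # saturation: the strong strand hits its bound, the weak one tops up
    list(A = rbind(c(10, 5, 0), c(0, 0, 10)), d = c(14, 6))
  )
  for (cs in cases) {
    oracle <- grid_oracle(cs$A, cs$d)
    sol <- qp(cs$A, cs$d, n_act = ncol(cs$A))
    expect_lt(abs(sum(sol$x^2) - oracle), 1e-3)
    expect_equal(as.numeric(cs$A %*% sol$x), cs$d, tolerance = 1e-8)
  }
})

test_that("doubling strand strength halves an interior solution", {
  A <- rbind(c(10, 8, 3), c(2, 9, 7))
  d <- c(4, 5)
  x1 <- qp(A, d, n_act = 3)$x
  x2 <- qp(2 * A, d, n_act = 3)$x
  expect_true(all(x1 > 0 & x1 < 1))
  expect_equal(x2, x1 / 2, tolerance = 1e-8)
})

test_that("zero demand recruits nothing", {
  model <- default_model()
  res <- solve_step(model, jaw_pose(3, 1), gravity_on = FALSE,
                    passive_on = FALSE)
  expect_true(res$feasible)
  expect_equal(res$activations, rep(0, 150), tolerance = 1e-10)
  expect_equal(res$objective, 0, tolerance = 1e-12)
})

test_that("loaded steps balance to tight residuals with admissible reactions", {
  model <- default_model()
  sch <- recruitment_scheme("crushing", model)
  res <- solve_step(model, jaw_pose(2.5, 4), bolus_force = c(-5, -1, -40),
                    bolus_site = "molar_right",
                    allowed = sch$allowed$slow_closing)
  expect_true(res$feasible)
  expect_lt(res$residual_force, 1e-6)
  expect_lt(res$residual_moment, 1e-4)
  expect_true(all(res$activations >= 0 & res$activations <= 1))
  expect_true(all(res$reaction_magnitudes >= -1e-9))
  for (side in c("right", "left")) {
    adm <- admissible_joint_reaction(
      res$joint_reactions[[side]],
      if (side == "right") model$fossa_normal_right else model$fossa_normal_left)
    expect_true(adm$admissible)
  }
})

test_that("solution is invariant to strand enumeration order", {
  model <- default_model()
  sch <- recruitment_scheme("crushing", model)
  res1 <- solve_step(model, jaw_pose(2.5, 4), bolus_force = c(-5, -1, -40),
                     bolus_site = "molar_right",
                     allowed = sch$allowed$slow_closing)
  set.seed(3)
  perm <- sample(150)
  model2 <- model
  model2$strands <- model$strands[perm]
  model2$strand_table <- model$strand_table[perm, ]
  model2$strand_table$index <- seq_len(150)
  allowed2 <- which(perm %in% sch$allowed$slow_closing)
  res2 <- solve_step(model2, jaw_pose(2.5, 4), bolus_force = c(-5, -1, -40),
                     bolus_site = "molar_right", allowed = allowed2)
  expect_equal(res2$activations, res1$activations[perm], tolerance = 1e-6)
  expect_equal(res2$objective, res1$objective, tolerance = 1e-8)
})

test_that("unreachable demands are flagged infeasible with minimal residual", {
  model <- default_model()
  # a 500 N lateral shove at the molar is far beyond shear capacity
  res <- solve_step(model, jaw_pose(2.5, 4), bolus_force = c(0, -500, 0),
                    bolus_site = "molar_right")
  expect_false(res$feasible)
  expect_gt(res$residual_force, 1e-3)
  # the reported state is still bounded and reactions compressive
  expect_true(all(res$activations >= 0 & res$activations <= 1))
})

test_that("incisor-mode ties force mirrored pairs to equal activation", {
  model <- default_model()
  sch <- recruitment_scheme("incisor", model)
  res <- solve_step(model, jaw_pose(2), bolus_force = c(0, 0, -30),
                    bolus_site = "incisor",
                    allowed = sch$allowed$slow_closing, ties = sch$ties)
  expect_true(res$feasible)
  a <- res$activations
  expect_equal(a[sch$ties[, 1]], a[sch$ties[, 2]], tolerance = 1e-12)
  expect_gt(max(a), 0.05)
})

test_that("recruitment scheme encodes the two muscle groups", {
  model <- default_model()
  sch <- recruitment_scheme("shearing", model)
  tab <- model$strand_table
  g1 <- tab[sch$group1, ]
  expect_true(all(g1$muscle[g1$side == "right"] %in%
                    c("posterior_deep_masseter",
                      "anterior_zygomaticomandibularis",
                      "posterior_zygomaticomandibularis",
                      "superficial_temporalis", "deep_temporalis")))
  expect_true(all(g1$muscle[g1$side == "left"] %in%
                    c("superficial_masseter", "medial_pterygoid",
                      "lateral_pterygoid")))
  # group 2 is the mirror image
  g2 <- tab[sch$group2, ]
  expect_equal(sort(paste(g2$muscle, ifelse(g2$side == "left", "right",
                                            "left"), g2$strand)),
               sort(paste(g1$muscle, g1$side, g1$strand)))
  expect_equal(sch$allowed$opening,
               tab$index[tab$muscle == "digastric"])
  expect_setequal(sch$allowed$slow_closing, c(sch$group1, sch$group2))
})
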