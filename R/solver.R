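# Minimum-effort muscle recruitment along a prescribed motion.
#
# At each timestep the solver finds bounded strand activations and
# admissible (compressive, frictionless) joint reactions satisfying the
# six degree-of-freedom mandible force balance, minimising the sum of
# squared activations. The problem is a convex quadratic program:
#
#   min  sum(a^2) + w_r * sum((r/s_r)^2)
#   s.t. W_a a + W_r r + w_0 = 0,  0 <= a <= 1,  r >= 0
#
# where W_a are strand unit-activation wrenches at the current pose, W_r the
# unit fossa-normal reaction wrenches at the condyles, and w_0 collects the
# known wrenches (gravity, passive tension, bolus force, inertial terms).
# The tiny reaction weight w_r regularises the otherwise unweighted
# reactions; it biases activations by less than 1e-3. The QP is solved with
# the dual active-set method (quadprog) and the solution is polished by an
# exact solve of the reduced KKT system on the free variable set. If the
# balance is unreachable the solver lexicographically minimises the residual
# norm (bounded, ridge-regularised least squares) and flags the step
# infeasible.

MOMENT_SCALE <- 50    # mm; puts moment rows on the force scale
REACTION_SCALE <- 100 # N per unit reaction variable

#' Recruitment scheme for a biting mode
#'
#' Encodes which strands the optimizer may recruit in each phase, following
#' the two-muscle-group structure of rabbit mastication. Group 1 (molar
#' occlusion: working-side posterior deep masseter, anterior and posterior
#' zygomaticomandibularis, superficial and deep temporalis, plus
#' balancing-side superficial masseter, medial and lateral pterygoid) is
#' eligible from fast closing onward; group 2 (its mirror image, producing
#' the shearing return toward the midline) becomes eligible at the onset of
#' slow closing. Opening is driven by the digastrics alone. Incisor biting
#' recruits all closers symmetrically with mirrored strand pairs tied equal.
#'
#' @param mode `"shearing"`, `"crushing"`, `"premolar"` or `"incisor"`.
#' @param model A [build_jaw_model()] model.
#' @return An object of class `recruitment_scheme` with per-phase allowed
#'   strand indices, the group index sets, and (incisor mode) mirrored tie
#'   pairs.
#' @export
recruitment_scheme <- function(mode, model) {
  mode <- match.arg(mode, profile_modes)
  tab <- model$strand_table
  working <- "right"; balancing <- "left"
  g1_muscles_w <- c("posterior_deep_masseter", "anterior_zygomaticomandibularis",
                    "posterior_zygomaticomandibularis", "superficial_temporalis",
                    "deep_temporalis")
  g1_muscles_b <- c("superficial_masseter", "medial_pterygoid",
                    "lateral_pterygoid")
  group1 <- tab$index[(tab$side == working & tab$muscle %in% g1_muscles_w) |
                        (tab$side == balancing & tab$muscle %in% g1_muscles_b)]
  group2 <- tab$index[(tab$side == balancing & tab$muscle %in% g1_muscles_w) |
                        (tab$side == working & tab$muscle %in% g1_muscles_b)]
  closers <- tab$index[tab$is_closer]
  digastric <- tab$index[tab$muscle == "digastric"]
  if (mode == "incisor") {
    allowed <- list(opening = digastric, fast_closing = closers,
                    slow_closing = closers)
    right <- tab[tab$side == "right" & tab$is_closer, ]
    left <- tab[tab$side == "left" & tab$is_closer, ]
    key_r <- paste(right$muscle, right$strand)
    key_l <- paste(left$muscle, left$strand)
    m <- match(key_r, key_l)
    ties <- cbind(right$index, left$index[m])
    ties <- ties[stats::complete.cases(ties), , drop = FALSE]
  } else {
    allowed <- list(opening = digastric, fast_closing = group1,
                    slow_closing = sort(c(group1, group2)))
    ties <- NULL
  }
  structure(list(mode = mode, allowed = allowed, group1 = sort(group1),
                 group2 = sort(group2), closers = closers,
                 digastric = digastric, ties = ties),
            class = "recruitment_scheme")
}

# Per-pose kinetics of every strand and the joint reaction directions:
# unit-activation wrench columns, passive tensions, reaction columns.
step_context <- function(model, pose, law = passive_law(),
                         passive_on = TRUE) {
  tr <- pose_transform(pose, model)
  ref <- tr$t
  n <- length(model$strands)
  W <- matrix(0, 6, n)      # wrench per unit tension
  passive <- numeric(n)
  shares <- numeric(n)
  for (i in seq_len(n)) {
    st <- model$strands[[i]]
    path <- st$path
    mand <- st$frames == "mandible"
    path[mand, ] <- transform_points(tr, path[mand, , drop = FALSE])
    npt <- nrow(path)
    w <- rep(0, 6)
    for (j in which(mand)) {
      f <- c(0, 0, 0)
      for (adj in c(j - 1, j + 1)) {
        if (adj < 1 || adj > npt) next
        seg <- path[adj, ] - path[j, ]
        len <- sqrt(sum(seg^2))
        if (len < 1e-9) stop("degenerate strand segment", call. = FALSE)
        f <- f + seg / len
      }
      w <- w + point_wrench(f, path[j, ], ref)
    }
    W[, i] <- w
    shares[i] <- st$max_force_share
    if (passive_on) {
      d <- diff(path)
      len <- sum(sqrt(rowSums(d^2)))
      strain <- (len - st$rest_length) / st$rest_length
      passive[i] <- passive_tension(strain, st$max_force_share, law)
    }
  }
  Wr <- matrix(0, 6, 2)
  Wr[, 1] <- point_wrench(model$fossa_normal_right,
                          transform_points(tr, model$condyle_right), ref)
  Wr[, 2] <- point_wrench(model$fossa_normal_left,
                          transform_points(tr, model$condyle_left), ref)
  list(tr = tr, ref = ref, W = W, Wr = Wr, passive = passive,
       shares = shares)
}

scale_rows <- function(M) {
  if (is.matrix(M)) M[4:6, ] <- M[4:6, ] / MOMENT_SCALE
  else M[4:6] <- M[4:6] / MOMENT_SCALE
  M
}

# Exact re-solve of the reduced KKT system on the free variable set.
polish_qp <- function(x, A, d, hdiag, n_act) {
  nv <- length(x)
  m <- nrow(A)
  act <- seq_len(n_act)
  at_lo <- x < 1e-9
  at_hi <- rep(FALSE, nv); at_hi[act] <- x[act] > 1 - 1e-9
  free <- !(at_lo | at_hi)
  if (!any(free)) return(NULL)
  rhs <- d - if (any(at_hi)) rowSums(A[, at_hi, drop = FALSE]) else rep(0, m)
  Af <- A[, free, drop = FALSE]
  Hf <- diag(hdiag[free], sum(free))
  K <- rbind(cbind(Hf, t(Af)), cbind(Af, matrix(0, m, m)))
  sol <- tryCatch(solve(K, c(rep(0, sum(free)), rhs)), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  xf <- sol[seq_len(sum(free))]
  xn <- numeric(nv)
  xn[at_hi] <- 1
  xn[free] <- xf
  lo_ok <- all(xn > -1e-7)
  hi_ok <- all(xn[act] < 1 + 1e-7)
  if (!lo_ok || !hi_ok || max(abs(xn - x)) > 1e-5) return(NULL)
  pmin(pmax(xn, 0), ifelse(seq_len(nv) %in% act, 1, Inf))
}

# Bounded, ridge-regularised least squares on the residual: the fallback
# when the equality system is unreachable.
bounded_residual_ls <- function(A, d, n_act, ridge = 1e-8) {
  nv <- ncol(A)
  fn <- function(x) {
    r <- A %*% x - d
    sum(r^2) + ridge * sum(x[seq_len(n_act)]^2)
  }
  gr <- function(x) {
    g <- 2 * crossprod(A, A %*% x - d)
    g[seq_len(n_act)] <- g[seq_len(n_act)] + 2 * ridge * x[seq_len(n_act)]
    as.numeric(g)
  }
  upper <- c(rep(1, n_act), rep(1e7, nv - n_act))
  res <- stats::optim(rep(0, nv), fn, gr, method = "L-BFGS-B",
                      lower = rep(0, nv), upper = upper,
                      control = list(maxit = 2000, factr = 10))
  pmin(pmax(res$par, 0), upper)
}

# Solve the recruitment QP for given wrench columns. A is the scaled 6 x nv
# equality matrix (activation variables first), d the scaled right-hand
# side.
solve_recruitment_qp <- function(A, d, n_act, reac_weight = 1e-2) {
  nv <- ncol(A)
  hdiag <- c(rep(1, n_act), rep(reac_weight, nv - n_act))
  Dmat <- diag(2 * hdiag, nv)
  Amat <- cbind(t(A), diag(nv),
                -diag(nv)[, seq_len(n_act), drop = FALSE])
  bvec <- c(d, rep(0, nv), rep(-1, n_act))
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, rep(0, nv), Amat, bvec, meq = nrow(A)),
    error = function(e) NULL)
  if (is.null(sol)) {
    x <- bounded_residual_ls(A, d, n_act)
    return(list(x = x, qp_ok = FALSE))
  }
  x <- pmin(pmax(sol$solution, 0), c(rep(1, n_act), rep(Inf, nv - n_act)))
  xp <- polish_qp(x, A, d, 2 * hdiag, n_act)
  if (!is.null(xp)) x <- xp
  list(x = x, qp_ok = TRUE)
}

#' Solve one recruitment timestep
#'
#' Finds the minimum-effort activations of the allowed strands and the
#' compressive joint reactions that balance the mandible at the given pose
#' under the known external wrenches. If the required wrench is unreachable
#' the residual norm is minimised instead and the step is flagged
#' infeasible.
#'
#' @param model A [build_jaw_model()] model.
#' @param pose A [jaw_pose()]; its velocity/acceleration drive the inertial
#'   terms when `dynamic = TRUE`.
#' @param bolus_force Known force on the lower bolus plate (N), or `NULL`.
#' @param bolus_site Bite point at which `bolus_force` acts.
#' @param allowed Integer indices of recruitable strands (default: all).
#' @param ties Optional two-column matrix of strand index pairs constrained
#'   to equal activation (mirrored pairs in incisor biting).
#' @param gravity_on,dynamic,law,passive_on See [equilibrium_residual()].
#' @param force_tol,moment_tol Feasibility tolerances on the residual, N and
#'   N mm.
#' @return An object of class `solver_result`: full activation vector,
#'   per-condyle reactions, residual, objective and feasibility flag.
#' @export
solve_step <- function(model, pose, bolus_force = NULL,
                       bolus_site = "incisor",
                       allowed = seq_along(model$strands), ties = NULL,
                       gravity_on = TRUE, dynamic = FALSE,
                       law = passive_law(), passive_on = TRUE,
                       force_tol = 1e-6, moment_tol = 1e-4) {
  ctx <- step_context(model, pose, law, passive_on)
  w0 <- as.numeric(ctx$W %*% ctx$passive)
  if (gravity_on) w0 <- w0 + gravity_wrench(model, pose, ctx$ref)
  if (!is.null(bolus_force)) {
    p <- transform_points(ctx$tr, model$bite_points[[bolus_site]])
    w0 <- w0 + point_wrench(bolus_force, p, ctx$ref)
  }
  if (dynamic) w0 <- w0 - inertial_wrench(model, pose, ctx$ref)

  # activation variables: merge tied pairs into single variables
  allowed <- sort(allowed)
  if (!is.null(ties)) {
    ties <- ties[ties[, 1] %in% allowed & ties[, 2] %in% allowed, ,
                 drop = FALSE]
    tied <- c(ties)
    singles <- setdiff(allowed, tied)
    var_members <- c(lapply(seq_len(nrow(ties)), function(k) ties[k, ]),
                     as.list(singles))
  } else {
    var_members <- as.list(allowed)
  }
  n_act <- length(var_members)
  cols_act <- vapply(var_members, function(idx) {
    as.numeric(ctx$W[, idx, drop = FALSE] %*% ctx$shares[idx])
  }, numeric(6))
  A <- cbind(cols_act, ctx$Wr * REACTION_SCALE)
  A_s <- scale_rows(A)
  d_s <- scale_rows(-w0)
  sol <- solve_recruitment_qp(A_s, d_s, n_act)
  x <- sol$x
  activations <- numeric(length(model$strands))
  for (k in seq_len(n_act)) activations[var_members[[k]]] <- x[k]
  reactions <- x[n_act + 1:2] * REACTION_SCALE
  residual <- as.numeric(A %*% x + w0)
  feasible <- sol$qp_ok &&
    max(abs(residual[1:3])) <= force_tol &&
    max(abs(residual[4:6])) <= moment_tol
  structure(list(
    activations = activations,
    joint_reactions = list(
      right = reactions[1] * model$fossa_normal_right,
      left = reactions[2] * model$fossa_normal_left),
    reaction_magnitudes = c(right = reactions[1], left = reactions[2]),
    residual = residual,
    residual_force = max(abs(residual[1:3])),
    residual_moment = max(abs(residual[4:6])),
    objective = sum(activations[allowed]^2),
    feasible = feasible
  ), class = "solver_result")
}

#' @export
print.solver_result <- function(x, ...) {
  cat(sprintf(
    "<solver_result> %s, objective %.4g, max |F| residual %.2e N, max |M| residual %.2e N mm\n",
    if (x$feasible) "feasible" else "INFEASIBLE", x$objective,
    x$residual_force, x$residual_moment))
  invisible(x)
}

#' Solve recruitment along a full motion profile
#'
#' Runs [solve_step()] at every timestep of a motion profile: evaluates the
#' pose, the bolus spring displacement and force, and the phase-dependent
#' allowed strand set, and collects activation, bite-force and joint
#' reaction time series.
#'
#' @param model A model.
#' @param profile A [motion_profile()].
#' @param bolus An attached bolus ([attach_bolus()]).
#' @param scheme A [recruitment_scheme()]; defaults to the profile's mode.
#' @param gravity_on,dynamic,law,passive_on Passed to [solve_step()].
#' @return An object of class `mastication_sim`; see [tidy.mastication_sim()]
#'   and [glance.mastication_sim()].
#' @export
solve_trajectory <- function(model, profile, bolus, scheme = NULL,
                             gravity_on = TRUE, dynamic = FALSE,
                             law = passive_law(), passive_on = TRUE) {
  if (is.null(scheme)) scheme <- recruitment_scheme(profile$mode, model)
  if (anyNA(bolus$stiffness)) bolus <- attach_bolus(bolus, model)
  times <- profile$times
  nt <- length(times)
  ns <- length(model$strands)
  act <- matrix(0, nt, ns)
  bolus_f <- matrix(0, nt, 3)
  react <- matrix(0, nt, 2)
  resid_f <- numeric(nt)
  resid_m <- numeric(nt)
  objective <- numeric(nt)
  feasible <- logical(nt)
  compression <- numeric(nt)
  site_pt <- model$bite_points[[bolus$site]]
  dt_s <- profile$dt * 1e-3
  for (i in seq_len(nt)) {
    pose <- jaw_pose(profile$sagittal[i], profile$frontal[i])
    if (dynamic) {
      qs <- function(j) c(profile$sagittal[j], profile$frontal[j], 0, 0, 0, 0)
      jm <- max(1, i - 1); jp <- min(nt, i + 1)
      pose$velocity <- (qs(jp) - qs(jm)) / ((jp - jm) * dt_s)
      pose$acceleration <- if (i > 1 && i < nt) {
        (qs(jp) - 2 * qs(i) + qs(jm)) / dt_s^2
      } else rep(0, 6)
    }
    gap <- tooth_gap(model, bolus$site, profile$sagittal[i],
                     profile$frontal[i])
    dc <- bolus$height - gap
    engaged <- profile$phase[i] == "slow_closing" && dc > -1e-9
    if (engaged) {
      p_now <- body_point_world(model, pose, site_pt)
      disp <- c(p_now[1:2] - profile$grip_point[1:2], max(dc, 0))
      fb <- bolus_force(bolus, disp)
      compression[i] <- max(dc, 0)
    } else {
      fb <- NULL
    }
    res <- solve_step(model, pose, bolus_force = fb,
                      bolus_site = bolus$site,
                      allowed = scheme$allowed[[profile$phase[i]]],
                      ties = scheme$ties,
                      gravity_on = gravity_on, dynamic = dynamic,
                      law = law, passive_on = passive_on)
    act[i, ] <- res$activations
    if (engaged) bolus_f[i, ] <- fb
    react[i, ] <- res$reaction_magnitudes
    resid_f[i] <- res$residual_force
    resid_m[i] <- res$residual_moment
    objective[i] <- res$objective
    feasible[i] <- res$feasible
  }
  series <- tibble::tibble(
    time = times, phase = profile$phase,
    sagittal = profile$sagittal, frontal = profile$frontal,
    compression = compression,
    bolus_fx = bolus_f[, 1], bolus_fy = bolus_f[, 2], bolus_fz = bolus_f[, 3],
    bite_fx = -bolus_f[, 1], bite_fy = -bolus_f[, 2], bite_fz = -bolus_f[, 3],
    joint_right = react[, 1], joint_left = react[, 2],
    residual_force = resid_f, residual_moment = resid_m,
    objective = objective, feasible = feasible
  )
  structure(list(
    mode = profile$mode, series = series, activations = act,
    model = model, profile = profile, bolus = bolus, scheme = scheme
  ), class = "mastication_sim")
}

#' @export
print.mastication_sim <- function(x, ...) {
  s <- x$series
  slow <- s[s$phase == "slow_closing", ]
  cat(sprintf("<mastication_sim> %s: %d steps (%d ms), %d strands\n",
              x$mode, nrow(s), max(s$time), ncol(x$activations)))
  cat(sprintf("  feasible steps: %d/%d; peak bite force %.1f N\n",
              sum(s$feasible), nrow(s),
              max(sqrt(slow$bite_fx^2 + slow$bite_fy^2 + slow$bite_fz^2))))
  invisible(x)
}
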