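# Orchestration of the biting experiments and the reported statistics.

#' Simulation configuration
#'
#' Collects the tunable run parameters with their defaults: phase durations
#' (opening 90 ms, fast closing 50 ms, slow closing 140 ms), 1 ms timestep,
#' 12 degree maximal sagittal gape, 4 degree working-side frontal rotation,
#' 25 N cm^-2 muscle stress, 75 strands per side, gravity and passive
#' tension on, and the synthetic-geometry parameters.
#'
#' @param ... Overrides of the defaults (matched by name; unknown names are
#'   an error). `geometry` and `bolus` take named lists of overrides for
#'   [synthetic_jaw_geometry()] and [make_bolus()].
#' @return A named list of class `mastication_config`.
#' @export
mastication_config <- function(...) {
  cfg <- list(
    phase_durations = c(90, 50, 140),
    dt = 1,
    max_sagittal = 12,
    max_frontal = 4,
    muscle_stress = 25,
    n_per_side = 75,
    gravity_on = TRUE,
    passive_on = TRUE,
    dynamic = FALSE,
    geometry = list(),
    bolus = list()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "mastication_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path File path.
#' @param config A [mastication_config()].
#' @return `read_config()` returns a validated configuration;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(mastication_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_model <- function(config) {
  geometry <- do.call(synthetic_jaw_geometry, config$geometry)
  build_jaw_model(geometry = geometry, n_per_side = config$n_per_side,
                  muscle_stress = config$muscle_stress)
}

#' Run one biting-mode simulation
#'
#' Executes the full three-phase reduction bite cycle for one mode: molar
#' shearing, molar crushing, incisor biting or premolar crushing. The food
#' bolus for the mode is built and attached at the mode's bite point (the
#' most posterior right molar for the molar modes, the right premolar for
#' premolar crushing, the incisor for incisor biting), the motion profile is
#' constructed so the slow-closing phase ends at half bolus compression, and
#' the recruitment scheme's muscle groups are solved timestep by timestep.
#'
#' @param mode `"shearing"`, `"crushing"`, `"incisor"` or `"premolar"`.
#' @param config A [mastication_config()].
#' @param model Optional prebuilt model (rebuilt from `config` if `NULL`).
#' @return A `mastication_sim` (see [solve_trajectory()]).
#' @export
run_mode <- function(mode, config = mastication_config(), model = NULL) {
  mode <- match.arg(mode, profile_modes)
  if (is.null(model)) model <- config_model(config)
  bolus_args <- config$bolus
  bolus_args$mode <- switch(mode, premolar = "crushing",
                            shearing = "shearing", crushing = "crushing",
                            incisor = "incisor")
  if (mode == "premolar" && is.null(bolus_args$site)) {
    bolus_args$site <- "premolar_right"
  }
  bolus <- attach_bolus(do.call(make_bolus, bolus_args), model,
                        max_frontal = config$max_frontal)
  profile <- motion_profile(mode, model, bolus,
                            phase_durations = config$phase_durations,
                            max_sagittal = config$max_sagittal,
                            max_frontal = config$max_frontal,
                            dt = config$dt)
  solve_trajectory(model, profile, bolus,
                   scheme = recruitment_scheme(mode, model),
                   gravity_on = config$gravity_on,
                   dynamic = config$dynamic,
                   passive_on = config$passive_on)
}

#' Bite-force component decomposition
#'
#' Splits a bite-force vector into its anteroposterior, mediolateral and
#' vertical components, the resultant, and each component's percentage of
#' the resultant (so the squared percentages sum to one).
#'
#' @param force Bite force 3-vector `(anteroposterior, mediolateral,
#'   vertical)`, N.
#' @param site,mode Optional labels carried into the record.
#' @return An object of class `bite_record`.
#' @export
bite_force_components <- function(force, site = NULL, mode = NULL) {
  stopifnot(length(force) == 3)
  resultant <- sqrt(sum(force^2))
  if (resultant == 0) {
    stop("bite force is zero: component percentages undefined", call. = FALSE)
  }
  comp <- stats::setNames(as.numeric(force),
                          c("anteroposterior", "mediolateral", "vertical"))
  structure(list(
    resultant = resultant,
    components = comp,
    percentages = 100 * abs(comp) / resultant,
    site = site, mode = mode
  ), class = "bite_record")
}

#' @export
print.bite_record <- function(x, ...) {
  cat(sprintf("<bite_record>%s resultant %.1f N\n",
              if (!is.null(x$mode)) paste0(" ", x$mode, ":") else "",
              x$resultant))
  p <- x$percentages
  cat(sprintf("  components (N): ap %.1f, ml %.1f, vertical %.1f (%.1f / %.1f / %.1f %% of resultant)\n",
              x$components[1], x$components[2], x$components[3],
              p[1], p[2], p[3]))
  invisible(x)
}

#' Peak bite-force record of a simulation
#'
#' The bite force transmitted through the bolus (equal and opposite to the
#' spring force on the mandible) at the instant of peak resultant during the
#' slow-closing phase.
#'
#' @param sim A `mastication_sim`.
#' @return A [bite_force_components()] record.
#' @export
peak_bite_record <- function(sim) {
  s <- sim$series
  slow <- which(s$phase == "slow_closing")
  resultant <- sqrt(s$bite_fx^2 + s$bite_fy^2 + s$bite_fz^2)
  i <- slow[which.max(resultant[slow])]
  rec <- bite_force_components(c(s$bite_fx[i], s$bite_fy[i], s$bite_fz[i]),
                               site = sim$bolus$site, mode = sim$mode)
  rec$time <- s$time[i]
  rec
}

#' Maximum incisor bite force
#'
#' Reproduces the maximum-bite-force experiment: a rigid bolus at the
#' incisors with the jaw at the measurement gape, every jaw closer at 100%
#' activation, and the six degree-of-freedom static balance solved for the
#' bite reaction and the compressive condylar reactions.
#'
#' @param model A model.
#' @param gape_mm Incisal gape at which the bite is taken, mm (default 5.5).
#' @param gravity_on Include gravity (default `TRUE`).
#' @param law,passive_on Passive tension law and switch.
#' @return A [bite_force_components()] record with the joint reactions, the
#'   static residual norm and an `indeterminate` flag (set if the reaction
#'   model cannot close the balance or a condylar reaction is tensile).
#' @export
max_incisor_bite_force <- function(model, gape_mm = 5.5, gravity_on = TRUE,
                                   law = passive_law(), passive_on = TRUE) {
  pose <- jaw_pose(sagittal_for_gape(model, gape_mm))
  ctx <- step_context(model, pose, law, passive_on)
  closer <- model$strand_table$is_closer
  tension <- ctx$shares * as.numeric(closer) + ctx$passive
  w0 <- as.numeric(ctx$W %*% tension)
  if (gravity_on) w0 <- w0 + gravity_wrench(model, pose, ctx$ref)
  p_inc <- transform_points(ctx$tr, model$bite_points$incisor)
  B <- vapply(1:3, function(k) {
    point_wrench(diag(3)[, k], p_inc, ctx$ref)
  }, numeric(6))
  A <- cbind(B, ctx$Wr)
  A_s <- scale_rows(A)
  d_s <- scale_rows(-w0)
  u <- qr.solve(A_s, d_s)
  residual <- as.numeric(A %*% u + w0)
  f_mand <- u[1:3]         # bolus force on the mandible
  reactions <- u[4:5]
  indeterminate <- max(abs(residual[1:3])) > 1e-6 ||
    max(abs(residual[4:6])) > 1e-4 || any(reactions < -1e-9)
  rec <- bite_force_components(-f_mand, site = "incisor", mode = "maxbite")
  rec$gape_mm <- gape_mm
  rec$joint_reactions <- stats::setNames(reactions, c("right", "left"))
  rec$residual <- residual
  rec$indeterminate <- indeterminate
  rec
}

#' Recruited fraction of the total available muscle force
#'
#' The activation-weighted total jaw-closer force divided by the total
#' available closer force (both sides, digastric excluded), as a
#' percentage: `100 * sum(a_i F_i) / sum(F_i)`.
#'
#' For a simulation, the snapshot defaults to the instant of peak total
#' recruited force. For a data frame of per-muscle peak activation
#' percentages (columns `muscle`, `activation`), the weighted sum runs over
#' the architecture's closer maximum forces, with both sides assumed to
#' follow the given activations unless a `side` column provides them
#' separately.
#'
#' @param x A `mastication_sim` or a data frame.
#' @param ... Method arguments.
#' @return Recruited fraction in percent.
#' @export
recruited_fraction <- function(x, ...) UseMethod("recruited_fraction")

#' @rdname recruited_fraction
#' @param at `"peak_total"` (default) or a time in ms.
#' @export
recruited_fraction.mastication_sim <- function(x, at = "peak_total", ...) {
  closer <- x$model$strand_table$is_closer
  shares <- x$model$strand_table$max_force_share
  tot <- as.numeric(x$activations[, closer, drop = FALSE] %*% shares[closer])
  i <- if (identical(at, "peak_total")) {
    which.max(tot)
  } else {
    which.min(abs(x$series$time - at))
  }
  100 * tot[i] / sum(shares[closer])
}

#' @rdname recruited_fraction
#' @param architecture Architecture tibble with `muscle` and `max_force`
#'   (one side); default [rabbit_muscle_architecture()].
#' @export
recruited_fraction.data.frame <- function(x, architecture =
                                            rabbit_muscle_architecture(),
                                          ...) {
  arch <- architecture[architecture$muscle != "digastric", ]
  if (!all(c("muscle", "activation") %in% names(x))) {
    stop("need columns 'muscle' and 'activation' (percent)", call. = FALSE)
  }
  if (!"side" %in% names(x)) {
    x <- dplyr::bind_rows(
      dplyr::mutate(x, side = "right"), dplyr::mutate(x, side = "left"))
  }
  merged <- dplyr::inner_join(x, arch[, c("muscle", "max_force")],
                              by = "muscle")
  if (nrow(merged) < 2 * nrow(arch)) {
    missing <- setdiff(arch$muscle, x$muscle)
    if (length(missing)) {
      stop("activation table missing muscle(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  100 * sum(merged$activation / 100 * merged$max_force) /
    (2 * sum(arch$max_force))
}

#' Per-muscle peak activation table
#'
#' For each muscle part and side, the force-weighted mean strand activation
#' is tracked over the cycle and its peak reported as a percentage of
#' maximum force. In incisor mode the two sides are symmetric and a single
#' side-averaged value is reported per muscle.
#'
#' @param sim A `mastication_sim`.
#' @return A tibble with `muscle`, `side`, `peak_activation` (percent).
#' @export
peak_activation_table <- function(sim) {
  tab <- sim$model$strand_table
  closers <- tab[tab$is_closer, ]
  out <- dplyr::group_modify(
    dplyr::group_by(closers, .data$muscle, .data$side),
    function(g, key) {
      w <- g$max_force_share / sum(g$max_force_share)
      series <- as.numeric(sim$activations[, g$index, drop = FALSE] %*% w)
      tibble::tibble(peak_activation = 100 * max(series))
    })
  out <- dplyr::ungroup(out)
  if (sim$mode == "incisor") {
    out <- dplyr::summarise(dplyr::group_by(out, .data$muscle),
                            side = "both",
                            peak_activation = mean(.data$peak_activation),
                            .groups = "drop")
  }
  out$muscle <- factor(out$muscle, levels = jaw_closer_parts())
  dplyr::arrange(out, .data$muscle)
}

#' Compare a predicted bite force with measured statistics
#'
#' @param bite A [bite_force_components()] record or a numeric force, N.
#' @param mean_force,sd_force Mean and standard deviation of the measured
#'   maximal incisor bite forces, N (defaults 69.1 and 13.3).
#' @param abs_max Absolute maximum measured force, N (default 95.2).
#' @return One-row tibble with the z-score, the within-one-standard-
#'   deviation flag and below-absolute-maximum flags (weak and strict).
#' @export
compare_with_measured <- function(bite, mean_force = 69.1, sd_force = 13.3,
                                  abs_max = 95.2) {
  if (inherits(bite, "bite_record")) bite <- bite$resultant
  if (sd_force <= 0) stop("sd_force must be positive", call. = FALSE)
  z <- (bite - mean_force) / sd_force
  tibble::tibble(
    predicted = bite, measured_mean = mean_force, measured_sd = sd_force,
    measured_abs_max = abs_max, z = z,
    within_1sd = abs(z) <= 1,
    below_abs_max = bite <= abs_max,
    strictly_below_abs_max = bite < abs_max
  )
}

#' Published reference peak activations
#'
#' Peak activation values (percent of maximum force) of the jaw closer
#' muscles during molar shearing, molar crushing and incisor biting,
#' reported for an adult rabbit in the experimental literature. Shipped as
#' a plain-text fixture; used to benchmark the recruited-fraction
#' arithmetic.
#'
#' @return Tibble with columns `muscle`, `mode`, `side`, `activation`
#'   (percent).
#' @export
reference_peak_activations <- function() {
  path <- system.file("extdata", "reference_peak_activations.csv",
                      package = "masticate", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
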