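# Prescribed jaw kinematics: the three-phase reduction bite cycle.
#
# Phases: (i) opening (sagittal 0 -> max gape), (ii) fast closing (max gape
# down to food contact; frontal rotation toward the working side develops),
# (iii) slow closing / power stroke (the bolus is compressed to half its
# height; shearing returns the jaw to the midline, crushing holds the
# lateral rotation, incisor biting stays in the midline). Waypoints are
# joined with cosine ramps; within the slow-closing phase the sagittal angle
# is solved at each instant so that the bolus compression follows its ramp.

cos_ramp <- function(u) (1 - cos(pi * pmin(pmax(u, 0), 1))) / 2

# Vertical drop (mm) of a mandibular tooth point below its closed-pose
# position: the local gape at that bite point.
tooth_gap <- function(model, site, sagittal, frontal = 0) {
  p <- model$bite_points[[site]]
  z_now <- body_point_world(model, jaw_pose(sagittal, frontal), p)[3]
  p[3] - z_now
}

# Sagittal angle at which the gap at `site` equals `gap` mm (frontal held).
sagittal_for_gap <- function(model, site, gap, frontal = 0, upper = 30) {
  stats::uniroot(function(th) tooth_gap(model, site, th, frontal) - gap,
                 lower = 0, upper = upper, tol = 1e-10)$root
}

#' Incisal gape of a pose
#'
#' Vertical separation (mm) of the incisal bite points (mandibular incisor
#' point below its occlusal position) under a pose.
#'
#' @param pose A [jaw_pose()].
#' @param model A [build_jaw_model()] model.
#' @return Gape in mm.
#' @export
incisal_gape_mm <- function(pose, model) {
  p <- model$bite_points$incisor
  p[3] - body_point_world(model, pose, p)[3]
}

#' Sagittal angle producing a given incisal gape
#'
#' Root-finding inverse of [incisal_gape_mm()] at midline frontal rotation.
#'
#' @param model A model.
#' @param gape_mm Target incisal gape, mm.
#' @return Sagittal angle in degrees.
#' @export
sagittal_for_gape <- function(model, gape_mm) {
  sagittal_for_gap(model, "incisor", gape_mm)
}

profile_modes <- c("shearing", "crushing", "incisor", "premolar")

#' Prescribed motion profile for a biting mode
#'
#' Builds the three-phase gape-angle trajectory for one reduction bite
#' cycle. The sagittal angle rises to `max_sagittal` during opening, falls
#' to the food-contact angle during fast closing (while the frontal angle
#' rotates to `max_frontal` toward the working side in the molar modes), and
#' during slow closing is solved so the bolus vertical compression follows a
#' cosine ramp to half the bolus height. Shearing returns the frontal angle
#' to the midline during slow closing; crushing (and premolar crushing)
#' holds it; incisor biting keeps the frontal angle at zero throughout.
#'
#' @param mode `"shearing"`, `"crushing"`, `"incisor"` or `"premolar"`.
#' @param model A [build_jaw_model()] model.
#' @param bolus The attached [make_bolus()] bolus (supplies height and site).
#' @param phase_durations Durations (ms) of (opening, fast closing, slow
#'   closing); default `c(90, 50, 140)`. Only the 140 ms slow close is
#'   empirically anchored; the others are literature-consistent defaults.
#' @param max_sagittal Maximal sagittal gape angle, degrees (default 12).
#' @param max_frontal Working-side frontal rotation, degrees (default 4).
#' @param dt Timestep, ms (default 1).
#' @return An object of class `motion_profile`.
#' @export
motion_profile <- function(mode, model, bolus,
                           phase_durations = c(90, 50, 140),
                           max_sagittal = 12, max_frontal = 4, dt = 1) {
  mode <- match.arg(mode, profile_modes)
  stopifnot(length(phase_durations) == 3, all(phase_durations > 0), dt > 0)
  site <- bolus$site
  h <- bolus$height
  frontal_target <- if (mode %in% c("incisor")) 0 else max_frontal
  sagittal_contact <- sagittal_for_gap(model, site, h, frontal_target)
  if (sagittal_contact >= max_sagittal) {
    stop("bolus too tall: contact angle exceeds the maximal gape",
         call. = FALSE)
  }
  t1 <- phase_durations[1]; t2 <- phase_durations[2]; t3 <- phase_durations[3]
  total <- t1 + t2 + t3
  # The power stroke is asymmetric: compression of the bolus is front-loaded
  # (the food yields early, sin ramp) while the shearing return to the
  # midline accelerates late (cos ramp), reproducing the in vivo sequence in
  # which the occlusion group peaks before the shearing group.
  frontal_slow <- function(s) {
    switch(mode,
      shearing = frontal_target * cos(pi * pmin(pmax(s, 0), 1) / 2),
      crushing = ,
      premolar = frontal_target,
      incisor = 0)
  }
  sagittal_slow <- function(s) {
    target_gap <- h - (h / 2) * sin(pi * pmin(pmax(s, 0), 1) / 2)
    sagittal_for_gap(model, site, target_gap, frontal_slow(s),
                     upper = max_sagittal + 5)
  }
  angle_fun <- function(t) {
    if (t < 0 || t > total) stop("time outside the bite cycle", call. = FALSE)
    if (t <= t1) {
      c(max_sagittal * cos_ramp(t / t1), 0)
    } else if (t <= t1 + t2) {
      u <- (t - t1) / t2
      c(max_sagittal + (sagittal_contact - max_sagittal) * cos_ramp(u),
        frontal_target * cos_ramp(u))
    } else {
      s <- (t - t1 - t2) / t3
      c(sagittal_slow(s), frontal_slow(s))
    }
  }
  times <- seq(0, total, by = dt)
  ang <- vapply(times, angle_fun, numeric(2))
  phase <- cut(times, breaks = c(-Inf, t1, t1 + t2, Inf),
               labels = c("opening", "fast_closing", "slow_closing"))
  phase[times == t1] <- "opening" # boundary instants close the earlier phase
  grip <- body_point_world(model, jaw_pose(sagittal_contact, frontal_target),
                           model$bite_points[[site]])
  structure(list(
    mode = mode, site = site, bolus_height = h,
    phase_durations = phase_durations, dt = dt, total = total,
    max_sagittal = max_sagittal, max_frontal = max_frontal,
    sagittal_contact = sagittal_contact, grip_point = grip,
    times = times, sagittal = ang[1, ], frontal = ang[2, ],
    phase = as.character(phase), angle_fun = angle_fun,
    working_side = "right"
  ), class = "motion_profile")
}

#' @export
print.motion_profile <- function(x, ...) {
  cat(sprintf(
    "<motion_profile> %s: phases %s ms, max sagittal %g deg, contact at %.2f deg\n",
    x$mode, paste(x$phase_durations, collapse = "/"), x$max_sagittal,
    x$sagittal_contact))
  invisible(x)
}

#' Gape angles at a time point
#'
#' Evaluates a motion profile's sagittal and frontal angle trajectories.
#'
#' @param profile A [motion_profile()].
#' @param t Time in ms, within `[0, sum(phase_durations)]`.
#' @return Named numeric vector `c(sagittal, frontal)` in degrees.
#' @export
gape_angles <- function(profile, t) {
  a <- profile$angle_fun(t)
  c(sagittal = a[1], frontal = a[2])
}

#' Time of first food contact
#'
#' Scans a motion profile for the first instant at which the vertical gap at
#' the bolus site has closed to the bolus height, i.e. the plates touch the
#' food and the slow-closing (power-stroke) phase begins.
#'
#' @param profile A [motion_profile()].
#' @param bolus A bolus (its height and site are used).
#' @param model The model.
#' @return Contact time in ms.
#' @export
contact_time <- function(profile, bolus, model) {
  gaps <- vapply(seq_along(profile$times), function(i) {
    tooth_gap(model, bolus$site, profile$sagittal[i], profile$frontal[i])
  }, numeric(1))
  # contact can only happen while closing (after peak opening)
  i_peak <- which.max(profile$sagittal)
  idx <- which(gaps <= bolus$height + 1e-9)
  idx <- idx[idx >= i_peak]
  if (!length(idx)) {
    stop("no bolus contact within the bite cycle", call. = FALSE)
  }
  profile$times[idx[1]]
}
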