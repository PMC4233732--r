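# Food bolus: two rigid plates joined by a capped tri-axial linear spring.
#
# The lower plate is tied to the mandibular tooth point at the bite site and
# the upper plate to the opposing maxillary point (the closed-pose position
# of the same tooth point, plus the bolus height). Each world axis carries a
# spring force proportional to the relative plate displacement, saturating
# at that axis' force cap. The vertical spring acts only in compression;
# the shear springs act in both directions.

bolus_modes <- c("shearing", "crushing", "incisor", "rigid")

#' Construct a food bolus
#'
#' Mode defaults: crushing — height 1.3 mm, vertical cap 100 N (complete
#' compression of a carrot-like bolus); shearing — height 1.3 mm, caps
#' (20, 20, 60) N in the anteroposterior, mediolateral and vertical
#' directions (hay/straw-like resistance); incisor — height 2.4 mm with the
#' same vertical law as crushing; rigid — a bolus stiff enough to compress
#' less than 1 um under 500 N, used for maximum-bite-force simulation.
#'
#' Vertical stiffness is cap / height so the cap is reached exactly at full
#' compression. Shear stiffnesses are food properties resolved against the
#' model geometry when the bolus is attached (see [attach_bolus()]): the
#' shear cap is reached when the lower plate has traversed the full
#' excursion of the working molar point over the 4 degree frontal return.
#'
#' @param mode One of `"shearing"`, `"crushing"`, `"incisor"`, `"rigid"`.
#' @param site Bite point name; defaults to `"molar_right"` for the molar
#'   modes, `"incisor"` for incisor/rigid.
#' @param height Bolus height, mm (mode default if `NULL`).
#' @param caps Force caps `(anteroposterior, mediolateral, vertical)`, N.
#' @param stiffness Optional explicit stiffness 3-vector, N mm^-1; if `NULL`
#'   the vertical stiffness is cap/height and shear stiffnesses are resolved
#'   geometrically by [attach_bolus()].
#' @return An object of class `food_bolus`.
#' @export
make_bolus <- function(mode, site = NULL, height = NULL, caps = NULL,
                       stiffness = NULL) {
  if (!mode %in% bolus_modes) {
    stop("unknown bolus mode '", mode, "'", call. = FALSE)
  }
  defaults <- switch(mode,
    shearing = list(site = "molar_right", height = 1.3, caps = c(20, 20, 60)),
    crushing = list(site = "molar_right", height = 1.3, caps = c(20, 20, 100)),
    incisor  = list(site = "incisor", height = 2.4, caps = c(20, 20, 100)),
    rigid    = list(site = "incisor", height = 0.0,
                    caps = c(Inf, Inf, Inf))
  )
  site <- site %||% defaults$site
  height <- height %||% defaults$height
  caps <- caps %||% defaults$caps
  if (mode != "rigid" && height <= 0) stop("bolus height must be positive",
                                           call. = FALSE)
  if (any(caps < 0)) stop("force caps must be non-negative", call. = FALSE)
  if (is.null(stiffness)) {
    stiffness <- c(NA_real_, NA_real_,
                   if (mode == "rigid") 1e6 else caps[3] / height)
  }
  structure(list(mode = mode, site = site, height = height, caps = caps,
                 stiffness = stiffness), class = "food_bolus")
}

#' @export
print.food_bolus <- function(x, ...) {
  cat(sprintf("<food_bolus> %s at %s: height %.2f mm, caps (%s) N\n",
              x$mode, x$site, x$height,
              paste(format(x$caps, digits = 3), collapse = ", ")))
  cat("  stiffness (N/mm):",
      paste(format(x$stiffness, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

# Mediolateral excursion of the working molar point over the frontal return
# at the contact sagittal angle: the shear travel that calibrates the spring.
# A small floor guards against degenerate travel.
shear_travel <- function(model, sagittal_contact, max_frontal = 4,
                         site = "molar_right", floor_mm = 0.02) {
  p <- model$bite_points[[site]]
  at <- function(f) body_point_world(model, jaw_pose(sagittal_contact, f), p)
  d <- at(max_frontal) - at(0)
  max(abs(d[2]), floor_mm)
}

#' Attach a bolus to a model, resolving shear stiffness from geometry
#'
#' Computes the mediolateral shear travel of the working molar point over
#' the slow-closing shearing movement (the 4 degree frontal return at the
#' contact gape) and sets the shear stiffness of both horizontal axes to
#' cap / travel, so the mediolateral resistance saturates exactly when the
#' full return excursion has been traversed. The resolved stiffness is a
#' food property: all modes share the shearing-movement calibration.
#'
#' @param bolus A [make_bolus()] bolus.
#' @param model A [build_jaw_model()] model.
#' @param sagittal_contact Sagittal angle at food contact, degrees; if
#'   `NULL` it is solved from the bolus height at the molar site.
#' @param max_frontal Frontal working-side rotation, degrees (default 4).
#' @return The bolus with numeric `stiffness` fully resolved.
#' @export
attach_bolus <- function(bolus, model, sagittal_contact = NULL,
                         max_frontal = 4) {
  if (!bolus$site %in% names(model$bite_points)) {
    stop("model has no bite point '", bolus$site, "'", call. = FALSE)
  }
  if (bolus$mode == "rigid") {
    bolus$stiffness <- c(1e6, 1e6, 1e6)
    return(bolus)
  }
  if (is.null(sagittal_contact)) {
    sagittal_contact <- sagittal_for_gap(model, "molar_right", 1.3,
                                         frontal = max_frontal)
  }
  travel <- shear_travel(model, sagittal_contact, max_frontal)
  if (is.na(bolus$stiffness[1])) bolus$stiffness[1] <- bolus$caps[1] / travel
  if (is.na(bolus$stiffness[2])) bolus$stiffness[2] <- bolus$caps[2] / travel
  bolus
}

#' Bolus spring force on the lower plate
#'
#' Per-axis force proportional to the relative plate displacement with
#' saturation at the axis cap, sign opposing the displacement. The
#' displacement convention is `(dx, dy, dc)`: `dx`, `dy` are the horizontal
#' (anteroposterior, mediolateral) offsets of the lower plate from its grip
#' position at food contact, and `dc` is the vertical compression of the
#' bolus (positive when the plates have approached by more than the rest
#' height). The vertical component acts only in compression (`dc > 0`); an
#' equal and opposite force acts on the upper plate (cranium).
#'
#' @param bolus A bolus with resolved stiffness (see [attach_bolus()]).
#' @param displacement Displacement 3-vector `(dx, dy, dc)`, mm.
#' @return Force on the lower plate, N (world axes).
#' @export
bolus_force <- function(bolus, displacement) {
  k <- bolus$stiffness
  if (anyNA(k)) {
    stop("bolus shear stiffness unresolved; call attach_bolus() first",
         call. = FALSE)
  }
  f <- numeric(3)
  for (ax in 1:2) {
    d <- displacement[ax]
    f[ax] <- -sign(d) * min(k[ax] * abs(d), bolus$caps[ax])
  }
  dc <- displacement[3]
  f[3] <- if (dc > 0) -min(k[3] * dc, bolus$caps[3]) else 0
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a
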