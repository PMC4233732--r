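# Synthetic rabbit-scale jaw geometry: landmarks and muscle attachment sites.
#
# Coordinate convention (mm): right-handed, origin at the midpoint between the
# mandibular condyles, +x anterior, +y toward the animal's left, +z dorsal.
# The working side is the right side (y < 0). The mandible body frame
# coincides with the world frame at the closed midline pose.

# Attachment layout for the RIGHT side at the reference jaw length (72 mm).
# Centroids and fan (spread) vectors per muscle part; strands are spaced
# along the spread. Via points, where present, model wrapping of the strand
# path around bone and are fixed to the cranium.
muscle_layout <- function() {
  lay <- function(muscle, origin_c, origin_spread, insertion_c,
                  insertion_spread, via_c = NULL, via_spread = NULL) {
    list(muscle = muscle, origin_c = origin_c, origin_spread = origin_spread,
         via_c = via_c, via_spread = via_spread,
         insertion_c = insertion_c, insertion_spread = insertion_spread)
  }
  list(
    lay("superficial_masseter", c(26, -19, -3), c(8, 0, 0),
        c(18, -13, -19), c(16, 0, 0)),
    lay("posterior_deep_masseter", c(14, -18, -2), c(6, 0, 0),
        c(19, -13.5, -17), c(6, 0, 0)),
    lay("anterior_zygomaticomandibularis", c(27, -16.5, -3), c(8, 0, 0),
        c(24, -12.5, -15), c(8, 0, 0)),
    lay("posterior_zygomaticomandibularis", c(16, -16.5, -3), c(6, 0, 0),
        c(20, -12.5, -15), c(6, 0, 0)),
    lay("superficial_temporalis", c(8, -11, 12), c(6, 0, 0),
        c(11, -11.5, -9), c(4, 0, 0),
        via_c = c(10, -12, 2), via_spread = c(4, 0, 0)),
    lay("deep_temporalis", c(2, -9, 10), c(8, 0, 0),
        c(14, -10.5, -4), c(5, 0, 0)),
    lay("medial_pterygoid", c(22, -1, -4), c(8, 0, 0),
        c(17, -12, -20), c(8, 0, 0),
        via_c = c(20, -7, -13), via_spread = c(4, 0, 0)),
    lay("lateral_pterygoid", c(24, -3, -4), c(5, 0, 0),
        c(3, -12, -4), c(3, 0, 0)),
    lay("digastric", c(-4, -7, -14), c(4, 0, 0),
        c(52, -4, -19), c(8, 0, 0))
  )
}

mirror_y <- function(p) {
  if (is.matrix(p)) p %*% diag(c(1, -1, 1)) else p * c(1, -1, 1)
}

#' Synthetic rabbit-scale jaw geometry
#'
#' Generates a bilaterally mirrored set of skull and mandible landmarks at
#' rabbit scale: condyle positions, the temporomandibular fossa contact
#' normals, tooth bite points (incisor, premolars, most posterior molars)
#' and per-muscle attachment centroids with fan vectors from which strand
#' polylines are built. All lengths are in millimetres in the condyle-centred
#' frame described in the package vignette. These defaults are calibration
#' parameters of the generator, not measured anatomy; they were fixed once so
#' the default model reproduces the qualitative mechanics of the rabbit jaw.
#'
#' @param jaw_length Condyle-to-incisor bite point distance, mm (default 72).
#'   All landmarks scale isotropically with `jaw_length / 72`.
#' @param condyle_halfwidth Half the intercondylar distance, mm.
#' @param tooth_row_halfwidth Lateral offset of the cheek-tooth row, mm.
#' @param occlusal_drop Depth of the occlusal plane below the condylar axis, mm.
#' @param molar_x,premolar_x Anterior offset of the most posterior molar and
#'   of the premolar bite points, mm.
#' @param incisor_z Height of the incisal bite point, mm.
#' @param fossa_tilt_deg Posteroventral tilt of the fossa contact normal
#'   away from straight ventral, degrees (default 12): the condyle braces
#'   against the articular eminence, so the compressive reaction on the
#'   mandible points partly posteriorly.
#' @param lever_scale Scale factor applied to the anteroposterior and
#'   vertical coordinates of the muscle attachment field (default 0.85),
#'   positioning the attachments relative to the condyle; the principal
#'   calibration knob for overall mechanical advantage.
#' @param jitter_sd Standard deviation (mm) of optional Gaussian jitter added
#'   to attachment centroids; 0 (default) disables it.
#' @param seed Integer seed used when `jitter_sd > 0`; jitter is deterministic
#'   given the seed.
#' @param symmetric If `TRUE` (default) the left side is an exact mirror image
#'   of the (possibly jittered) right side; if `FALSE`, jitter is drawn
#'   independently per side.
#' @return An object of class `jaw_geometry`.
#' @export
synthetic_jaw_geometry <- function(jaw_length = 72,
                                   condyle_halfwidth = 14,
                                   tooth_row_halfwidth = 9,
                                   occlusal_drop = 18,
                                   molar_x = 28,
                                   premolar_x = 38,
                                   incisor_z = -14,
                                   fossa_tilt_deg = 12,
                                   lever_scale = 0.85,
                                   jitter_sd = 0,
                                   seed = 1L,
                                   symmetric = TRUE) {
  s <- jaw_length / 72
  layout <- muscle_layout()
  lever <- c(lever_scale, 1, lever_scale)
  jit <- function(p) {
    if (is.null(p)) return(NULL)
    p <- p * lever
    if (jitter_sd > 0) p + stats::rnorm(3, 0, jitter_sd) else p
  }
  build_side <- function(side) {
    sgn <- if (side == "right") 1 else -1
    purrr::map(layout, function(m) {
      flip <- function(p) if (is.null(p)) NULL else if (sgn == 1) p else mirror_y(p)
      list(
        muscle = m$muscle, side = side,
        origin_c = flip(jit(m$origin_c)) * s,
        origin_spread = flip(m$origin_spread * lever) * s,
        via_c = if (is.null(m$via_c)) NULL else flip(jit(m$via_c)) * s,
        via_spread = if (is.null(m$via_spread)) NULL else
          flip(m$via_spread * lever) * s,
        insertion_c = flip(jit(m$insertion_c)) * s,
        insertion_spread = flip(m$insertion_spread * lever) * s
      )
    })
  }
  if (jitter_sd > 0) set.seed(seed)
  right <- build_side("right")
  if (symmetric) {
    left <- purrr::map(right, function(m) {
      out <- m
      out$side <- "left"
      for (f in c("origin_c", "origin_spread", "via_c", "via_spread",
                  "insertion_c", "insertion_spread")) {
        if (!is.null(out[[f]])) out[[f]] <- mirror_y(out[[f]])
      }
      out
    })
  } else {
    left <- build_side("left")
  }
  bp <- list(
    incisor = c(jaw_length, 0, incisor_z * s),
    premolar_right = c(premolar_x, -tooth_row_halfwidth - 0.5, -occlusal_drop) * s,
    molar_right = c(molar_x, -tooth_row_halfwidth, -occlusal_drop) * s,
    molar_left = c(molar_x, tooth_row_halfwidth, -occlusal_drop) * s,
    premolar_left = c(premolar_x, tooth_row_halfwidth + 0.5, -occlusal_drop) * s
  )
  structure(list(
    jaw_length = jaw_length,
    condyle_right = c(0, -condyle_halfwidth, 0) * s,
    condyle_left = c(0, condyle_halfwidth, 0) * s,
    fossa_normal_right = c(-sin(fossa_tilt_deg * pi / 180), 0,
                           -cos(fossa_tilt_deg * pi / 180)),
    fossa_normal_left = c(-sin(fossa_tilt_deg * pi / 180), 0,
                          -cos(fossa_tilt_deg * pi / 180)),
    bite_points = bp,
    muscles = c(right, left),
    symmetric = symmetric
  ), class = "jaw_geometry")
}

#' @export
print.jaw_geometry <- function(x, ...) {
  cat("<jaw_geometry> jaw length", x$jaw_length, "mm,",
      length(x$muscles), "muscle-side attachment fans,",
      if (x$symmetric) "mirror-symmetric" else "asymmetric", "\n")
  invisible(x)
}

# ---- attachment table I/O -------------------------------------------------

attachment_columns <- c("muscle", "side", "strand", "role", "frame",
                        "x", "y", "z", "ordinal")

#' Attachment table of a musculoskeletal model
#'
#' Flattens every strand path of a model into a per-point table: one row per
#' polyline point with its role (origin, via, insertion), the frame the point
#' is fixed in (cranium or mandible) and millimetre coordinates. The table
#' round-trips losslessly through [write_attachments()]/[read_attachments()].
#'
#' @param model A model built by [build_jaw_model()].
#' @return A tibble with columns muscle, side, strand, role, frame, x, y, z,
#'   ordinal.
#' @export
as_attachment_table <- function(model) {
  purrr::imap_dfr(model$strands, function(st, i) {
    n <- nrow(st$path)
    role <- c("origin", rep("via", max(0, n - 2)), "insertion")
    tibble::tibble(
      muscle = st$muscle, side = st$side, strand = st$index_within,
      role = role, frame = st$frames,
      x = st$path[, 1], y = st$path[, 2], z = st$path[, 3],
      ordinal = seq_len(n)
    )
  })
}

#' Write / read muscle attachment coordinates
#'
#' CSV dialect for muscle origin, via and insertion coordinates: UTF-8,
#' header row, columns muscle, side, strand, role, frame, x, y, z, ordinal
#' (coordinates in mm). `read_attachments()` validates the schema and
#' reports the offending row on error.
#'
#' @param model Model whose strand paths are written.
#' @param path File path.
#' @return `write_attachments()` returns `path` invisibly;
#'   `read_attachments()` returns a validated attachment tibble ordered by
#'   muscle, side, strand and ordinal.
#' @export
write_attachments <- function(model, path) {
  tab <- as_attachment_table(model)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_attachments
#' @export
read_attachments <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(attachment_columns, names(raw))
  if (length(missing_cols)) {
    stop("attachment file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_muscle <- which(!raw$muscle %in% muscle_parts())
  if (length(bad_muscle)) {
    stop("unknown muscle '", raw$muscle[bad_muscle[1]], "' in attachment row ",
         bad_muscle[1], call. = FALSE)
  }
  bad_side <- which(!raw$side %in% c("left", "right"))
  if (length(bad_side)) {
    stop("invalid side in attachment row ", bad_side[1], call. = FALSE)
  }
  bad_frame <- which(!raw$frame %in% c("cranium", "mandible") | is.na(raw$frame))
  if (length(bad_frame)) {
    stop("missing or invalid frame in attachment row ", bad_frame[1],
         call. = FALSE)
  }
  bad_role <- which(!raw$role %in% c("origin", "via", "insertion"))
  if (length(bad_role)) {
    stop("invalid role in attachment row ", bad_role[1], call. = FALSE)
  }
  for (col in c("x", "y", "z", "ordinal", "strand")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(vals)) {
      stop("non-numeric '", col, "' in attachment row ",
           which(is.na(vals))[1], call. = FALSE)
    }
    raw[[col]] <- vals
  }
  tab <- tibble::as_tibble(raw)
  dplyr::arrange(tab, .data$muscle, .data$side, .data$strand, .data$ordinal)
}
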