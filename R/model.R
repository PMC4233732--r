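# Assembly of the musculoskeletal jaw model: architecture + geometry -> strands.

make_strand <- function(muscle, side, index_within, path, frames, share,
                        closer) {
  if (nrow(path) < 2) stop("strand path needs at least two points", call. = FALSE)
  structure(list(
    muscle = muscle, side = side, index_within = index_within,
    path = path, frames = frames, max_force_share = share,
    rest_length = polyline_length(path), is_closer = closer
  ), class = "muscle_strand")
}

polyline_length <- function(path) {
  d <- diff(path)
  sum(sqrt(rowSums(d^2)))
}

strands_from_geometry <- function(geometry, architecture, allocation) {
  out <- list()
  for (m in geometry$muscles) {
    arch_row <- architecture[architecture$muscle == m$muscle, ]
    if (nrow(arch_row) != 1) next
    n <- allocation[[m$muscle]]
    share <- arch_row$max_force / n
    tk <- if (n == 1) 0 else seq(-1, 1, length.out = n)
    for (k in seq_len(n)) {
      origin <- m$origin_c + tk[k] / 2 * m$origin_spread
      insertion <- m$insertion_c + tk[k] / 2 * m$insertion_spread
      if (!is.null(m$via_c)) {
        via <- m$via_c + tk[k] / 2 * m$via_spread
        path <- rbind(origin, via, insertion)
        frames <- c("cranium", "cranium", "mandible")
      } else {
        path <- rbind(origin, insertion)
        frames <- c("cranium", "mandible")
      }
      rownames(path) <- NULL
      out[[length(out) + 1]] <- make_strand(
        m$muscle, m$side, k, path, frames, share,
        closer = m$muscle != "digastric")
    }
  }
  out
}

strands_from_attachments <- function(attachments, architecture) {
  need <- jaw_closer_parts()
  have <- unique(attachments$muscle)
  missing <- setdiff(need, have)
  if (length(missing)) {
    stop("attachment table is missing muscle(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  groups <- dplyr::group_split(
    dplyr::group_by(attachments, .data$muscle, .data$side, .data$strand))
  counts <- table(paste(
    purrr::map_chr(groups, ~ .x$muscle[1]),
    purrr::map_chr(groups, ~ .x$side[1])))
  out <- list()
  for (g in groups) {
    g <- g[order(g$ordinal), ]
    if (g$frame[1] != "cranium") {
      stop("strand for ", g$muscle[1], " (", g$side[1],
           ") must start at a cranium-frame origin", call. = FALSE)
    }
    if (g$frame[nrow(g)] != "mandible") {
      stop("strand for ", g$muscle[1], " (", g$side[1],
           ") must end at a mandible-frame insertion", call. = FALSE)
    }
    arch_row <- architecture[architecture$muscle == g$muscle[1], ]
    n_here <- counts[[paste(g$muscle[1], g$side[1])]]
    share <- arch_row$max_force / n_here
    out[[length(out) + 1]] <- make_strand(
      g$muscle[1], g$side[1], g$strand[1],
      as.matrix(g[, c("x", "y", "z")]), g$frame, share,
      closer = g$muscle[1] != "digastric")
  }
  out
}

#' Build the musculoskeletal jaw model
#'
#' Combines the muscle architecture table (maximum forces per muscle part)
#' with attachment geometry — either the synthetic rabbit-scale generator or
#' an attachment coordinate table/CSV — into the full model used by the
#' simulator: muscle strands with force shares and rest lengths, condyles and
#' fossa contact normals, tooth bite points, and the rigid mandible body.
#' With the default configuration the model carries 150 strands, 75 per side,
#' and each muscle's summed strand shares equal its architecture maximum
#' force.
#'
#' @param architecture Architecture tibble (one side), default
#'   [rabbit_muscle_architecture()] at `muscle_stress`.
#' @param geometry A [synthetic_jaw_geometry()] object.
#' @param attachments Optional attachment tibble (or CSV path) in the
#'   [read_attachments()] dialect; overrides the geometry's muscle fans.
#' @param n_per_side Strands per side (default 75).
#' @param strand_allocation Optional named integer vector of per-muscle
#'   strand counts per side; must sum to `n_per_side`. Default: proportional
#'   to maximum force via [allocate_strands()].
#' @param muscle_stress Muscle stress in N cm^-2 (default 25) used to scale
#'   the default architecture.
#' @param mandible A [mandible_body()]; default ellipsoidal approximation.
#' @param gravity Gravitational acceleration, m s^-2 (default 9.81).
#' @return An object of class `jaw_model`.
#' @export
build_jaw_model <- function(architecture = NULL,
                            geometry = synthetic_jaw_geometry(),
                            attachments = NULL,
                            n_per_side = 75,
                            strand_allocation = NULL,
                            muscle_stress = 25,
                            mandible = default_mandible_body(),
                            gravity = 9.81) {
  if (is.null(architecture)) {
    architecture <- rabbit_muscle_architecture(muscle_stress = muscle_stress)
  }
  if (!is.null(attachments)) {
    if (is.character(attachments)) attachments <- read_attachments(attachments)
    strands <- strands_from_attachments(attachments, architecture)
  } else {
    if (is.null(strand_allocation)) {
      strand_allocation <- allocate_strands(architecture, n_per_side)
    }
    if (sum(strand_allocation) != n_per_side) {
      stop("strand_allocation must sum to n_per_side (", n_per_side, ")",
           call. = FALSE)
    }
    if (!setequal(names(strand_allocation), architecture$muscle)) {
      stop("strand_allocation must name every muscle part", call. = FALSE)
    }
    strands <- strands_from_geometry(geometry, architecture, strand_allocation)
  }
  strand_table <- purrr::imap_dfr(strands, function(st, i) {
    tibble::tibble(
      index = i, muscle = st$muscle, side = st$side,
      strand = st$index_within, max_force_share = st$max_force_share,
      is_closer = st$is_closer)
  })
  structure(list(
    architecture = architecture,
    strands = strands,
    strand_table = strand_table,
    condyle_right = geometry$condyle_right,
    condyle_left = geometry$condyle_left,
    fossa_normal_right = geometry$fossa_normal_right,
    fossa_normal_left = geometry$fossa_normal_left,
    bite_points = geometry$bite_points,
    mandible = mandible,
    muscle_stress = muscle_stress,
    gravity = gravity,
    geometry = geometry
  ), class = "jaw_model")
}

#' @export
print.jaw_model <- function(x, ...) {
  per_side <- table(x$strand_table$side)
  cat("<jaw_model>", length(x$strands), "muscle strands (",
      paste(per_side, collapse = "/"), "per side ),",
      nrow(x$architecture), "muscle parts, mandible", x$mandible$mass,
      "g\n")
  cat("  total closer max force:",
      round(sum(x$strand_table$max_force_share[x$strand_table$is_closer]), 1),
      "N (both sides)\n")
  invisible(x)
}

# Summed strand force shares per muscle and side.
muscle_force_totals <- function(model) {
  dplyr::summarise(
    dplyr::group_by(model$strand_table, .data$muscle, .data$side),
    max_force = sum(.data$max_force_share), .groups = "drop")
}
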