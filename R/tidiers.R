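# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a mastication simulation
#'
#' Long per-timestep, per-muscle activation table: the force-weighted mean
#' strand activation of each muscle part and side, as a fraction of maximum
#' force, with the phase and bite-force series attached.
#'
#' @param x A `mastication_sim`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `phase`, `muscle`, `side`,
#'   `activation`.
#' @export
tidy.mastication_sim <- function(x, ...) {
  tab <- x$model$strand_table
  closers <- split(tab[tab$is_closer, ],
                   paste(tab$muscle[tab$is_closer], tab$side[tab$is_closer]))
  purrr::imap_dfr(closers, function(g, key) {
    w <- g$max_force_share / sum(g$max_force_share)
    tibble::tibble(
      time = x$series$time, phase = x$series$phase,
      muscle = g$muscle[1], side = g$side[1],
      activation = as.numeric(x$activations[, g$index, drop = FALSE] %*% w))
  })
}

#' One-row summary of a mastication simulation
#'
#' @param x A `mastication_sim`.
#' @param ... Unused.
#' @return Tibble with the mode, peak bite-force resultant and components,
#'   recruited fraction, feasible-step fraction and worst residuals over
#'   feasible steps.
#' @export
glance.mastication_sim <- function(x, ...) {
  rec <- peak_bite_record(x)
  s <- x$series
  feas <- s$feasible
  tibble::tibble(
    mode = x$mode,
    n_steps = nrow(s),
    peak_bite_force = rec$resultant,
    bite_ap = rec$components[1], bite_ml = rec$components[2],
    bite_vertical = rec$components[3],
    vertical_pct = rec$percentages[3],
    recruited_fraction = recruited_fraction(x),
    prop_feasible = mean(feas),
    max_residual_force = if (any(feas)) max(s$residual_force[feas]) else NA_real_,
    max_residual_moment = if (any(feas)) max(s$residual_moment[feas]) else NA_real_
  )
}

#' @export
tidy.bite_record <- function(x, ...) {
  tibble::tibble(
    axis = names(x$components),
    force = as.numeric(x$components),
    pct_of_resultant = as.numeric(x$percentages),
    resultant = x$resultant,
    site = x$site %||% NA_character_,
    mode = x$mode %||% NA_character_
  )
}

#' Activation-profile plot of a simulation
#'
#' Muscle activation (percent of maximum force) against time, one facet per
#' side, coloured by muscle, with phase boundaries marked.
#'
#' @param object A `mastication_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mastication_sim <- function(object, ...) {
  d <- tidy(object)
  bounds <- cumsum(object$profile$phase_durations)[1:2]
  ggplot2::ggplot(d, ggplot2::aes(.data$time, 100 * .data$activation,
                                  colour = .data$muscle)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = bounds, linetype = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$side)) +
    ggplot2::labs(x = "time (ms)", y = "activation (% of max force)",
                  colour = NULL,
                  title = paste("Muscle activation:", object$mode)) +
    ggplot2::theme_minimal()
}

#' Bite-force component plot
#'
#' @param object A `bite_record`.
#' @param ... Unused.
#' @return A ggplot bar chart of component percentages of the resultant.
#' @export
autoplot.bite_record <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$axis, .data$pct_of_resultant)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of resultant",
                  title = sprintf("Bite force components (resultant %.1f N)",
                                  object$resultant)) +
    ggplot2::theme_minimal()
}

#' Bolus and bite force time series plot
#'
#' @param sim A `mastication_sim`.
#' @return A ggplot of bite-force components against time.
#' @export
plot_bite_forces <- function(sim) {
  s <- sim$series
  d <- tidyr::pivot_longer(
    s[, c("time", "bite_fx", "bite_fy", "bite_fz")],
    -"time", names_to = "axis", values_to = "force")
  d$axis <- dplyr::recode(d$axis, bite_fx = "anteroposterior",
                          bite_fy = "mediolateral", bite_fz = "vertical")
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$force,
                                  colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "bite force (N)", colour = NULL,
                  title = paste("Bite force:", sim$mode)) +
    ggplot2::theme_minimal()
}
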