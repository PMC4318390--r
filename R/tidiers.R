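# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' Tidy mined patterns
#'
#' @param x A `fresco_patterns` tibble.
#' @param matches Unnest the per-structure best matches into long form?
#' @param ... Unused.
#' @return A plain tibble: one row per pattern, or per (pattern,
#'   structure) when `matches = TRUE`.
#' @export
tidy.fresco_patterns <- function(x, matches = FALSE, ...) {
  if (!matches) {
    return(tibble::tibble(pattern = x$pattern, size = x$size,
                          support = x$support, n_supporting = x$n_supporting,
                          cohesive_radius = x$cohesive_radius))
  }
  tibble::tibble(pattern = x$pattern, matches = x$matches) |>
    tidyr::unnest("matches") |>
    dplyr::select("pattern", "structure_id", "radius")
}

#' @rdname tidy.fresco_patterns
#' @return `glance()` returns a one-row run summary.
#' @export
glance.fresco_patterns <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_patterns = nrow(x),
    n_doublets = sum(x$size == 2),
    n_triplets = sum(x$size == 3),
    n_structures = attr(x, "n_structures") %||% NA_integer_,
    min_support = cfg$min_support %||% NA_real_,
    max_radius = cfg$max_radius %||% NA_real_,
    mode = cfg$mode %||% NA_character_
  )
}

#' Tidy significance results
#'
#' @param x A `fresco_significance` tibble.
#' @param ... Unused.
#' @return A plain tibble without the background list-column.
#' @export
tidy.fresco_significance <- function(x, ...) {
  tibble::tibble(pattern = x$pattern, size = x$size,
                 observed_R = x$observed_R,
                 background_mean = x$background_mean,
                 background_sd = x$background_sd,
                 p_value = x$p_value, significant = x$significant)
}

#' @rdname tidy.fresco_significance
#' @export
glance.fresco_significance <- function(x, ...) {
  tibble::tibble(n_tested = nrow(x), n_significant = sum(x$significant),
                 alpha = attr(x, "alpha") %||% NA_real_,
                 n_perm = attr(x, "n_perm") %||% NA_integer_)
}

#' Plot mined patterns: support against cohesive radius
#'
#' @param object A `fresco_patterns` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fresco_patterns <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cohesive_radius,
                                    y = .data$support,
                                    colour = factor(.data$size))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "cohesive radius (Å)", y = "support",
                  colour = "pattern size") +
    ggplot2::theme_minimal()
}

#' Plot significance results: observed against background radius
#'
#' @param object A `fresco_significance` tibble.
#' @param ... Unused.
#' @return A ggplot; the dashed line is observed = background.
#' @export
autoplot.fresco_significance <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$background_mean,
                                    y = .data$observed_R,
                                    colour = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "background mean radius (Å)",
                  y = "observed cohesive radius (Å)") +
    ggplot2::theme_minimal()
}

#' Histogram of best-match sequence separations
#'
#' @param separation Output of [sequence_separation()].
#' @param binwidth Histogram bin width in residues.
#' @return A ggplot of the separation distribution, colored by class.
#' @export
plot_separation <- function(separation, binwidth = 2) {
  dat <- separation[!is.na(separation$separation), , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$separation,
                                    fill = .data$class)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = "sequence separation (residues)", y = "matches") +
    ggplot2::theme_minimal()
}
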