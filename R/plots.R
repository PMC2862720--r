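#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_col geom_errorbar
#'   geom_line geom_point labs scale_fill_identity scale_y_continuous
#'   coord_equal theme_minimal facet_wrap
#' @importFrom generics tidy glance
#' @importFrom grDevices rgb
#' @importFrom rlang .data
NULL

#' Plot a synthetic or segmented IHC field
#'
#' Renders either the RGB micrograph or its label mask as a raster.
#'
#' @param object An `ihc_field` from [generate_ihc_field()].
#' @param what `"rgb"` or `"labels"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ihc_field <- function(object, what = c("rgb", "labels"), ...) {
  what <- match.arg(what)
  h <- nrow(object$labels); w <- ncol(object$labels)
  df <- tidyr::expand_grid(y = seq_len(h), x = seq_len(w))
  if (what == "rgb") {
    df$fill <- grDevices::rgb(object$rgb[, , 1] / 255, object$rgb[, , 2] / 255,
                              object$rgb[, , 3] / 255)
  } else {
    pal <- c(SP = "#8b5a2b", NSP = "#7878b4", BG = "#ebe6eb")
    df$fill <- pal[as.vector(object$labels)]
  }
  ggplot(df, aes(.data$x, .data$y, fill = .data$fill)) +
    geom_raster() +
    scale_fill_identity() +
    coord_equal(expand = FALSE) +
    ggplot2::scale_y_reverse() +
    theme_minimal() +
    labs(x = NULL, y = NULL, title = if (what == "rgb") "Synthetic IHC field" else "Label mask")
}

#' Plot per-field expression for a quantified channel
#'
#' @param object An `ihc_field_set` from [aggregate_fields()] or
#'   [quantify_fields()].
#' @param ... Unused.
#' @return A ggplot bar chart of per-field expression levels with the
#'   channel mean as a horizontal line.
#' @export
autoplot.ihc_field_set <- function(object, ...) {
  fields <- attr(object, "fields")
  fields$field <- fields$field_id %||% as.character(seq_len(nrow(fields)))
  ggplot(fields, aes(.data$field, .data$expression_level)) +
    geom_col(fill = "#8b5a2b") +
    ggplot2::geom_hline(yintercept = object$mean_expression, linetype = 2) +
    theme_minimal() +
    labs(x = "field", y = "expression level",
         title = sprintf("Channel mean expression = %.3f", object$mean_expression))
}

#' Plot the bound-receptor time course of a channel simulation
#'
#' @param object A `channel_sim` from [simulate_transport()].
#' @param ... Unused.
#' @return A ggplot line chart of mean bound density over time.
#' @export
autoplot.channel_sim <- function(object, ...) {
  ggplot(object$bound_series, aes(.data$time, .data$mean_bound)) +
    geom_line(colour = "#8b5a2b") +
    theme_minimal() +
    labs(x = "time (s)", y = expression(bar(B) ~ (mol / m^2)),
         title = sprintf("Mean velocity %.2g m/s", object$channel$mean_velocity))
}

#' Plot an agreement report as a concordance chart
#'
#' @param object An `agreement_report` (or the per-biomarker tibble from
#'   [concordance_report()]).
#' @param ... Unused.
#' @return A ggplot of percent concordance with exact 95% intervals.
#' @export
autoplot.agreement_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"biomarker" %in% names(df)) df$biomarker <- "all"
  ggplot(df, aes(.data$biomarker, .data$concordance_pct)) +
    geom_col(fill = "#7878b4") +
    geom_errorbar(aes(ymin = .data$ci_lo, ymax = .data$ci_hi), width = 0.2) +
    scale_y_continuous(limits = c(0, 100)) +
    theme_minimal() +
    labs(x = NULL, y = "% concordance (95% CI)")
}

#' @rdname autoplot.agreement_report
#' @param x An `agreement_report`.
#' @export
tidy.agreement_report <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(
      c("W", "chi2", "kappa", "concordance_pct"),
      names_to = "statistic", values_to = "value"
    ) |>
    dplyr::select("statistic", "value", dplyr::any_of(c("n", "df")))
}

#' @rdname autoplot.agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::as_tibble(x)[, c("n", "W", "kappa", "concordance_pct")]
}
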