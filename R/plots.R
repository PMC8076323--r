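#' Plot sample-side loadings against the covariate
#'
#' Line-and-point plot of the first few PC loadings (or HOSVD sample
#' factors) across the covariate, the standard visual check for which
#' component tracks time.
#'
#' @param object A `gram_pca` fit.
#' @param components Which components to draw (default first 4).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gram_pca
#' @export
autoplot.gram_pca <- function(object, components = 1:4, ...) {
  df <- tidy(object, "loadings")
  components <- intersect(components, unique(df$component))
  df <- df[df$component %in% components, ]
  if (all(is.na(df$covariate))) df$covariate <- df$sample
  ggplot2::ggplot(df, ggplot2::aes(.data$covariate, .data$loading,
                                   colour = factor(.data$component),
                                   group = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "covariate", y = "loading", colour = "component") +
    ggplot2::theme_minimal()
}

#' Plot one mode's factor vectors from an HOSVD fit
#'
#' @param object A `hosvd` fit.
#' @param mode Mode to display (index or name), default 2 (typically the
#'   time mode of a feature x time x condition tensor).
#' @param components Which components to draw (default all, capped at 4).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hosvd
#' @export
autoplot.hosvd <- function(object, mode = 2, components = NULL, ...) {
  df <- tidy(object, mode = mode)
  components <- components %||% utils::head(unique(df$component), 4)
  df <- df[df$component %in% components, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$level, .data$value,
                                   colour = factor(.data$component),
                                   group = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = unique(df$mode), y = "factor value",
                  colour = "component") +
    ggplot2::theme_minimal()
}

#' Plot a feature-selection table
#'
#' Scores against their chi-squared P-values with the selection
#' highlighted; a quick look at how sharply the selected features
#' separate from the null bulk.
#'
#' @param object An `fe_selection` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fe_selection
#' @export
autoplot.fe_selection <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$score, -log10(.data$p_adjusted),
                               colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "component score", y = "-log10 adjusted P",
                  colour = "selected") +
    ggplot2::theme_minimal()
}
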