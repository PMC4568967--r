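#' Reversal-quadrant scatter plot
#'
#' Plots the diet-effect slope against the age-effect slope per feature,
#' coloured by significance class. Features in the top-left and bottom-right
#' quadrants are those for which dietary restriction reverses the effect of
#' age; top-right and bottom-left are exacerbations.
#'
#' @param rtbl a `reversal_tbl` from [reversal_classification()].
#' @param significant_only drop features significant for neither predictor.
#' @return a ggplot object.
#' @export
plot_reversal <- function(rtbl, significant_only = TRUE) {
  df <- as_tibble(rtbl)
  if (significant_only) df <- df[df$class != "none", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta_diet, y = .data$beta_age,
                                   colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`age-only` = "#377EB8",
                                            `diet-only` = "#4DAF4A",
                                            both = "#FF7F00",
                                            none = "grey70")) +
    ggplot2::labs(x = expression(beta[diet] ~ "(DR - AL, log2 units)"),
                  y = expression(beta[age] ~ "(per day, log2 units)"),
                  colour = "significant for") +
    ggplot2::theme_minimal()
}

#' @rdname plot_reversal
#' @param object a `reversal_tbl`.
#' @param ... passed to [plot_reversal()].
#' @exportS3Method ggplot2::autoplot
autoplot.reversal_tbl <- function(object, ...) plot_reversal(object, ...)

#' Histogram of pairwise correlations per condition
#'
#' The panel-per-condition view of the correlation distribution, with a
#' vertical line at each condition's mean — the display used to compare
#' network connectivity between diets or ages.
#'
#' @param cors a list from [condition_correlations()] (or any named list of
#'   correlation matrices).
#' @param bins histogram bins.
#' @return a ggplot object.
#' @export
plot_correlation_distributions <- function(cors, bins = 60) {
  df <- purrr::map_dfr(names(cors), function(nm) {
    cc <- .cond_cor(cors[[nm]])
    tibble(condition = nm, r = cc[upper.tri(cc)])
  })
  means <- df %>% dplyr::group_by(.data$condition) %>%
    dplyr::summarise(mean_r = mean(.data$r), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$mean_r),
                        colour = "red", linewidth = 0.7) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "pairwise Pearson correlation", y = "pairs") +
    ggplot2::theme_minimal()
}

#' PCA score plot
#'
#' @param object a `metab_pca` from [pca_scores()].
#' @param design optional design tibble; its `diet`/`age` columns colour and
#'   shape the points.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.metab_pca <- function(object, design = NULL, ...) {
  df <- object$scores
  if (!is.null(design)) {
    df <- dplyr::left_join(df, design, by = "sample_id")
  }
  aes <- ggplot2::aes(x = .data$PC1, y = .data$PC2)
  if (!is.null(design) && "diet" %in% names(df)) aes$colour <- rlang::quo(.data$diet)
  if (!is.null(design) && "age" %in% names(df)) aes$shape <- rlang::quo(factor(.data$age))
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      shape = "age (days)") +
    ggplot2::theme_minimal()
}
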