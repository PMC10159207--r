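## Thin plotting layer over the plot-data producers. Each function takes
## the plain data the analytics emit and returns a ggplot object; nothing
## here computes statistics.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("the 'ggplot2' package is required for plotting")
}

#' Bar plot of global feature importance
#'
#' @param importance An [importance_vector()].
#' @param max_display Features shown (default 15).
#' @return A ggplot object.
#' @export
plot_importance_bar <- function(importance, max_display = 15L) {
  need_ggplot()
  ord <- order(-as.numeric(importance))
  keep <- ord[seq_len(min(max_display, length(importance)))]
  df <- data.frame(feature = factor(names(importance)[keep],
                                    levels = rev(names(importance)[keep])),
                   score = as.numeric(importance)[keep])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = attr(importance, "method"), y = NULL)
}

#' Beeswarm summary plot
#'
#' @param bees Records from [beeswarm_data()].
#' @return A ggplot object (jittered strip per feature, coloured low-high).
#' @export
plot_beeswarm <- function(bees) {
  need_ggplot()
  bees$feature <- factor(bees$feature, levels = rev(unique(bees$feature)))
  ggplot2::ggplot(bees, ggplot2::aes(x = .data$phi, y = .data$feature,
                                     colour = .data$color)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, size = 1) +
    ggplot2::scale_colour_gradient(low = "blue", high = "red",
                                   name = "feature value") +
    ggplot2::labs(x = "SHAP value", y = NULL)
}

#' SHAP dependence plot
#'
#' @param dep Records from [dependence_data()].
#' @return A ggplot object.
#' @export
plot_dependence <- function(dep) {
  need_ggplot()
  p <- ggplot2::ggplot(dep, ggplot2::aes(x = .data$value, y = .data$phi))
  if (!all(is.na(dep$interaction_value)))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$interaction_value)) +
      ggplot2::scale_colour_gradient(low = "blue", high = "red",
                                     name = attr(dep, "interaction"))
  else p <- p + ggplot2::geom_point()
  p + ggplot2::labs(x = attr(dep, "feature"),
                    y = paste0("SHAP value (", attr(dep, "feature"), ")"))
}

#' Waterfall plot of a local decomposition
#'
#' @param decomp A [local_decomposition()].
#' @return A ggplot object stepping from the base value to the model output.
#' @export
plot_waterfall <- function(decomp) {
  need_ggplot()
  base <- attr(decomp, "base_value")
  steps <- rev(c(decomp$phi, attr(decomp, "remainder")))
  labels <- rev(c(decomp$feature, "other features"))
  start <- base + c(0, cumsum(steps))[seq_along(steps)]
  df <- data.frame(feature = factor(labels, levels = labels),
                   from = start, to = start + steps,
                   sign = ifelse(steps >= 0, "positive", "negative"))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$feature)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$from, xend = .data$to,
                                       yend = .data$feature,
                                       colour = .data$sign),
                          linewidth = 4, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(positive = "red",
                                            negative = "blue")) +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::geom_vline(xintercept = attr(decomp, "model_output"),
                        linetype = 3) +
    ggplot2::labs(x = "model output", y = NULL)
}

#' SHAP embedding scatter, coloured by one feature's SHAP values
#'
#' @param coords Output of [shap_embedding()].
#' @param S The `shap_matrix` used to build it.
#' @param feature Feature id whose SHAP values colour the points.
#' @return A ggplot object.
#' @export
plot_embedding <- function(coords, S, feature) {
  need_ggplot()
  j <- match(feature, S$feature_ids)
  if (is.na(j)) stop("unknown feature id: ", feature)
  df <- data.frame(PC1 = coords[, 1L], PC2 = coords[, 2L],
                   phi = S$values[, j])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$phi)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey85",
                                    high = "red", midpoint = 0,
                                    name = paste0("SHAP(", feature, ")")) +
    ggplot2::labs(x = "PC1", y = "PC2")
}
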