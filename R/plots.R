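# --- diagnostic plots ---------------------------------------------------

#' Plot a neutral model fit
#'
#' Scatter of observed pairwise divergence against divergence time with
#' the fitted neutral-model curve overlaid.
#'
#' @param object A `neutral_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot neutral_fit
#' @export
autoplot.neutral_fit <- function(object, ...) {
  df <- dplyr::mutate(object$data, delta_t = .data$tau_i + .data$tau_j)
  grid <- tibble::tibble(delta_t = seq(0, max(df$delta_t), length.out = 200))
  grid$D <- model_divergence(object$params, grid$delta_t / 2,
                             grid$delta_t / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_t, y = .data$D)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "divergence time (years)",
                  y = "methylation divergence D",
                  title = "Neutral epimutation model fit",
                  subtitle = sprintf(
                    "alpha = %.3g, beta = %.3g per site per year",
                    object$estimates[["alpha"]], object$estimates[["beta"]])) +
    ggplot2::theme_minimal()
}

#' Plot divergence groups of a stem design
#'
#' Box plots of replicate (RR) and opposite-side (RS) methylation
#' divergence by treatment.
#'
#' @param divergences Tibble with columns `treatment`, `comparison`,
#'   `divergence` (e.g. [stem_design_divergence()]).
#' @return A ggplot object.
#' @export
plot_divergence_groups <- function(divergences) {
  df <- dplyr::mutate(divergences, group = ifelse(
    .data$comparison == "RR", "RR",
    paste0(.data$treatment, " RS")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$divergence)) +
    ggplot2::geom_boxplot(outlier.colour = "red") +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 15) +
    ggplot2::labs(x = NULL, y = "methylation divergence",
                  title = "Stem methylation divergence by comparison group") +
    ggplot2::theme_minimal()
}

#' Plot a divergence-based sample clustering
#'
#' @param object A `divergence_clustering`.
#' @param ... Unused.
#' @return A ggplot object (dendrogram drawn with segments).
#' @method autoplot divergence_clustering
#' @export
autoplot.divergence_clustering <- function(object, ...) {
  hc <- object$hclust
  dend <- as.dendrogram_segments(hc)
  ggplot2::ggplot(dend$segments) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_text(data = dend$labels,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       angle = 90, hjust = 1, nudge_y = -0.02 * max(hc$height)) +
    ggplot2::labs(y = "divergence", x = NULL,
                  title = "UPGMA clustering of samples") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

# minimal hclust -> segment coordinates (avoids a ggdendro dependency)
as.dendrogram_segments <- function(hc) {
  n <- length(hc$order)
  x_leaf <- setNames(seq_len(n), hc$order)
  xpos <- numeric(nrow(hc$merge)); seg <- list()
  node_x <- function(k) if (k < 0) x_leaf[[as.character(-k)]] else xpos[k]
  node_y <- function(k) if (k < 0) 0 else hc$height[k]
  for (k in seq_len(nrow(hc$merge))) {
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    xa <- node_x(a); xb <- node_x(b)
    xpos[k] <- (xa + xb) / 2
    h <- hc$height[k]
    seg[[length(seg) + 1]] <- tibble::tibble(
      x = c(xa, xb, xa), y = c(node_y(a), node_y(b), h),
      xend = c(xa, xb, xb), yend = c(h, h, h))
  }
  list(segments = dplyr::bind_rows(seg),
       labels = tibble::tibble(x = seq_len(n), y = 0,
                               label = hc$labels[hc$order]))
}
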