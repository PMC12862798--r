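#' Heatmap of a (reordered) correlation matrix
#'
#' @param model a `"cd_correlation"`, typically after
#'   [reorder_block_diagonal()].
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_correlation_matrix <- function(model) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_correlation_matrix requires ggplot2")
  }
  m <- model$matrix
  df <- data.frame(
    x = factor(rep(model$features, each = nrow(m)), levels = model$features),
    y = factor(rep(model$features, nrow(m)), levels = rev(model$features)),
    value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "similarity") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Dynamical content profile on a log time axis
#'
#' @param content a `"cd_content"`.
#' @return a ggplot object with the total in bold and one line per cluster.
#' @export
plot_dynamical_content <- function(content) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_dynamical_content requires ggplot2")
  }
  df <- data.frame(tau = content$taus, value = content$total, which = "total")
  if (!is.null(content$per_cluster)) {
    for (cl in colnames(content$per_cluster)) {
      df <- rbind(df, data.frame(tau = content$taus,
                                 value = content$per_cluster[, cl], which = cl))
    }
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$value,
                                   color = .data$which,
                                   linewidth = .data$which == "total")) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_linewidth_manual(values = c(`TRUE` = 1.2, `FALSE` = 0.5),
                                    guide = "none") +
    ggplot2::labs(x = "tau (ns)", y = "dynamical content D(tau)",
                  color = NULL) +
    ggplot2::theme_minimal()
}
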