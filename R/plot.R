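# ggplot2 displays for fits, loops and probability matrices.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the training curve of a mapper fit
#'
#' @param object a `mapper_fit`.
#' @param ... unused.
#' @return a ggplot: training (and validation, when present) loss per epoch.
#' @export
autoplot.mapper_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, cols = c("loss", "val_loss"),
                            names_to = "series", values_to = "value")
  df <- df[!is.na(df$value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(loss = "#1b7837", val_loss = "#762a83"),
      labels = c(loss = "training", val_loss = "validation")) +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the active-learning trajectory
#'
#' Verified template count and pool coverage per iteration, the two
#' quantities that summarize how fast the library saturates the dataset.
#'
#' @param object an `aam_loop`.
#' @param ... unused.
#' @return a ggplot with two panels.
#' @export
autoplot.aam_loop <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$stats, cols = c("verified_templates", "coverage"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "active-learning iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a mapping probability matrix
#'
#' @param P a probability matrix from [predict_mapping_matrix()].
#' @return a ggplot tile map of p(reactant atom | product atom).
#' @export
plot_mapping_matrix <- function(P) {
  pe <- attr(P, "product_elements")
  re <- attr(P, "reactant_elements")
  df <- tidyr::expand_grid(product = seq_len(nrow(P)),
                           reactant = seq_len(ncol(P)))
  df$p <- P[cbind(df$product, df$reactant)]
  labs_p <- if (is.null(pe)) as.character(seq_len(nrow(P))) else
    paste0(pe, seq_len(nrow(P)))
  labs_r <- if (is.null(re)) as.character(seq_len(ncol(P))) else
    paste0(re, seq_len(ncol(P)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reactant, y = .data$product,
                                   fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(P)), labels = labs_r) +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(P)), labels = labs_p) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "reactant atom", y = "product atom",
                  fill = "p(r | p)") +
    ggplot2::theme_minimal()
}
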