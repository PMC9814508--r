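#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a feature matrix as a time-frequency heat map
#'
#' @param object A `feature_matrix` from [improved_mfcc()].
#' @param block `"stacked"`, `"mfcc"`, `"delta"` or `"delta2"`.
#' @param ... Unused.
#' @return A ggplot object (frames on x, coefficients on y).
#' @export
autoplot.feature_matrix <- function(object, block = "stacked", ...) {
  m <- object[[block]]
  df <- tidyr::expand_grid(frame = seq_len(nrow(m)),
                           coefficient = seq_len(ncol(m)))
  df$value <- as.vector(m)[(df$coefficient - 1) * nrow(m) + df$frame]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$coefficient,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::labs(x = "frame", y = "coefficient",
                  title = paste0("improved MFCC (", block, ")")) +
    ggplot2::theme_minimal()
}

#' Plot training curves of a fitted model
#'
#' @param object A `pcg_model_fit`.
#' @param ... Unused.
#' @return A ggplot with loss and accuracy per epoch (validation curves
#'   included when tracked).
#' @export
autoplot.pcg_model_fit <- function(object, ...) {
  h <- object$history
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "metric",
                              values_to = "value")
  long$split <- ifelse(grepl("^val_", long$metric), "validation", "training")
  long$metric <- sub("^val_", "", long$metric)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = paste0("training history (", object$model$name,
                                 ")"), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object A [confusion_matrix()].
#' @param ... Unused.
#' @return A ggplot tile plot with counts.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 guide = "none") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation training curves
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot of per-fold loss/accuracy against epoch.
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c(-"epoch", -"fold"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = factor(.data$fold))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(colour = "fold") +
    ggplot2::theme_minimal()
}

#' Plot a recording waveform
#'
#' @param rec An [audio_recording()].
#' @return A ggplot of amplitude against time.
#' @export
plot_recording <- function(rec) {
  stopifnot(inherits(rec, "audio_recording"))
  df <- tibble::tibble(
    time_s = (seq_along(rec$samples) - 1) / rec$sample_rate_hz,
    amplitude = rec$samples)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(title = rec$id, x = "time (s)", y = "amplitude") +
    ggplot2::theme_minimal()
}
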