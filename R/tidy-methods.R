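# Broom-style accessors and ggplot2 autoplot methods for the package's
# result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training history
#'
#' @param x An `snn_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (loss terms, accuracy, learning
#'   rate, temperature).
#' @export
tidy.snn_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x An `snn_fit`.
#' @param ... Unused.
#' @return Tibble with epochs trained, final loss and accuracy, parameter
#'   count and the ablation flags.
#' @export
glance.snn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    loss = h$loss[nrow(h)],
    accuracy = h$accuracy[nrow(h)],
    params = count_params(x$model),
    attention = x$model$config$attention,
    learnable = x$model$config$learnable
  )
}

#' @export
tidy.firing_rate_report <- function(x, ...) x$table

#' @export
glance.firing_rate_report <- function(x, ...) {
  tibble::tibble(mean_rate = x$mean,
                 layers = nrow(x$rates), steps = x$steps)
}

#' @export
tidy.mac_report <- function(x, ...) {
  tibble::tibble(
    component = c("spiking", "encoder_dense", "generator", "decoder", "total"),
    macs = c(x$spiking, x$dense_encoder, x$dense_generator,
             x$dense_decoder, x$total)
  )
}

#' @export
tidy.snn_experiment <- function(x, ...) x$per_seed

#' @export
glance.snn_experiment <- function(x, ...) x$summary

#' @export
tidy.snn_ablation <- function(x, ...) x$table

#' Plot training curves
#'
#' @param object An `snn_fit`.
#' @param ... Unused.
#' @return A ggplot of loss terms and training accuracy per epoch.
#' @export
autoplot.snn_fit <- function(object, ...) {
  h <- object$history
  long <- tidyr_pivot(h)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history")
}

tidyr_pivot <- function(h) {
  metrics <- c("loss", "loss_class", "loss_attention", "accuracy")
  dplyr::bind_rows(lapply(metrics, function(m) {
    tibble::tibble(epoch = h$epoch, metric = m, value = h[[m]])
  }))
}

#' Plot an attention map
#'
#' @param object An `attention_map` (gate matrix).
#' @param ... Unused.
#' @return A ggplot raster of the gates (0 = suppressed, 1 = passed).
#' @export
autoplot.attention_map <- function(object, ...) {
  m <- unclass(object)
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    gate = as.numeric(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$gate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "gate")
}

#' Plot a firing-rate heatmap (layer x step)
#'
#' @param object A `firing_rate_report`.
#' @param ... Unused.
#' @return A ggplot heatmap of per-layer per-step firing proportions.
#' @export
autoplot.firing_rate_report <- function(object, ...) {
  tab <- object$table
  tab$layer <- factor(tab$layer, levels = rev(rownames(object$rates)))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$step, y = .data$layer,
                                    fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "time step", y = NULL, fill = "firing\nrate")
}

#' @importFrom rlang .data
NULL
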