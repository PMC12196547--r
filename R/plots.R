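#' Plot segmentation diagnostics
#'
#' Smoothed ankle elevation curves with detected step starts
#' (right-foot landings, green) and step ends (left-foot landings, red);
#' stationary spans are shaded.
#'
#' @param object a `step_boundaries` result from [extract_steps()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.step_boundaries <- function(object, ...) {
  er <- attr(object, "elevation_right")
  el <- attr(object, "elevation_left")
  df <- tibble::tibble(
    frame = rep(seq_along(er), 2),
    elevation = c(er, el),
    ankle = rep(c("right", "left"), each = length(er))
  )
  stat <- attr(object, "stationary")
  runs <- rle(stat)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  shade <- tibble::tibble(start = starts[runs$values], end = ends[runs$values])
  marks <- tibble::tibble(
    frame = c(object$start_frame, object$end_frame),
    type = rep(c("step start", "step end"), each = nrow(object))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$elevation))
  if (nrow(shade) > 0) {
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85", alpha = 0.6
    )
  }
  p +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$ankle), linewidth = 0.4) +
    ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$frame, colour = .data$type),
      linewidth = 0.5
    ) +
    ggplot2::scale_colour_manual(values = c("step start" = "#2e9e4f", "step end" = "#d03a2f")) +
    ggplot2::labs(
      x = "frame", y = "smoothed ankle elevation (px)",
      colour = NULL, linetype = NULL,
      title = paste("Single-step segmentation:", attr(object, "subject_id"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a training log
#'
#' Loss components and validation metrics across epochs.
#'
#' @param object a `fusion_fit`.
#' @param ... unused.
#' @export
autoplot.fusion_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$log[, c("epoch", "loss", "loss_w", "val_acc", "val_f1")],
    -"epoch",
    names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training trajectory") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object a `fusion_cv`.
#' @param ... unused.
#' @export
autoplot.fusion_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$folds[, c("fold", "acc", "prec", "rec", "f1")],
    -"fold",
    names_to = "metric", values_to = "percent"
  )
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$fold), .data$percent)) +
    ggplot2::geom_col(fill = "#4878a8") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(
      x = "fold", y = "percent",
      title = "Subject-grouped cross-validation"
    ) +
    ggplot2::theme_minimal()
}

#' Plot prior-head weights
#'
#' Signed per-prior influence on the PD class: positive (blue) pushes
#' toward PD, negative (red) away from it.
#'
#' @param object a `prior_head`.
#' @param ... unused.
#' @export
autoplot.prior_head <- function(object, ...) {
  df <- tidy(object)
  df$direction <- ifelse(df$pd_influence >= 0, "toward PD", "away from PD")
  ggplot2::ggplot(df, ggplot2::aes(
    stats::reorder(.data$prior, .data$pd_influence),
    .data$pd_influence,
    fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(
      "toward PD" = "#3b6fb6",
      "away from PD" = "#c23b2e"
    )) +
    ggplot2::labs(
      x = NULL, y = "signed influence on PD class",
      fill = NULL, title = "Prior-information weights"
    ) +
    ggplot2::theme_minimal()
}
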