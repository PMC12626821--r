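# ggplot2 renderings of training curves, masks and metric reports.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_col
#'   scale_fill_manual labs facet_wrap coord_fixed theme_minimal
#' @export
ggplot2::autoplot

mask_class_colors <- function() {
  c(BACKGROUND = "#222222", ET = "#f2c14e", HHB = "#a0522d",
    XB = "#6a9fb5", LF = "#e8a1b0", RF = "#b8e0a1")
}

#' Plot training/validation curves
#'
#' @param object a `train_result`.
#' @param ... unused.
#' @return a ggplot of loss and mean-IoU per epoch.
#' @export
autoplot.train_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log,
                              c("train_loss", "val_loss", "train_miou", "val_miou"),
                              names_to = "series", values_to = "value")
  long <- dplyr::filter(long, is.finite(.data$value))
  long$panel <- ifelse(grepl("loss", long$series), "loss", "mean IoU")
  ggplot(long, aes(x = .data$epoch, y = .data$value, colour = .data$series)) +
    geom_line() +
    facet_wrap(~panel, scales = "free_y") +
    labs(x = "epoch", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Plot a segmentation mask
#'
#' @param mask integer `[H, W]` matrix of schema labels.
#' @param schema label schema (name -> index).
#' @return a ggplot raster with the package's class colors.
#' @export
plot_mask <- function(mask, schema = label_schema()) {
  df <- tidyr::expand_grid(col = seq_len(ncol(mask)), row = seq_len(nrow(mask)))
  df$class <- factor(names(schema)[as.integer(mask) + 1L], levels = names(schema))
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$class)) +
    geom_raster() +
    scale_fill_manual(values = mask_class_colors(), drop = FALSE) +
    coord_fixed() +
    labs(x = NULL, y = NULL, fill = "class") +
    theme_minimal()
}

#' Plot per-class metrics
#'
#' @param object a `seg_metrics`.
#' @param ... unused.
#' @return a ggplot of per-class IoU / F1 / precision / recall.
#' @export
autoplot.seg_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_class,
                              c("iou", "f1", "precision", "recall"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = factor(.data$class), y = .data$value)) +
    geom_col(fill = "#4477aa") +
    facet_wrap(~metric) +
    labs(x = "class", y = NULL) +
    theme_minimal()
}
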