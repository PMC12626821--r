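# Evaluation and prediction: aggregate a single confusion matrix over all
# pixels of a collection, derive the seven metrics, per-image lesion Dice and
# one-vs-rest AUCs; render boundary overlays and class-probability heatmaps.

#' Evaluate a checkpoint (or parameter set) on a collection
#'
#' @param checkpoint path to a checkpoint file, or a list with `params` and
#'   `config` (as returned by [load_checkpoint()]).
#' @param items a `seg_dataset` collection.
#' @param lesion_class class whose per-image Dice is averaged (default HHB,
#'   the melasma lesion class).
#' @param manifest,train_manifest optional tibbles (`basename`, ...) used for
#'   a train/test leakage check: evaluation refuses a collection whose
#'   basenames overlap the training manifest unless `allow_overlap = TRUE`.
#' @param allow_overlap override the leakage check.
#' @return an `eval_result`: list with `metrics` (a `seg_metrics`, macro
#'   tibble extended with `dice`), `confusion`, `auc` (per-class one-vs-rest),
#'   `dice` (mean per-image lesion Dice).
#' @export
evaluate <- function(checkpoint, items, lesion_class = label_schema()[["HHB"]],
                     manifest = NULL, train_manifest = NULL,
                     allow_overlap = FALSE) {
  ck <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else checkpoint
  if (is.null(ck$params) || is.null(ck$config))
    abort_config("checkpoint does not contain parameters and a network config")
  if (!is.null(manifest) && !is.null(train_manifest) && !allow_overlap) {
    overlap <- intersect(manifest$basename, train_manifest$basename)
    if (length(overlap) > 0L)
      abort_validation(sprintf(
        "collection overlaps the training manifest (%d item(s), e.g. '%s'); pass allow_overlap = TRUE to force",
        length(overlap), overlap[1]))
  }
  k <- ck$config$num_classes
  cm <- matrix(0L, k, k)
  dice <- numeric(length(items))
  probs_list <- vector("list", length(items))
  refs_list <- vector("list", length(items))
  for (i in seq_along(items)) {
    it <- items[[i]]
    pr <- hhbsnet_forward(it$image, ck$params, ck$config, training = FALSE)
    pm <- prob_to_mask(pr)
    cm <- cm + confusion_matrix(pm, it$mask, k)
    dice[i] <- dice_per_image(pm, it$mask, lesion_class)
    d <- dim(pr)
    probs_list[[i]] <- matrix(pr, d[1] * d[2], d[3])
    refs_list[[i]] <- as.integer(it$mask)
  }
  probs <- do.call(rbind, probs_list)
  refs <- unlist(refs_list)
  auc <- roc_auc_ovr(probs, refs)
  metrics <- segmentation_metrics(cm)
  metrics$macro$dice <- mean(dice)
  structure(list(metrics = metrics, confusion = cm, auc = auc,
                 dice = mean(dice), dice_per_image = dice),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  print(x$metrics)
  cat("mean per-image lesion Dice:", format(x$dice, digits = 4), "\n")
  cat("one-vs-rest AUC:\n"); print(round(x$auc, 4))
  invisible(x)
}

#' @export
tidy.eval_result <- function(x, ...) x$metrics$per_class

#' @export
glance.eval_result <- function(x, ...) x$metrics$macro

#' 4-connected boundary of a binary mask
#'
#' The morphological gradient: pixels belonging to the mask with at least one
#' 4-neighbour outside it (image borders count as outside).
#'
#' @param bin logical matrix.
#' @return logical matrix of boundary pixels.
#' @export
mask_boundary <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- bin
  inner <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  bin & !inner
}

#' Predict a mask with overlay and heatmap renderings
#'
#' Runs the network on one image and returns the argmax mask, an overlay
#' image with the lesion (HHB) boundary drawn in red and the face contour
#' (non-background region) in green, and the per-class probability heatmap.
#' Images whose size is not divisible by the backbone's largest stride are
#' zero-padded, predicted, and cropped back (with a notice).
#'
#' @param checkpoint path or loaded checkpoint list.
#' @param image `[H, W, 3]` array.
#' @return list with `mask`, `overlay` (`[H, W, 3]`), `probs`
#'   (`[H, W, K]`).
#' @export
predict_overlay <- function(checkpoint, image) {
  ck <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else checkpoint
  smax <- max(backbone_adapter(ck$config$backbone)$feature_strides)
  d <- dim(image)
  padded <- FALSE
  if (d[1] %% smax != 0L || d[2] %% smax != 0L) {
    Hp <- ceiling(d[1] / smax) * smax
    Wp <- ceiling(d[2] / smax) * smax
    message(sprintf("padding input %dx%d to %dx%d for the backbone stride",
                    d[1], d[2], Hp, Wp))
    imp <- array(0, c(Hp, Wp, 3L))
    imp[seq_len(d[1]), seq_len(d[2]), ] <- image
    image_in <- imp; padded <- TRUE
  } else image_in <- image
  probs <- hhbsnet_forward(image_in, ck$params, ck$config, training = FALSE)
  if (padded) probs <- probs[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
  mask <- prob_to_mask(probs)
  sch <- label_schema()
  overlay <- image
  lesion_b <- mask_boundary(mask == sch[["HHB"]])
  face_b <- mask_boundary(mask != sch[["BACKGROUND"]])
  for (ch in 1:3) {
    plane <- overlay[, , ch]
    plane[face_b] <- c(0, 1, 0)[ch]
    plane[lesion_b] <- c(1, 0, 0)[ch]
    overlay[, , ch] <- plane
  }
  list(mask = mask, overlay = overlay, probs = probs)
}

#' Render a probability channel as a heat-colored image
#'
#' Simple blue-to-red ramp; used for the class-probability heatmap outputs.
#'
#' @param p `[H, W]` matrix in `[0, 1]`.
#' @return `[H, W, 3]` RGB array.
#' @export
heatmap_image <- function(p) {
  p <- pmin(pmax(p, 0), 1)
  r <- pmin(2 * p, 1)
  b <- pmin(2 * (1 - p), 1)
  g <- 1 - abs(2 * p - 1)
  array(c(r, g * 0.6, b), c(dim(p), 3L))
}
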