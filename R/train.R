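# SGD-with-momentum training of the network on (image, mask) collections,
# with on-the-fly augmentation, step-decayed learning rate, per-epoch
# train/validation logging and best/last checkpointing.

#' Training configuration
#'
#' Defaults follow the reference recipe: SGD with momentum 0.9, initial
#' learning rate 7e-3, 180 epochs, batch size 8, step-decayed learning rate.
#'
#' @param epochs number of passes over the training set.
#' @param batch_size images per gradient step (gradients are averaged).
#' @param lr initial learning rate.
#' @param momentum SGD momentum coefficient.
#' @param lr_factor,lr_period step decay: lr at epoch `e` (1-based) is
#'   `lr * lr_factor^floor((e - 1) / lr_period)`.
#' @param loss a [loss_config()].
#' @param augment apply random flip/crop augmentation during training.
#' @param seed integer seed controlling initialization, shuffling and
#'   augmentation draws.
#' @param target_train_miou optional early-stop threshold: training halts
#'   once the running training mean-IoU reaches it (useful for capability
#'   checks); `NULL` disables.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 180L, batch_size = 8L, lr = 7e-3,
                         momentum = 0.9, lr_factor = 0.1, lr_period = 60L,
                         loss = loss_config(), augment = TRUE, seed = 1L,
                         target_train_miou = NULL) {
  if (epochs < 1L) abort_validation("epochs must be >= 1")
  if (batch_size < 1L) abort_validation("batch_size must be >= 1")
  if (lr <= 0) abort_validation("learning rate must be positive")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, momentum = momentum, lr_factor = lr_factor,
                 lr_period = as.integer(lr_period), loss = loss,
                 augment = isTRUE(augment), seed = as.integer(seed),
                 target_train_miou = target_train_miou),
            class = "train_config")
}

# elementwise-walk two parallel parameter trees
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) {
      if (nm %in% c("running_mean", "running_var", "groups")) next
      out[[nm]] <- tree_map2(a[[nm]], b[[nm]], f)
    }
    out
  } else f(a, b)
}

tree_zero <- function(a) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) {
      if (nm %in% c("running_mean", "running_var", "groups")) next
      out[[nm]] <- tree_zero(a[[nm]])
    }
    out
  } else a * 0
}

# the gradient tree mirrors the parameter tree but with bn gradients named
# gamma/beta; align the names before mapping
align_grads <- function(params, grads) {
  if (is.list(params)) {
    out <- params
    for (nm in names(params)) {
      if (nm %in% c("running_mean", "running_var", "groups")) {
        out[[nm]] <- NULL; next
      }
      g <- grads[[nm]]
      if (is.null(g)) g <- if (is.list(params[[nm]]))
        tree_zero(params[[nm]]) else params[[nm]] * 0
      out[[nm]] <- align_grads(params[[nm]], g)
    }
    out
  } else grads
}

sgd_step <- function(params, grads, velocity, lr, momentum) {
  walk <- function(p, g, v) {
    if (is.list(p)) {
      np <- p; nv <- v
      for (nm in names(p)) {
        if (nm %in% c("running_mean", "running_var", "groups")) next
        r <- walk(p[[nm]], g[[nm]], v[[nm]])
        np[[nm]] <- r$p; nv[[nm]] <- r$v
      }
      list(p = np, v = nv)
    } else {
      vnew <- momentum * v - lr * g
      list(p = p + vnew, v = vnew)
    }
  }
  walk(params, grads, velocity)
}

#' Train the network
#'
#' Runs the full loop: shuffled mini-batches with optional on-the-fly
#' augmentation, hybrid loss backpropagation, SGD with momentum, step-decayed
#' learning rate, per-epoch training loss / validation loss / validation
#' mean-IoU logging, and best-validation-mIoU plus last checkpoints.
#'
#' @param cfg a [train_config()].
#' @param net_cfg a [network_config()].
#' @param train_items,val_items `seg_dataset` collections (lists of
#'   `list(name, image, mask)`).
#' @param out_dir directory for checkpoints (created); `NULL` keeps
#'   checkpoints in memory only.
#' @param params optional initial parameters; default fresh initialization
#'   from `cfg$seed`.
#' @param resume path to (or loaded list of) a checkpoint written by a
#'   previous [train()] call: parameters, SGD velocity and the completed
#'   epoch count are restored, and training continues to `cfg$epochs` total
#'   epochs, reproducing an uninterrupted run exactly.
#' @param verbose print one line per epoch.
#' @return a `train_result`: list with `log` (tibble: epoch, lr, train_loss,
#'   train_miou, val_loss, val_miou), `params` (final), `best_params`,
#'   `checkpoints` (paths or NULL), `config`, `net_config`.
#' @export
train <- function(cfg, net_cfg, train_items, val_items = NULL,
                  out_dir = NULL, params = NULL, resume = NULL,
                  verbose = FALSE) {
  if (length(train_items) == 0L) abort_validation("empty training collection")
  start_epoch <- 1L
  velocity <- NULL
  if (!is.null(resume)) {
    ck <- if (is.character(resume)) load_checkpoint(resume) else resume
    params <- ck$params
    velocity <- ck$velocity
    if (!is.null(ck$epoch)) start_epoch <- ck$epoch + 1L
  }
  if (is.null(params)) params <- init_network_params(net_cfg, cfg$seed)
  if (is.null(velocity)) velocity <- tree_zero(params)
  k <- net_cfg$num_classes
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_rows <- vector("list", cfg$epochs)
  best_miou <- -Inf; best_params <- params
  n <- length(train_items)
  stop_early <- FALSE
  if (start_epoch > cfg$epochs)
    abort_validation("checkpoint has already completed the requested epochs")
  for (epoch in seq(start_epoch, cfg$epochs)) {
    lr <- cfg$lr * cfg$lr_factor^((epoch - 1L) %/% cfg$lr_period)
    ord <- withr::with_seed(cfg$seed + epoch, sample.int(n))
    epoch_loss <- 0; nb <- 0L
    cm_train <- matrix(0L, k, k)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      gacc <- NULL; bloss <- 0
      for (i in idx) {
        it <- train_items[[i]]
        im <- it$image; mk <- it$mask
        if (cfg$augment) {
          au <- augment(im, mk, seed = cfg$seed + epoch * 100003L + i)
          im <- au$image; mk <- au$mask
        }
        fw <- net_fw(im, params, net_cfg, training = TRUE, keep_cache = TRUE)
        params <- merge_bn_state(params, fw$state)
        lg <- hybrid_loss_grad(fw$logits, mk, cfg$loss)
        if (!is.finite(lg$loss))
          rlang::abort(sprintf("non-finite loss at epoch %d", epoch),
                       class = "melseg_error_runtime")
        bw <- net_bw(lg$dlogits, fw$cache, params)
        g <- align_grads(params, bw$grads)
        gacc <- if (is.null(gacc)) g else tree_map2(gacc, g, `+`)
        bloss <- bloss + lg$loss
        cm_train <- cm_train + confusion_matrix(prob_to_mask(
          softmax_channels(fw$logits)), mk, k)
      }
      m <- length(idx)
      gacc <- tree_map2(gacc, gacc, function(a, b) a / m)
      upd <- sgd_step(params, gacc, velocity, lr, cfg$momentum)
      params <- upd$p; velocity <- upd$v
      epoch_loss <- epoch_loss + bloss / m
      nb <- nb + 1L
    }
    train_miou <- segmentation_metrics(cm_train)$macro$miou
    val_loss <- NA_real_; val_miou <- NA_real_
    if (!is.null(val_items) && length(val_items) > 0L) {
      vl <- 0; cm <- matrix(0L, k, k)
      for (it in val_items) {
        pr <- hhbsnet_forward(it$image, params, net_cfg, training = FALSE)
        vl <- vl + hybrid_loss(pr, it$mask, cfg$loss)
        cm <- cm + confusion_matrix(prob_to_mask(pr), it$mask, k)
      }
      val_loss <- vl / length(val_items)
      val_miou <- segmentation_metrics(cm)$macro$miou
    }
    sel_miou <- if (is.na(val_miou)) train_miou else val_miou
    if (sel_miou > best_miou) { best_miou <- sel_miou; best_params <- params }
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, train_loss = epoch_loss / nb,
      train_miou = train_miou, val_loss = val_loss, val_miou = val_miou)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  train mIoU %.4f  val mIoU %s",
                      epoch, lr, epoch_loss / nb, train_miou,
                      ifelse(is.na(val_miou), "-", sprintf("%.4f", val_miou))))
    if (!is.null(cfg$target_train_miou) &&
        train_miou >= cfg$target_train_miou) stop_early <- TRUE
    if (stop_early) break
  }
  log <- dplyr::bind_rows(log_rows[!vapply(log_rows, is.null, logical(1))])
  ckpt <- NULL
  if (!is.null(out_dir)) {
    best_path <- file.path(out_dir, "checkpoint_best.rds")
    last_path <- file.path(out_dir, "checkpoint_last.rds")
    last_epoch <- max(c(0L, log$epoch))
    save_checkpoint(best_params, net_cfg, best_path,
                    extra = list(train_config = unclass(cfg)))
    save_checkpoint(params, net_cfg, last_path,
                    extra = list(train_config = unclass(cfg),
                                 velocity = velocity, epoch = last_epoch))
    ckpt <- c(best = best_path, last = last_path)
    utils::write.csv(log, file.path(out_dir, "curves.csv"), row.names = FALSE)
  }
  structure(list(log = log, params = params, best_params = best_params,
                 checkpoints = ckpt, config = cfg, net_config = net_cfg),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("melseg training run: %d epoch(s)\n", nrow(x$log)))
  print(utils::tail(as.data.frame(x$log), 3), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy a training log
#'
#' @param x a `train_result`.
#' @param ... unused.
#' @return the per-epoch log tibble.
#' @export
tidy.train_result <- function(x, ...) x$log

#' @export
glance.train_result <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(epochs = nrow(x$log), final_train_loss = last$train_loss,
                 final_train_miou = last$train_miou,
                 best_val_miou = suppressWarnings(max(x$log$val_miou, na.rm = TRUE)))
}
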