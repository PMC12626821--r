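# Full HHBSNet assembly: backbone -> infusion of the first and last feature
# levels -> GCSA -> MCF -> global feature fusion -> 1x1 classifier head ->
# bilinear upsampling to input resolution -> per-pixel softmax.

#' Network configuration
#'
#' @param num_classes number of segmentation classes (default 6: BACKGROUND,
#'   ET, HHB, XB, LF, RF).
#' @param input_size nominal square input size in pixels.
#' @param working_width channel width of the post-infusion trunk; must be
#'   divisible by 4.
#' @param backbone `"tiny"` (desk-scale, strides 2/4/8/16) or `"mobile"`
#'   (inverted-residual, strides 4/8/16/32).
#' @param mcf_residual include the residual addition inside the MCF block.
#' @return a `network_config` list.
#' @export
network_config <- function(num_classes = 6L, input_size = 512L,
                           working_width = 256L, backbone = "mobile",
                           mcf_residual = TRUE) {
  if (num_classes < 2L) abort_config("num_classes must be at least 2")
  if (working_width %% 4L != 0L)
    abort_config("working_width must be divisible by 4")
  structure(list(num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 working_width = as.integer(working_width),
                 backbone = backbone,
                 mcf_residual = isTRUE(mcf_residual)),
            class = "network_config")
}

#' Desk-scale configuration with the tiny backbone
#'
#' Small trunk used for tests, demonstrations and CPU training on synthetic
#' scenes.
#'
#' @param num_classes,input_size,working_width see [network_config()].
#' @return a `network_config`.
#' @export
tiny_network_config <- function(num_classes = 6L, input_size = 64L,
                                working_width = 32L) {
  network_config(num_classes = num_classes, input_size = input_size,
                 working_width = working_width, backbone = "tiny")
}

#' Initialize all network parameters
#'
#' @param cfg a [network_config()].
#' @param seed integer seed; initialization is fully deterministic given it.
#' @return nested parameter list (backbone, infusion, gcsa, mcf, gff, head).
#' @export
init_network_params <- function(cfg, seed = 1L) {
  adapter <- backbone_adapter(cfg$backbone)
  ww <- cfg$working_width
  w <- adapter$feature_widths
  withr::with_seed(as.integer(seed), {
    list(backbone = init_backbone_params(adapter),
         infusion = init_conv(1L, 1L, w[1] + w[4], ww),
         gcsa = init_gcsa_params(ww),
         mcf = init_mcf_params(ww),
         gff_global = init_conv(1L, 1L, ww, ww),
         gff_proj = init_conv(1L, 1L, 2L * ww, ww),
         head = init_conv(1L, 1L, ww, cfg$num_classes))
  })
}

#' Fuse shallow and deep backbone features (infusion block)
#'
#' The deepest feature map is bilinearly upsampled to the shallow map's
#' spatial size, the two are concatenated (shallow first) and a 1x1
#' convolution projects to the working width.
#'
#' @param shallow,deep feature maps from the first and last backbone levels.
#' @param p infusion conv parameters (`W`, `b`).
#' @return `[H_shallow, W_shallow, working_width]` array.
#' @export
infusion_forward <- function(shallow, deep, p) {
  infusion_fw(shallow, deep, p)$out
}

infusion_fw <- function(shallow, deep, p) {
  ds <- dim(shallow)
  up <- bilinear_resize(deep, ds[1], ds[2])
  cat2 <- array(c(shallow, up), c(ds[1], ds[2], ds[3] + dim(deep)[3]))
  pr <- conv2d_fw(cat2, p$W, p$b)
  list(out = pr$out,
       cache = list(pr = pr$cache, ds = ds, ddeep = dim(deep)))
}

infusion_bw <- function(dout, cache, p) {
  b <- conv2d_bw(dout, cache$pr, p$W)
  ds <- cache$ds; dd <- cache$ddeep
  dshallow <- b$dx[, , seq_len(ds[3]), drop = FALSE]
  dup <- b$dx[, , ds[3] + seq_len(dd[3]), drop = FALSE]
  ddeep <- bilinear_resize_bw(dup, dd[1], dd[2])
  list(dshallow = dshallow, ddeep = ddeep,
       grads = list(infusion = list(W = b$dW, b = b$db)))
}

#' Global feature fusion
#'
#' Global average pooling extracts the overall image semantics; a 1x1
#' convolution transforms the pooled vector, which is broadcast over space,
#' concatenated with the local features and projected back to the input
#' channel count.
#'
#' @param f `[H, W, C]` feature map.
#' @param pg,pp 1x1 conv parameters for the global transform and the final
#'   projection.
#' @return `[H, W, C]` array.
#' @export
global_feature_fusion <- function(f, pg, pp) {
  gff_fw(f, pg, pp)$out
}

gff_fw <- function(f, pg, pp) {
  d <- dim(f)
  g <- gap_fw(f)
  gl <- linear_fw(g$out, list(W = matrix(pg$W, d[3], d[3]), b = pg$b))
  gb <- array(rep(as.vector(gl$out), each = d[1] * d[2]), d)
  cat2 <- array(c(f, gb), c(d[1], d[2], 2L * d[3]))
  pr <- conv2d_fw(cat2, pp$W, pp$b)
  list(out = pr$out,
       cache = list(pr = pr$cache, gap = g$cache, gl = gl$cache, dims = d))
}

gff_bw <- function(dout, cache, pg, pp) {
  d <- cache$dims
  b <- conv2d_bw(dout, cache$pr, pp$W)
  df <- b$dx[, , seq_len(d[3]), drop = FALSE]
  dgb <- b$dx[, , d[3] + seq_len(d[3]), drop = FALSE]
  dgvec <- colSums(matrix(dgb, d[1] * d[2], d[3]))
  glb <- linear_bw(dgvec, cache$gl, list(W = matrix(pg$W, d[3], d[3]), b = pg$b))
  df <- df + gap_bw(as.vector(glb$dx), cache$gap)
  list(dx = df,
       grads = list(gff_global = list(W = array(glb$dW, dim(pg$W)), b = glb$db),
                    gff_proj = list(W = b$dW, b = b$db)))
}

#' Full network forward pass
#'
#' @param image `[H, W, 3]` numeric array, values typically in `[0, 1]`,
#'   spatial size divisible by the backbone's largest stride.
#' @param params parameters from [init_network_params()] or a checkpoint.
#' @param cfg the matching [network_config()].
#' @param training batch-normalization mode.
#' @return `[H, W, num_classes]` probability array; every pixel's class
#'   vector sums to 1.
#' @export
hhbsnet_forward <- function(image, params, cfg, training = FALSE) {
  softmax_channels(net_fw(image, params, cfg, training)$logits)
}

#' Per-pixel class logits (pre-softmax)
#'
#' @inheritParams hhbsnet_forward
#' @return `[H, W, num_classes]` logit array at input resolution.
#' @export
hhbsnet_logits <- function(image, params, cfg, training = FALSE) {
  net_fw(image, params, cfg, training)$logits
}

net_fw <- function(image, params, cfg, training = FALSE, keep_cache = FALSE) {
  adapter <- backbone_adapter(cfg$backbone)
  bb <- backbone_fw(image, adapter, params$backbone, training)
  feats <- bb$out
  inf <- infusion_fw(feats[[1]], feats[[4]], params$infusion)
  ga <- gcsa_fw(inf$out, params$gcsa, training)
  mc <- mcf_fw(ga$out, params$mcf, training, cfg$mcf_residual)
  gf <- gff_fw(mc$out, params$gff_global, params$gff_proj)
  hd <- conv2d_fw(gf$out, params$head$W, params$head$b)
  d <- dim(image)
  logits <- bilinear_resize(hd$out, d[1], d[2])
  out <- list(logits = logits,
              state = list(backbone = bb$state, gcsa = ga$state,
                           mcf = mc$state))
  if (keep_cache)
    out$cache <- list(bb = bb$cache, inf = inf$cache, ga = ga$cache,
                      mc = mc$cache, gf = gf$cache, hd = hd$cache,
                      trunk_hw = dim(hd$out)[1:2], adapter = adapter)
  out
}

net_bw <- function(dlogits, cache, params) {
  thw <- cache$trunk_hw
  dhd <- bilinear_resize_bw(dlogits, thw[1], thw[2])
  hb <- conv2d_bw(dhd, cache$hd, params$head$W)
  gb <- gff_bw(hb$dx, cache$gf, params$gff_global, params$gff_proj)
  mb <- mcf_bw(gb$dx, cache$mc, params$mcf)
  ab <- gcsa_bw(mb$dx, cache$ga, params$gcsa)
  ib <- infusion_bw(ab$dx, cache$inf, params$infusion)
  dfeats <- list(ib$dshallow, NULL, NULL, ib$ddeep)
  bbb <- backbone_bw(dfeats, cache$bb, cache$adapter, params$backbone)
  list(grads = list(backbone = bbb$grads,
                    infusion = ib$grads$infusion,
                    gcsa = ab$grads,
                    mcf = mb$grads,
                    gff_global = gb$grads$gff_global,
                    gff_proj = gb$grads$gff_proj,
                    head = list(W = hb$dW, b = hb$db)))
}

# write updated BN running statistics (returned by a training-mode forward)
# back into the parameter tree
merge_bn_state <- function(params, state) {
  for (nm in names(state)) {
    el <- state[[nm]]
    if (is.list(el) && !is.null(el$running_mean)) {
      params[[nm]]$running_mean <- el$running_mean
      params[[nm]]$running_var <- el$running_var
    } else if (is.list(el)) {
      params[[nm]] <- merge_bn_state(params[[nm]], el)
    }
  }
  params
}

#' Predicted class mask from an image
#'
#' Per-pixel argmax of the class probabilities; ties break toward the lower
#' class index. Labels are 0-based class indices.
#'
#' @inheritParams hhbsnet_forward
#' @return integer `[H, W]` matrix of class labels in `0..num_classes-1`.
#' @export
hhbsnet_predict_mask <- function(image, params, cfg) {
  p <- hhbsnet_forward(image, params, cfg, training = FALSE)
  prob_to_mask(p)
}

prob_to_mask <- function(p) {
  d <- dim(p)
  pm <- matrix(p, d[1] * d[2], d[3])
  matrix(max.col(pm, ties.method = "first") - 1L, d[1], d[2])
}

#' Count trainable parameters
#'
#' Tallies every weight, bias and batch-norm affine parameter (running
#' statistics are buffers, not parameters).
#'
#' @param params a network (or block) parameter list.
#' @return integer count.
#' @export
count_parameters <- function(params) {
  n <- 0L
  walk <- function(x, nm = "") {
    if (is.list(x)) {
      for (k in seq_along(x)) walk(x[[k]], names(x)[k])
    } else if (is.numeric(x) && !nm %in% c("running_mean", "running_var") &&
               nm != "groups") {
      n <<- n + length(x)
    }
  }
  walk(params)
  n
}

#' Save / load a network checkpoint
#'
#' A checkpoint stores parameters, the network configuration, the backbone
#' identifier and a format version; it is written with `saveRDS`.
#'
#' @param params parameter list.
#' @param cfg [network_config()].
#' @param path file path.
#' @param extra optional named list stored alongside (e.g. training state).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, cfg, path, extra = list()) {
  obj <- c(list(format = "melseg-checkpoint", version = 1L,
                params = params, config = unclass(cfg),
                backbone = cfg$backbone), extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "melseg-checkpoint"))
    abort_validation(sprintf("'%s' is not a melseg checkpoint", path))
  obj$config <- structure(obj$config, class = "network_config")
  obj
}
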