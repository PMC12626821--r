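# Backbone feature extractors. Two adapters are provided:
#  * "tiny"      -- a small random-init CNN (four conv-BN-ReLU stages at
#                   strides 2/4/8/16) used in tests and desk-scale runs; no
#                   downloaded weights are ever needed.
#  * "mobile"    -- an inverted-residual (MobileNetV2-style) lightweight
#                   backbone at strides 4/8/16/32, randomly initialized.
# Both expose exactly four feature levels with strictly increasing strides.

#' Describe a backbone adapter
#'
#' @param identifier `"tiny"` or `"mobile"`.
#' @return a `backbone_adapter` list with `identifier`, `feature_strides` and
#'   `feature_widths`.
#' @export
backbone_adapter <- function(identifier = c("tiny", "mobile")) {
  identifier <- match.arg(identifier)
  out <- switch(identifier,
    tiny = list(identifier = "tiny",
                feature_strides = c(2L, 4L, 8L, 16L),
                feature_widths = c(8L, 16L, 24L, 32L)),
    mobile = list(identifier = "mobile",
                  feature_strides = c(4L, 8L, 16L, 32L),
                  feature_widths = c(24L, 32L, 64L, 96L)))
  structure(out, class = "backbone_adapter")
}

init_backbone_params <- function(adapter) {
  w <- adapter$feature_widths
  if (adapter$identifier == "tiny") {
    cin <- c(3L, w[1], w[2], w[3])
    stages <- lapply(1:4, function(i)
      list(conv = init_conv(3L, 3L, cin[i], w[i]), bn = init_bn(w[i])))
    names(stages) <- paste0("stage", 1:4)
    stages
  } else {
    ir <- function(cin, cout, expand = 4L) {
      ce <- cin * expand
      list(pw1 = init_conv(1L, 1L, cin, ce), bn1 = init_bn(ce),
           dw = init_dwconv(3L, 3L, ce), bn2 = init_bn(ce),
           pw2 = init_conv(1L, 1L, ce, cout), bn3 = init_bn(cout))
    }
    list(stem = list(conv = init_conv(3L, 3L, 3L, 16L), bn = init_bn(16L)),
         stage1 = ir(16L, w[1]), stage2 = ir(w[1], w[2]),
         stage3 = ir(w[2], w[3]), stage4 = ir(w[3], w[4]))
  }
}

conv_bn_relu_fw <- function(x, p, training, stride = 1L, dilation = 1L) {
  cv <- conv2d_fw(x, p$conv$W, p$conv$b, stride = stride, dilation = dilation)
  nb <- bn_fw(cv$out, p$bn, training)
  rl <- relu_fw(nb$out)
  list(out = rl$out, state = list(bn = nb$state),
       cache = list(cv = cv$cache, nb = nb$cache, rl = rl$cache))
}

conv_bn_relu_bw <- function(dout, cache, p) {
  dr <- relu_bw(dout, cache$rl)
  bb <- bn_bw(dr, cache$nb)
  cb <- conv2d_bw(bb$dx, cache$cv, p$conv$W)
  list(dx = cb$dx,
       grads = list(conv = list(W = cb$dW, b = cb$db),
                    bn = list(gamma = bb$dgamma, beta = bb$dbeta)))
}

ir_block_fw <- function(x, p, training, stride = 2L) {
  c1 <- conv2d_fw(x, p$pw1$W, p$pw1$b)
  n1 <- bn_fw(c1$out, p$bn1, training); r1 <- relu_fw(n1$out)
  dw <- depthwise_conv2d_fw(r1$out, p$dw$W, p$dw$b, stride = stride, pad = 1L)
  n2 <- bn_fw(dw$out, p$bn2, training); r2 <- relu_fw(n2$out)
  c2 <- conv2d_fw(r2$out, p$pw2$W, p$pw2$b)
  n3 <- bn_fw(c2$out, p$bn3, training)
  list(out = n3$out,
       state = list(bn1 = n1$state, bn2 = n2$state, bn3 = n3$state),
       cache = list(c1 = c1$cache, n1 = n1$cache, r1 = r1$cache, dw = dw$cache,
                    n2 = n2$cache, r2 = r2$cache, c2 = c2$cache, n3 = n3$cache))
}

ir_block_bw <- function(dout, cache, p) {
  b3 <- bn_bw(dout, cache$n3)
  cb2 <- conv2d_bw(b3$dx, cache$c2, p$pw2$W)
  dr2 <- relu_bw(cb2$dx, cache$r2)
  b2 <- bn_bw(dr2, cache$n2)
  dwb <- depthwise_conv2d_bw(b2$dx, cache$dw, p$dw$W)
  dr1 <- relu_bw(dwb$dx, cache$r1)
  b1 <- bn_bw(dr1, cache$n1)
  cb1 <- conv2d_bw(b1$dx, cache$c1, p$pw1$W)
  list(dx = cb1$dx,
       grads = list(pw1 = list(W = cb1$dW, b = cb1$db),
                    bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                    dw = list(W = dwb$dW, b = dwb$db),
                    bn2 = list(gamma = b2$dgamma, beta = b2$dbeta),
                    pw2 = list(W = cb2$dW, b = cb2$db),
                    bn3 = list(gamma = b3$dgamma, beta = b3$dbeta)))
}

#' Extract the four backbone feature levels
#'
#' @param image `[H, W, 3]` numeric array with `H`, `W` divisible by the
#'   adapter's largest stride.
#' @param adapter a [backbone_adapter()].
#' @param params backbone parameters (from the network checkpoint or
#'   random-init).
#' @param training batch-normalization mode.
#' @return list of four `[H/s, W/s, width]` feature maps at the adapter's
#'   declared strides and widths.
#' @export
backbone_features <- function(image, adapter, params, training = FALSE) {
  backbone_fw(image, adapter, params, training)$out
}

backbone_fw <- function(image, adapter, params, training = FALSE) {
  check_feature_map(image, "image")
  d <- dim(image)
  smax <- max(adapter$feature_strides)
  if (d[1] %% smax != 0L || d[2] %% smax != 0L)
    abort_shape(sprintf("input size %dx%d not divisible by the largest stride %d",
                        d[1], d[2], smax))
  if (adapter$identifier == "tiny") {
    feats <- vector("list", 4L); caches <- vector("list", 4L)
    states <- vector("list", 4L)
    x <- image
    for (i in 1:4) {
      st <- conv_bn_relu_fw(x, params[[paste0("stage", i)]], training, stride = 2L)
      x <- st$out; feats[[i]] <- x; caches[[i]] <- st$cache
      states[[i]] <- st$state
    }
    names(states) <- paste0("stage", 1:4)
    list(out = feats, state = states, cache = caches)
  } else {
    stem <- conv_bn_relu_fw(image, params$stem, training, stride = 2L)
    feats <- vector("list", 4L); caches <- vector("list", 5L)
    states <- list(stem = stem$state)
    caches[[1]] <- stem$cache
    x <- stem$out
    for (i in 1:4) {
      st <- ir_block_fw(x, params[[paste0("stage", i)]], training, stride = 2L)
      x <- st$out; feats[[i]] <- x; caches[[i + 1L]] <- st$cache
      states[[paste0("stage", i)]] <- st$state
    }
    list(out = feats, state = states, cache = caches)
  }
}

# dfeats: list of four gradients (NULL allowed) w.r.t. the four levels
backbone_bw <- function(dfeats, cache, adapter, params) {
  if (adapter$identifier == "tiny") {
    grads <- list()
    dx <- NULL
    for (i in 4:1) {
      d <- dfeats[[i]]
      dcur <- if (is.null(dx)) d else if (is.null(d)) dx else dx + d
      bb <- conv_bn_relu_bw(dcur, cache[[i]], params[[paste0("stage", i)]])
      grads[[paste0("stage", i)]] <- bb$grads
      dx <- bb$dx
    }
    list(dx = dx, grads = grads)
  } else {
    grads <- list()
    dx <- NULL
    for (i in 4:1) {
      d <- dfeats[[i]]
      dcur <- if (is.null(dx)) d else if (is.null(d)) dx else dx + d
      bb <- ir_block_bw(dcur, cache[[i + 1L]], params[[paste0("stage", i)]])
      grads[[paste0("stage", i)]] <- bb$grads
      dx <- bb$dx
    }
    sb <- conv_bn_relu_bw(dx, cache[[1]], params$stem)
    grads$stem <- sb$grads
    list(dx = sb$dx, grads = grads)
  }
}
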