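# Global channel-spatial attention (GCSA): per-pixel channel attention with a
# C -> C/4 -> C multilayer perceptron, a 4-group channel shuffle, then 7x7
# spatial attention with batch-normalized convolutions. The channel MLP acts
# along the channel axis independently at every spatial position -- there is
# no global pooling in this block.

#' Initialize GCSA block parameters
#'
#' @param channels channel count `C` of the feature maps the block will see;
#'   must be divisible by 4 (the bottleneck reduces to `C/4`).
#' @param groups group count of the channel shuffle (fixed default 4).
#' @return a parameter list (`mlp1`, `mlp2`, `conv1`, `bn1`, `conv2`, `bn2`,
#'   `groups`).
#' @export
init_gcsa_params <- function(channels, groups = 4L) {
  if (channels %% 4L != 0L)
    abort_config("GCSA requires a channel count divisible by 4")
  if (channels %% groups != 0L)
    abort_config("shuffle group count must divide the channel count")
  cb <- channels %/% 4L
  list(
    mlp1 = init_linear(channels, cb),
    mlp2 = init_linear(cb, channels),
    conv1 = init_conv(7L, 7L, channels, cb),
    bn1 = init_bn(cb),
    conv2 = init_conv(7L, 7L, cb, channels),
    bn2 = init_bn(channels),
    groups = as.integer(groups)
  )
}

check_gcsa <- function(f, p) {
  check_feature_map(f, "f")
  C <- dim(f)[3]
  if (C %% 4L != 0L)
    abort_config("GCSA input channel count must be divisible by 4")
  if (nrow(p$mlp1$W) != C)
    abort_shape(sprintf("GCSA parameters sized for %d channels, input has %d",
                        nrow(p$mlp1$W), C))
  invisible(TRUE)
}

#' Per-pixel channel attention
#'
#' At every spatial position the channel vector is passed through a two-layer
#' MLP (`C -> C/4`, ReLU, `C/4 -> C`) and a sigmoid; the resulting gate in
#' (0, 1) multiplies the input element-wise.
#'
#' @param f `[H, W, C]` feature map with `C` divisible by 4.
#' @param p GCSA parameters from [init_gcsa_params()].
#' @param training unused by this sub-block (no normalization inside); kept
#'   for a uniform block signature.
#' @return `[H, W, C]` array, same shape as `f`.
#' @export
channel_attention_forward <- function(f, p, training = FALSE) {
  channel_attention_fw(f, p)$out
}

channel_attention_fw <- function(f, p) {
  check_gcsa(f, p)
  d <- dim(f)
  xm <- matrix(f, d[1] * d[2], d[3])
  l1 <- linear_fw(xm, p$mlp1)
  r1 <- relu_fw(l1$out)
  l2 <- linear_fw(r1$out, p$mlp2)
  s <- sigmoid_fw(l2$out)
  out <- array(xm * s$out, d)
  list(out = out,
       cache = list(xm = xm, l1 = l1$cache, r1 = r1$cache, l2 = l2$cache,
                    s = s$cache, dims = d))
}

channel_attention_bw <- function(dout, cache, p) {
  d <- cache$dims
  dm <- matrix(dout, d[1] * d[2], d[3])
  dgate <- dm * cache$xm
  dxm <- dm * cache$s
  ds <- sigmoid_bw(dgate, cache$s)
  b2 <- linear_bw(ds, cache$l2, p$mlp2)
  dr <- relu_bw(b2$dx, cache$r1)
  b1 <- linear_bw(dr, cache$l1, p$mlp1)
  dxm <- dxm + b1$dx
  list(dx = array(dxm, d),
       grads = list(mlp1 = list(W = b1$dW, b = b1$db),
                    mlp2 = list(W = b2$dW, b = b2$db)))
}

shuffle_perm <- function(C, groups) {
  if (C %% groups != 0L)
    abort_config("shuffle group count must divide the channel count")
  as.vector(t(matrix(seq_len(C), nrow = C %/% groups)))
}

#' Grouped channel shuffle
#'
#' Splits the channels into `groups` contiguous groups, transposes the
#' (group, within-group) index pair and flattens, interleaving channels across
#' groups. Spatial content of each channel plane is untouched; the operation
#' is a pure permutation of channel planes.
#'
#' @param f `[H, W, C]` feature map.
#' @param groups group count; must divide `C`.
#' @return `[H, W, C]` array with permuted channels.
#' @export
channel_shuffle <- function(f, groups = 4L) {
  check_feature_map(f, "f")
  f[, , shuffle_perm(dim(f)[3], as.integer(groups)), drop = FALSE]
}

channel_shuffle_bw <- function(dout, groups) {
  perm <- shuffle_perm(dim(dout)[3], groups)
  inv <- order(perm)
  dout[, , inv, drop = FALSE]
}

#' Spatial attention with 7x7 convolutions
#'
#' Pipeline `conv7x7 (C -> C/4) -> BN -> ReLU -> conv7x7 (C/4 -> C) -> BN ->
#' sigmoid`, multiplied element-wise with the block input. Zero padding 3
#' preserves the spatial size.
#'
#' @inheritParams channel_attention_forward
#' @param training if `TRUE`, batch normalization uses the statistics of the
#'   current map (and updates its running statistics); otherwise running
#'   statistics are used.
#' @return `[H, W, C]` array, same shape as `f`.
#' @export
spatial_attention_forward <- function(f, p, training = FALSE) {
  spatial_attention_fw(f, p, training)$out
}

spatial_attention_fw <- function(f, p, training = FALSE) {
  check_gcsa(f, p)
  c1 <- conv2d_fw(f, p$conv1$W, p$conv1$b)
  n1 <- bn_fw(c1$out, p$bn1, training)
  r1 <- relu_fw(n1$out)
  c2 <- conv2d_fw(r1$out, p$conv2$W, p$conv2$b)
  n2 <- bn_fw(c2$out, p$bn2, training)
  s <- sigmoid_fw(n2$out)
  list(out = f * s$out,
       state = list(bn1 = n1$state, bn2 = n2$state),
       cache = list(f = f, c1 = c1$cache, n1 = n1$cache, r1 = r1$cache,
                    c2 = c2$cache, n2 = n2$cache, s = s$cache))
}

spatial_attention_bw <- function(dout, cache, p) {
  dgate <- dout * cache$f
  df <- dout * cache$s
  ds <- sigmoid_bw(dgate, cache$s)
  bn2 <- bn_bw(ds, cache$n2)
  b2 <- conv2d_bw(bn2$dx, cache$c2, p$conv2$W)
  dr <- relu_bw(b2$dx, cache$r1)
  bn1 <- bn_bw(dr, cache$n1)
  b1 <- conv2d_bw(bn1$dx, cache$c1, p$conv1$W)
  df <- df + b1$dx
  list(dx = df,
       grads = list(conv1 = list(W = b1$dW, b = b1$db),
                    bn1 = list(gamma = bn1$dgamma, beta = bn1$dbeta),
                    conv2 = list(W = b2$dW, b = b2$db),
                    bn2 = list(gamma = bn2$dgamma, beta = bn2$dbeta)))
}

#' GCSA block forward pass
#'
#' Composition channel attention -> grouped channel shuffle -> spatial
#' attention. Shape is preserved.
#'
#' @inheritParams spatial_attention_forward
#' @return `[H, W, C]` array, same shape as `f`.
#' @export
gcsa_forward <- function(f, p, training = FALSE) {
  gcsa_fw(f, p, training)$out
}

gcsa_fw <- function(f, p, training = FALSE) {
  ca <- channel_attention_fw(f, p)
  xs <- channel_shuffle(ca$out, p$groups)
  sa <- spatial_attention_fw(xs, p, training)
  list(out = sa$out, state = sa$state,
       cache = list(ca = ca$cache, sa = sa$cache, groups = p$groups))
}

gcsa_bw <- function(dout, cache, p) {
  sa <- spatial_attention_bw(dout, cache$sa, p)
  dxs <- channel_shuffle_bw(sa$dx, cache$groups)
  ca <- channel_attention_bw(dxs, cache$ca, p)
  list(dx = ca$dx, grads = c(ca$grads, sa$grads))
}
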