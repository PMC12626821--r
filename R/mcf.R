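# Multi-scale cavity fusion (MCF): five parallel branches -- a 1x1 conv,
# three depthwise-separable 3x3 convolutions dilated at rates 6/12/18, and a
# global-average-pooling branch -- concatenated and projected back to C
# channels, then calibrated by channel and spatial attention and residually
# fused. Dilated branches use "same" padding equal to the dilation rate so
# resolution is never reduced.

MCF_RATES <- c(6L, 12L, 18L)

#' Initialize MCF block parameters
#'
#' @param channels working channel count `C`; must be divisible by 4 (the
#'   channel-calibration bottleneck is `C/4`).
#' @return parameter list with the five branches, projection, calibration and
#'   output-fusion layers.
#' @export
init_mcf_params <- function(channels) {
  if (channels %% 4L != 0L)
    abort_config("MCF requires a channel count divisible by 4")
  br <- function() list(dw = init_dwconv(3L, 3L, channels),
                        pw = init_conv(1L, 1L, channels, channels),
                        bn = init_bn(channels))
  list(
    branch1 = list(conv = init_conv(1L, 1L, channels, channels),
                   bn = init_bn(channels)),
    branch2 = br(), branch3 = br(), branch4 = br(),
    branch5 = list(fc = init_linear(channels, channels)),
    proj_in = init_conv(1L, 1L, 5L * channels, channels),
    ca_fc1 = init_linear(channels, channels %/% 4L),
    ca_fc2 = init_linear(channels %/% 4L, channels),
    sa_conv = init_conv(1L, 1L, 2L, 1L),
    proj_out = init_conv(1L, 1L, channels, channels)
  )
}

#' The five parallel MCF branches
#'
#' Branch 1: 1x1 conv, BN, ReLU. Branches 2-4: depthwise 3x3 convolution at
#' dilation rate 6, 12 and 18 followed by a pointwise 1x1 conv, BN, ReLU.
#' Branch 5: global average pooling, a 1x1 conv (a linear map on the pooled
#' vector), ReLU, broadcast back to `H x W` (spatially constant).
#'
#' @param x `[H, W, C]` feature map, `C` divisible by 4.
#' @param p MCF parameters from [init_mcf_params()].
#' @param training batch-normalization mode.
#' @return list of five `[H, W, C]` arrays.
#' @export
mcf_branches <- function(x, p, training = FALSE) {
  mcf_branches_fw(x, p, training)$out
}

mcf_branches_fw <- function(x, p, training = FALSE) {
  check_feature_map(x, "x")
  d <- dim(x)
  # branch 1
  c1 <- conv2d_fw(x, p$branch1$conv$W, p$branch1$conv$b)
  n1 <- bn_fw(c1$out, p$branch1$bn, training)
  r1 <- relu_fw(n1$out)
  dilated <- vector("list", 3L)
  for (k in 1:3) {
    bp <- p[[paste0("branch", k + 1L)]]
    dw <- depthwise_conv2d_fw(x, bp$dw$W, bp$dw$b, dilation = MCF_RATES[k])
    pw <- conv2d_fw(dw$out, bp$pw$W, bp$pw$b)
    nb <- bn_fw(pw$out, bp$bn, training)
    rb <- relu_fw(nb$out)
    dilated[[k]] <- list(out = rb$out, dw = dw$cache, pw = pw$cache,
                         bn = nb$cache, bn_state = nb$state, relu = rb$cache)
  }
  g <- gap_fw(x)
  l5 <- linear_fw(g$out, p$branch5$fc)
  r5 <- relu_fw(as.vector(l5$out))
  b5 <- array(rep(r5$out, each = d[1] * d[2]), d)
  states <- list(branch1 = list(bn = n1$state),
                 branch2 = list(bn = dilated[[1]]$bn_state),
                 branch3 = list(bn = dilated[[2]]$bn_state),
                 branch4 = list(bn = dilated[[3]]$bn_state))
  list(out = list(r1$out, dilated[[1]]$out, dilated[[2]]$out,
                  dilated[[3]]$out, b5),
       state = states,
       cache = list(dims = d, c1 = c1$cache, n1 = n1$cache, r1 = r1$cache,
                    dilated = dilated, gap = g$cache, l5 = l5$cache,
                    r5 = r5$cache))
}

mcf_branches_bw <- function(douts, cache, p) {
  d <- cache$dims
  # branch 1
  dr1 <- relu_bw(douts[[1]], cache$r1)
  bn1 <- bn_bw(dr1, cache$n1)
  b1 <- conv2d_bw(bn1$dx, cache$c1, p$branch1$conv$W)
  dx <- b1$dx
  grads <- list(branch1 = list(conv = list(W = b1$dW, b = b1$db),
                               bn = list(gamma = bn1$dgamma, beta = bn1$dbeta)))
  for (k in 1:3) {
    bp <- p[[paste0("branch", k + 1L)]]
    cc <- cache$dilated[[k]]
    drb <- relu_bw(douts[[k + 1L]], cc$relu)
    bnb <- bn_bw(drb, cc$bn)
    pwb <- conv2d_bw(bnb$dx, cc$pw, bp$pw$W)
    dwb <- depthwise_conv2d_bw(pwb$dx, cc$dw, bp$dw$W)
    dx <- dx + dwb$dx
    grads[[paste0("branch", k + 1L)]] <-
      list(dw = list(W = dwb$dW, b = dwb$db),
           pw = list(W = pwb$dW, b = pwb$db),
           bn = list(gamma = bnb$dgamma, beta = bnb$dbeta))
  }
  dvec5 <- colSums(matrix(douts[[5]], d[1] * d[2], d[3]))
  dr5 <- relu_bw(dvec5, cache$r5)
  l5b <- linear_bw(dr5, cache$l5, p$branch5$fc)
  dx <- dx + gap_bw(as.vector(l5b$dx), cache$gap)
  grads$branch5 <- list(fc = list(W = l5b$dW, b = l5b$db))
  list(dx = dx, grads = grads)
}

#' Concatenate the five branch outputs and project back to C channels
#'
#' @param branches list of five `[H, W, C]` arrays of identical shape.
#' @param p MCF parameters.
#' @return `[H, W, C]` array.
#' @export
mcf_concat_project <- function(branches, p) {
  mcf_concat_project_fw(branches, p)$out
}

mcf_concat_project_fw <- function(branches, p) {
  dims <- lapply(branches, dim)
  if (length(branches) != 5L || length(unique(lapply(dims, identity))) != 1L)
    abort_shape("mcf_concat_project expects five feature maps of identical shape")
  d <- dims[[1]]
  cat5 <- array(unlist(branches, use.names = FALSE), c(d[1], d[2], 5L * d[3]))
  pr <- conv2d_fw(cat5, p$proj_in$W, p$proj_in$b)
  list(out = pr$out, cache = list(pr = pr$cache, d = d))
}

mcf_concat_project_bw <- function(dout, cache, p) {
  b <- conv2d_bw(dout, cache$pr, p$proj_in$W)
  d <- cache$d
  douts <- lapply(0:4, function(k) b$dx[, , k * d[3] + seq_len(d[3]), drop = FALSE])
  list(dbranches = douts,
       grads = list(proj_in = list(W = b$dW, b = b$db)))
}

#' Channel calibration of the merged MCF map
#'
#' `w_c = sigmoid(FC2(ReLU(FC1(global average pool))))`, broadcast over space
#' and multiplied with the input.
#'
#' @param f `[H, W, C]` merged feature map.
#' @param p MCF parameters.
#' @return `[H, W, C]` array.
#' @export
mcf_channel_calibration <- function(f, p) {
  mcf_channel_calibration_fw(f, p)$out
}

mcf_channel_calibration_fw <- function(f, p) {
  check_feature_map(f, "f")
  d <- dim(f)
  if (nrow(p$ca_fc1$W) != d[3]) abort_shape("channel calibration sized for a different C")
  g <- gap_fw(f)
  l1 <- linear_fw(g$out, p$ca_fc1)
  r1 <- relu_fw(l1$out)
  l2 <- linear_fw(r1$out, p$ca_fc2)
  w <- sigmoid_fw(as.vector(l2$out))
  out <- sweep(f, 3L, w$out, "*")
  list(out = out,
       cache = list(f = f, gap = g$cache, l1 = l1$cache, r1 = r1$cache,
                    l2 = l2$cache, w = w$cache, dims = d))
}

mcf_channel_calibration_bw <- function(dout, cache, p) {
  d <- cache$dims
  dw_vec <- colSums(matrix(dout * cache$f, d[1] * d[2], d[3]))
  df <- sweep(dout, 3L, cache$w, "*")
  ds <- sigmoid_bw(dw_vec, cache$w)
  l2b <- linear_bw(ds, cache$l2, p$ca_fc2)
  drb <- relu_bw(l2b$dx, cache$r1)
  l1b <- linear_bw(drb, cache$l1, p$ca_fc1)
  df <- df + gap_bw(as.vector(l1b$dx), cache$gap)
  list(dx = df,
       grads = list(ca_fc1 = list(W = l1b$dW, b = l1b$db),
                    ca_fc2 = list(W = l2b$dW, b = l2b$db)))
}

#' Spatial calibration of the merged MCF map
#'
#' Per-pixel channel mean and channel max are stacked into a 2-channel map, a
#' 1x1 convolution and sigmoid produce a `[H, W, 1]` weight map, which gates
#' every channel of the input.
#'
#' @inheritParams mcf_channel_calibration
#' @return `[H, W, C]` array.
#' @export
mcf_spatial_calibration <- function(f, p) {
  mcf_spatial_calibration_fw(f, p)$out
}

mcf_spatial_calibration_fw <- function(f, p) {
  check_feature_map(f, "f")
  d <- dim(f)
  xm <- matrix(f, d[1] * d[2], d[3])
  mean_map <- rowMeans(xm)
  which_max <- max.col(xm, ties.method = "first")
  max_map <- xm[cbind(seq_len(nrow(xm)), which_max)]
  fs <- array(c(mean_map, max_map), c(d[1], d[2], 2L))
  cv <- conv2d_fw(fs, p$sa_conv$W, p$sa_conv$b)
  w <- sigmoid_fw(cv$out)                       # [H, W, 1]
  out <- f * as.vector(w$out)
  list(out = out,
       cache = list(f = f, which_max = which_max, cv = cv$cache, w = w$cache,
                    dims = d))
}

mcf_spatial_calibration_bw <- function(dout, cache, p) {
  d <- cache$dims
  wmap <- as.vector(cache$w)
  df <- dout * wmap
  dwmap <- rowSums(matrix(dout * cache$f, d[1] * d[2], d[3]))
  ds <- sigmoid_bw(array(dwmap, c(d[1], d[2], 1L)), cache$w)
  cvb <- conv2d_bw(ds, cache$cv, p$sa_conv$W)
  dmean <- as.vector(cvb$dx[, , 1L]) / d[3]
  dmax <- as.vector(cvb$dx[, , 2L])
  dfm <- matrix(df, d[1] * d[2], d[3])
  dfm <- dfm + dmean                                    # mean spreads evenly
  dfm[cbind(seq_len(nrow(dfm)), cache$which_max)] <-
    dfm[cbind(seq_len(nrow(dfm)), cache$which_max)] + dmax
  list(dx = array(dfm, d),
       grads = list(sa_conv = list(W = cvb$dW, b = cvb$db)))
}

#' Residual fusion of the calibrated maps
#'
#' `proj_out(F_c' + F_s' + original)`: the channel- and spatially-calibrated
#' maps are added element-wise, the original merged map is added residually,
#' and a 1x1 convolution integrates the result.
#'
#' @param fc,fs,original `[H, W, C]` arrays of identical shape.
#' @param p MCF parameters.
#' @return `[H, W, C]` array.
#' @export
mcf_fuse <- function(fc, fs, original, p) {
  mcf_fuse_fw(fc, fs, original, p)$out
}

mcf_fuse_fw <- function(fc, fs, original, p) {
  if (!identical(dim(fc), dim(fs)) || !identical(dim(fc), dim(original)))
    abort_shape("mcf_fuse expects three maps of identical shape")
  s <- fc + fs + original
  pr <- conv2d_fw(s, p$proj_out$W, p$proj_out$b)
  list(out = pr$out, cache = pr$cache)
}

mcf_fuse_bw <- function(dout, cache, p) {
  b <- conv2d_bw(dout, cache, p$proj_out$W)
  list(dsum = b$dx, grads = list(proj_out = list(W = b$dW, b = b$db)))
}

#' MCF block forward pass
#'
#' Full composition: branches -> concat/project -> channel and spatial
#' calibration of the projected map -> residual fusion with the projected map.
#' Shape `[H, W, C]` is preserved.
#'
#' @inheritParams mcf_branches
#' @param residual include the residual addition of the merged map (default
#'   `TRUE`).
#' @return `[H, W, C]` array.
#' @export
mcf_forward <- function(x, p, training = FALSE, residual = TRUE) {
  mcf_fw(x, p, training, residual)$out
}

mcf_fw <- function(x, p, training = FALSE, residual = TRUE) {
  br <- mcf_branches_fw(x, p, training)
  cp <- mcf_concat_project_fw(br$out, p)
  merged <- cp$out
  cc <- mcf_channel_calibration_fw(merged, p)
  sc <- mcf_spatial_calibration_fw(merged, p)
  orig <- if (residual) merged else array(0, dim(merged))
  fu <- mcf_fuse_fw(cc$out, sc$out, orig, p)
  list(out = fu$out, state = br$state,
       cache = list(br = br$cache, cp = cp$cache, cc = cc$cache, sc = sc$cache,
                    fu = fu$cache, residual = residual))
}

mcf_bw <- function(dout, cache, p) {
  fu <- mcf_fuse_bw(dout, cache$fu, p)
  dsum <- fu$dsum
  cc <- mcf_channel_calibration_bw(dsum, cache$cc, p)
  sc <- mcf_spatial_calibration_bw(dsum, cache$sc, p)
  dmerged <- cc$dx + sc$dx
  if (cache$residual) dmerged <- dmerged + dsum
  cp <- mcf_concat_project_bw(dmerged, cache$cp, p)
  br <- mcf_branches_bw(cp$dbranches, cache$br, p)
  list(dx = br$dx,
       grads = c(br$grads, cp$grads, cc$grads, sc$grads, fu$grads))
}
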