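# Minimal dense tensor engine for the network: feature maps are [H, W, C]
# arrays, convolutions are im2col + matmul, and every forward op has an
# analytic backward so the whole network trains with plain R.

.idx_cache <- new.env(parent = emptyenv())

# Linear indices into a padded [Hp, Wp, C] array that gather im2col patches
# as a [Ho*Wo, kh*kw*C] matrix (tap index fastest, then channel).
im2col_index <- function(H, W, C, kh, kw, stride, dilation, pad) {
  key <- paste(H, W, C, kh, kw, stride, dilation, pad, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - (kh - 1L) * dilation - 1L) %/% stride + 1L
  Wo <- (Wp - (kw - 1L) * dilation - 1L) %/% stride + 1L
  if (Ho < 1L || Wo < 1L) abort_shape("spatial extent too small for this kernel")
  hh <- (seq_len(Ho) - 1L) * stride + 1L
  ww <- (seq_len(Wo) - 1L) * stride + 1L
  base <- as.vector(outer(hh, (ww - 1L) * Hp, "+"))            # [Ho*Wo]
  taps <- as.vector(outer((seq_len(kh) - 1L) * dilation,
                          (seq_len(kw) - 1L) * dilation * Hp, "+")) # [kh*kw]
  chan <- (seq_len(C) - 1L) * (Hp * Wp)
  idx <- outer(outer(base, taps, "+"), chan, "+")
  # keep as a dimensionless integer vector: matrix subscripts with ncol == 3
  # would be read as (i, j, k) coordinates, not linear indices
  dim(idx) <- NULL
  idx <- as.integer(idx)
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp,
              ncol = kh * kw * C)
  .idx_cache[[key]] <- out
  out
}

pad_map <- function(x, pad, mode = "zero") {
  if (pad == 0L) return(x)
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  xp <- array(0, c(Hp, Wp, C))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  if (mode == "circular") {
    ih <- ((seq_len(Hp) - pad - 1L) %% H) + 1L
    iw <- ((seq_len(Wp) - pad - 1L) %% W) + 1L
    xp <- x[ih, iw, , drop = FALSE]
  }
  xp
}

same_pad <- function(k, dilation) as.integer(((k - 1L) * dilation) %/% 2L)

#' 2-D convolution over an [H, W, C] feature map
#'
#' Dense cross-correlation with odd square kernels, "same" zero padding by
#' default, arbitrary stride and dilation. Weights are `[kh, kw, Cin, Cout]`.
#'
#' @param x `[H, W, C]` numeric array.
#' @param weight `[kh, kw, Cin, Cout]` numeric array.
#' @param bias length-`Cout` numeric vector (or `NULL` for none).
#' @param stride,dilation positive integers.
#' @param pad integer padding per side, or `"same"` to preserve spatial size
#'   at stride 1.
#' @param pad_mode `"zero"` or `"circular"` (periodic) padding.
#' @return `[Ho, Wo, Cout]` numeric array.
#' @export
conv2d <- function(x, weight, bias = NULL, stride = 1L, dilation = 1L,
                   pad = "same", pad_mode = "zero") {
  conv2d_fw(x, weight, bias, stride, dilation, pad, pad_mode)$out
}

conv2d_fw <- function(x, weight, bias = NULL, stride = 1L, dilation = 1L,
                      pad = "same", pad_mode = "zero") {
  d <- dim(x); dw <- dim(weight)
  if (d[3] != dw[3])
    abort_shape(sprintf("input has %d channels but kernel expects %d", d[3], dw[3]))
  if (dw[1] == 1L && dw[2] == 1L && stride == 1L) {
    # pointwise fast path: a 1x1 conv is a per-pixel linear map
    cols <- x
    dim(cols) <- c(d[1] * d[2], d[3])
    Wm <- weight
    dim(Wm) <- c(d[3], dw[4])
    out <- cols %*% Wm
    if (!is.null(bias)) out <- out + rep(bias, each = nrow(out))
    dim(out) <- c(d[1], d[2], dw[4])
    return(list(out = out,
                cache = list(cols = cols, dims = d, dw = dw, pad = 0L,
                             stride = 1L, dilation = 1L,
                             ii = list(Ho = d[1], Wo = d[2]),
                             pad_mode = pad_mode, pointwise = TRUE)))
  }
  p <- if (identical(pad, "same")) same_pad(dw[1], dilation) else as.integer(pad)
  ii <- im2col_index(d[1], d[2], d[3], dw[1], dw[2],
                     as.integer(stride), as.integer(dilation), p)
  xp <- pad_map(x, p, pad_mode)
  cols <- xp[ii$idx]
  dim(cols) <- c(ii$Ho * ii$Wo, ii$ncol)
  Wm <- weight
  dim(Wm) <- c(dw[1] * dw[2] * dw[3], dw[4])
  out <- cols %*% Wm
  if (!is.null(bias)) out <- out + rep(bias, each = nrow(out))
  dim(out) <- c(ii$Ho, ii$Wo, dw[4])
  list(out = out,
       cache = list(cols = cols, dims = d, dw = dw, pad = p, stride = stride,
                    dilation = dilation, ii = ii, pad_mode = pad_mode))
}

conv2d_bw <- function(dout, cache, weight, has_bias = TRUE) {
  dw <- cache$dw; ii <- cache$ii; d <- cache$dims
  dm <- dout
  dim(dm) <- c(ii$Ho * ii$Wo, dw[4])
  dWm <- crossprod(cache$cols, dm)
  db <- if (has_bias) colSums(dm) else NULL
  if (isTRUE(cache$pointwise)) {
    Wm <- weight
    dim(Wm) <- c(d[3], dw[4])
    dx <- tcrossprod(dm, Wm)
    dim(dx) <- d
    return(list(dx = dx, dW = array(dWm, dw), db = db))
  }
  if (cache$stride == 1L && cache$pad_mode == "zero" &&
      ii$Ho == d[1] && ii$Wo == d[2]) {
    # "same"-padded stride-1 case: the input gradient is the convolution of
    # dout with the spatially flipped, channel-transposed kernel
    Wt <- aperm(weight[dw[1]:1, dw[2]:1, , , drop = FALSE], c(1, 2, 4, 3))
    dx <- conv2d(dout, Wt, NULL, stride = 1L, dilation = cache$dilation,
                 pad = cache$pad)
  } else {
    Wm <- weight
    dim(Wm) <- c(dw[1] * dw[2] * dw[3], dw[4])
    dcols <- tcrossprod(dm, Wm)                    # [HoWo, khkwC]
    dxp <- array(0, c(ii$Hp, ii$Wp, d[3]))
    kh <- dw[1]; kw <- dw[2]; khkw <- kh * kw
    hh <- (seq_len(ii$Ho) - 1L) * cache$stride
    ww <- (seq_len(ii$Wo) - 1L) * cache$stride
    for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
      tap <- (kj - 1L) * kh + ki
      hi <- hh + 1L + (ki - 1L) * cache$dilation
      wi <- ww + 1L + (kj - 1L) * cache$dilation
      blk <- dcols[, tap + (seq_len(d[3]) - 1L) * khkw, drop = FALSE]
      dim(blk) <- c(ii$Ho, ii$Wo, d[3])
      dxp[hi, wi, ] <- dxp[hi, wi, ] + blk
    }
    p <- cache$pad
    dx <- if (p > 0L) {
      if (cache$pad_mode == "circular") {
        acc <- array(0, d)
        ih <- ((seq_len(ii$Hp) - p - 1L) %% d[1]) + 1L
        iw <- ((seq_len(ii$Wp) - p - 1L) %% d[2]) + 1L
        for (a in seq_len(ii$Hp)) for (b in seq_len(ii$Wp))
          acc[ih[a], iw[b], ] <- acc[ih[a], iw[b], ] + dxp[a, b, ]
        acc
      } else dxp[p + seq_len(d[1]), p + seq_len(d[2]), , drop = FALSE]
    } else dxp
  }
  list(dx = dx, dW = array(dWm, dw), db = db)
}

#' Depthwise 2-D convolution
#'
#' Each channel is convolved with its own `[kh, kw]` kernel; used by the
#' dilated branches of the multi-scale cavity fusion block.
#'
#' @param x `[H, W, C]` array.
#' @param weight `[kh, kw, C]` array, one kernel per channel.
#' @param bias length-`C` vector or `NULL`.
#' @inheritParams conv2d
#' @return `[Ho, Wo, C]` array.
#' @export
depthwise_conv2d <- function(x, weight, bias = NULL, stride = 1L,
                             dilation = 1L, pad = "same", pad_mode = "zero") {
  depthwise_conv2d_fw(x, weight, bias, stride, dilation, pad, pad_mode)$out
}

depthwise_conv2d_fw <- function(x, weight, bias = NULL, stride = 1L,
                                dilation = 1L, pad = "same", pad_mode = "zero") {
  d <- dim(x); dw <- dim(weight)
  if (d[3] != dw[3]) abort_shape("depthwise kernel count must equal channel count")
  p <- if (identical(pad, "same")) same_pad(dw[1], dilation) else as.integer(pad)
  ii <- im2col_index(d[1], d[2], d[3], dw[1], dw[2],
                     as.integer(stride), as.integer(dilation), p)
  xp <- pad_map(x, p, pad_mode)
  cols <- xp[ii$idx]
  dim(cols) <- c(ii$Ho * ii$Wo, ii$ncol)
  khkw <- dw[1] * dw[2]
  n <- ii$Ho * ii$Wo
  wm <- weight
  dim(wm) <- c(khkw, d[3])
  out <- matrix(0, n, d[3])
  cix <- (seq_len(d[3]) - 1L) * khkw
  for (k in seq_len(khkw)) {
    out <- out + cols[, k + cix, drop = FALSE] * rep(wm[k, ], each = n)
  }
  if (!is.null(bias)) out <- out + rep(bias, each = nrow(out))
  dim(out) <- c(ii$Ho, ii$Wo, d[3])
  list(out = out,
       cache = list(cols = cols, dims = d, dw = dw, pad = p, stride = stride,
                    dilation = dilation, ii = ii, pad_mode = pad_mode))
}

depthwise_conv2d_bw <- function(dout, cache, weight, has_bias = TRUE) {
  dw <- cache$dw; ii <- cache$ii; d <- cache$dims
  khkw <- dw[1] * dw[2]
  dm <- dout
  dim(dm) <- c(ii$Ho * ii$Wo, d[3])
  dWm <- matrix(0, khkw, d[3])
  cix <- (seq_len(d[3]) - 1L) * khkw
  for (k in seq_len(khkw)) {
    dWm[k, ] <- colSums(cache$cols[, k + cix, drop = FALSE] * dm)
  }
  dW <- array(dWm, dw)
  db <- if (has_bias) colSums(dm) else NULL
  if (cache$stride == 1L && cache$pad_mode == "zero" &&
      ii$Ho == d[1] && ii$Wo == d[2]) {
    Wt <- weight[dw[1]:1, dw[2]:1, , drop = FALSE]
    dx <- depthwise_conv2d(dout, Wt, NULL, stride = 1L,
                           dilation = cache$dilation, pad = cache$pad)
    return(list(dx = dx, dW = dW, db = db))
  }
  dcols <- matrix(0, nrow(cache$cols), ncol(cache$cols))
  for (c in seq_len(d[3])) {
    sl <- (c - 1L) * khkw + seq_len(khkw)
    dcols[, sl] <- tcrossprod(dm[, c], as.vector(weight[, , c]))
  }
  dxp <- array(0, c(ii$Hp, ii$Wp, d[3]))
  hh <- (seq_len(ii$Ho) - 1L) * cache$stride
  ww <- (seq_len(ii$Wo) - 1L) * cache$stride
  for (kj in seq_len(dw[2])) for (ki in seq_len(dw[1])) {
    tap <- (kj - 1L) * dw[1] + ki
    hi <- hh + 1L + (ki - 1L) * cache$dilation
    wi <- ww + 1L + (kj - 1L) * cache$dilation
    blk <- dcols[, tap + (seq_len(d[3]) - 1L) * khkw, drop = FALSE]
    dim(blk) <- c(ii$Ho, ii$Wo, d[3])
    dxp[hi, wi, ] <- dxp[hi, wi, ] + blk
  }
  p <- cache$pad
  dx <- if (p > 0L) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = db)
}

# ---- batch normalization (per channel over H x W) --------------------------

bn_fw <- function(x, p, training = FALSE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- x
  dim(xm) <- c(n, d[3])
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    v <- colMeans(xc * xc)
    p$running_mean <- (1 - momentum) * p$running_mean + momentum * mu
    p$running_var <- (1 - momentum) * p$running_var +
      momentum * v * n / max(n - 1, 1)
  } else {
    mu <- p$running_mean
    v <- p$running_var
    xc <- xm - rep(mu, each = n)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = n)
  out <- xhat * rep(p$gamma, each = n) + rep(p$beta, each = n)
  dim(out) <- d
  list(out = out, state = p,
       cache = list(xhat = xhat, inv = inv, dims = d, training = training,
                    gamma = p$gamma))
}

bn_bw <- function(dout, cache) {
  d <- cache$dims; n <- d[1] * d[2]
  dm <- dout
  dim(dm) <- c(n, d[3])
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- dm * rep(cache$gamma, each = n)
  if (cache$training) {
    t1 <- dxhat - rep(colMeans(dxhat), each = n)
    t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)
    dx <- (t1 - t2) * rep(cache$inv, each = n)
  } else {
    dx <- dxhat * rep(cache$inv, each = n)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- pointwise nonlinearities ----------------------------------------------

relu_fw <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bw <- function(dout, cache) dout * cache
sigmoid <- function(x) 1 / (1 + exp(-x))
sigmoid_fw <- function(x) { y <- sigmoid(x); list(out = y, cache = y) }
sigmoid_bw <- function(dout, cache) dout * cache * (1 - cache)

# ---- global average pooling ------------------------------------------------

gap_fw <- function(x) {
  d <- dim(x)
  list(out = colMeans(matrix(x, d[1] * d[2], d[3])), cache = d)
}
gap_bw <- function(dvec, cache) {
  d <- cache
  array(rep(dvec / (d[1] * d[2]), each = d[1] * d[2]), d)
}

# ---- linear (fully connected) ----------------------------------------------

linear_fw <- function(x, p) {
  xm <- if (is.matrix(x)) x else matrix(x, 1L)
  list(out = sweep(xm %*% p$W, 2L, p$b, "+"), cache = xm)
}
linear_bw <- function(dout, cache, p) {
  dm <- if (is.matrix(dout)) dout else matrix(dout, 1L)
  list(dx = tcrossprod(dm, p$W), dW = crossprod(cache, dm), db = colSums(dm))
}

# ---- bilinear interpolation ------------------------------------------------

.interp_cache <- new.env(parent = emptyenv())

interp_matrix <- function(n_in, n_out) {
  key <- paste(n_in, n_out, sep = "_")
  hit <- .interp_cache[[key]]
  if (!is.null(hit)) return(hit)
  src <- pmin(pmax((seq_len(n_out) - 0.5) * n_in / n_out - 0.5, 0), n_in - 1)
  i0 <- floor(src); w1 <- src - i0
  i1 <- pmin(i0 + 1, n_in - 1)
  R <- matrix(0, n_out, n_in)
  R[cbind(seq_len(n_out), i0 + 1)] <- R[cbind(seq_len(n_out), i0 + 1)] + (1 - w1)
  R[cbind(seq_len(n_out), i1 + 1)] <- R[cbind(seq_len(n_out), i1 + 1)] + w1
  .interp_cache[[key]] <- R
  R
}

apply_row_col <- function(x, Ry, Rx) {
  d <- dim(x)
  t1 <- Ry %*% matrix(x, d[1], d[2] * d[3])            # [Ho, W*C]
  a1 <- array(t1, c(nrow(Ry), d[2], d[3]))
  m2 <- matrix(aperm(a1, c(2, 1, 3)), d[2], nrow(Ry) * d[3])
  t2 <- Rx %*% m2                                      # [Wo, Ho*C]
  aperm(array(t2, c(nrow(Rx), nrow(Ry), d[3])), c(2, 1, 3))
}

#' Bilinear resize of a feature map
#'
#' Pixel-center aligned bilinear interpolation (the convention used for the
#' decoder upsampling and image resizing throughout the package).
#'
#' @param x `[H, W, C]` array.
#' @param h_out,w_out output spatial size.
#' @return `[h_out, w_out, C]` array.
#' @export
bilinear_resize <- function(x, h_out, w_out) {
  d <- dim(x)
  apply_row_col(x, interp_matrix(d[1], h_out), interp_matrix(d[2], w_out))
}

bilinear_resize_bw <- function(dout, h_in, w_in) {
  d <- dim(dout)
  apply_row_col(dout, t(interp_matrix(h_in, d[1])), t(interp_matrix(w_in, d[2])))
}

#' Nearest-neighbour resize (used for label masks)
#'
#' @param x matrix or `[H, W, C]` array.
#' @param h_out,w_out output spatial size.
#' @return resized object of the same kind.
#' @export
nearest_resize <- function(x, h_out, w_out) {
  d <- dim(x)
  ih <- pmin(pmax(ceiling((seq_len(h_out) - 0.5) * d[1] / h_out), 1L), d[1])
  iw <- pmin(pmax(ceiling((seq_len(w_out) - 0.5) * d[2] / w_out), 1L), d[2])
  if (length(d) == 2L) x[ih, iw, drop = FALSE] else x[ih, iw, , drop = FALSE]
}

softmax_channels <- function(z) {
  d <- dim(z)
  zm <- matrix(z, d[1] * d[2], d[3])
  zm <- zm - zm[cbind(seq_len(nrow(zm)), max.col(zm, ties.method = "first"))]
  p <- exp(zm)
  p <- p / rowSums(p)
  array(p, d)
}

# separable gaussian blur on a single-channel matrix, zero padded
blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  mp <- rbind(matrix(0, r, W), m, matrix(0, r, W))
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * mp[(i - 1L) + seq_len(H), ]
  mp <- cbind(matrix(0, H, r), out, matrix(0, H, r))
  out2 <- matrix(0, H, W)
  for (i in seq_along(k)) out2 <- out2 + k[i] * mp[, (i - 1L) + seq_len(W)]
  out2
}

# ---- parameter initializers ------------------------------------------------

init_conv <- function(kh, kw, cin, cout, gain = 2) {
  list(W = array(stats::rnorm(kh * kw * cin * cout,
                              sd = sqrt(gain / (kh * kw * cin))),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
}
init_dwconv <- function(kh, kw, c, gain = 2) {
  list(W = array(stats::rnorm(kh * kw * c, sd = sqrt(gain / (kh * kw))),
                 c(kh, kw, c)),
       b = numeric(c))
}
init_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       running_mean = numeric(c), running_var = rep(1, c))
}
init_linear <- function(cin, cout, gain = 2) {
  list(W = matrix(stats::rnorm(cin * cout, sd = sqrt(gain / cin)), cin, cout),
       b = numeric(cout))
}
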