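# shared fixtures: tiny deterministic feature maps and parameter sets

rand_map <- function(H, W, C, seed = 1) {
  withr::with_seed(seed, array(stats::rnorm(H * W * C), c(H, W, C)))
}

# naive nested-loop 2-D convolution oracle ("same" zero padding, stride 1)
naive_conv <- function(x, W, b = NULL, dilation = 1) {
  d <- dim(x); dw <- dim(W)
  pad <- (dw[1] - 1) * dilation / 2
  out <- array(0, c(d[1], d[2], dw[4]))
  for (co in seq_len(dw[4])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    s <- if (is.null(b)) 0 else b[co]
    for (ki in seq_len(dw[1])) for (kj in seq_len(dw[2])) for (ci in seq_len(d[3])) {
      ii <- i + (ki - 1) * dilation - pad
      jj <- j + (kj - 1) * dilation - pad
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
        s <- s + x[ii, jj, ci] * W[ki, kj, ci, co]
    }
    out[i, j, co] <- s
  }
  out
}

naive_depthwise <- function(x, W, b = NULL, dilation = 1) {
  d <- dim(x); dw <- dim(W)
  pad <- (dw[1] - 1) * dilation / 2
  out <- array(0, d)
  for (c in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    s <- if (is.null(b)) 0 else b[c]
    for (ki in seq_len(dw[1])) for (kj in seq_len(dw[2])) {
      ii <- i + (ki - 1) * dilation - pad
      jj <- j + (kj - 1) * dilation - pad
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
        s <- s + x[ii, jj, c] * W[ki, kj, c]
    }
    out[i, j, c] <- s
  }
  out
}

# brute-force confusion-matrix / metric tally, independent of the package
brute_metrics <- function(pred, ref, k) {
  cm <- matrix(0, k, k)
  for (i in seq_along(pred)) cm[ref[i] + 1, pred[i] + 1] <- cm[ref[i] + 1, pred[i] + 1] + 1
  res <- list(cm = cm, acc = sum(diag(cm)) / sum(cm))
  iou <- prec <- rec <- spec <- f1 <- rep(NA_real_, k)
  for (c in seq_len(k)) {
    tp <- cm[c, c]; fp <- sum(cm[, c]) - tp; fn <- sum(cm[c, ]) - tp
    tn <- sum(cm) - tp - fp - fn
    if (tp + fp + fn > 0) iou[c] <- tp / (tp + fp + fn)
    if (tp + fp > 0) prec[c] <- tp / (tp + fp)
    if (tp + fn > 0) rec[c] <- tp / (tp + fn)
    if (tn + fp > 0) spec[c] <- tn / (tn + fp)
    if (!is.na(prec[c]) && !is.na(rec[c]) && prec[c] + rec[c] > 0)
      f1[c] <- 2 * prec[c] * rec[c] / (prec[c] + rec[c])
  }
  res$iou <- iou; res$precision <- prec; res$recall <- rec
  res$specificity <- spec; res$f1 <- f1
  res$miou <- mean(iou, na.rm = TRUE)
  res
}

# Mann-Whitney pair-counting AUC oracle
pair_auc <- function(score, pos) {
  ps <- score[pos]; ns <- score[!pos]
  if (length(ps) == 0 || length(ns) == 0) return(NA_real_)
  tot <- 0
  for (a in ps) for (b in ns) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ps) * length(ns))
}
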