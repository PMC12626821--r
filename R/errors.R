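#' @importFrom rlang abort
NULL

abort_shape <- function(msg) rlang::abort(msg, class = "melseg_error_shape")
abort_config <- function(msg) rlang::abort(msg, class = "melseg_error_config")
abort_validation <- function(msg) rlang::abort(msg, class = "melseg_error_validation")
abort_degenerate <- function(msg) rlang::abort(msg, class = "melseg_error_degenerate")

check_feature_map <- function(x, arg = "x") {
  if (!is.array(x) || length(dim(x)) != 3L)
    abort_shape(sprintf("`%s` must be an [H, W, C] array", arg))
  if (!all(is.finite(x)))
    abort_validation(sprintf("`%s` contains non-finite values", arg))
  invisible(x)
}
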