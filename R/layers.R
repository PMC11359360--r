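# Neural building blocks. A "module" is an environment holding persistent
# parameter environments (see param() in autograd.R); forward_* functions
# consume and return ag_node objects. Feature maps are channels x points
# matrices; pointwise 1x1 convolutions are therefore plain matrix products.

nn_linear <- function(c_in, c_out, bias = TRUE, sd = sqrt(2 / c_in)) {
  mod <- new.env(parent = emptyenv())
  mod$W <- param(matrix(rnorm(c_out * c_in, sd = sd), c_out, c_in))
  mod$b <- if (bias) param(matrix(0, c_out, 1)) else NULL
  class(mod) <- "nn_linear"
  mod
}

forward_linear <- function(mod, x) {
  ag_linear_wxb(ag_leaf(mod$W),
                if (!is.null(mod$b)) ag_leaf(mod$b), x)
}

nn_bn <- function(c) {
  mod <- new.env(parent = emptyenv())
  mod$gamma <- param(matrix(1, c, 1))
  mod$beta <- param(matrix(0, c, 1))
  mod$running_mean <- rep(0, c)
  mod$running_var <- rep(1, c)
  class(mod) <- "nn_bn"
  mod
}

# Convolution + batch norm + activation; act is "relu" or "prelu" (the
# CRA-MLP stack uses PReLU, the PESA output path uses ReLU: "CBR").
nn_convblock <- function(c_in, c_out, act = c("relu", "prelu")) {
  act <- match.arg(act)
  mod <- new.env(parent = emptyenv())
  mod$lin <- nn_linear(c_in, c_out)
  mod$bn <- nn_bn(c_out)
  mod$act <- act
  if (act == "prelu") mod$alpha <- param(matrix(0.25, c_out, 1))
  class(mod) <- "nn_convblock"
  mod
}

forward_convblock <- function(mod, x, training) {
  h <- ag_batchnorm(forward_linear(mod$lin, x), mod$bn, training)
  if (mod$act == "prelu") ag_prelu(h, ag_leaf(mod$alpha)) else ag_relu(h)
}

#' Squeeze-excitation channel attention module
#'
#' Two bias-free linear maps with reduction ratio `reduction` (weights
#' `W1` of shape C/r x C and `W2` of shape C x C/r) that turn the globally
#' average-pooled feature vector into per-channel gate coefficients
#' `omega = sigmoid(W2 relu(W1 avgpool(FD)))` in (0, 1).
#'
#' @param c channel count (must be divisible by `reduction`).
#' @param reduction reduction ratio (default 4).
#' @return an `nn_se` module.
#' @export
se_module <- function(c, reduction = 4L) {
  if (c %% reduction != 0L)
    stopf("channel count %d not divisible by reduction %d", c, reduction)
  mod <- new.env(parent = emptyenv())
  mod$W1 <- param(matrix(rnorm(c / reduction * c, sd = sqrt(2 / c)),
                         c / reduction, c))
  mod$W2 <- param(matrix(rnorm(c * c / reduction, sd = sqrt(2 / (c / reduction))),
                         c, c / reduction))
  class(mod) <- "nn_se"
  mod
}

forward_se <- function(mod, x) {
  pooled <- ag_rowmeans(x)
  h <- ag_relu(ag_matmul(ag_leaf(mod$W1), pooled))
  ag_sigmoid(ag_matmul(ag_leaf(mod$W2), h))
}

#' Per-channel gate coefficients of a feature map
#'
#' Numeric front end of the squeeze-excitation computation: global average
#' pooling over the point dimension, the two linear maps, and the sigmoid.
#'
#' @param fd numeric channels x points feature map.
#' @param se an [se_module()].
#' @return numeric vector of per-channel weights in (0, 1).
#' @export
channel_attention_weights <- function(fd, se) {
  ag_reset()
  as.vector(forward_se(se, ag_const(as.matrix(fd)))$value)
}

#' Apply a channel gate with residual connection
#'
#' `FD * omega + FD`, broadcasting the per-channel weights over points: the
#' residual form of squeeze-excitation gating. With `omega = 0` this is the
#' identity; with `omega = 1` it doubles the features.
#'
#' @param fd numeric channels x points feature map.
#' @param omega numeric per-channel weights.
#' @return gated feature map, same shape as `fd`.
#' @export
channel_gate_residual <- function(fd, omega) {
  fd <- as.matrix(fd)
  fd * as.vector(omega) + fd
}

#' Parametric ReLU
#'
#' `f(x) = x` for `x >= 0` and `alpha * x` otherwise. With `alpha = 0` this
#' reduces exactly to ReLU.
#'
#' @param x numeric array.
#' @param alpha negative-side slope; scalar or one value per row of `x`.
#' @return array of the same shape.
#' @export
prelu <- function(x, alpha = 0.25) {
  if (length(alpha) > 1L) {
    x <- as.matrix(x)
    if (length(alpha) != nrow(x))
      stopf("alpha must be scalar or one slope per channel (row)")
    ifelse(x >= 0, x, x * alpha)
  } else {
    ifelse(x >= 0, x, alpha * x)
  }
}

#' Channel residual attention perceptron (CRA-MLP)
#'
#' The shared perceptron used throughout the network: a two-layer
#' convolution / batch-norm / PReLU stack followed by squeeze-excitation
#' channel gating with a residual add, `out = FD * omega + FD`. With
#' `use_cra = FALSE` the module degrades to the plain convolution /
#' batch-norm / ReLU stack of the unmodified set-abstraction backbone
#' (the ablation baseline).
#'
#' @param c_in,c_out input and output channel counts.
#' @param reduction squeeze-excitation reduction ratio.
#' @param use_cra enable PReLU + channel attention + residual (default).
#' @return an `nn_cra` module.
#' @export
cra_mlp_module <- function(c_in, c_out, reduction = 4L, use_cra = TRUE) {
  mod <- new.env(parent = emptyenv())
  act <- if (use_cra) "prelu" else "relu"
  mod$block1 <- nn_convblock(c_in, c_out, act)
  mod$block2 <- nn_convblock(c_out, c_out, act)
  mod$se <- if (use_cra) se_module(c_out, reduction) else NULL
  mod$use_cra <- use_cra
  class(mod) <- "nn_cra"
  mod
}

forward_cra <- function(mod, x, training) {
  fd <- forward_convblock(mod$block2,
                          forward_convblock(mod$block1, x, training), training)
  if (!mod$use_cra) return(fd)
  omega <- forward_se(mod$se, fd)
  ag_add(ag_rowscale(fd, omega), fd)
}

#' @rdname cra_mlp_module
#' @param fd numeric channels x points input feature map.
#' @param mod an `nn_cra` module built by `cra_mlp_module`.
#' @param training use batch statistics (TRUE) or running statistics.
#' @return `cra_mlp`: the output feature map, channels = `c_out`.
#' @export
cra_mlp <- function(fd, mod, training = FALSE) {
  ag_reset()
  forward_cra(mod, ag_const(as.matrix(fd)), training)$value
}
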