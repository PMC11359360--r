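# Position-enhanced self-attention (PESA). Coordinates are lifted to the
# feature width, gated by a feature-attention layer derived from their Gram
# matrix, fused multiplicatively with the features, and run through offset
# self-attention with doubly normalized weights and a residual CBR branch.

#' Position enhancement module
#'
#' Lifts the 3-channel stage coordinates to `c` channels with a
#' convolution / batch-norm / ReLU perceptron (`Pi`), forms the channel
#' Gram matrix `Pi Pi^T`, collapses it over its first index to one
#' length-`c` row, maps that through a linear layer and a sigmoid into a
#' per-channel gate in (0, 1), and returns `Po = Pi * gate`. The Gram
#' matrix is divided by the number of points so the gate input does not
#' grow with stage resolution.
#'
#' @param c target channel count.
#' @return an `nn_pe` module.
#' @export
position_enhance_module <- function(c) {
  mod <- new.env(parent = emptyenv())
  mod$mlp <- nn_convblock(3L, c, "relu")
  mod$gate <- nn_linear(c, c, bias = TRUE, sd = 1 / c)
  class(mod) <- "nn_pe"
  mod
}

forward_pe <- function(mod, p, training) {
  pi_ <- forward_convblock(mod$mlp, p, training)
  n <- ncol(pi_$value)
  gram <- ag_scale(ag_matmul(pi_, pi_, tb = TRUE), 1 / n)
  ones <- ag_const(matrix(1, 1, nrow(gram$value)))
  s <- ag_t(ag_matmul(ones, gram))                  # C x 1 summed rows
  gate <- ag_sigmoid(forward_linear(mod$gate, s))
  list(po = ag_rowscale(pi_, gate), gate = gate, pi = pi_)
}

#' @rdname position_enhance_module
#' @param p numeric 3 x points matrix of stage coordinates.
#' @param mod an `nn_pe` module.
#' @param training use batch statistics (TRUE) or running statistics.
#' @return `position_enhance`: list with `po` (c x points enhanced
#'   positions), `gate` (per-channel gate in (0, 1)) and `pi` (the lifted
#'   positions before gating).
#' @export
position_enhance <- function(p, mod, training = FALSE) {
  ag_reset()
  res <- forward_pe(mod, ag_const(as.matrix(p)), training)
  list(po = res$po$value, gate = as.vector(res$gate$value), pi = res$pi$value)
}

#' Position-enhanced self-attention module
#'
#' Query and key projections share the reduced width `c / reduction`; the
#' value projection keeps width `c`. All three are bias-free linear maps.
#' The output path is a CBR (convolution + batch norm + ReLU) block applied
#' to the offset `Fsa - F'`, added back to `F'`.
#'
#' @param c channel count of the incoming feature map.
#' @param reduction query/key width reduction (default 4).
#' @return an `nn_pesa` module.
#' @export
pesa_module <- function(c, reduction = 4L) {
  mod <- new.env(parent = emptyenv())
  mod$pe <- position_enhance_module(c)
  mod$wq <- nn_linear(c, c %/% reduction, bias = FALSE, sd = sqrt(1 / c))
  mod$wk <- nn_linear(c, c %/% reduction, bias = FALSE, sd = sqrt(1 / c))
  mod$wv <- nn_linear(c, c, bias = FALSE, sd = sqrt(1 / c))
  mod$cbr <- nn_convblock(c, c, "relu")
  class(mod) <- "nn_pesa"
  mod
}

forward_pesa <- function(mod, fi, p, training, po_override = NULL,
                         keep_attention = FALSE) {
  po <- if (is.null(po_override)) forward_pe(mod$pe, p, training)$po
        else as_node(po_override)
  fp <- ag_mul(po, fi)                               # F' = Po * Fi
  q <- forward_linear(mod$wq, fp)
  k <- forward_linear(mod$wk, fp)
  v <- forward_linear(mod$wv, fp)
  e <- ag_matmul(q, k, ta = TRUE)                    # E[i, j] = q_i . k_j
  a <- ag_colsoftmax(e)                              # softmax over queries
  A <- ag_rownorm_l1(a)                              # rows sum to 1
  fsa <- ag_matmul(v, A, tb = TRUE)                  # Fsa[, i] = sum_j A_ij V_j
  fo <- ag_add(forward_convblock(mod$cbr, ag_sub(fsa, fp), training), fp)
  if (keep_attention) list(out = fo, attention = A$value, fp = fp)
  else list(out = fo, fp = fp)
}

#' Position-enhanced self-attention
#'
#' Numeric front end of the PESA block: positions are enhanced and fused
#' multiplicatively with the features (`F' = Po * Fi`), attention weights
#' are computed from query/key projections (softmax over the query axis
#' followed by l1 row normalization, so every row of the attention matrix
#' sums to 1), the values are aggregated, and the offset `Fsa - F'` passes
#' through the CBR branch before the residual add.
#'
#' @param fi numeric c x points feature map.
#' @param p numeric 3 x points coordinates (ignored when `po_override`
#'   given).
#' @param mod an [pesa_module()].
#' @param training use batch statistics (TRUE) or running statistics.
#' @param po_override optional numeric c x points matrix standing in for
#'   the enhanced positions (diagnostic use).
#' @return list with `out` (c x points output feature map) and `attention`
#'   (points x points row-stochastic attention matrix).
#' @export
pesa <- function(fi, p = NULL, mod, training = FALSE, po_override = NULL) {
  ag_reset()
  res <- forward_pesa(mod, ag_const(as.matrix(fi)),
                      if (is.null(p)) NULL else ag_const(as.matrix(p)),
                      training, po_override = po_override,
                      keep_attention = TRUE)
  list(out = res$out$value, attention = res$attention)
}

# All parameter environments of a module tree, for the optimizer and for
# checkpointing. Order is deterministic (environment creation order within
# the recursive walk).
module_params <- function(mod) {
  out <- list()
  walk <- function(m) {
    if (inherits(m, "ag_param")) {
      out[[length(out) + 1L]] <<- m
    } else if (is.environment(m)) {
      for (nm in sort(ls(m))) {
        v <- get(nm, envir = m)
        if (is.environment(v) || is.list(v)) walk(v)
      }
    } else if (is.list(m)) {
      for (v in m) if (is.environment(v) || is.list(v)) walk(v)
    }
  }
  walk(mod)
  out
}

# Running batch-norm statistics of a module tree (for checkpointing).
module_bn_stats <- function(mod) {
  out <- list()
  walk <- function(m) {
    if (inherits(m, "nn_bn")) {
      out[[length(out) + 1L]] <<- m
    } else if (is.environment(m)) {
      for (nm in sort(ls(m))) {
        v <- get(nm, envir = m)
        if (is.environment(v) || is.list(v)) walk(v)
      }
    } else if (is.list(m)) {
      for (v in m) if (is.environment(v) || is.list(v)) walk(v)
    }
  }
  walk(mod)
  out
}
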