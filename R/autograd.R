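# Minimal reverse-mode automatic differentiation on matrices.
#
# A forward pass records nodes on a tape; ag_backward() walks the tape in
# reverse, calling each node's backward closure to push gradients to its
# parents. Values are base-R matrices so all heavy lifting is BLAS.
# Parameters live in persistent environments (see param()) whose $grad
# accumulates across a batch until the optimizer consumes it.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

ag_reset <- function() {
  .ag$tape <- vector("list", 256L)
  .ag$n <- 0L
  invisible(NULL)
}

ag_record <- function(node) {
  n <- .ag$n + 1L
  if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
  .ag$tape[[n]] <- node
  .ag$n <- n
  node
}

new_node <- function(value, backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$backward <- backward
  class(node) <- "ag_node"
  ag_record(node)
}

ag_const <- function(value) new_node(value)

is_node <- function(x) inherits(x, "ag_node")

as_node <- function(x) if (is_node(x)) x else ag_const(x)

ag_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Trainable parameter: persistent environment; $grad accumulates across the
# steps of a batch, $m/$v hold Adam state.
param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  class(p) <- "ag_param"
  p
}

# Leaf node view of a parameter for the current tape.
ag_leaf <- function(p) {
  node <- new_node(p$value)
  node$backward <- function() {
    p$grad <- if (is.null(p$grad)) node$grad else p$grad + node$grad
  }
  node
}

# Run backward from a scalar loss node.
ag_backward <- function(loss) {
  loss$grad <- 1
  for (i in seq(.ag$n, 1L)) {
    node <- .ag$tape[[i]]
    if (!is.null(node$grad) && !is.null(node$backward)) node$backward()
  }
  invisible(NULL)
}

# --- primitive operations --------------------------------------------------

ag_matmul <- function(a, b, ta = FALSE, tb = FALSE) {
  av <- a$value; bv <- b$value
  v <- if (!ta && !tb) av %*% bv
       else if (ta && !tb) crossprod(av, bv)
       else if (!ta && tb) tcrossprod(av, bv)
       else t(bv %*% av)
  node <- new_node(v)
  node$backward <- function() {
    g <- node$grad
    ga <- if (!ta) {
      if (!tb) tcrossprod(g, bv) else g %*% bv
    } else {
      if (!tb) tcrossprod(bv, g) else crossprod(bv, g)
    }
    gb <- if (!tb) {
      if (!ta) crossprod(av, g) else av %*% g
    } else {
      if (!ta) crossprod(g, av) else tcrossprod(g, av)
    }
    ag_accum(a, ga)
    ag_accum(b, gb)
  }
  node
}

ag_add <- function(a, b) {
  node <- new_node(a$value + b$value)
  node$backward <- function() {
    ag_accum(a, node$grad)
    ag_accum(b, node$grad)
  }
  node
}

ag_sub <- function(a, b) {
  node <- new_node(a$value - b$value)
  node$backward <- function() {
    ag_accum(a, node$grad)
    ag_accum(b, -node$grad)
  }
  node
}

ag_mul <- function(a, b) {
  node <- new_node(a$value * b$value)
  node$backward <- function() {
    ag_accum(a, node$grad * b$value)
    ag_accum(b, node$grad * a$value)
  }
  node
}

# Fused affine map: W x + b (b broadcast over columns). One node instead of
# matmul + bias, saving allocations in the innermost blocks.
ag_linear_wxb <- function(W, b, x) {
  Wv <- W$value
  v <- Wv %*% x$value
  if (!is.null(b)) v <- v + as.vector(b$value)
  node <- new_node(v)
  node$backward <- function() {
    g <- node$grad
    ag_accum(W, tcrossprod(g, x$value))
    if (!is.null(b)) ag_accum(b, matrix(rowSums(g), ncol = 1))
    ag_accum(x, crossprod(Wv, g))
  }
  node
}

# x: C x N, bias: C x 1 broadcast over columns.
ag_add_bias <- function(x, bias) {
  node <- new_node(x$value + as.vector(bias$value))
  node$backward <- function() {
    ag_accum(x, node$grad)
    ag_accum(bias, matrix(rowSums(node$grad), ncol = 1))
  }
  node
}

# x: C x N scaled per row (channel) by w: C x 1.
ag_rowscale <- function(x, w) {
  wv <- as.vector(w$value)
  node <- new_node(x$value * wv)
  node$backward <- function() {
    ag_accum(x, node$grad * wv)
    ag_accum(w, matrix(rowSums(node$grad * x$value), ncol = 1))
  }
  node
}

# x: C x N scaled per column by v (plain numeric length N).
ag_colscale <- function(x, v) {
  node <- new_node(sweep(x$value, 2, v, `*`))
  node$backward <- function() ag_accum(x, sweep(node$grad, 2, v, `*`))
  node
}

ag_scale <- function(x, s) {
  node <- new_node(x$value * s)
  node$backward <- function() ag_accum(x, node$grad * s)
  node
}

ag_relu <- function(x) {
  mask <- x$value > 0
  node <- new_node(x$value * mask)
  node$backward <- function() ag_accum(x, node$grad * mask)
  node
}

# alpha: C x 1 per-channel negative slope.
ag_prelu <- function(x, alpha) {
  av <- as.vector(alpha$value)
  xv <- x$value
  neg <- xv < 0
  fac <- 1 - neg + neg * av          # av recycles down columns (per channel)
  node <- new_node(xv * fac)
  node$backward <- function() {
    ag_accum(x, node$grad * fac)
    ag_accum(alpha, matrix(rowSums(node$grad * xv * neg), ncol = 1))
  }
  node
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  node <- new_node(s)
  node$backward <- function() ag_accum(x, node$grad * s * (1 - s))
  node
}

# Row means over columns: C x N -> C x 1 (global average pooling).
ag_rowmeans <- function(x) {
  n <- ncol(x$value)
  node <- new_node(matrix(rowMeans(x$value), ncol = 1))
  node$backward <- function()
    ag_accum(x, matrix(node$grad, nrow(x$value), n) / n)
  node
}

ag_t <- function(x) {
  node <- new_node(t(x$value))
  node$backward <- function() ag_accum(x, t(node$grad))
  node
}

ag_concat_rows <- function(a, b) {
  na <- nrow(a$value)
  node <- new_node(rbind(a$value, b$value))
  node$backward <- function() {
    ag_accum(a, node$grad[seq_len(na), , drop = FALSE])
    ag_accum(b, node$grad[-seq_len(na), , drop = FALSE])
  }
  node
}

# Column gather: y = x[, idx]; backward scatter-adds duplicated columns.
ag_gather_cols <- function(x, idx) {
  node <- new_node(x$value[, idx, drop = FALSE])
  node$backward <- function() {
    ag_accum(x, cpp_scatter_add_cols(node$grad, idx, ncol(x$value)))
  }
  node
}

# Max pooling over contiguous groups of K columns: C x (M*K) -> C x M.
ag_group_maxpool <- function(x, K) {
  xv <- x$value
  C <- nrow(xv)
  M <- ncol(xv) %/% K
  base_cols <- (seq_len(M) - 1L) * K
  best <- xv[, base_cols + 1L, drop = FALSE]
  arg <- matrix(1L, C, M)
  if (K > 1L) for (k in 2L:K) {
    cand <- xv[, base_cols + k, drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    arg[upd] <- k
  }
  node <- new_node(best)
  node$backward <- function() {
    dx <- matrix(0, C, ncol(xv))
    col <- rep(base_cols, each = C) + as.vector(arg)
    li <- (col - 1L) * C + rep(seq_len(C), M)
    dx[li] <- dx[li] + as.vector(node$grad)
    ag_accum(x, dx)
  }
  node
}

col_max <- function(x) {
  if (nrow(x) == 2L) pmax.int(x[1L, ], x[2L, ]) else apply(x, 2, max)
}

# Softmax over rows within every column (normalizes each column to sum 1).
ag_colsoftmax <- function(x) {
  xv <- x$value
  shifted <- sweep(xv, 2, col_max(xv))
  e <- exp(shifted)
  s <- sweep(e, 2, colSums(e), `/`)
  node <- new_node(s)
  node$backward <- function() {
    g <- node$grad
    dot <- colSums(g * s)
    ag_accum(x, s * sweep(g, 2, dot))
  }
  node
}

# l1 normalization of every row: A_ij = a_ij / (1e-9 + sum_k a_ik).
ag_rownorm_l1 <- function(a) {
  av <- a$value
  s <- 1e-9 + rowSums(av)
  A <- av / s
  node <- new_node(A)
  node$backward <- function() {
    g <- node$grad
    ag_accum(a, g / s - rowSums(g * av) / s^2)
  }
  node
}

# Inverse-distance interpolation: y[, i] = sum_k w[k, i] * x[, idx[k, i]].
ag_interp <- function(x, idx, w) {
  K <- nrow(idx)
  out <- NULL
  for (k in seq_len(K)) {
    term <- ag_colscale(ag_gather_cols(x, idx[k, ]), w[k, ])
    out <- if (is.null(out)) term else ag_add(out, term)
  }
  out
}

# Inverted dropout over all entries; identity when p = 0 or not training.
ag_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(x)
  keep <- (matrix(runif(length(x$value)), nrow(x$value)) >= p) / (1 - p)
  node <- new_node(x$value * keep)
  node$backward <- function() ag_accum(x, node$grad * keep)
  node
}

# Batch normalization over the point (column) dimension per channel.
# bn: module environment with gamma/beta params and running stats. The
# per-map (column) statistics are used both in training and at inference:
# with one cloud per pass this is per-cloud normalization, deterministic
# for a fixed input, and avoids any train/eval statistics mismatch.
# Running averages are still tracked and used for degenerate single-column
# maps.
ag_batchnorm <- function(x, bn, training, eps = 1e-5) {
  gamma_leaf <- ag_leaf(bn$gamma)
  beta_leaf <- ag_leaf(bn$beta)
  xv <- x$value
  n <- ncol(xv)
  batch_stats <- n > 1L
  if (batch_stats) {
    mu <- rowMeans(xv)
    xc <- xv - mu
    va <- rowMeans(xc * xc)
    if (training) {
      bn$running_mean <- 0.9 * bn$running_mean + 0.1 * mu
      bn$running_var <- 0.9 * bn$running_var + 0.1 * va * n / max(n - 1L, 1L)
    }
  } else {
    mu <- bn$running_mean
    va <- bn$running_var
    xc <- xv - mu
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gamma <- as.vector(bn$gamma$value)
  node <- new_node(xhat * gamma + as.vector(bn$beta$value))
  node$backward <- function() {
    g <- node$grad
    ag_accum(gamma_leaf, matrix(rowSums(g * xhat), ncol = 1))
    ag_accum(beta_leaf, matrix(rowSums(g), ncol = 1))
    if (batch_stats) {
      gm <- rowMeans(g)
      gxh <- rowMeans(g * xhat)
      dx <- (gamma * inv) * (g - gm - xhat * gxh)
    } else {
      dx <- (gamma * inv) * g
    }
    ag_accum(x, dx)
  }
  node
}
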