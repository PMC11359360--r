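#' Loss configuration
#'
#' Weights of the hybrid cross-entropy + Dice loss and the Dice smoothing
#' term. The default splits the weight evenly between the two components.
#'
#' @param weight_ce cross-entropy weight (>= 0).
#' @param weight_dice Dice weight (>= 0); the two must not both be 0.
#' @param epsilon Dice smoothing term (> 0).
#' @return a `loss_config` list.
#' @export
loss_config <- function(weight_ce = 0.5, weight_dice = 0.5, epsilon = 1e-5) {
  if (weight_ce < 0 || weight_dice < 0) stopf("loss weights must be >= 0")
  if (weight_ce + weight_dice <= 0)
    stopf("at least one loss weight must be positive")
  if (epsilon <= 0) stopf("epsilon must be positive")
  structure(list(weight_ce = weight_ce, weight_dice = weight_dice,
                 epsilon = epsilon), class = "loss_config")
}

# Normalize probability input to an N_total x C matrix and labels to a
# 1-based class index vector.
flatten_probs <- function(probabilities, labels) {
  p <- if (is.array(probabilities) && length(dim(probabilities)) == 3L) {
    d <- dim(probabilities)
    matrix(aperm(probabilities, c(2, 1, 3)), d[1] * d[2], d[3])
  } else {
    as.matrix(probabilities)
  }
  y <- as.integer(labels) + 1L
  if (length(y) != nrow(p))
    stopf("labels length %d does not match %d points", length(y), nrow(p))
  if (any(y < 1L) || any(y > ncol(p)))
    stopf("labels out of range for %d classes", ncol(p))
  list(p = p, y = y)
}

#' Point-wise cross-entropy loss
#'
#' Mean over all points of `-log p` at the true class,
#' `-(1/N) sum_i sum_c y_ic log p_ic`. Probabilities are floored at 1e-12
#' to keep the logarithm finite.
#'
#' @param probabilities points x classes matrix (or batch x points x
#'   classes array) of per-point class probabilities; rows must sum to 1.
#' @param labels integer class labels, 0-based, matching the points.
#' @return scalar loss (>= 0; 0 iff predictions are one-hot correct).
#' @export
cross_entropy <- function(probabilities, labels) {
  fl <- flatten_probs(probabilities, labels)
  p_true <- fl$p[cbind(seq_len(nrow(fl$p)), fl$y)]
  -mean(log(pmax(p_true, 1e-12)))
}

#' Soft Dice loss
#'
#' Per class `1 - (2 * intersection + eps) / (pred_sum + target_sum + eps)`
#' on the soft probabilities, macro-averaged over the classes.
#'
#' @inheritParams cross_entropy
#' @param epsilon smoothing term avoiding division by zero.
#' @return scalar loss in \[0, 1).
#' @export
dice_loss <- function(probabilities, labels, epsilon = 1e-5) {
  fl <- flatten_probs(probabilities, labels)
  k <- ncol(fl$p)
  terms <- vapply(seq_len(k), function(c) {
    yc <- as.numeric(fl$y == c)
    inter <- sum(fl$p[, c] * yc)
    1 - (2 * inter + epsilon) / (sum(fl$p[, c]) + sum(yc) + epsilon)
  }, numeric(1))
  mean(terms)
}

#' Hybrid cross-entropy + Dice loss
#'
#' `weight_ce * cross_entropy + weight_dice * dice_loss`: the training loss
#' balancing point-wise classification against boundary/shape matching.
#'
#' @inheritParams cross_entropy
#' @param config a [loss_config()].
#' @return scalar loss.
#' @export
hce_dice <- function(probabilities, labels, config = loss_config()) {
  stopifnot(inherits(config, "loss_config"))
  config$weight_ce * cross_entropy(probabilities, labels) +
    config$weight_dice * dice_loss(probabilities, labels, config$epsilon)
}

# --- differentiable versions (probabilities as classes x points node) -----

ag_cross_entropy <- function(prob, y1) {
  pv <- prob$value
  n <- ncol(pv)
  sel <- cbind(y1, seq_len(n))           # [class, point] of the true class
  p_true <- pv[sel]
  node <- new_node(-mean(log(pmax(p_true, 1e-12))))
  node$backward <- function() {
    dp <- matrix(0, nrow(pv), n)
    ok <- p_true > 1e-12
    dp[sel[ok, , drop = FALSE]] <- -1 / (n * p_true[ok])
    ag_accum(prob, node$grad * dp)
  }
  node
}

ag_dice <- function(prob, y1, epsilon = 1e-5) {
  pv <- prob$value
  k <- nrow(pv)
  n <- ncol(pv)
  Y <- matrix(0, k, n)
  Y[cbind(y1, seq_len(n))] <- 1
  inter <- rowSums(pv * Y)
  ps <- rowSums(pv)
  ts <- rowSums(Y)
  denom <- ps + ts + epsilon
  numer <- 2 * inter + epsilon
  node <- new_node(mean(1 - numer / denom))
  node$backward <- function() {
    # d term_c / d p_ci = -(2 Y_ci denom_c - numer_c) / denom_c^2, / k
    dp <- -(2 * Y * denom - numer) / denom^2 / k
    ag_accum(prob, node$grad * dp)
  }
  node
}

ag_loss <- function(prob, y1, loss_name, config) {
  switch(loss_name,
         ce = ag_cross_entropy(prob, y1),
         dice = ag_dice(prob, y1, config$epsilon),
         hce = {
           ce <- ag_cross_entropy(prob, y1)
           di <- ag_dice(prob, y1, config$epsilon)
           ag_add(ag_scale(ce, config$weight_ce),
                  ag_scale(di, config$weight_dice))
         },
         stopf("unknown loss '%s' (use ce, dice or hce)", loss_name))
}
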