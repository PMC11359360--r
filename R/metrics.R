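#' Per-class confusion counts
#'
#' Exact true-positive, false-positive and false-negative counts per class.
#' Counts are additive: summing the counts of two batches equals the counts
#' of their union.
#'
#' @param pred integer predicted labels (0-based).
#' @param truth integer reference labels, same length.
#' @param n_classes number of classes (default 2).
#' @return an `eval_counts` data frame with columns `class`, `tp`, `fp`,
#'   `fn`.
#' @export
confusion <- function(pred, truth, n_classes = 2L) {
  if (length(pred) != length(truth))
    stopf("pred has %d labels, truth has %d", length(pred), length(truth))
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  if (any(pred < 0L | pred >= n_classes) || any(truth < 0L | truth >= n_classes))
    stopf("labels out of range 0..%d", n_classes - 1L)
  cls <- seq_len(n_classes) - 1L
  tp <- vapply(cls, function(c) sum(pred == c & truth == c), numeric(1))
  fp <- vapply(cls, function(c) sum(pred == c & truth != c), numeric(1))
  fn <- vapply(cls, function(c) sum(pred != c & truth == c), numeric(1))
  structure(data.frame(class = cls, tp = tp, fp = fp, fn = fn),
            class = c("eval_counts", "data.frame"))
}

#' @rdname confusion
#' @param a,b `eval_counts` objects to add.
#' @export
add_counts <- function(a, b) {
  stopifnot(identical(a$class, b$class))
  out <- a
  out$tp <- a$tp + b$tp
  out$fp <- a$fp + b$fp
  out$fn <- a$fn + b$fn
  out
}

# Classes with no support anywhere (tp + fp + fn = 0) are excluded from the
# class means, with a warning.
active_classes <- function(counts) {
  active <- counts$tp + counts$fp + counts$fn > 0
  if (!all(active))
    warning(sprintf("class(es) %s have no points and are excluded",
                    paste(counts$class[!active], collapse = ", ")),
            call. = FALSE)
  active
}

#' Class-averaged segmentation metrics
#'
#' `miou` averages `TP / (TP + FP + FN)` over classes; `mp` averages
#' precision `TP / (TP + FP)`; `mr` averages recall `TP / (TP + FN)`;
#' `mf1` averages the per-class harmonic mean `2PR / (P + R)`. All are
#' reported as percentages. A class with no points at all is excluded from
#' the mean with a warning.
#'
#' @param counts an [confusion()] `eval_counts` object.
#' @return percentage in \[0, 100\].
#' @export
miou <- function(counts) {
  a <- active_classes(counts)
  100 * mean(counts$tp[a] / (counts$tp[a] + counts$fp[a] + counts$fn[a]))
}

#' @rdname miou
#' @export
mp <- function(counts) {
  a <- active_classes(counts)
  p <- counts$tp[a] / pmax(counts$tp[a] + counts$fp[a], 1)
  100 * mean(p)
}

#' @rdname miou
#' @export
mr <- function(counts) {
  a <- active_classes(counts)
  r <- counts$tp[a] / pmax(counts$tp[a] + counts$fn[a], 1)
  100 * mean(r)
}

#' @rdname miou
#' @export
mf1 <- function(counts) {
  a <- active_classes(counts)
  p <- counts$tp[a] / pmax(counts$tp[a] + counts$fp[a], 1)
  r <- counts$tp[a] / pmax(counts$tp[a] + counts$fn[a], 1)
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  100 * mean(f1)
}

#' Segmentation speed
#'
#' Average number of clouds segmented per second: the reciprocal of the
#' mean per-cloud inference time.
#'
#' @param total_time total inference time in seconds (> 0).
#' @param n_clouds number of clouds segmented.
#' @return clouds per second.
#' @export
speed <- function(total_time, n_clouds = 1L) {
  if (total_time <= 0) stopf("total_time must be positive")
  n_clouds / total_time
}

#' Full metric report
#'
#' @param counts an `eval_counts` object.
#' @param total_time optional inference time for the speed column.
#' @param n_clouds number of clouds behind `counts`.
#' @return a `metric_report` list with `miou`, `mp`, `mr`, `mf1` (percent),
#'   optional `speed`, and the per-class breakdown.
#' @export
metric_report <- function(counts, total_time = NULL, n_clouds = 1L) {
  per_class <- data.frame(
    class = counts$class,
    name = class_names()[counts$class + 1L],
    iou = 100 * counts$tp / pmax(counts$tp + counts$fp + counts$fn, 1),
    precision = 100 * counts$tp / pmax(counts$tp + counts$fp, 1),
    recall = 100 * counts$tp / pmax(counts$tp + counts$fn, 1))
  structure(list(miou = miou(counts), mp = mp(counts), mr = mr(counts),
                 mf1 = mf1(counts),
                 speed = if (!is.null(total_time)) speed(total_time, n_clouds),
                 per_class = per_class, counts = counts),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("mIoU %.1f%%  mP %.1f%%  mR %.1f%%  mF1 %.1f%%%s\n",
              x$miou, x$mp, x$mr, x$mf1,
              if (!is.null(x$speed)) sprintf("  speed %.3f clouds/s", x$speed)
              else ""))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
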