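# Protein-centric (Fmax, F1, Macro-F1, subset accuracy) and term-centric
# (micro/macro AUPR) evaluation, following the CAFA conventions: a
# prediction exists where the score strictly exceeds the threshold, and
# precision averages only over proteins with at least one prediction.

#' Protein-centric precision and recall at a threshold
#'
#' A term is predicted for a protein when its score strictly exceeds `tau`.
#' Precision is averaged over the `s_tau` proteins with at least one
#' prediction; recall is averaged over the proteins with at least one true
#' term. If no protein makes a prediction, precision is defined as 0.
#'
#' @param p Score matrix in `[0, 1]` (proteins x terms).
#' @param y Binary label matrix, same shape.
#' @param tau Threshold in `[0, 1)`.
#' @return List with `precision`, `recall` and `s_tau`.
#' @export
#' @examples
#' precision_recall_at_tau(rbind(c(0.9, 0.6), c(0.4, 0.8)),
#'                         rbind(c(1, 0), c(1, 1)), 0.7)
precision_recall_at_tau <- function(p, y, tau) {
  if (!all(dim(p) == dim(y))) stop("score and label matrices differ in shape")
  pred <- p > tau
  tp <- rowSums(pred & y == 1)
  npred <- rowSums(pred)
  npos <- rowSums(y == 1)
  covered <- npred > 0
  s_tau <- sum(covered)
  precision <- if (s_tau > 0) mean(tp[covered] / npred[covered]) else 0
  has_pos <- npos > 0
  recall <- if (any(has_pos)) mean(tp[has_pos] / npos[has_pos]) else 0
  list(precision = precision, recall = recall, s_tau = s_tau)
}

#' Fmax: the CAFA protein-centric F-measure
#'
#' Maximum over a threshold grid of the harmonic mean of protein-centric
#' precision and recall; `F = 0` where precision + recall = 0. Ties pick the
#' smallest threshold.
#'
#' @inheritParams precision_recall_at_tau
#' @param grid Threshold grid (default 0.01 to 0.99, step 0.01).
#' @return List with `fmax` and `tau_star` (the attaining threshold).
#' @export
fmax <- function(p, y, grid = seq(0.01, 0.99, by = 0.01)) {
  f <- vapply(grid, function(tau) {
    pr <- precision_recall_at_tau(p, y, tau)
    if (pr$precision + pr$recall == 0) 0 else
      2 * pr$precision * pr$recall / (pr$precision + pr$recall)
  }, numeric(1))
  best <- which.max(f)  # which.max takes the first (smallest tau) on ties
  list(fmax = f[best], tau_star = grid[best])
}

# Average precision of a ranked binary list; ties handled by grouping equal
# scores into one threshold step. AP = sum over steps of (delta recall) *
# precision-at-step, i.e. step-function (not trapezoidal) interpolation.
average_precision <- function(scores, labels) {
  pos <- sum(labels == 1)
  if (pos == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # indices where a threshold group (equal scores) ends
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(l)[grp_end]
  n_at <- grp_end
  prec <- tp / n_at
  rec <- tp / pos
  drec <- diff(c(0, rec))
  sum(drec * prec)
}

#' Micro-averaged area under the precision-recall curve
#'
#' AUPR over the flattened (protein, term) score/label pairs.
#'
#' @inheritParams precision_recall_at_tau
#' @return Scalar in `[0, 1]`.
#' @export
aupr_micro <- function(p, y) {
  if (!all(dim(p) == dim(y))) stop("score and label matrices differ in shape")
  if (sum(y == 1) == 0) stop("micro-AUPR undefined: no positive labels")
  average_precision(as.numeric(p), as.numeric(y))
}

#' Macro-averaged area under the precision-recall curve
#'
#' Unweighted mean of per-term AUPRs; terms with no positive protein are
#' skipped (their count is reported as an attribute).
#'
#' @inheritParams precision_recall_at_tau
#' @return Scalar in `[0, 1]` with attribute `n_skipped`.
#' @export
aupr_macro <- function(p, y) {
  if (!all(dim(p) == dim(y))) stop("score and label matrices differ in shape")
  vals <- vapply(seq_len(ncol(y)), function(k) {
    average_precision(p[, k], y[, k])
  }, numeric(1))
  skipped <- sum(is.na(vals))
  if (skipped == ncol(y)) stop("macro-AUPR undefined: no term has a positive")
  out <- mean(vals, na.rm = TRUE)
  attr(out, "n_skipped") <- skipped
  out
}

#' Subset accuracy
#'
#' Fraction of proteins whose thresholded prediction set equals the true
#' term set exactly (proteins with no true terms and no predictions count as
#' correct). The threshold is conventionally the validation-selected
#' `tau_star`.
#'
#' @inheritParams precision_recall_at_tau
#' @return Scalar in `[0, 1]`.
#' @export
subset_accuracy <- function(p, y, tau) {
  if (!all(dim(p) == dim(y))) stop("score and label matrices differ in shape")
  pred <- p > tau
  mean(rowSums(pred != (y == 1)) == 0)
}

#' Micro and macro F1 at a threshold
#'
#' `f1_micro` pools true/false positives over all (protein, term) pairs;
#' `f1_macro` is the unweighted mean of per-term F1 (terms with no positives
#' and no predictions contribute 0).
#'
#' @inheritParams precision_recall_at_tau
#' @return Scalar in `[0, 1]`.
#' @export
f1_micro <- function(p, y, tau) {
  pred <- p > tau
  tp <- sum(pred & y == 1)
  fp <- sum(pred & y == 0)
  fn <- sum(!pred & y == 1)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

#' @rdname f1_micro
#' @export
f1_macro <- function(p, y, tau) {
  pred <- p > tau
  f1s <- vapply(seq_len(ncol(y)), function(k) {
    tp <- sum(pred[, k] & y[, k] == 1)
    fp <- sum(pred[, k] & y[, k] == 0)
    fn <- sum(!pred[, k] & y[, k] == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s)
}

#' Naive frequency baseline
#'
#' Scores every test protein for term `k` with the relative frequency of `k`
#' among the training proteins.
#'
#' @param train_y Binary training label matrix (proteins x terms).
#' @param n_test Number of test proteins to score.
#' @return `n_test` x K score matrix (constant across proteins per term).
#' @export
naive_predict <- function(train_y, n_test) {
  stopifnot(is.matrix(train_y), nrow(train_y) >= 1, n_test >= 1)
  freq <- colMeans(train_y == 1)
  matrix(freq, n_test, ncol(train_y), byrow = TRUE,
         dimnames = list(NULL, colnames(train_y)))
}

#' Full evaluation bundle
#'
#' Computes every reported metric on one (scores, labels) pair: Fmax and its
#' attaining threshold, micro/macro AUPR, and F1 / Macro-F1 / subset
#' accuracy at a caller-supplied threshold (conventionally the
#' validation-set `tau_star`; defaults to this split's own `tau_star`).
#'
#' @inheritParams precision_recall_at_tau
#' @param tau Threshold for the thresholded metrics; default: the Fmax
#'   threshold of `(p, y)` itself.
#' @return An object of class `eval_result` (a named list).
#' @export
evaluate_predictions <- function(p, y, tau = NULL) {
  fm <- fmax(p, y)
  if (is.null(tau)) tau <- fm$tau_star
  res <- list(
    fmax = fm$fmax,
    tau_star = fm$tau_star,
    m_aupr = aupr_micro(p, y),
    M_aupr = as.numeric(aupr_macro(p, y)),
    macro_f1 = f1_macro(p, y, tau),
    f1 = f1_micro(p, y, tau),
    accuracy = subset_accuracy(p, y, tau))
  structure(res, class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "Fmax %.4f (tau* = %.2f)  m-AUPR %.4f  M-AUPR %.4f  M-F1 %.4f  F1 %.4f  acc %.4f\n",
    x$fmax, x$tau_star, x$m_aupr, x$M_aupr, x$macro_f1, x$f1, x$accuracy))
  invisible(x)
}

#' Write an evaluation report as JSON and TSV
#'
#' @param result An [evaluate_predictions()] result.
#' @param path_prefix Output prefix; writes `<prefix>.json` and
#'   `<prefix>.tsv`.
#' @param aspect Optional aspect tag recorded in the report.
#' @return The JSON path, invisibly.
#' @export
write_eval_report <- function(result, path_prefix, aspect = NA_character_) {
  stopifnot(inherits(result, "eval_result"))
  out <- c(list(aspect = aspect), unclass(result))
  jsonlite::write_json(out, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  tab <- data.frame(aspect = aspect, metric = names(unclass(result)),
                    value = unlist(result, use.names = FALSE))
  data.table::fwrite(tab, paste0(path_prefix, ".tsv"), sep = "\t")
  invisible(paste0(path_prefix, ".json"))
}
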