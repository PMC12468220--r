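#' Pixelwise confusion counts between two masks
#'
#' `TRUE` = nucleus. Counts true/false positives/negatives against the
#' ground-truth mask.
#'
#' @param pred,truth Logical matrices of identical shape.
#' @return List with `tp`, `fp`, `tn`, `fn` (their sum is the pixel count).
#' @export
confusion <- function(pred, truth) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth")
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must have the same shape", call. = FALSE)
  list(tp = sum(pred & truth), fp = sum(pred & !truth),
       tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

#' Precision, recall, F1 and accuracy from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `F1` the harmonic mean of
#' the two, `accuracy = (TP+TN)/total`. Degenerate cases follow fixed,
#' flagged conventions: an empty prediction has precision 1 (no false
#' positives); an empty prediction against an empty truth has recall 1 and
#' F1 1. These keep batch tables NaN-free while `flag` marks the rows.
#'
#' @param c Confusion counts from [confusion()].
#' @return List: `precision`, `recall`, `f1`, `accuracy`, `flag` (`""` or a
#'   short degeneracy label).
#' @export
seg_metrics <- function(c) {
  total <- c$tp + c$fp + c$tn + c$fn
  if (total <= 0) stop("no pixels to compare", call. = FALSE)
  flag <- ""
  if (c$tp + c$fp == 0) {
    precision <- 1
    flag <- "empty_prediction"
  } else precision <- c$tp / (c$tp + c$fp)
  if (c$tp + c$fn == 0) {
    recall <- 1
    flag <- paste0(flag, if (nzchar(flag)) "+", "empty_truth")
  } else recall <- c$tp / (c$tp + c$fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  if (c$tp == 0 && c$fn > 0) f1 <- 0      # empty prediction, non-empty truth
  list(precision = precision, recall = recall, f1 = f1,
       accuracy = (c$tp + c$tn) / total, flag = flag)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(MAX^2 / MSE)` with `MAX = 1` on the normalized scale;
#' `Inf` when the images are identical.
#'
#' @param reference,test Single-channel matrices in \[0,1\], same shape.
#' @return PSNR in decibels (possibly `Inf`).
#' @export
psnr <- function(reference, test) {
  assert_channel(reference, "reference"); assert_channel(test, "test")
  if (!all(dim(reference) == dim(test)))
    stop("reference and test must have the same shape", call. = FALSE)
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

#' Paired t-test on per-trial metric values
#'
#' Classical paired t on the differences `a - b`:
#' `t = mean(d) / (sd(d)/sqrt(n))`, two-sided p from the t distribution with
#' `n - 1` degrees of freedom. Zero-variance differences are reported with a
#' degeneracy flag (`t = 0, p = 1` when all differences are zero; `p = 0`
#' when the common difference is nonzero).
#'
#' @param a,b Equal-length numeric vectors (`n >= 2`), paired by trial.
#' @param alpha Significance level reported alongside (default 0.05).
#' @return List: `mean_difference`, `t`, `p_value`, `df`, `significant`,
#'   `flag`.
#' @export
paired_t_test <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least 2 paired observations", call. = FALSE)
  d <- a - b
  md <- mean(d)
  s <- sd(d)
  flag <- ""
  if (s == 0) {
    if (md == 0) {
      t <- 0; p <- 1; flag <- "all_differences_zero"
    } else {
      t <- sign(md) * Inf; p <- 0; flag <- "zero_variance"
    }
  } else {
    t <- md / (s / sqrt(n))
    p <- 2 * pt(-abs(t), df = n - 1L)
  }
  list(mean_difference = md, t = t, p_value = p, df = n - 1L,
       significant = is.finite(p) && p < alpha && flag != "all_differences_zero",
       flag = flag)
}

#' Evaluate a batch of predicted masks against ground truth
#'
#' Per-image precision/recall/F1/accuracy, optional PSNR between paired
#' original and enhanced grayscales, and mean +/- sample standard deviation
#' summary rows (overall and, when `groups` is given, per group plus the
#' macro average of group means).
#'
#' @param preds,truths Lists of logical masks, paired by position.
#' @param originals,enhanced Optional lists of \[0,1\] grayscale matrices for
#'   the PSNR column (reference = original, test = enhanced).
#' @param ids Optional character identifiers (defaults to `img_1, ...`).
#' @param groups Optional character group labels (e.g. normal/abnormal).
#' @return List of data frames: `per_image` (columns image, group, precision,
#'   recall, f1, accuracy, psnr, flags) and `summary` (scope, metric columns
#'   as mean, and `*_sd` columns).
#' @export
evaluate_batch <- function(preds, truths, originals = NULL, enhanced = NULL,
                           ids = NULL, groups = NULL) {
  if (!is.list(preds) || !is.list(truths) || length(preds) != length(truths) ||
      length(preds) < 1L)
    stop("preds and truths must be non-empty lists of equal length", call. = FALSE)
  n <- length(preds)
  if (is.null(ids)) ids <- paste0("img_", seq_len(n))
  with_psnr <- !is.null(originals) && !is.null(enhanced)
  if (with_psnr && (length(originals) != n || length(enhanced) != n))
    stop("originals and enhanced must pair with preds", call. = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- seg_metrics(confusion(preds[[i]], truths[[i]]))
    rows[[i]] <- data.frame(
      image = ids[i],
      group = if (is.null(groups)) NA_character_ else groups[i],
      precision = m$precision, recall = m$recall, f1 = m$f1,
      accuracy = m$accuracy,
      psnr = if (with_psnr) psnr(originals[[i]], enhanced[[i]]) else NA_real_,
      flags = m$flag, stringsAsFactors = FALSE)
  }
  per_image <- do.call(rbind, rows)
  metric_cols <- c("precision", "recall", "f1", "accuracy", "psnr")
  summarize <- function(df, scope) {
    means <- vapply(metric_cols, function(cn) mean(df[[cn]]), numeric(1))
    sds <- vapply(metric_cols, function(cn)
      if (nrow(df) > 1L) sd(df[[cn]]) else 0, numeric(1))
    out <- data.frame(scope = scope, stringsAsFactors = FALSE)
    for (cn in metric_cols) out[[cn]] <- means[[cn]]
    for (cn in metric_cols) out[[paste0(cn, "_sd")]] <- sds[[cn]]
    out
  }
  summary <- summarize(per_image, "overall")
  if (!is.null(groups)) {
    for (g in unique(groups))
      summary <- rbind(summary, summarize(per_image[per_image$group == g, ], g))
    gm <- summary[summary$scope != "overall", metric_cols, drop = FALSE]
    macro <- data.frame(scope = "macro_average", stringsAsFactors = FALSE)
    for (cn in metric_cols) macro[[cn]] <- mean(gm[[cn]])
    for (cn in metric_cols) macro[[paste0(cn, "_sd")]] <- NA_real_
    summary <- rbind(summary, macro)
  }
  list(per_image = per_image, summary = summary)
}
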