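## Performance and model-geometry metrics: cross-validated AUCs,
## sensitivity/specificity at an FLR threshold, footprint-background
## similarity, and peak signal-to-noise.

#' Area under the ROC curve
#'
#' Rank statistic with mid-rank tie handling (equivalent to trapezoidal
#' integration of the ROC curve).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical (or 0/1) true labels.
#' @return AUROC in `[0, 1]`; NA if only one class is present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integration over the recall grid of the full ranking,
#' with ties grouped so that all items of equal score enter together.
#'
#' @inheritParams auroc
#' @return AUPR in `[0, 1]`; NA if there are no positives.
#' @export
aupr <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  if (n1 == 0L) return(NA_real_)
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)   # end of each tie group
  tp <- tp[last]; fp <- fp[last]
  recall <- c(0, tp / n1)
  precision <- c(1, tp / (tp + fp))
  sum(diff(recall) * (utils::head(precision, -1) +
                        utils::tail(precision, -1)) / 2)
}

#' Cross-validated footprinting AUCs
#'
#' Stratified fold assignment; for each fold the footprint model is
#' initialized from the training sites' ChIP-positive aggregate, fitted
#' by EM on the training sites with their fixed backgrounds, and the
#' held-out sites are scored by FLR against their own backgrounds.
#' AUROC and AUPR are computed per fold against the ChIP labels and
#' averaged.
#'
#' @param matrix site x position count matrix.
#' @param backgrounds per-site background multinomials (n x W).
#' @param chip_labels logical truth labels per site.
#' @param folds number of folds (default 4).
#' @param seed RNG seed for the fold assignment (mandatory).
#' @param ... passed to [fit_em()].
#' @return an `eval_report`: list with `auroc`, `aupr` (means),
#'   `per_fold` data frame, `n_sites`, `n_positives`, `folds`, `seed`.
#' @export
cv_auc <- function(matrix, backgrounds, chip_labels, folds = 4L, seed,
                   ...) {
  if (missing(seed)) stop("a seed for the fold assignment is required")
  labels <- as.logical(chip_labels)
  n <- nrow(matrix)
  stopifnot(length(labels) == n, nrow(backgrounds) == n)
  if (sum(labels) < folds || sum(!labels) < folds)
    stop("need at least `folds` sites of each class")
  assign_folds <- function(s) {
    set.seed(s)
    f <- integer(n)
    f[labels] <- sample(rep_len(seq_len(folds), sum(labels)))
    f[!labels] <- sample(rep_len(seq_len(folds), sum(!labels)))
    f
  }
  fold_id <- assign_folds(seed)
  for (attempt in seq_len(10L)) {
    ok <- all(vapply(seq_len(folds), function(k)
      length(unique(labels[fold_id == k])) == 2L, logical(1)))
    if (ok) break
    if (attempt == 10L)
      stop("could not produce folds with both classes after 10 attempts")
    fold_id <- assign_folds(seed + attempt)
  }
  per_fold <- data.frame(fold = seq_len(folds), auroc = NA_real_,
                         aupr = NA_real_)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    init <- initialize_footprint(matrix[tr, , drop = FALSE], labels[tr])
    model <- fit_em(matrix[tr, , drop = FALSE], init,
                    backgrounds[tr, , drop = FALSE], ...)
    scores <- flr(matrix[!tr, , drop = FALSE], model,
                  background = backgrounds[!tr, , drop = FALSE])
    per_fold$auroc[k] <- auroc(scores, labels[!tr])
    per_fold$aupr[k] <- aupr(scores, labels[!tr])
  }
  structure(list(auroc = mean(per_fold$auroc), aupr = mean(per_fold$aupr),
                 per_fold = per_fold, n_sites = n,
                 n_positives = sum(labels), folds = folds, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report: %d sites (%d positive), %d-fold CV: AUROC %.3f, AUPR %.3f\n",
    x$n_sites, x$n_positives, x$folds, x$auroc, x$aupr))
  invisible(x)
}

#' Footprint-background model similarity
#'
#' Pearson correlation between the fitted footprint multinomial and the
#' mean of the per-site background multinomials. High similarity means
#' the sequence-bias background itself looks footprint-like, which
#' impedes separating bound from unbound sites.
#'
#' @param model a `footprint_model` from [fit_em()].
#' @return correlation in `[-1, 1]`. If either profile has zero variance
#'   (e.g. a uniform background) the correlation is undefined; 0 is
#'   returned with attribute `degenerate = TRUE`.
#' @export
model_similarity <- function(model) {
  f <- model$footprint
  b <- colMeans(model$backgrounds)
  if (stats::sd(f) == 0 || stats::sd(b) == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  stats::cor(f, b)
}

#' Signal-to-noise ratio of a peak set
#'
#' log2 of the mean per-base cut count inside the peaks over the mean
#' per-base count in the `flank`-bp regions immediately upstream and
#' downstream of each peak (both sides pooled, clipped at chromosome
#' ends).
#'
#' @param track a [cut_track()].
#' @param peaks interval data frame (chrom, start, end; 0-based
#'   half-open).
#' @param flank flank width in bp (default 300).
#' @param pseudocount added to both means before the ratio (default 0;
#'   set a small value when flanks may be empty).
#' @return log2 ratio.
#' @export
signal_to_noise <- function(track, peaks, flank = 300L, pseudocount = 0) {
  .check_intervals(peaks, "peaks")
  in_sum <- in_len <- fl_sum <- fl_len <- 0
  for (chrom in unique(peaks$chrom)) {
    pooled <- pooled_counts(track, chrom)
    n <- length(pooled)
    sub <- peaks[peaks$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      s <- sub$start[i]; e <- sub$end[i]
      in_sum <- in_sum + sum(pooled[(s + 1L):e])
      in_len <- in_len + (e - s)
      ls <- max(s - flank, 0L); rs <- min(e + flank, n)
      if (s > ls) {
        fl_sum <- fl_sum + sum(pooled[(ls + 1L):s])
        fl_len <- fl_len + (s - ls)
      }
      if (rs > e) {
        fl_sum <- fl_sum + sum(pooled[(e + 1L):rs])
        fl_len <- fl_len + (rs - e)
      }
    }
  }
  num <- in_sum / in_len + pseudocount
  den <- fl_sum / fl_len + pseudocount
  if (den == 0)
    stop("no signal in flanking regions; use a pseudocount")
  log2(num / den)
}

#' Sensitivity and specificity at a score threshold
#'
#' @param flr_scores numeric scores.
#' @param labels logical truth labels.
#' @param threshold calls are `score > threshold` (default 0, the natural
#'   FLR decision point).
#' @return list with `sensitivity` (TP/(TP+FN)) and `specificity`
#'   (TN/(TN+FP)); a rate whose denominator is empty is NA.
#' @export
sensitivity_specificity <- function(flr_scores, labels, threshold = 0) {
  labels <- as.logical(labels)
  call <- flr_scores > threshold
  tp <- sum(call & labels); fn <- sum(!call & labels)
  tn <- sum(!call & !labels); fp <- sum(call & !labels)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}
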