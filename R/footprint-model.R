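## Two-component multinomial mixture over per-site cut-count windows:
## one footprint component shared across sites, one (bias-derived or
## uniform) background per site, mixed with weight pi and fitted by EM
## with the backgrounds held fixed. Multinomial likelihoods omit the
## combinatorial coefficient throughout: it cancels both in the EM
## responsibilities and in the footprint log-likelihood ratio.

#' Build the site-by-position cut-count matrix
#'
#' Collects strand-summed cut counts in a window of motif length plus
#' `pad` bp on each side around every candidate site. Minus-strand sites
#' have their window reversed so that position 1 is always the motif's
#' 5' flank in motif orientation.
#'
#' @param track a [cut_track()].
#' @param sites data frame with chrom, start, end (0-based half-open) and
#'   strand.
#' @param pad flank width in bp (default 25).
#' @return matrix of dim (retained sites) x (L + 2 pad), with attribute
#'   `kept` giving the row indices of `sites` that were in bounds; sites
#'   too close to a chromosome edge are dropped with a warning.
#' @export
build_site_matrix <- function(track, sites, pad = 25L) {
  L <- unique(sites$end - sites$start)
  if (length(L) != 1) stop("all sites must have equal length")
  W <- L + 2L * pad
  lens <- unname(track$seqlengths[sites$chrom])
  ok <- !is.na(lens) & sites$start - pad >= 0L & sites$end + pad <= lens
  if (any(!ok))
    warning(sum(!ok), " site(s) too close to a chromosome edge dropped")
  keep <- which(ok)
  mat <- matrix(0L, length(keep), W)
  for (chrom in unique(sites$chrom[keep])) {
    pooled <- pooled_counts(track, chrom)
    rows <- keep[sites$chrom[keep] == chrom]
    for (i in rows) {
      v <- pooled[(sites$start[i] - pad + 1L):(sites$end[i] + pad)]
      if (sites$strand[i] == "-") v <- rev(v)
      mat[match(i, keep), ] <- v
    }
  }
  attr(mat, "kept") <- keep
  mat
}

.normalize <- function(x) x / sum(x)

#' Initialize the footprint component from ChIP-labeled sites
#'
#' The aggregate (column-summed) cut profile over sites overlapping
#' ChIP-seq peaks for the factor, pseudocount-smoothed and normalized,
#' is the starting value for the footprint multinomial before EM.
#'
#' @param matrix site x position count matrix from [build_site_matrix()].
#' @param chip_labels logical vector, TRUE for sites overlapping a
#'   ChIP-seq peak. If none are TRUE the all-site aggregate is used with
#'   a warning.
#' @param pseudocount smoothing added to each column sum (default 0.5).
#' @return numeric vector of W probabilities summing to 1.
#' @export
initialize_footprint <- function(matrix, chip_labels = NULL,
                                 pseudocount = 0.5) {
  if (is.null(chip_labels)) chip_labels <- rep(TRUE, nrow(matrix))
  if (!any(chip_labels)) {
    warning("no positive labels; initializing from the all-site aggregate")
    chip_labels <- rep(TRUE, nrow(matrix))
  }
  .normalize(colSums(matrix[chip_labels, , drop = FALSE]) + pseudocount)
}

#' Per-site background multinomials
#'
#' In `"bias"` mode each site's background is the cut profile expected
#' from its sequence alone under the protocol's k-mer bias table (the
#' signal a naked-DNA digest would produce there); in `"uniform"` mode
#' every position gets 1/W, the no-correction variant.
#'
#' @param sites data frame with chrom, start, end, strand.
#' @param genome named character vector of sequences (required for bias
#'   mode).
#' @param mode `"bias"` or `"uniform"`.
#' @param table [kmer_bias_table()] (bias mode).
#' @param pad flank width matching [build_site_matrix()].
#' @return matrix of dim n_sites x W, rows summing to 1.
#' @export
build_backgrounds <- function(sites, genome = NULL,
                              mode = c("bias", "uniform"), table = NULL,
                              pad = 25L) {
  mode <- match.arg(mode)
  L <- unique(sites$end - sites$start)
  if (length(L) != 1) stop("all sites must have equal length")
  W <- L + 2L * pad
  n <- nrow(sites)
  if (mode == "uniform")
    return(matrix(1 / W, n, W))
  if (is.null(table)) stop("bias mode requires a kmer bias table")
  .check_genome(genome)
  half <- table$k %/% 2L
  s0 <- sites$start - pad - half
  e0 <- sites$end + pad + half
  if (any(s0 < 0L | e0 > nchar(genome[sites$chrom])))
    stop("some sites lack k/2 bp of context for the bias profile")
  seqs <- substr(genome[sites$chrom], s0 + 1L, e0)
  minus <- sites$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  bg <- matrix(NA_real_, n, W)
  for (i in seq_len(n)) bg[i, ] <- expected_cut_profile(seqs[i], table)
  bg
}

# floor and renormalize background rows for likelihood stability
.prep_backgrounds <- function(backgrounds, floor = 1e-8) {
  b <- pmax(backgrounds, floor)
  b / rowSums(b)
}

#' Fit the footprint/background mixture by EM
#'
#' E-step: the responsibility of the footprint component for site i is
#' `r_i = pi P(x_i | f) / (pi P(x_i | f) + (1 - pi) P(x_i | b_i))` with
#' multinomial likelihoods. M-step: the footprint multinomial f is the
#' responsibility-weighted, pseudocount-smoothed normalized column sum of
#' counts, and pi the mean responsibility. Per-site backgrounds are held
#' fixed by default; with `fixed_background = FALSE` a single shared
#' background multinomial is re-estimated from the complementary weights
#' instead. The observed-data log likelihood is non-decreasing across
#' iterations.
#'
#' @param matrix site x position count matrix.
#' @param init_footprint initial footprint multinomial (length W), e.g.
#'   from [initialize_footprint()].
#' @param backgrounds n x W matrix of per-site background multinomials.
#' @param fixed_background keep backgrounds fixed (default TRUE).
#' @param pi_init initial mixture weight of the footprint component.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @param pseudocount smoothing for the footprint M-step.
#' @return a `footprint_model`: list with `footprint`, `backgrounds`,
#'   `pi`, `responsibilities`, `loglik` (per-iteration trace),
#'   `converged`, `n_iter`.
#' @export
fit_em <- function(matrix, init_footprint, backgrounds,
                   fixed_background = TRUE, pi_init = 0.5, tol = 1e-6,
                   max_iter = 200L, pseudocount = 0.5) {
  x <- as.matrix(matrix)
  n <- nrow(x); W <- ncol(x)
  stopifnot(length(init_footprint) == W, ncol(backgrounds) == W,
            nrow(backgrounds) == n)
  if (any(init_footprint <= 0))
    stop("init footprint has non-positive entries; use a pseudocount")
  f <- .normalize(init_footprint)
  b <- .prep_backgrounds(backgrounds)
  lb <- log(b)
  pi <- pi_init
  ll_bg <- rowSums(x * lb)              # fixed unless background updated
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ll_f <- as.vector(x %*% log(f))
    a1 <- log(pi) + ll_f
    a0 <- log1p(-pi) + ll_bg
    m <- pmax(a1, a0)
    ll <- sum(m + log(exp(a1 - m) + exp(a0 - m)))
    if (!is.finite(ll))
      stop("non-finite likelihood; increase the pseudocount")
    trace <- c(trace, ll)
    r <- 1 / (1 + exp(a0 - a1))
    f <- .normalize(as.vector(crossprod(x, r)) + pseudocount)
    if (!fixed_background) {
      shared <- .normalize(as.vector(crossprod(x, 1 - r)) + pseudocount)
      b <- matrix(shared, n, W, byrow = TRUE)
      lb <- log(b)
      ll_bg <- rowSums(x * lb)
    }
    pi <- mean(r)
    pi <- min(max(pi, 1e-6), 1 - 1e-6)
    if (it > 1L && (ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  structure(list(footprint = f, backgrounds = b, pi = pi,
                 responsibilities = r, loglik = trace,
                 converged = converged, n_iter = length(trace)),
            class = "footprint_model")
}

#' @export
print.footprint_model <- function(x, ...) {
  cat(sprintf(
    "footprint_model: W=%d, pi=%.3f, %d EM iteration(s), %sconverged\n",
    length(x$footprint), x$pi, x$n_iter, if (x$converged) "" else "not "))
  invisible(x)
}

#' Footprint log-likelihood ratio (FLR)
#'
#' Per-site log odds of the footprint versus the background component:
#' `FLR = log P(x | footprint) - log P(x | background_i)` under the
#' multinomial models (combinatorial coefficient cancels). Positive FLR
#' means the cut profile looks more like a bound site than like the
#' bias-expected background. The mixture prior-odds term
#' `log(pi / (1 - pi))` is excluded by default.
#'
#' @param counts count vector of length W, or an n x W matrix for many
#'   sites at once.
#' @param model a `footprint_model` from [fit_em()], or a list with
#'   `footprint` and `backgrounds` of matching shape.
#' @param background optional background multinomial(s) overriding the
#'   model's (vector of length W or n x W matrix).
#' @param include_prior_odds add `log(pi / (1 - pi))` to every score.
#' @return numeric vector of FLR values (length n).
#' @export
flr <- function(counts, model, background = NULL,
                include_prior_odds = FALSE) {
  x <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1L)
  W <- length(model$footprint)
  if (ncol(x) != W) stop("counts have ", ncol(x), " columns, expected ", W)
  b <- if (!is.null(background)) background else model$backgrounds
  if (!is.matrix(b)) b <- matrix(b, nrow(x), W, byrow = TRUE)
  if (nrow(b) == 1L && nrow(x) > 1L)
    b <- matrix(b[1L, ], nrow(x), W, byrow = TRUE)
  b <- .prep_backgrounds(b)
  out <- as.vector(x %*% log(model$footprint)) - rowSums(x * log(b))
  if (include_prior_odds) out <- out + log(model$pi / (1 - model$pi))
  out
}

#' Write a footprint model as plain text
#'
#' @param model a `footprint_model`.
#' @param path output TSV path.
#' @export
write_footprint_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#pi\t", model$pi),
               paste0("#iterations\t", model$n_iter),
               paste0("#converged\t", model$converged),
               "position\tfootprint\tmean_background"), con)
  utils::write.table(
    data.frame(position = seq_along(model$footprint),
               footprint = model$footprint,
               mean_background = colMeans(model$backgrounds)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Apparent footprint width of a fitted profile
#'
#' Number of window positions whose footprint probability falls below
#' half the profile mean; a crude but model-free summary of how wide the
#' protected region is.
#'
#' @param footprint multinomial over W positions.
#' @return integer width in bp.
#' @export
footprint_width <- function(footprint) {
  sum(footprint < 0.5 * mean(footprint))
}
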