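## PWM scanning against a local first-order Markov background.
##
## The background for a candidate position is a first-order Markov chain
## estimated from the 500-bp window centered on that position, using both
## strands of the window (strand-symmetric counts) with add-one smoothing
## over the 16 transitions, so a single background model serves plus- and
## minus-strand matches at the same locus.

#' Position weight matrix
#'
#' @param freq 4 x L numeric matrix of per-position nucleotide
#'   frequencies, rows in A, C, G, T order; columns need not be exactly
#'   normalized on input.
#' @param name motif name.
#' @param pseudocount value added to every frequency before column
#'   renormalization, guaranteeing non-zero entries (default 0.0005).
#' @return a `pwm` object (4 x L matrix with attributes).
#' @export
pwm <- function(freq, name = "motif", pseudocount = 0.0005) {
  freq <- as.matrix(freq)
  if (nrow(freq) != 4) stop("freq must have 4 rows (A, C, G, T)")
  if (any(freq < 0)) stop("negative frequencies")
  freq <- sweep(freq, 2, colSums(freq), "/")
  freq <- freq + pseudocount
  freq <- sweep(freq, 2, colSums(freq), "/")
  rownames(freq) <- c("A", "C", "G", "T")
  structure(freq, class = "pwm", name = name, pseudocount = pseudocount)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': length %d, consensus %s\n", attr(x, "name"),
              ncol(x), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param x a [pwm()].
#' @return character string of most-probable bases.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x)[apply(unclass(x), 2, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#'
#' @param x a [pwm()].
#' @return the reverse-complemented `pwm`.
#' @export
pwm_revcomp <- function(x) {
  m <- unclass(x)[4:1, rev(seq_len(ncol(x))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  structure(m, class = "pwm", name = attr(x, "name"),
            pseudocount = attr(x, "pseudocount"))
}

#' Read a JASPAR PFM text file
#'
#' Accepts both the bracketed JASPAR format (`A [ 1 2 3 ]`) and plain
#' 4-row count matrices under a `>` header.
#'
#' @param path PFM file.
#' @param pseudocount passed to [pwm()].
#' @return a [pwm()].
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.0005) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- "motif"
  if (startsWith(lines[1], ">")) {
    name <- trimws(sub("^>\\s*", "", lines[1]))
    lines <- lines[-1]
  }
  if (length(lines) < 4) stop("PFM must have 4 matrix rows")
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
    l <- gsub("[\\[\\]]", "", l, perl = TRUE)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  if (length(unique(lengths(rows))) != 1)
    stop("PFM rows have unequal lengths")
  pwm(do.call(rbind, rows), name = name, pseudocount = pseudocount)
}

# first-order Markov model from integer codes of a context sequence,
# counting both the given strand and its reverse complement; add-one
# smoothing on the 16 transitions and the 4 initial-base counts.
.markov_fit_codes <- function(codes) {
  n <- length(codes)
  trans <- matrix(0, 4, 4)
  if (n >= 2) {
    idx <- 4L * codes[-n] + codes[-1L] + 1L   # NA where either base is N
    tab <- tabulate(idx[!is.na(idx)], nbins = 16L)
    fwd <- matrix(tab, 4, 4, byrow = TRUE)
    trans <- fwd + t(fwd[4:1, 4:1])        # + reverse-complement strand
  }
  base <- tabulate(codes[!is.na(codes)] + 1L, nbins = 4L)
  base <- base + rev(base)                 # symmetric base counts
  list(trans = (trans + 1) / rowSums(trans + 1),
       init = (base + 1) / sum(base + 1))
}

#' Fit a first-order Markov background model
#'
#' @param context character string of background sequence (<= 500 bp when
#'   used as a local window).
#' @return list with `init` (4 initial-base probabilities) and `trans`
#'   (4 x 4 row-stochastic transition matrix), both strand-symmetric and
#'   add-one smoothed.
#' @export
markov_background <- function(context) {
  .markov_fit_codes(.encode_dna(context))
}

# log probability of an encoded window under a Markov model
.markov_logprob_codes <- function(codes, model) {
  if (anyNA(codes)) return(NA_real_)
  lp <- log(model$init[codes[1L] + 1L])
  if (length(codes) >= 2L) {
    n <- length(codes)
    lp <- lp + sum(log(model$trans[cbind(codes[-n] + 1L, codes[-1L] + 1L)]))
  }
  lp
}

# log probability of an encoded window under a PWM
.pwm_logprob_codes <- function(codes, pwm) {
  if (anyNA(codes) || length(codes) != ncol(pwm)) return(NA_real_)
  sum(log(unclass(pwm)[cbind(codes + 1L, seq_along(codes))]))
}

#' TFBS log-likelihood score of one window
#'
#' log of P(window | PWM) over P(window | first-order Markov chain
#' estimated from the local context).
#'
#' @param window_sequence string of length equal to the PWM.
#' @param pwm a [pwm()].
#' @param local_context string of background sequence (nominally the
#'   500-bp window centered on the position; shorter contexts, e.g.
#'   clipped at chromosome ends, are used as-is).
#' @return the log-likelihood ratio; `NA` if the window contains an
#'   ambiguous base.
#' @export
tfbs_score <- function(window_sequence, pwm, local_context) {
  codes <- .encode_dna(window_sequence)
  model <- markov_background(local_context)
  .pwm_logprob_codes(codes, pwm) - .markov_logprob_codes(codes, model)
}

# vectorized scan of one chromosome on one strand orientation.
# Returns the score for every 0-based window start (NA where ambiguous).
.scan_chrom_strand <- function(codes, pwm, centers, bg_at, strand) {
  L <- ncol(pwm)
  n <- length(codes)
  m <- n - L + 1L
  if (m < 1L) return(numeric(0))
  use_pwm <- if (strand == "+") pwm else pwm_revcomp(pwm)
  lpw <- log(unclass(use_pwm))
  score <- numeric(m)
  ok <- rep(TRUE, m)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + m - 1L)]
    ok <- ok & !is.na(cj)
    cj[is.na(cj)] <- 1L
    score <- score + lpw[cbind(cj + 1L, j)]
  }
  # background: per-window local Markov model, shared lookup tables
  # bg_at[[i]] gives, for window start i, the row index into the
  # precomputed per-center transition/init tables
  lp_init <- log(bg_at$init)[cbind(bg_at$row, codes[seq_len(m)] + 1L)]
  lp_bg <- lp_init
  if (L >= 2L) {
    for (j in seq_len(L - 1L)) {
      a <- codes[j:(j + m - 1L)]
      b <- codes[(j + 1L):(j + m)]
      t_idx <- 4L * a + b + 1L
      t_idx[is.na(t_idx)] <- 1L
      lp_bg <- lp_bg + log(bg_at$trans)[cbind(bg_at$row, t_idx)]
    }
  }
  if (strand == "-") {
    # minus-strand window prob under the same symmetric background equals
    # the prob of the reverse-complemented sequence; recompute directly
    rc_codes <- 3L - codes
    lp_bg <- log(bg_at$init)[cbind(bg_at$row, rc_codes[(seq_len(m)) + L - 1L] + 1L)]
    if (L >= 2L) {
      for (j in seq_len(L - 1L)) {
        a <- rc_codes[(j + 1L):(j + m)]      # rc read right-to-left
        b <- rc_codes[j:(j + m - 1L)]
        t_idx <- 4L * a + b + 1L
        t_idx[is.na(t_idx)] <- 1L
        lp_bg <- lp_bg + log(bg_at$trans)[cbind(bg_at$row, t_idx)]
      }
    }
  }
  out <- score - lp_bg
  out[!ok] <- NA_real_
  out
}

# precompute strand-symmetric Markov backgrounds for a set of window
# centers: cumulative transition/base counts give each center's local
# 500-bp counts in O(1).
.local_backgrounds <- function(codes, centers, bg_window = 500L) {
  n <- length(codes)
  half <- bg_window %/% 2L
  cc <- codes
  cc_na <- is.na(cc)
  # cumulative counts of the 16 transitions and 4 bases
  t_id <- 4L * cc[-n] + cc[-1L] + 1L
  t_id[is.na(t_id)] <- 0L
  base_id <- cc + 1L
  base_id[cc_na] <- 0L
  cum_t <- matrix(0, n, 16L)
  cum_b <- matrix(0, n + 1L, 4L)
  for (t in 1:16) cum_t[, t] <- c(0, cumsum(t_id == t))
  for (b in 1:4) cum_b[, b] <- c(0, cumsum(base_id == b))
  lo <- pmax(centers - half, 0L)                     # [lo, hi) 0-based
  hi <- pmin(centers + half, n)
  tc <- cum_t[hi, , drop = FALSE] -
    cum_t[lo + 1L, , drop = FALSE]         # transitions fully inside [lo,hi)
  bc <- cum_b[hi + 1L, , drop = FALSE] - cum_b[lo + 1L, , drop = FALSE]
  # strand-symmetrize: count(a,b) + count(comp b, comp a); base + comp
  sym_idx <- as.vector(t(outer(0:3, 0:3,
                               function(a, b) 4L * (3L - b) + (3L - a) + 1L)))
  tc_sym <- tc + tc[, sym_idx, drop = FALSE]
  bc_sym <- bc + bc[, 4:1, drop = FALSE]
  # add-one smoothing; row-normalize transitions per from-base
  tc_sym <- tc_sym + 1
  row_tot <- sapply(0:3, function(a)
    rowSums(tc_sym[, (4L * a + 1L):(4L * a + 4L), drop = FALSE]))
  if (is.null(dim(row_tot))) row_tot <- matrix(row_tot, nrow = 1L)
  trans <- tc_sym
  for (a in 0:3)
    trans[, (4L * a + 1L):(4L * a + 4L)] <-
      tc_sym[, (4L * a + 1L):(4L * a + 4L), drop = FALSE] / row_tot[, a + 1L]
  bc_sym <- bc_sym + 1
  init <- bc_sym / rowSums(bc_sym)
  list(trans = trans, init = init)
}

#' Scan a genome for candidate TF binding sites
#'
#' Scores every window of PWM length on both strands as the log
#' likelihood of the sequence under the PWM versus a first-order Markov
#' chain estimated from the 500-bp window centered on the position
#' (clipped at chromosome ends), and returns the `top_n` highest-scoring
#' unambiguous sites. Overlapping matches are all retained; ties at the
#' `top_n` boundary are kept.
#'
#' @param genome named character vector of chromosome sequences.
#' @param pwm a [pwm()].
#' @param top_n number of sites to return (default 50000; `Inf` for all).
#' @param bg_window local background window size in bp (default 500).
#' @param block_size optional speed/accuracy trade-off: when set, one
#'   background per `block_size`-bp block (centered on the block) is
#'   reused for all positions in it instead of a fresh background per
#'   position.
#' @return data frame of candidate sites: chrom, start, end (0-based
#'   half-open), strand, tfbs_score, rank, sorted by descending score.
#' @export
scan_genome <- function(genome, pwm, top_n = 50000L, bg_window = 500L,
                        block_size = NULL) {
  .check_genome(genome)
  L <- ncol(pwm)
  hits <- list()
  for (chrom in names(genome)) {
    codes <- .encode_dna(genome[[chrom]])
    n <- length(codes)
    if (n < L) next
    m <- n - L + 1L
    starts0 <- 0:(m - 1L)
    centers <- starts0 + L %/% 2L
    if (!is.null(block_size)) {
      block <- centers %/% block_size
      ucent <- unique(block) * block_size + block_size %/% 2L
      ucent <- pmin(pmax(ucent, 0L), n)
      bgs <- .local_backgrounds(codes, ucent, bg_window)
      row <- match(block, unique(block))
    } else {
      bgs <- .local_backgrounds(codes, centers, bg_window)
      row <- seq_len(m)
    }
    bg_at <- list(trans = bgs$trans, init = bgs$init, row = row)
    for (s in c("+", "-")) {
      sc <- .scan_chrom_strand(codes, pwm, centers, bg_at, s)
      keep <- which(!is.na(sc))
      if (length(keep))
        hits[[paste0(chrom, s)]] <- data.frame(
          chrom = chrom, start = starts0[keep], end = starts0[keep] + L,
          strand = s, tfbs_score = sc[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      tfbs_score = numeric(), rank = integer()))
  all <- do.call(rbind, hits)
  ord <- order(-all$tfbs_score, all$chrom, all$start,
               method = "radix")
  all <- all[ord, , drop = FALSE]
  if (is.finite(top_n) && nrow(all) > top_n) {
    cutoff <- all$tfbs_score[top_n]
    all <- all[all$tfbs_score >= cutoff, , drop = FALSE]  # keep ties
  }
  all$rank <- seq_len(nrow(all))
  rownames(all) <- NULL
  all
}

#' Sample sequences from a PWM
#'
#' @param pwm a [pwm()].
#' @param n number of sequences.
#' @return character vector of n sequences of PWM length.
#' @export
sample_pwm_sequences <- function(pwm, n) {
  L <- ncol(pwm)
  mat <- unclass(pwm)
  cols <- vapply(seq_len(L), function(j)
    sample.int(4L, n, replace = TRUE, prob = mat[, j]), integer(n))
  if (n == 1L) cols <- matrix(cols, nrow = 1L)
  apply(cols, 1L, function(cc) .decode_dna(cc - 1L))
}

#' Sample sequences from a first-order Markov model
#'
#' @param model list with `init` and `trans` as from
#'   [markov_background()].
#' @param n number of sequences.
#' @param len sequence length.
#' @return character vector of n sequences.
#' @export
sample_markov_sequences <- function(model, n, len) {
  out <- character(n)
  for (i in seq_len(n)) {
    cc <- integer(len)
    cc[1L] <- sample.int(4L, 1L, prob = model$init) - 1L
    for (j in seq_len(len - 1L))
      cc[j + 1L] <- sample.int(4L, 1L, prob = model$trans[cc[j] + 1L, ]) - 1L
    out[i] <- .decode_dna(cc)
  }
  out
}

#' Empirical p value of a motif set's minimum TFBS score
#'
#' Simulates sequences from the PWM (positive set) and from a first-order
#' Markov background (negative set), scores both sets as log P(seq | PWM)
#' minus log P(seq | background), finds the negative-set score cutoff at
#' each false-positive rate on a grid, and reports the grid cutoff
#' closest to the observed minimum score together with its FPR as the
#' empirical p value.
#'
#' @param pwm a [pwm()].
#' @param negative_model first-order Markov model (see
#'   [markov_background()]), e.g. fitted on hypersensitive-site sequence.
#' @param observed_min_score lowest TFBS score in the motif set under
#'   assessment.
#' @param n_samples simulated sequences per set; must be at least
#'   10 / min(fpr_grid).
#' @param fpr_grid decreasing grid of false-positive rates (default
#'   10^-(1..6)).
#' @return list with `score_cutoff`, `empirical_p`, and the full
#'   `grid` (fpr, cutoff) table.
#' @export
empirical_pvalue <- function(pwm, negative_model, observed_min_score,
                             n_samples = 1e5,
                             fpr_grid = 10^-(1:6)) {
  if (n_samples < 10 / min(fpr_grid))
    stop("n_samples too small for FPR ", min(fpr_grid),
         "; need at least ", format(10 / min(fpr_grid), scientific = FALSE))
  L <- ncol(pwm)
  score_one <- function(seqs) {
    vapply(seqs, function(s) {
      codes <- .encode_dna(s)
      .pwm_logprob_codes(codes, pwm) -
        .markov_logprob_codes(codes, negative_model)
    }, numeric(1), USE.NAMES = FALSE)
  }
  neg <- score_one(sample_markov_sequences(negative_model, n_samples, L))
  cutoffs <- stats::quantile(neg, probs = 1 - fpr_grid, names = FALSE,
                             type = 1)
  grid <- data.frame(fpr = fpr_grid, cutoff = cutoffs)
  i <- which.min(abs(grid$cutoff - observed_min_score))
  list(score_cutoff = grid$cutoff[i], empirical_p = grid$fpr[i],
       grid = grid)
}
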