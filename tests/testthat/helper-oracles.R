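# Independent brute-force oracles used to check the package's vectorized
# implementations. These deliberately use naive string slicing and loops
# rather than the package's internal code paths.

BASES <- c("A", "C", "G", "T")

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# k-mer bias estimation by direct enumeration: every cut-centered k-mer
# (gap convention: plus cut at base b -> gap b; minus cut at base b ->
# gap b + 1; k-mer = [gap - k/2, gap + k/2), revcomp on minus), every
# genomic k-mer on both strands, pseudo-count 1 per k-mer.
oracle_kmer_bias <- function(track, genome, k = 6) {
  half <- k / 2
  kmers <- all_kmers(k)
  cuts <- setNames(rep(0, length(kmers)), kmers)
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    n <- nchar(seq)
    for (strand in c("plus", "minus")) {
      counts <- track[[strand]][[chrom]]
      for (b in which(counts > 0) - 1) {
        gap <- if (strand == "plus") b else b + 1
        if (gap - half < 0 || gap + half > n) next
        km <- substr(seq, gap - half + 1, gap + half)
        if (strand == "minus") km <- oracle_revcomp(km)
        if (km %in% kmers) cuts[km] <- cuts[km] + counts[b + 1]
      }
    }
  }
  bg <- setNames(rep(0, length(kmers)), kmers)
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    for (j in 1:(nchar(seq) - k + 1)) {
      km <- substr(seq, j, j + k - 1)
      if (km %in% kmers) {
        bg[km] <- bg[km] + 1
        bg[oracle_revcomp(km)] <- bg[oracle_revcomp(km)] + 1
      }
    }
  }
  cuts <- cuts + 1
  if (any(bg == 0)) bg <- bg + 1            # same pseudo-frequency rule
  (cuts / sum(cuts)) / (bg / sum(bg))
}

# expected cut profile by per-position slicing
oracle_expected_profile <- function(seq_with_context, table) {
  k <- table$k
  W <- nchar(seq_with_context) - k
  w <- numeric(W)
  for (i in 1:W) w[i] <- table$propensity[[substr(seq_with_context, i,
                                                  i + k - 1)]]
  w / sum(w)
}

# strand-symmetric first-order Markov model with add-one smoothing,
# estimated from a context string (given + reverse complement); counts
# are re-derived per call by direct tabulation
oracle_markov <- function(context) {
  cc <- match(strsplit(context, "")[[1]], BASES)
  n <- length(cc)
  tid <- 4 * (cc[-n] - 1) + cc[-1]
  trans <- matrix(tabulate(tid[!is.na(tid)], 16), 4, 4, byrow = TRUE)
  base <- tabulate(cc[!is.na(cc)], 4)
  # reverse-complement strand: count(a,b) on rc equals count(comp b,
  # comp a) forward, and base counts complement-swap
  trans <- trans + t(trans[4:1, 4:1]) + 1
  base <- base + rev(base) + 1
  dimnames(trans) <- list(BASES, BASES)
  list(init = setNames(base / sum(base), BASES),
       trans = trans / rowSums(trans))
}

# all-window, both-strand scan oracle for one chromosome; returns a data
# frame (start, strand, score) built by per-position re-estimation
oracle_scan_chrom <- function(genome, chrom, pwm_mat, bg_window = 500) {
  L <- ncol(pwm_mat)
  n <- nchar(genome[[chrom]])
  m <- n - L + 1
  out <- vector("list", m)
  for (s0 in 0:(m - 1)) {
    center <- s0 + L %/% 2
    lo <- max(center - bg_window %/% 2, 0)
    hi <- min(center + bg_window %/% 2, n)
    mk <- oracle_markov(substr(genome[[chrom]], lo + 1, hi))
    win <- substr(genome[[chrom]], s0 + 1, s0 + L)
    score_one <- function(w) {
      chars <- strsplit(w, "")[[1]]
      if (anyNA(match(chars, BASES))) return(NA_real_)
      lp_pwm <- sum(log(pwm_mat[cbind(match(chars, BASES),
                                      seq_along(chars))]))
      lp_bg <- log(mk$init[[chars[1]]]) +
        sum(log(mk$trans[cbind(chars[-L], chars[-1])]))
      lp_pwm - lp_bg
    }
    out[[s0 + 1]] <- data.frame(
      start = s0, strand = c("+", "-"),
      score = c(score_one(win), score_one(oracle_revcomp(win))))
  }
  do.call(rbind, out)
}

oracle_tfbs_score <- function(window, pwm_mat, context) {
  m <- oracle_markov(context)
  chars <- strsplit(window, "")[[1]]
  lp_pwm <- sum(log(pwm_mat[cbind(match(chars, BASES),
                                  seq_along(chars))]))
  lp_bg <- log(m$init[[chars[1]]])
  if (length(chars) > 1)
    for (j in 2:length(chars))
      lp_bg <- lp_bg + log(m$trans[chars[j - 1], chars[j]])
  lp_pwm - lp_bg
}

# scan oracle: score of the window starting at 0-based `start` on a
# chromosome, on either strand, with the local 500-bp background
oracle_scan_score <- function(genome, chrom, start, strand, pwm_mat,
                              bg_window = 500) {
  L <- ncol(pwm_mat)
  n <- nchar(genome[[chrom]])
  center <- start + L %/% 2
  lo <- max(center - bg_window %/% 2, 0)
  hi <- min(center + bg_window %/% 2, n)
  ctx <- substr(genome[[chrom]], lo + 1, hi)
  win <- substr(genome[[chrom]], start + 1, start + L)
  if (strand == "-") win <- oracle_revcomp(win)
  oracle_tfbs_score(win, pwm_mat, ctx)
}

# multinomial log-likelihood difference (no combinatorial coefficient)
oracle_flr <- function(counts, footprint, background) {
  s <- 0
  for (j in seq_along(counts))
    s <- s + counts[j] * (log(footprint[j]) - log(background[j]))
  s
}

# quadratic interval-overlap oracle (0-based half-open)
oracle_overlap <- function(a, b, min_overlap = 1) {
  hits <- logical(nrow(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_overlap) hits[i] <- TRUE
  }
  hits
}

# simple data generators shared by tests
test_pwm <- function(L = 10, strong = 12) {
  m <- matrix(1, 4, L)
  cons <- rep_len(1:4, L)
  m[cbind(cons, 1:L)] <- strong
  pwm(m, name = "testTF")
}

test_reads <- function(n, seqlen, seed = 1) {
  set.seed(seed)
  start <- sample.int(seqlen - 40L, n, replace = TRUE) - 1L
  data.frame(chrom = "chr1", start = start, end = start + 30L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             is_proper_pair = TRUE,
             fragment_length = sample(38:300, n, replace = TRUE))
}
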