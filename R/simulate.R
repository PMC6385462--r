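## Fully seeded generators for synthetic genomes, bias tables, motif
## sites and cut-count data with known ground truth. Every other module
## is testable against these without external downloads.

#' Simulate an i.i.d. random genome
#'
#' @param lengths named integer vector of chromosome lengths (>= 1 kb
#'   each).
#' @param gc GC content in (0, 1).
#' @param seed RNG seed.
#' @return named character vector of sequences.
#' @export
simulate_genome <- function(lengths = c(chr1 = 1e5), gc = 0.5, seed = 1L) {
  if (gc <= 0 || gc >= 1) stop("gc must be strictly inside (0, 1)")
  if (any(lengths < 1000)) stop("chromosome lengths must be >= 1 kb")
  set.seed(seed)
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- vapply(lengths, function(n)
    paste(sample(names(prob), n, replace = TRUE, prob = prob),
          collapse = ""), character(1))
  names(out) <- names(lengths)
  out
}

#' Simulate a k-mer bias table with hot k-mers
#'
#' Starts from a flat table, multiplies `n_hot` randomly chosen k-mers by
#' `strength`, and optionally roughens all propensities with mild
#' log-normal noise, emulating the skewed hexamer preference of a real
#' cleavage/transposition enzyme.
#'
#' @param k k-mer length.
#' @param n_hot number of elevated k-mers.
#' @param strength multiplicative elevation of hot k-mers.
#' @param noise_sd sd of natural-log-normal noise on all k-mers; the
#'   default 1.25 spreads propensities over roughly two to three orders
#'   of magnitude, the span reported for DNase I and Tn5 hexamer
#'   preferences.
#' @param seed RNG seed.
#' @param protocol provenance tag.
#' @param symmetric make the table reverse-complement symmetric
#'   (propensity of a k-mer equals that of its reverse complement), the
#'   palindromic preference expected of a homodimeric enzyme cutting
#'   both strands; default TRUE for the ATAC protocol, FALSE otherwise.
#' @return a [kmer_bias_table()].
#' @export
simulate_bias_table <- function(k = 6L, n_hot = 40L, strength = 8,
                                noise_sd = 1.25, seed = 1L,
                                protocol = "ATAC",
                                symmetric = identical(protocol, "ATAC")) {
  set.seed(seed)
  kmers <- all_kmers(k)
  prop <- rep(1, length(kmers))
  hot <- sample.int(length(kmers), n_hot)
  prop[hot] <- prop[hot] * strength
  if (noise_sd > 0) prop <- prop * exp(stats::rnorm(length(prop), 0,
                                                    noise_sd))
  if (symmetric) {
    # one draw per reverse-complement pair, copied to the partner, so the
    # palindromic preference keeps the full propensity spread
    rc <- .revcomp_code_map(k) + 1L
    canonical <- seq_along(prop) <= rc
    prop[!canonical] <- prop[rc[!canonical]]
  }
  kmer_bias_table(stats::setNames(prop, kmers), k = k,
                  protocol = protocol, source = "simulated")
}

# per-gap cut weights on one strand of one chromosome, proportional to
# the bias propensity of the k-mer centered on the gap; returns the
# 0-based counted-base position for each eligible gap plus its weight
.gap_weights <- function(codes, table, strand) {
  k <- table$k
  half <- k %/% 2L
  n <- length(codes)
  kidx <- .kmer_codes(codes, k)              # k-mer starting at base j
  # gap p has k-mer start p - half; eligible p in [half, n - half]
  p <- half:(n - half)
  ki <- kidx[p - half + 1L]
  w <- table$propensity[ki + 1L]
  w[is.na(w)] <- 0
  base <- if (strand == "+") p else p - 1L
  ok <- base >= 0L & base < n
  list(base = base[ok], w = w[ok])
}

#' Simulate naked-DNA cuts driven by a bias table
#'
#' Places `n_cuts` cut events on a genome with per-gap probability
#' proportional to the propensity of the k-mer centered on the gap
#' (reverse-complemented on the minus strand), emulating an enzyme digest
#' of deproteinized DNA. Used to validate bias estimation.
#'
#' @param genome named character vector of sequences.
#' @param table a [kmer_bias_table()].
#' @param n_cuts total number of cut events (split roughly evenly across
#'   strands).
#' @param seed RNG seed.
#' @param stranded simulate both strands (default) or plus only.
#' @param paired emulate the strand symmetry of a double-strand
#'   transposition event: each of the `n_cuts / 2` events deposits a
#'   plus-strand cut and the mirrored minus-strand cut at the same gap,
#'   so the k-mers seen by the two strands are exact reverse
#'   complements. With `paired = FALSE` (default) the strands are
#'   sampled independently from the same table.
#' @return a [cut_track()].
#' @export
simulate_naked_cuts <- function(genome, table, n_cuts, seed = 1L,
                                stranded = TRUE, paired = FALSE) {
  .check_genome(genome)
  set.seed(seed)
  lens <- vapply(genome, nchar, integer(1))
  track <- cut_track(lens)
  strands <- if (stranded) c("+", "-") else "+"
  n_events <- if (paired) n_cuts / 2 else n_cuts / length(strands)
  per <- round(n_events * lens / sum(lens))
  for (chrom in names(genome)) {
    codes <- .encode_dna(genome[[chrom]])
    rc_codes <- rev(3L - codes)
    n <- length(codes)
    gw_plus <- .gap_weights(codes, table, "+")
    g <- .gap_weights(rc_codes, table, "+")
    # base b' on rc maps to genome base n - 1 - b'; the rc "+" gap
    # convention lands the count on the base 5' of the gap on minus
    gw_minus <- list(base = n - 1L - g$base, w = g$w)
    if (paired) {
      if (!length(gw_plus$base) || sum(gw_plus$w) == 0) next
      draws <- stats::rmultinom(1L, per[[chrom]], gw_plus$w)[, 1L]
      track$plus[[chrom]][gw_plus$base + 1L] <- draws
      # mirrored minus cut of a plus cut at gap p sits at base p - 1
      mb <- gw_plus$base - 1L
      ok <- mb >= 0L
      track$minus[[chrom]][mb[ok] + 1L] <- draws[ok]
      next
    }
    for (s in strands) {
      gw <- if (s == "+") gw_plus else gw_minus
      if (!length(gw$base) || sum(gw$w) == 0) next
      draws <- stats::rmultinom(1L, per[[chrom]], gw$w)[, 1L]
      slot <- if (s == "+") "plus" else "minus"
      track[[slot]][[chrom]][gw$base + 1L] <-
        track[[slot]][[chrom]][gw$base + 1L] + draws
    }
  }
  track
}

#' Plant motif sites into a genome
#'
#' Samples `n_bound + n_unbound` non-overlapping loci (padded so that
#' footprint windows stay in bounds), draws a sequence from the PWM for
#' each, writes it into the genome on a random strand, and records the
#' truth labels.
#'
#' @param genome named character vector.
#' @param pwm a [pwm()].
#' @param n_bound,n_unbound numbers of truly bound / unbound sites.
#' @param seed RNG seed.
#' @param margin bp kept free at chromosome ends and between sites
#'   (default 100, comfortably above motif + flanks + k-mer context).
#' @return list with `genome` (modified) and `sites` (data frame: chrom,
#'   start, end, strand, bound).
#' @export
plant_sites <- function(genome, pwm, n_bound, n_unbound, seed = 1L,
                        margin = 100L) {
  .check_genome(genome)
  set.seed(seed)
  L <- ncol(pwm)
  n <- n_bound + n_unbound
  lens <- vapply(genome, nchar, integer(1))
  slot_w <- L + margin
  n_slots <- pmax((lens - 2L * margin) %/% slot_w, 0L)
  if (sum(n_slots) < n)
    stop("genome too small to place ", n, " non-overlapping sites")
  chrom_of <- rep(names(lens), n_slots)
  slot_of <- unlist(lapply(n_slots, seq_len), use.names = FALSE)
  pick <- sample.int(length(chrom_of), n)
  # jitter within the slot, bounded so that even adjacent sites keep
  # their padded footprint windows (site +/- 25 bp plus k-mer context)
  # disjoint
  jitter_max <- max(margin - 70L, 1L)
  starts <- margin + (slot_of[pick] - 1L) * slot_w +
    sample.int(jitter_max, n, replace = TRUE)
  chroms <- chrom_of[pick]
  strands <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- sample_pwm_sequences(pwm, n)
  minus <- strands == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  ins_chars <- strsplit(seqs, "", fixed = TRUE)
  for (chrom in unique(chroms)) {          # splice per chromosome in one pass
    chars <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
    for (i in which(chroms == chrom))
      chars[(starts[i] + 1L):(starts[i] + L)] <- ins_chars[[i]]
    genome[[chrom]] <- paste(chars, collapse = "")
  }
  bound <- c(rep(TRUE, n_bound), rep(FALSE, n_unbound))[sample.int(n)]
  sites <- data.frame(chrom = chroms, start = starts, end = starts + L,
                      strand = strands, bound = bound,
                      stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]
  rownames(sites) <- NULL
  list(genome = genome, sites = sites)
}

#' Parametric footprint shapes
#'
#' Protection profiles over the W = L + 2 pad window. The `"dnase"`
#' preset confines protection to the motif; the `"atac"` preset protects
#' the motif plus ~10 bp on each side and adds shoulder peaks at the
#' protection edges, the wider protection characteristic of the bulkier
#' transposase.
#'
#' @param L motif length.
#' @param pad flank width (default 25).
#' @param preset `"dnase"` or `"atac"`.
#' @param protection residual cut probability inside the protected
#'   region relative to open flanks (default 0.15).
#' @param shoulder multiplicative enrichment of the 3 bp flanking the
#'   protected region (default 2 for atac, 1 for dnase).
#' @return multinomial of length W.
#' @export
footprint_shape <- function(L, pad = 25L, preset = c("dnase", "atac"),
                            protection = 0.15, shoulder = NULL) {
  preset <- match.arg(preset)
  W <- L + 2L * pad
  extra <- if (preset == "atac") 10L else 0L
  if (is.null(shoulder)) shoulder <- if (preset == "atac") 2 else 1
  w <- rep(1, W)
  lo <- max(pad - extra + 1L, 1L)
  hi <- min(pad + L + extra, W)
  w[lo:hi] <- protection
  sh <- c(max(lo - 3L, 1L):(lo - 1L), (hi + 1L):min(hi + 3L, W))
  sh <- sh[sh >= 1L & sh <= W & (sh < lo | sh > hi)]
  w[sh] <- shoulder
  .normalize(w)
}

#' Simulate per-site cut counts from the two-component model
#'
#' Mirrors the two-component multinomial mixture: bound sites draw their
#' counts from the shared footprint multinomial, unbound sites from
#' their own sequence's bias-expected profile; partial/transient
#' occupancy is a convex mixture of the two. Replicates are independent
#' multinomial draws; an optional per-site log-normal factor shared
#' across replicates adds correlated depth noise.
#'
#' @param sites site data frame with a logical `bound` column.
#' @param genome genome the sites live on (for bias profiles).
#' @param shape footprint multinomial over W (see [footprint_shape()]).
#' @param table [kmer_bias_table()] driving unbound-site profiles.
#' @param depth mean reads per site.
#' @param replicate_depths vector of per-replicate mean depths (default
#'   one replicate at `depth`).
#' @param pad flank width.
#' @param overdispersion coefficient of variation of the log-normal
#'   per-site depth factor shared across replicates (0 = none). Site
#'   accessibility and occupancy in real data are heavy-tailed; a CV
#'   above 1 reproduces the orders-of-magnitude spread of per-site
#'   signal while keeping nearly every site visible.
#' @param spurious_frac fraction of unbound sites in variably-open
#'   chromatin that show a partial footprint-like profile whose
#'   strength fluctuates independently between replicates (cell-state
#'   variation, transient binding). These sites produce the
#'   positive-FLR-but-rank-discordant population that the IDR step
#'   exists to remove; a generator without them makes replicate
#'   selection vacuous. Default 0.15.
#' @param spurious_strength upper bound of the per-replicate uniform
#'   footprint mixing weight at a spurious site (default 0.65); transient protection is weaker than a stable footprint.
#' @param bound_strength_range range of the per-site fractional
#'   occupancy of bound sites (uniform draw, shared across replicates):
#'   a bound site's profile is `w * shape + (1 - w) * background`.
#'   Real sites differ stably in occupancy, which is what makes their
#'   replicate score rankings concordant. Default `c(1, 1)` (homogeneous).
#' @param seed RNG seed.
#' @return list of per-replicate site x W count matrices.
#' @export
simulate_site_counts <- function(sites, genome, shape, table, depth = 50,
                                 replicate_depths = depth, pad = 25L,
                                 overdispersion = 0, spurious_frac = 0.15,
                                 spurious_strength = 0.65,
                                 bound_strength_range = c(1, 1),
                                 seed = 1L) {
  set.seed(seed)
  n <- nrow(sites)
  W <- length(shape)
  bg <- build_backgrounds(sites, genome, mode = "bias", table = table,
                          pad = pad)
  size_factor <- if (overdispersion > 0) {
    s2 <- log(1 + overdispersion^2)        # mean-1 log-normal
    stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
  } else rep(1, n)
  spur <- !sites$bound & stats::runif(n) < spurious_frac  # site property
  occ <- stats::runif(n, bound_strength_range[1], bound_strength_range[2])
  site_profile <- function(i, w) {           # w = footprint mixing weight
    w * shape + (1 - w) * bg[i, ]
  }
  lapply(replicate_depths, function(d) {
    mat <- matrix(0L, n, W)
    w <- stats::runif(n, 0, spurious_strength)  # fluctuates per replicate
    for (i in seq_len(n)) {
      p <- if (sites$bound[i]) site_profile(i, occ[i])
      else if (spur[i]) site_profile(i, w[i])
      else bg[i, ]
      ni <- stats::rpois(1L, d * size_factor[i])
      if (ni > 0L) mat[i, ] <- stats::rmultinom(1L, ni, p)[, 1L]
    }
    mat
  })
}

#' Simulate genomic cut tracks for planted sites
#'
#' Writes per-site counts (drawn as in [simulate_site_counts()]) onto
#' genome coordinates, un-reversing minus-strand sites, and optionally
#' adds diffuse background cuts proportional to the bias table, giving
#' one [cut_track()] per replicate. All counts land on the plus strand;
#' the footprint model consumes strand-summed counts.
#'
#' @inheritParams simulate_site_counts
#' @param background_cuts diffuse bias-driven cuts to scatter over the
#'   genome per replicate (default 0).
#' @return list of `cut_track`s, one per replicate, with the per-site
#'   count matrices attached as attribute `site_counts`.
#' @export
simulate_cuts <- function(sites, genome, shape, table, depth = 50,
                          replicate_depths = depth, pad = 25L,
                          overdispersion = 0, background_cuts = 0,
                          seed = 1L) {
  mats <- simulate_site_counts(sites, genome, shape, table, depth,
                               replicate_depths, pad, overdispersion,
                               seed)
  lens <- vapply(genome, nchar, integer(1))
  out <- vector("list", length(mats))
  for (r in seq_along(mats)) {
    track <- if (background_cuts > 0)
      simulate_naked_cuts(genome, table, background_cuts,
                          seed = seed + 1000L * r)
    else cut_track(lens)
    for (i in seq_len(nrow(sites))) {
      v <- mats[[r]][i, ]
      if (sites$strand[i] == "-") v <- rev(v)
      at <- (sites$start[i] - pad + 1L):(sites$end[i] + pad)
      track$plus[[sites$chrom[i]]][at] <-
        track$plus[[sites$chrom[i]]][at] + v
    }
    attr(track, "site_counts") <- mats[[r]]
    out[[r]] <- track
  }
  out
}

#' Simulate counts from an explicit two-component mixture
#'
#' Low-level generator for EM recovery studies: each site is bound with
#' probability `pi` and draws a multinomial of size `depth` from the
#' footprint or from its own background row.
#'
#' @param n_sites number of sites.
#' @param depth reads per site.
#' @param footprint multinomial over W.
#' @param backgrounds n x W matrix (or single vector recycled).
#' @param pi footprint mixture weight.
#' @param seed RNG seed.
#' @return list with `counts` (n x W) and `bound` (latent labels).
#' @export
simulate_mixture_counts <- function(n_sites, depth, footprint,
                                    backgrounds, pi = 0.4, seed = 1L) {
  set.seed(seed)
  W <- length(footprint)
  if (!is.matrix(backgrounds))
    backgrounds <- matrix(backgrounds, n_sites, W, byrow = TRUE)
  bound <- stats::runif(n_sites) < pi
  counts <- matrix(0L, n_sites, W)
  for (i in seq_len(n_sites)) {
    p <- if (bound[i]) footprint else backgrounds[i, ]
    counts[i, ] <- stats::rmultinom(1L, depth, p)[, 1L]
  }
  list(counts = counts, bound = bound)
}
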