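## k-mer cleavage/transposition bias: estimation from deproteinized-DNA cut
## sites and derivation of per-site expected cut profiles.
##
## Cut/k-mer convention: a cut counted at base b is the event at the gap
## immediately 5' of b on the cut's strand. On the plus strand that gap has
## genomic coordinate b; on the minus strand it is b + 1. The k-mer
## associated with a cut at gap p on strand s is the genomic window
## [p - k/2, p + k/2) read on strand s (reverse complement for minus), so
## the event falls between the k/2-th and (k/2+1)-th nucleotide of the
## k-mer. This makes plus- and minus-strand k-mers of a blunt double-strand
## event reverse complements of each other, which is what allows one shared
## bias table for both strands.

#' k-mer bias table
#'
#' Relative cleavage/transposition propensity per k-mer: the ratio of a
#' k-mer's frequency among cut-centered k-mers to its frequency in the
#' (mappable) genome. 1 means no bias.
#'
#' @param propensity named numeric vector over all 4^k k-mers (names in
#'   any order covering `all_kmers(k)`), all values > 0.
#' @param k k-mer length (even).
#' @param protocol optional protocol tag, e.g. "DNase" or "ATAC".
#' @param source optional source-library annotation.
#' @return a `kmer_bias_table`.
#' @export
kmer_bias_table <- function(propensity, k = 6L, protocol = NA_character_,
                            source = NA_character_) {
  stopifnot(k %% 2 == 0)
  kmers <- all_kmers(k)
  if (!setequal(names(propensity), kmers))
    stop("propensity must be named by all ", 4^k, " k-mers")
  propensity <- propensity[kmers]
  if (any(!is.finite(propensity)) || any(propensity <= 0))
    stop("all propensities must be finite and > 0")
  structure(list(k = as.integer(k), propensity = propensity,
                 protocol = protocol, source = source),
            class = "kmer_bias_table")
}

#' @export
print.kmer_bias_table <- function(x, ...) {
  cat(sprintf("kmer_bias_table: k=%d, protocol=%s, range [%.3g, %.3g]\n",
              x$k, x$protocol, min(x$propensity), max(x$propensity)))
  invisible(x)
}

#' A bias table with every propensity equal to 1
#'
#' @param k k-mer length.
#' @return an unbiased `kmer_bias_table`.
#' @export
uniform_bias_table <- function(k = 6L) {
  kmer_bias_table(stats::setNames(rep(1, 4^k), all_kmers(k)), k = k)
}

# per-chromosome k-mer codes for each cut gap, on one strand.
# Returns list(idx = k-mer code (0-based) per retained cut base,
#              w = count weight), already reverse-complemented for minus.
.cut_kmer_codes <- function(counts, codes, k, strand, rc_map) {
  half <- k %/% 2L
  n <- length(codes)
  nz <- which(counts > 0L)
  if (!length(nz)) return(list(idx = integer(0), w = numeric(0)))
  b <- nz - 1L                               # 0-based base positions
  gap <- if (strand == "+") b else b + 1L
  start <- gap - half                        # 0-based k-mer start
  ok <- start >= 0L & start + k <= n
  b <- b[ok]; start <- start[ok]
  kidx <- .kmer_codes(codes, k)[start + 1L]
  if (strand == "-") kidx <- rc_map[kidx + 1L]
  keep <- !is.na(kidx)
  list(idx = kidx[keep], w = as.numeric(counts[b[keep] + 1L]))
}

# counts of all k-mers in the genome (both strands), optionally masked.
.genome_kmer_counts <- function(genome, k, mappable_mask = NULL) {
  rc_map <- .revcomp_code_map(k)
  acc <- numeric(4L^k)
  for (chrom in names(genome)) {
    codes <- .encode_dna(genome[[chrom]])
    kidx <- .kmer_codes(codes, k)
    if (!is.null(mappable_mask)) {
      keep <- rep(FALSE, length(kidx))
      sub <- mappable_mask[mappable_mask$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        lo <- max(sub$start[i], 0L)                  # k-mer fully inside
        hi <- min(sub$end[i], length(codes)) - k
        if (hi >= lo) keep[(lo + 1L):(hi + 1L)] <- TRUE
      }
      kidx <- kidx[keep]
    }
    kidx <- kidx[!is.na(kidx)]
    fwd <- tabulate(kidx + 1L, nbins = 4L^k)
    acc <- acc + fwd + fwd[rc_map + 1L]              # plus + minus strand
  }
  acc
}

.bias_from_counts <- function(cut_counts, genome_counts, k, pseudo = 1,
                              protocol = NA_character_,
                              source = NA_character_) {
  if (any(genome_counts == 0)) {
    warning("some k-mers are absent from the background genome; ",
            "adding a pseudo-frequency of 1 occurrence to every k-mer")
    genome_counts <- genome_counts + 1
  }
  cut_counts <- cut_counts + pseudo
  prop <- (cut_counts / sum(cut_counts)) /
    (genome_counts / sum(genome_counts))
  kmer_bias_table(stats::setNames(prop, all_kmers(k)), k = k,
                  protocol = protocol, source = source)
}

#' Estimate k-mer bias from deproteinized-DNA cut sites
#'
#' For every cut event the genomic k-mer centered on the cut gap is
#' retrieved (reverse-complemented for minus-strand cuts) and the relative
#' frequency of each k-mer among cut-centered k-mers is divided by its
#' relative frequency in the genome (both strands, optionally restricted
#' to a mappable mask). A pseudo-count of one cut per k-mer keeps all
#' propensities strictly positive.
#'
#' @param track [cut_track()] of cut sites from a deproteinized (naked)
#'   DNA library.
#' @param genome named character vector of chromosome sequences.
#' @param k k-mer length (even; default 6).
#' @param mappable_mask optional data frame (chrom, start, end; 0-based
#'   half-open) restricting the background k-mer counts.
#' @param strand estimate from `"both"` strands (default) or from one.
#' @param protocol,source provenance recorded in the table.
#' @return a [kmer_bias_table()].
#' @export
estimate_kmer_bias <- function(track, genome, k = 6L, mappable_mask = NULL,
                               strand = c("both", "plus", "minus"),
                               protocol = NA_character_,
                               source = NA_character_) {
  strand <- match.arg(strand)
  .check_genome(genome)
  stopifnot(k %% 2 == 0)
  if (!all(names(track$seqlengths) %in% names(genome)))
    stop("track and genome chromosome names do not match")
  rc_map <- .revcomp_code_map(k)
  cuts <- numeric(4L^k)
  for (chrom in names(track$seqlengths)) {
    codes <- .encode_dna(genome[[chrom]])
    for (s in c("+", "-")) {
      if (strand == "plus" && s == "-") next
      if (strand == "minus" && s == "+") next
      slot <- if (s == "+") "plus" else "minus"
      cc <- .cut_kmer_codes(track[[slot]][[chrom]], codes, k, s, rc_map)
      if (length(cc$idx)) {
        agg <- rowsum(cc$w, cc$idx)
        at <- as.integer(rownames(agg)) + 1L
        cuts[at] <- cuts[at] + agg[, 1L]
      }
    }
  }
  bg <- .genome_kmer_counts(genome, k, mappable_mask)
  .bias_from_counts(cuts, bg, k, protocol = protocol, source = source)
}

#' Compare bias tables estimated from each strand separately
#'
#' Estimates one k-mer bias table from plus-strand cuts only and one from
#' minus-strand cuts only (minus-strand k-mers reverse-complemented) and
#' reports the Pearson correlation of their log10 propensities. A high
#' correlation justifies applying one shared table to reads of both
#' strands.
#'
#' @inheritParams estimate_kmer_bias
#' @return list with `plus_table`, `minus_table` (both
#'   [kmer_bias_table()]) and `correlation`.
#' @export
strand_symmetry_report <- function(track, genome, k = 6L,
                                   mappable_mask = NULL) {
  n_plus <- sum(vapply(track$plus, sum, numeric(1)))
  n_minus <- sum(vapply(track$minus, sum, numeric(1)))
  if (n_plus == 0L) stop("no cuts on the plus strand")
  if (n_minus == 0L) stop("no cuts on the minus strand")
  pt <- estimate_kmer_bias(track, genome, k, mappable_mask, strand = "plus")
  mt <- estimate_kmer_bias(track, genome, k, mappable_mask, strand = "minus")
  list(plus_table = pt, minus_table = mt,
       correlation = stats::cor(log10(pt$propensity), log10(mt$propensity)))
}

#' Expected cut profile of a site from its sequence
#'
#' The per-position cut probability expected solely from sequence bias:
#' the weight at window position i is proportional to the propensity of
#' the k-mer centered on the gap 5' of base i, normalized to sum to 1.
#' The supplied sequence must carry k/2 extra context bases on each side
#' of the scored window (total length = window + k).
#'
#' @param site_sequence_with_flanks character string of length W + k,
#'   already oriented to the site strand.
#' @param table a [kmer_bias_table()].
#' @return numeric vector of W weights summing to 1. Positions whose
#'   k-mer contains an ambiguous base receive the table's geometric-mean
#'   propensity and the result carries attribute `flagged = TRUE`.
#' @export
expected_cut_profile <- function(site_sequence_with_flanks, table) {
  k <- table$k
  len <- nchar(site_sequence_with_flanks)
  W <- len - k
  if (W < 1) stop("sequence too short for window plus k/2 context per side")
  codes <- .encode_dna(site_sequence_with_flanks)
  kidx <- .kmer_codes(codes, k)[seq_len(W)]
  w <- table$propensity[kidx + 1L]
  flagged <- anyNA(w)
  if (flagged) w[is.na(w)] <- exp(mean(log(table$propensity)))
  out <- w / sum(w)
  names(out) <- NULL
  attr(out, "flagged") <- flagged
  out
}

#' Average bias propensity over a site
#'
#' Mean propensity of all k-mers fully contained in the site sequence
#' (without flanks). Used to ask whether a motif's sequence content alone
#' predisposes it to a footprint-like bias profile.
#'
#' @param site_sequence character string of length >= k.
#' @param table a [kmer_bias_table()].
#' @return positive scalar; 1 for an unbiased table.
#' @export
average_site_propensity <- function(site_sequence, table) {
  k <- table$k
  if (nchar(site_sequence) < k)
    stop("site sequence shorter than k = ", k)
  codes <- .encode_dna(site_sequence)
  kidx <- .kmer_codes(codes, k)
  kidx <- kidx[!is.na(kidx)]
  if (!length(kidx)) stop("no unambiguous k-mers in site")
  mean(table$propensity[kidx + 1L])
}

#' Write a k-mer bias table as TSV
#'
#' Two columns (kmer, propensity) preceded by `#k` and `#protocol`
#' metadata lines.
#'
#' @param table a [kmer_bias_table()].
#' @param path output file.
#' @export
write_bias_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#k\t", table$k),
               paste0("#protocol\t", table$protocol),
               "kmer\tpropensity"), con)
  utils::write.table(
    data.frame(kmer = names(table$propensity),
               propensity = table$propensity),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a k-mer bias table TSV
#'
#' @param path file written by [write_bias_table()].
#' @return a [kmer_bias_table()].
#' @export
read_bias_table <- function(path) {
  header <- readLines(path, n = 10L)
  meta <- header[startsWith(header, "#")]
  k <- 6L; protocol <- NA_character_
  for (m in meta) {
    kv <- strsplit(sub("^#", "", m), "\t")[[1]]
    if (kv[1] == "k") k <- as.integer(kv[2])
    if (kv[1] == "protocol") protocol <- kv[2]
  }
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           skip = length(meta) + 1L,
                           col.names = c("kmer", "propensity"))
  kmer_bias_table(stats::setNames(tab$propensity, tab$kmer), k = k,
                  protocol = protocol)
}

#' Pool bias tables from several libraries
#'
#' Depth-weighted geometric mean of per-library propensities, for use when
#' multiple deproteinized-DNA libraries are available.
#'
#' @param tables list of [kmer_bias_table()] with identical k.
#' @param weights optional library weights (e.g. read depths); equal by
#'   default.
#' @return a pooled [kmer_bias_table()].
#' @export
pool_bias_tables <- function(tables, weights = NULL) {
  stopifnot(length(tables) >= 1)
  k <- tables[[1]]$k
  if (!all(vapply(tables, function(t) t$k, integer(1)) == k))
    stop("all tables must share the same k")
  if (is.null(weights)) weights <- rep(1, length(tables))
  weights <- weights / sum(weights)
  logp <- Reduce(`+`, Map(function(t, w) w * log(t$propensity),
                          tables, as.list(weights)))
  kmer_bias_table(exp(logp), k = k, protocol = tables[[1]]$protocol,
                  source = "pooled")
}
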