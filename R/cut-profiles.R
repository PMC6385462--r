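## Turning aligned reads into filtered single-nucleotide cut-site tracks.
##
## Reads are plain data frames with columns chrom, start, end (0-based
## half-open), strand ("+"/"-"), and optionally is_proper_pair and
## fragment_length (paired-end data). The 5' end of a plus-strand read is
## its leftmost aligned base; of a minus-strand read its rightmost.

.check_reads <- function(reads) {
  need <- c("chrom", "start", "end", "strand")
  missing <- setdiff(need, names(reads))
  if (length(missing))
    stop("reads are missing column(s): ", paste(missing, collapse = ", "))
  if (any(reads$start >= reads$end))
    stop("malformed reads: start must be < end")
  if (!all(reads$strand %in% c("+", "-")))
    stop("read strand must be '+' or '-'")
  invisible(reads)
}

#' Extract single-nucleotide cut sites from aligned reads
#'
#' Each read contributes one count at its 5'-end base: the leftmost aligned
#' base for plus-strand reads, the rightmost for minus-strand reads. These
#' positions are the actual cleavage (DNase I) or transposition (Tn5)
#' sites. The conventional ATAC-seq +4/-5 shift, which instead centers
#' counts on the 9-bp Tn5 duplication, is available as `shift_mode =
#' "plus4_minus5"`; the default keeps the unshifted 5' ends so that a
#' single strand-symmetric k-mer bias table applies to both strands.
#'
#' @param reads data frame of aligned reads (see Details).
#' @param seqlengths named integer vector of chromosome lengths.
#' @param shift_mode `"none"` (default) or `"plus4_minus5"` (+4 on plus
#'   strand, -5 on minus strand).
#' @return a [cut_track()]; reads falling outside chromosome bounds after
#'   shifting are skipped and counted in `$n_skipped` (with a warning).
#' @export
extract_cut_sites <- function(reads, seqlengths,
                              shift_mode = c("none", "plus4_minus5")) {
  shift_mode <- match.arg(shift_mode)
  .check_reads(reads)
  track <- cut_track(seqlengths)
  pos <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  if (shift_mode == "plus4_minus5")
    pos <- pos + ifelse(reads$strand == "+", 4L, -5L)
  skipped <- 0L
  for (chrom in unique(reads$chrom)) {
    if (!chrom %in% names(seqlengths)) {
      skipped <- skipped + sum(reads$chrom == chrom)
      next
    }
    len <- seqlengths[[chrom]]
    for (s in c("+", "-")) {
      sel <- reads$chrom == chrom & reads$strand == s
      p <- pos[sel]
      ok <- p >= 0L & p < len
      skipped <- skipped + sum(!ok)
      slot <- if (s == "+") "plus" else "minus"
      track[[slot]][[chrom]] <- track[[slot]][[chrom]] +
        tabulate(p[ok] + 1L, nbins = len)
    }
  }
  if (skipped > 0L)
    warning(skipped, " read(s) outside genome bounds were skipped")
  track$n_skipped <- skipped
  track
}

#' Filter paired-end reads by fragment length
#'
#' Keeps only proper pairs whose fragment length lies in the expected
#' range (inclusive on both ends); the defaults retain fragments of
#' 38-1500 bp, the span from the shortest insert Tn5 can produce up to the
#' aligner's pairing limit.
#'
#' @param reads data frame of aligned reads with `is_proper_pair` and
#'   `fragment_length` columns.
#' @param min_len,max_len inclusive fragment-length bounds in bp.
#' @return the retained reads. Single-end input (no `fragment_length`
#'   column or all NA) is passed through unchanged with a warning.
#' @export
filter_fragments <- function(reads, min_len = 38L, max_len = 1500L) {
  .check_reads(reads)
  if (is.null(reads$fragment_length) || all(is.na(reads$fragment_length))) {
    warning("no fragment lengths present (single-end data?); ",
            "reads passed through unfiltered")
    return(reads)
  }
  proper <- if (is.null(reads$is_proper_pair)) TRUE else reads$is_proper_pair
  keep <- proper & !is.na(reads$fragment_length) &
    reads$fragment_length >= min_len & reads$fragment_length <= max_len
  reads[keep, , drop = FALSE]
}

#' Remove PCR pile-up artifacts from a cut track
#'
#' A base is zeroed when its strand-summed count reaches `pile_min` and
#' constitutes at least `frac` of all counts in the surrounding
#' `window`-bp window. The window is taken as [b - window/2, b + window/2)
#' around base b, clipped at chromosome ends, and both the pile and the
#' window total are computed on pooled (strand-summed) counts; a flagged
#' base has both strands zeroed.
#'
#' @param track a [cut_track()].
#' @param pile_min minimum count at a single base to be considered a pile.
#' @param window window size in bp for the local total.
#' @param frac minimum fraction of the window total concentrated at the
#'   base.
#' @return the filtered `cut_track`. The operation is idempotent.
#' @export
filter_pcr_artifacts <- function(track, pile_min = 10L, window = 30L,
                                 frac = 0.70) {
  half <- window %/% 2L
  for (chrom in names(track$seqlengths)) {
    pooled <- pooled_counts(track, chrom)
    n <- length(pooled)
    cand <- which(pooled >= pile_min)
    if (!length(cand)) next
    cs <- cumsum(c(0, pooled))
    lo <- pmax(cand - half, 1L)           # [b-half, b+half) clipped
    hi <- pmin(cand + half - 1L, n)
    win_total <- cs[hi + 1L] - cs[lo]
    bad <- cand[pooled[cand] / win_total >= frac]
    if (length(bad)) {
      track$plus[[chrom]][bad] <- 0L
      track$minus[[chrom]][bad] <- 0L
    }
  }
  track
}

#' Read aligned reads from a BAM file
#'
#' Thin wrapper over Rsamtools returning the read data frame consumed by
#' [extract_cut_sites()] and [filter_fragments()]. Secondary/supplementary
#' and unmapped records are excluded.
#'
#' @param path indexed BAM file.
#' @param exclude_chroms chromosomes to drop (default mitochondrial and Y,
#'   plus anything whose name contains an underscore, i.e. contigs).
#' @return data frame with chrom, start, end, strand, is_proper_pair,
#'   fragment_length.
#' @export
read_bam_reads <- function(path, exclude_chroms = c("chrM", "MT", "chrY")) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to read BAM files")
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  par <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "strand", "flag", "isize"),
    flag = flag)
  res <- Rsamtools::scanBam(path, param = par)[[1]]
  proper <- bitwAnd(res$flag, 2L) > 0L
  reads <- data.frame(
    chrom = as.character(res$rname),
    start = res$pos - 1L,                       # BAM is 1-based
    end = res$pos - 1L + res$qwidth,
    strand = as.character(res$strand),
    is_proper_pair = proper,
    fragment_length = ifelse(res$isize == 0L, NA_integer_, abs(res$isize)),
    stringsAsFactors = FALSE)
  drop <- reads$chrom %in% exclude_chroms | grepl("_", reads$chrom)
  reads[!drop, , drop = FALSE]
}
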