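## Low-level sequence helpers shared by the bias, scan and simulation code.
## Genomes are held as named character vectors (one string per chromosome);
## all genomic coordinates are 0-based half-open.

# base -> code lookup over raw byte values; A/C/G/T -> 0:3, anything else NA
.DNA_CODE <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A") + 1L] <- 0L
  v[utf8ToInt("C") + 1L] <- 1L
  v[utf8ToInt("G") + 1L] <- 2L
  v[utf8ToInt("T") + 1L] <- 3L
  v[utf8ToInt("a") + 1L] <- 0L
  v[utf8ToInt("c") + 1L] <- 1L
  v[utf8ToInt("g") + 1L] <- 2L
  v[utf8ToInt("t") + 1L] <- 3L
  v
})

#' Encode a DNA string as integer codes
#'
#' @param seq single character string (A/C/G/T, case-insensitive).
#' @return integer vector with A=0, C=1, G=2, T=3 and `NA` for any other
#'   character (e.g. N).
#' @keywords internal
#' @noRd
.encode_dna <- function(seq) {
  .DNA_CODE[utf8ToInt(seq) + 1L]
}

.decode_dna <- function(codes) {
  intToUtf8(utf8ToInt("ACGT")[codes + 1L])
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Rolling k-mer codes along an encoded sequence
#'
#' Code of the k-mer starting at each position (base-4, first base most
#' significant). Positions whose k-mer contains a non-ACGT base get NA.
#'
#' @param codes integer codes from `.encode_dna`.
#' @param k k-mer length.
#' @return integer vector of length `length(codes) - k + 1` (empty if the
#'   sequence is shorter than k).
#' @keywords internal
#' @noRd
.kmer_codes <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  out <- integer(m)
  for (t in seq_len(k)) {
    out <- out + codes[t:(t + m - 1L)] * 4L^(k - t)
  }
  out
}

# code of the reverse complement for every k-mer code 0:(4^k - 1)
.revcomp_code_map <- function(k) {
  codes <- 0:(4L^k - 1L)
  out <- integer(length(codes))
  rem <- codes
  for (t in seq_len(k)) {
    digit <- rem %% 4L          # digit t counted from the least-significant
    rem <- rem %/% 4L           # (i.e. 3'-most) base
    out <- out + (3L - digit) * 4L^(k - t)
  }
  out
}

#' All k-mer strings in canonical code order
#'
#' @param k k-mer length
#' @return character vector of length 4^k ordered by base-4 code.
#' @export
all_kmers <- function(k) {
  stopifnot(k >= 1, k <= 12)
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                      stringsAsFactors = FALSE)[, k:1, drop = FALSE]
  do.call(paste0, grid)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector, one uppercase string per sequence.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# fetch genome[chrom][start, end) (0-based half-open), 1 string
.fetch_seq <- function(genome, chrom, start, end) {
  substr(genome[[chrom]], start + 1L, end)
}

.check_genome <- function(genome) {
  if (!is.character(genome) || is.null(names(genome)) || any(names(genome) == ""))
    stop("genome must be a named character vector of chromosome sequences")
  invisible(genome)
}
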