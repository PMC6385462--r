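#' Per-base cut-site track
#'
#' A `cut_track` stores, per chromosome, two integer vectors of
#' single-nucleotide cut counts (plus and minus strand). A "cut" is the
#' cleavage/transposition event taken from a read 5' end; the count is
#' placed on the first aligned base, and the event itself is modelled as
#' the gap immediately 5' of that base on the read's strand.
#'
#' @param seqlengths named integer vector of chromosome lengths.
#' @return an empty `cut_track`.
#' @export
cut_track <- function(seqlengths) {
  stopifnot(is.numeric(seqlengths), !is.null(names(seqlengths)),
            all(seqlengths >= 1))
  seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
  zero <- lapply(seqlengths, function(n) integer(n))
  structure(
    list(plus = zero, minus = zero, seqlengths = seqlengths,
         n_skipped = 0L),
    class = "cut_track"
  )
}

#' @export
print.cut_track <- function(x, ...) {
  cat("cut_track:", length(x$seqlengths), "chromosome(s),",
      sum(x$seqlengths), "bp, total counts", total_counts(x), "\n")
  invisible(x)
}

#' Total number of cut events in a track
#'
#' @param track a `cut_track`.
#' @return integer total over both strands and all chromosomes.
#' @export
total_counts <- function(track) {
  sum(vapply(track$plus, sum, numeric(1))) +
    sum(vapply(track$minus, sum, numeric(1)))
}

#' Strand-summed counts for one chromosome
#'
#' @param track a `cut_track`.
#' @param chrom chromosome name.
#' @return integer vector of per-base counts (plus + minus).
#' @export
pooled_counts <- function(track, chrom) {
  track$plus[[chrom]] + track$minus[[chrom]]
}

#' Write a cut track as per-strand bedGraph files
#'
#' Emits one line per base with a nonzero count, 0-based half-open.
#'
#' @param track a `cut_track`.
#' @param prefix output path prefix; files `<prefix>_plus.bedGraph` and
#'   `<prefix>_minus.bedGraph` are written.
#' @return the two file paths, invisibly.
#' @export
write_cut_bedgraph <- function(track, prefix) {
  paths <- c(plus = paste0(prefix, "_plus.bedGraph"),
             minus = paste0(prefix, "_minus.bedGraph"))
  for (s in c("plus", "minus")) {
    rows <- list()
    for (chrom in names(track$seqlengths)) {
      v <- track[[s]][[chrom]]
      nz <- which(v > 0L)
      if (length(nz))
        rows[[chrom]] <- data.frame(chrom = chrom, start = nz - 1L,
                                    end = nz, count = v[nz])
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), start = integer(),
                 end = integer(), count = integer())
    utils::write.table(tab, paths[[s]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Read per-strand bedGraph files into a cut track
#'
#' @param plus_path,minus_path bedGraph files as written by
#'   [write_cut_bedgraph()].
#' @param seqlengths named integer vector of chromosome lengths.
#' @return a `cut_track`.
#' @export
read_cut_bedgraph <- function(plus_path, minus_path, seqlengths) {
  track <- cut_track(seqlengths)
  for (s in c("plus", "minus")) {
    path <- if (s == "plus") plus_path else minus_path
    tab <- tryCatch(
      utils::read.table(path, sep = "\t", col.names = c("chrom", "start",
                                                        "end", "count")),
      error = function(e) NULL)
    if (is.null(tab)) next
    for (chrom in unique(tab$chrom)) {
      sub <- tab[tab$chrom == chrom, ]
      track[[s]][[chrom]][sub$start + 1L] <- as.integer(sub$count)
    }
  }
  track
}
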