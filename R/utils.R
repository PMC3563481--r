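#' @import methods
#' @importFrom stats rnorm runif rbinom setNames cor
#' @importFrom utils head tail write.table read.table
NULL

# data.table is used via :: throughout
.datatable.aware <- TRUE

# All genomic intervals in this package are BED-style: 0-based start,
# exclusive end. Positions are 0-based unless a function says otherwise
# (VCF output is 1-based on write).

#' Construct a set of genomic intervals
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, 0-based exclusive; must satisfy `start < end`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @export
genomic_intervals <- function(chrom, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(chrom) == 1L && length(start) > 1L)
    chrom <- rep(chrom, length(start))
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start, end must have equal length")
  bad <- which(!(start >= 0L & start < end))
  if (length(bad))
    stop("invalid interval at row ", bad[1], ": [", start[bad[1]], ",",
         end[bad[1]], ")")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Read a BED file (first three columns)
#' @param path file path.
#' @return interval data.frame as from [genomic_intervals()].
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  genomic_intervals(x[[1]], x[[2]], x[[3]])
}

#' Write intervals as 3-column BED
#' @param intervals interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(intervals[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences as FASTA
#' @param genome named character vector.
#' @param path output path.
#' @param width line wrap width (default 60).
#' @export
write_genome_fasta <- function(genome, path, width = 60L) {
  x <- Biostrings::DNAStringSet(unname(genome))
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Reverse-complement nucleotide strings
#' @param x character vector over the ACGTN alphabet.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# vectorized membership test: is 0-based position inside any interval?
in_intervals <- function(chrom, pos, intervals) {
  out <- logical(length(pos))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (!any(sel)) next
    ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    q <- IRanges::IRanges(start = pos[sel] + 1L, width = 1L)
    out[sel] <- IRanges::overlapsAny(q, ir)
  }
  out
}

# total length of a set of non-overlapping intervals
intervals_length <- function(intervals) sum(intervals$end - intervals$start)

`%||%` <- function(a, b) if (is.null(a)) b else a
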