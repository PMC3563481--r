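# Minimal SAM text interchange: enough of the format to round-trip this
# package's alignment records and to plug external aligners in. Mapped
# records carry the NM tag (mismatch count); FLAG encodes pairing, strand,
# mate strand, first/second of pair and the duplicate mark; MAPQ is 0 for
# reads with more than one equal-best placement (the convention used to
# infer non-uniqueness from external SAM) and 60 otherwise. SEQ is stored
# in reference orientation, as the format requires.

flag_bits <- c(paired = 1L, proper = 2L, unmapped = 4L, mate_unmapped = 8L,
               reverse = 16L, mate_reverse = 32L, first = 64L,
               second = 128L, duplicate = 1024L)

#' Write alignment records as SAM
#'
#' @param records alignment record data.frame (as from [map_pairs()]).
#' @param reads data.frame with columns `read_id`, `mate`, `seq` giving
#'   each read in sequencing orientation.
#' @param ref_lengths named integer vector for the `@SQ` header lines.
#' @param path output path.
#' @param paired whether records are mate pairs (default TRUE).
#' @export
write_sam <- function(records, reads, ref_lengths, path, paired = TRUE) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(ref_lengths), "\tLN:",
                  as.integer(ref_lengths)))
  key <- paste(reads$read_id, reads$mate)
  seqs <- setNames(toupper(reads$seq), key)
  rec_seq <- seqs[paste(records$read_id, records$mate)]
  if (anyNA(rec_seq)) stop("read sequence missing for some records")
  flag <- integer(nrow(records))
  if (paired) {
    flag <- flag + flag_bits["paired"] +
      ifelse(records$mate == 1L, flag_bits["first"], flag_bits["second"]) +
      ifelse(records$proper_pair, flag_bits["proper"], 0L)
    mate_mapped <- !is.na(records$mate_ref)
    flag <- flag + ifelse(mate_mapped, 0L, flag_bits["mate_unmapped"])
    # mate strand: look up the other mate's record
    okey <- paste(records$read_id, 3L - records$mate)
    idx <- match(okey, paste(records$read_id, records$mate))
    mate_rev <- !is.na(idx) & !is.na(records$strand[idx]) &
      records$strand[idx] == "-"
    flag <- flag + ifelse(mate_rev, flag_bits["mate_reverse"], 0L)
  }
  flag <- flag + ifelse(records$mapped, 0L, flag_bits["unmapped"]) +
    ifelse(!is.na(records$strand) & records$strand == "-",
           flag_bits["reverse"], 0L) +
    ifelse(records$is_duplicate, flag_bits["duplicate"], 0L)
  seq_out <- ifelse(!is.na(records$strand) & records$strand == "-",
                    revcomp(rec_seq), rec_seq)
  mapq <- ifelse(!records$mapped, 0L,
                 ifelse(records$n_best_hits > 1L, 0L, 60L))
  lines <- paste(records$read_id, flag,
                 ifelse(records$mapped, records$ref, "*"),
                 ifelse(records$mapped, records$pos + 1L, 0L),
                 mapq,
                 ifelse(records$mapped, paste0(records$qwidth, "M"), "*"),
                 ifelse(is.na(records$mate_ref), "*",
                        ifelse(!is.na(records$ref) &
                                 records$mate_ref == records$ref, "=",
                               records$mate_ref)),
                 ifelse(is.na(records$mate_pos), 0L, records$mate_pos + 1L),
                 0L, seq_out, "*",
                 ifelse(records$mapped,
                        paste0("NM:i:", records$mismatches), ""),
                 sep = "\t")
  lines <- sub("\t$", "", lines)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a SAM file into alignment records
#'
#' Parses the subset of SAM this package writes (ungapped single-block
#' CIGARs). Mismatch counts are taken from the NM tag; records with
#' mapping quality 0 and no better information are treated as non-unique
#' (`n_best_hits = 2`).
#'
#' @param path SAM file path.
#' @return list with `records` (alignment record data.frame), `reads`
#'   (`read_id`, `mate`, `seq` in sequencing orientation) and
#'   `ref_lengths`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  ref_lengths <- setNames(
    as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq)),
    sub(".*\tSN:([^\t]+).*", "\\1", sq))
  if (!length(body))
    return(list(records = empty_records(),
                reads = data.frame(read_id = character(0), mate = integer(0),
                                   seq = character(0)),
                ref_lengths = ref_lengths))
  f <- strsplit(body, "\t", fixed = TRUE)
  getf <- function(i) vapply(f, `[`, "", i)
  flag <- as.integer(getf(2))
  has <- function(bit) bitwAnd(flag, flag_bits[[bit]]) != 0L
  mapped <- !has("unmapped")
  strand <- ifelse(mapped, ifelse(has("reverse"), "-", "+"), NA_character_)
  nm <- rep(NA_integer_, length(f))
  for (i in seq_along(f)) {
    tags <- f[[i]][-(1:11)]
    hit <- grep("^NM:i:", tags, value = TRUE)
    if (length(hit)) nm[i] <- as.integer(sub("^NM:i:", "", hit[1]))
  }
  mapq <- as.integer(getf(5))
  rname <- getf(3); pos1 <- as.integer(getf(4))
  mrname <- getf(7); mpos1 <- as.integer(getf(8))
  seq_ref <- getf(10)
  mate <- ifelse(has("second"), 2L, 1L)
  records <- data.frame(
    read_id = getf(1), mate = mate,
    ref = ifelse(mapped, rname, NA_character_),
    pos = ifelse(mapped, pos1 - 1L, NA_integer_),
    strand = strand, qwidth = nchar(seq_ref),
    mismatches = nm, mapped = mapped,
    n_best_hits = ifelse(!mapped, 0L, ifelse(mapq == 0L, 2L, 1L)),
    proper_pair = has("proper"),
    mate_ref = ifelse(mrname == "*", NA_character_,
                      ifelse(mrname == "=", rname, mrname)),
    mate_pos = ifelse(mpos1 == 0L, NA_integer_, mpos1 - 1L),
    is_duplicate = has("duplicate"), stringsAsFactors = FALSE)
  reads <- data.frame(
    read_id = records$read_id, mate = records$mate,
    seq = ifelse(!is.na(strand) & strand == "-", revcomp(seq_ref), seq_ref),
    stringsAsFactors = FALSE)
  list(records = records, reads = reads, ref_lengths = ref_lengths)
}

#' Write paired reads as two FASTQ files
#'
#' @param pairs data.frame with `read_id`, `seq1`, `seq2`.
#' @param path1,path2 output paths for mate 1 and mate 2.
#' @param quality_char flat Phred quality character (default `"I"`).
#' @export
write_fastq_pair <- function(pairs, path1, path2, quality_char = "I") {
  wr <- function(ids, seqs, path, mate) {
    writeLines(as.vector(rbind(paste0("@", ids, "/", mate), seqs,
                               "+", strrep(quality_char, nchar(seqs)))),
               path)
  }
  wr(pairs$read_id, pairs$seq1, path1, 1L)
  wr(pairs$read_id, pairs$seq2, path2, 2L)
  invisible(c(path1, path2))
}

#' Read paired FASTQ files written by [write_fastq_pair()]
#'
#' Accepts `/1` `/2` suffixes or bare identical ids in the two files.
#'
#' @param path1,path2 FASTQ paths for mate 1 and mate 2.
#' @return data.frame with `read_id`, `seq1`, `seq2`.
#' @export
read_fastq_pair <- function(path1, path2) {
  rd <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    ids <- sub("\\s.*$", "", names(x))
    ids <- sub("/[12]$", "", ids)
    setNames(as.character(x), ids)
  }
  s1 <- rd(path1); s2 <- rd(path2)
  if (!identical(names(s1), names(s2)))
    stop("mate files disagree on read identifiers")
  data.frame(read_id = names(s1), seq1 = unname(s1), seq2 = unname(s2),
             stringsAsFactors = FALSE)
}
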