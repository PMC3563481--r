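# Independent brute-force oracles and small fixture builders. These are
# deliberately naive (pure R, exhaustive) and share no code with the
# package's implementations.

rand_genome <- function(lengths) {
  vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    "")
}

# exhaustive all-offsets, both-strands alignment oracle; returns the
# equal-best placements (ref, pos, strand, mismatches) or NULL
oracle_map <- function(read, genome, max_mm) {
  out <- list()
  rc_read <- revcomp(read)
  for (nm in names(genome)) {
    sc <- strsplit(genome[[nm]], "")[[1]]
    for (strand in c("+", "-")) {
      pc <- strsplit(if (strand == "+") read else rc_read, "")[[1]]
      l <- length(pc)
      if (l > length(sc)) next
      for (s in 0:(length(sc) - l)) {
        w <- sc[(s + 1):(s + l)]
        mm <- sum(w != pc | w == "N" | pc == "N")
        if (mm <= max_mm)
          out[[length(out) + 1L]] <- data.frame(
            ref = nm, pos = s, strand = strand, mismatches = mm,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(NULL)
  o <- do.call(rbind, out)
  o <- o[o$mismatches == min(o$mismatches), , drop = FALSE]
  o <- o[order(match(o$ref, names(genome)), o$pos, o$strand), ,
         drop = FALSE]
  rownames(o) <- NULL
  o
}

# mask-painting oracle for pad-and-merge: paint padded bases onto a
# boolean per-chromosome mask and read off the runs
oracle_pad_merge <- function(targets, pad, chrom_lengths) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    mask <- logical(chrom_lengths[[ch]])
    iv <- targets[targets$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(iv))) {
      lo <- max(iv$start[j] - pad, 0L) + 1L
      hi <- min(iv$end[j] + pad, chrom_lengths[[ch]])
      mask[lo:hi] <- TRUE
    }
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep] - 1L,
                              end = ends[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# per-position recount oracle for pileups: re-derive base counts from
# scratch for one (ref, pos)
oracle_recount <- function(records, reads, ref, pos) {
  counts <- matrix(0L, 4, 2, dimnames = list(c("A", "C", "G", "T"),
                                             c("f", "r")))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (!r$mapped || r$is_duplicate || r$ref != ref) next
    if (pos < r$pos || pos >= r$pos + r$qwidth) next
    seq <- reads$seq[reads$read_id == r$read_id & reads$mate == r$mate]
    if (r$strand == "-") seq <- revcomp(seq)
    b <- substr(seq, pos - r$pos + 1L, pos - r$pos + 1L)
    if (b %in% rownames(counts))
      counts[b, if (r$strand == "+") "f" else "r"] <-
        counts[b, if (r$strand == "+") "f" else "r"] + 1L
  }
  counts
}

# a deterministic two-locus paralog toy: chr1 carries the target copy,
# chr2 a copy diverged at the given (1-based-within-span) positions
toy_paralog_genome <- function(span = 200L, divergence_at = c(50L, 120L),
                               seed = 9L) {
  set.seed(seed)
  left <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  core <- paste(sample(c("A", "C", "G", "T"), span, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  other <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  core2 <- strsplit(core, "")[[1]]
  for (p in divergence_at)
    core2[p] <- setdiff(c("A", "C", "G", "T"), core2[p])[1]
  chr1 <- paste0(left, core, right)
  chr2 <- paste0(other, paste(core2, collapse = ""), other)
  list(genome = c(chr1 = chr1, chr2 = chr2),
       core_start_chr1 = 400L, core_start_chr2 = 300L, span = span,
       divergence_chr1 = 400L + divergence_at - 1L,
       divergence_chr2 = 300L + divergence_at - 1L)
}

# reads table from a pairs data.frame (test-local convenience)
pairs_to_reads_test <- function(pairs) {
  data.frame(read_id = rep(pairs$read_id, 2L),
             mate = rep(c(1L, 2L), each = nrow(pairs)),
             seq = c(pairs$seq1, pairs$seq2), stringsAsFactors = FALSE)
}

# logical index of calls whose position lies inside any target interval
in_target_test <- function(calls, targets) {
  vapply(seq_len(nrow(calls)), function(i)
    any(targets$chrom == calls$ref[i] & targets$start <= calls$pos[i] &
          calls$pos[i] < targets$end), TRUE)
}

# 4x2 strand-aware count matrix shorthand for genotyping tests
counts_mat <- function(A_f = 0, A_r = 0, C_f = 0, C_r = 0, G_f = 0,
                       G_r = 0, T_f = 0, T_r = 0) {
  matrix(as.integer(c(A_f, C_f, G_f, T_f, A_r, C_r, G_r, T_r)), 4, 2,
         dimnames = list(c("A", "C", "G", "T"), c("f", "r")))
}
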