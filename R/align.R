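# Deterministic exhaustive k-mismatch read alignment.
#
# Every ungapped placement of a read (both strands, every reference
# sequence, fully inside the reference) is scored by its Hamming mismatch
# count; placements achieving the minimum count are returned when that
# minimum is within the mismatch budget. A read base aligned against a
# reference N counts as a mismatch (N never matches anything, including
# N), so placements spanning the N spacers of a TR reference are
# penalised out.
#
# Engine: exact-match seed lookup with max_mismatches + 1 disjoint seeds
# per read, which is exhaustive by pigeonhole (a placement with <= k
# mismatches must contain at least one mismatch-free seed), followed by
# vectorised Hamming verification of all candidate offsets. Reads too
# short to carry informative seeds fall back to a C-level exhaustive scan
# (Biostrings::matchPattern).

BASES <- c("A", "C", "G", "T")

empty_records <- function() {
  data.frame(read_id = character(0), mate = integer(0), ref = character(0),
             pos = integer(0), strand = character(0), qwidth = integer(0),
             mismatches = integer(0), mapped = logical(0),
             n_best_hits = integer(0), proper_pair = logical(0),
             mate_ref = character(0), mate_pos = integer(0),
             is_duplicate = logical(0), stringsAsFactors = FALSE)
}

# integer encoding A,C,G,T = 1..4, anything else (N) = 5; 5 never matches
encode_seq <- function(s) {
  x <- match(strsplit(s, "", fixed = TRUE)[[1]], BASES)
  x[is.na(x)] <- 5L
  x
}

#' Build a reusable alignment index for a reference
#'
#' @param reference named character vector of sequences or a
#'   `tr_reference` object.
#' @return an opaque index object accepted by the mapping functions;
#'   passing it instead of the raw reference avoids rebuilding the k-mer
#'   tables on every call.
#' @export
ref_index <- function(reference) {
  if (inherits(reference, "backmapr_ref_index")) return(reference)
  if (inherits(reference, "tr_reference"))
    reference <- setNames(reference$sequence, reference$name)
  stopifnot(is.character(reference), !is.null(names(reference)))
  seqs <- toupper(unname(reference))
  structure(list(names = names(reference),
                 seqs = seqs,
                 enc = lapply(seqs, encode_seq),
                 lengths = nchar(seqs),
                 subjects = lapply(seqs, Biostrings::DNAString),
                 kmer_cache = new.env(parent = emptyenv())),
            class = "backmapr_ref_index")
}

# keyed table of all reference k-mers of length w: (kmer, ref_i, pos0)
kmer_table <- function(ridx, w) {
  key <- as.character(w)
  if (!is.null(ridx$kmer_cache[[key]])) return(ridx$kmer_cache[[key]])
  acc <- list()
  for (i in seq_along(ridx$seqs)) {
    L <- ridx$lengths[i]
    if (L < w) next
    starts <- seq_len(L - w + 1L)
    km <- substring(ridx$seqs[i], starts, starts + w - 1L)
    keep <- !grepl("N", km, fixed = TRUE)
    acc[[i]] <- data.table::data.table(kmer = km[keep], ref_i = i,
                                       pos0 = starts[keep] - 1L)
  }
  tab <- data.table::rbindlist(acc)
  data.table::setkey(tab, kmer)
  ridx$kmer_cache[[key]] <- tab
  tab
}

# exhaustive placements of one oriented sequence on one subject via the
# C-level scan; returns data.table(pos0, mm) or NULL
scan_subject <- function(pattern, subject, max_mm) {
  hits <- Biostrings::matchPattern(pattern, subject, max.mismatch = max_mm,
                                   with.indels = FALSE, fixed = TRUE)
  if (length(hits) == 0L) return(NULL)
  st <- IRanges::start(hits)
  keep <- st >= 1L & IRanges::end(hits) <= length(subject)
  if (!any(keep)) return(NULL)
  st <- st[keep]
  mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pattern), subject,
                                    starting.at = st, with.indels = FALSE,
                                    fixed = TRUE)
  data.table::data.table(pos0 = st - 1L, mm = as.integer(mm))
}

# All placements with mm <= max_mm for a batch of oriented sequences of a
# common width. seqs: character vector; returns
# data.table(seq_i, ref_i, pos0, mm).
placements_fixed_width <- function(seqs, ridx, max_mm) {
  qw <- nchar(seqs[1])
  n_seeds <- max_mm + 1L
  seed_len <- qw %/% n_seeds
  if (seed_len < 4L) return(placements_scan(seqs, ridx, max_mm))
  tab <- kmer_table(ridx, seed_len)
  seed_off <- (seq_len(n_seeds) - 1L) * seed_len
  q <- data.table::data.table(
    seq_i = rep(seq_along(seqs), each = n_seeds),
    off = rep(seed_off, length(seqs)),
    kmer = as.vector(vapply(seqs, function(s)
      substring(s, seed_off + 1L, seed_off + seed_len), character(n_seeds))))
  cand <- tab[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(cand)) return(NULL)
  cand[, start0 := pos0 - off]
  cand <- unique(cand[, .(seq_i, ref_i, start0)])
  cand <- cand[start0 >= 0L & start0 + qw <= ridx$lengths[ref_i]]
  if (!nrow(cand)) return(NULL)
  # vectorised Hamming verification, one pass per read position
  mm <- integer(nrow(cand))
  enc_reads <- lapply(seqs, encode_seq)
  read_mat <- matrix(unlist(enc_reads), nrow = qw)  # qw x n_seqs
  ref_i <- cand$ref_i; start0 <- cand$start0; seq_i <- cand$seq_i
  by_ref <- split(seq_len(nrow(cand)), ref_i)
  for (ri in names(by_ref)) {
    idx <- by_ref[[ri]]
    enc <- ridx$enc[[as.integer(ri)]]
    s0 <- start0[idx]
    m <- integer(length(idx))
    for (j in seq_len(qw)) {
      rb <- read_mat[j, seq_i[idx]]
      fb <- enc[s0 + j]
      m <- m + as.integer(fb != rb | fb == 5L | rb == 5L)
    }
    mm[idx] <- m
  }
  cand[, mm := mm]
  cand <- cand[mm <= max_mm]
  if (!nrow(cand)) return(NULL)
  data.table::setnames(cand, "start0", "pos0")
  cand[, .(seq_i, ref_i, pos0, mm)]
}

# fallback for short reads: per-read C-level exhaustive scan
placements_scan <- function(seqs, ridx, max_mm) {
  acc <- list(); k <- 0L
  for (si in seq_along(seqs)) {
    for (i in seq_along(ridx$subjects)) {
      if (nchar(seqs[si]) > ridx$lengths[i]) next
      h <- scan_subject(seqs[si], ridx$subjects[[i]], max_mm)
      if (is.null(h)) next
      k <- k + 1L
      acc[[k]] <- data.table::data.table(seq_i = si, ref_i = i,
                                         pos0 = h$pos0, mm = h$mm)
    }
  }
  if (!k) return(NULL)
  data.table::rbindlist(acc)
}

# all placements (both strands) for a batch of reads; returns
# data.table(seq_i, ref, pos0, strand, mm) sorted deterministically
placements_batch <- function(seqs, ridx, max_mm) {
  if (any(!nzchar(seqs))) stop("empty read")
  seqs <- toupper(seqs)
  rc <- revcomp(seqs)
  n <- length(seqs)
  all_seqs <- c(seqs, rc)
  strand_of <- rep(c("+", "-"), each = n)
  acc <- list(); k <- 0L
  for (qw in unique(nchar(all_seqs))) {
    sel <- which(nchar(all_seqs) == qw)
    h <- placements_fixed_width(all_seqs[sel], ridx, max_mm)
    if (is.null(h)) next
    h[, seq_i := sel[seq_i]]
    k <- k + 1L
    acc[[k]] <- h
  }
  if (!k) return(NULL)
  h <- data.table::rbindlist(acc)
  h[, strand := strand_of[seq_i]]
  h[, seq_i := ((seq_i - 1L) %% n) + 1L]
  h[, ref := ridx$names[ref_i]]
  data.table::setorder(h, seq_i, ref_i, pos0, strand)
  h[, .(seq_i, ref, ref_i, pos0, strand, mm)]
}

# reduce a placement table to equal-best placements per read, adding n_best
best_per_read <- function(h) {
  if (is.null(h)) return(NULL)
  h[, best := min(mm), by = seq_i]
  h <- h[mm == best]
  h[, n_best := .N, by = seq_i]
  h[, best := NULL]
  h
}

#' Map a single read, returning all equal-best placements
#'
#' @param read nucleotide string (ACGTN alphabet).
#' @param reference named character vector of sequences, a
#'   `tr_reference`, or a [ref_index()].
#' @param max_mismatches mismatch budget (default 5).
#' @param read_id identifier stored on the records.
#' @return data.frame of alignment records, one row per equal-best
#'   placement (each with `n_best_hits` set to the number of such
#'   placements), or a single unmapped record if no placement is within
#'   budget.
#' @export
map_read <- function(read, reference, max_mismatches = 5L,
                     read_id = "read") {
  read <- unname(read)
  ridx <- ref_index(reference)
  h <- best_per_read(placements_batch(read, ridx, as.integer(max_mismatches)))
  if (is.null(h) || !nrow(h))
    return(data.frame(read_id = read_id, mate = 1L, ref = NA_character_,
                      pos = NA_integer_, strand = NA_character_,
                      qwidth = nchar(read), mismatches = NA_integer_,
                      mapped = FALSE, n_best_hits = 0L, proper_pair = FALSE,
                      mate_ref = NA_character_, mate_pos = NA_integer_,
                      is_duplicate = FALSE, stringsAsFactors = FALSE))
  data.frame(read_id = read_id, mate = 1L, ref = h$ref, pos = h$pos0,
             strand = h$strand, qwidth = nchar(read), mismatches = h$mm,
             mapped = TRUE, n_best_hits = h$n_best, proper_pair = FALSE,
             mate_ref = NA_character_, mate_pos = NA_integer_,
             is_duplicate = FALSE, stringsAsFactors = FALSE)
}

#' Map read pairs (FR orientation)
#'
#' Each mate is placed independently at its equal-best positions; a
#' properly paired combination (same reference, opposite strands, forward
#' mate leftmost, outer insert within `insert_range`) is preferred when
#' one exists, minimising the pair's total mismatch count with a
#' deterministic tie-break. `n_best_hits` on each record always counts the
#' mate's own equal-best placements: mate placement never affects a read's
#' uniqueness status.
#'
#' @param pairs data.frame with columns `read_id`, `seq1`, `seq2` (`seq2`
#'   in sequencing orientation, i.e. the reverse-complemented fragment
#'   end).
#' @param reference named character vector / `tr_reference` /
#'   [ref_index()].
#' @param max_mismatches mismatch budget per read (default 5).
#' @param insert_range numeric length-2 allowed outer insert size
#'   (default `c(100, 400)`).
#' @return data.frame of alignment records, two rows per pair (mates 1
#'   and 2), cross-linked through `mate_ref`/`mate_pos`.
#' @export
map_pairs <- function(pairs, reference, max_mismatches = 5L,
                      insert_range = c(100, 400)) {
  ridx <- ref_index(reference)
  n <- nrow(pairs)
  if (!n) return(empty_records())
  max_mismatches <- as.integer(max_mismatches)
  len1 <- nchar(pairs$seq1); len2 <- nchar(pairs$seq2)
  h <- placements_batch(c(pairs$seq1, pairs$seq2), ridx, max_mismatches)
  h <- best_per_read(h)
  hl <- if (is.null(h)) list() else split(h, by = "seq_i", keep.by = TRUE)
  hget <- function(i) hl[[as.character(i)]]
  # per-pair placement choice; records assembled in one pass afterwards
  sel1 <- vector("list", n); sel2 <- vector("list", n)
  proper <- logical(n)
  for (i in seq_len(n)) {
    h1 <- hget(i); h2 <- hget(n + i)
    if (!is.null(h1) && !is.null(h2)) {
      ii <- data.table::CJ(a = seq_len(nrow(h1)), b = seq_len(nrow(h2)),
                           sorted = FALSE)
      a <- h1[ii$a]; b <- h2[ii$b]
      fw_pos <- ifelse(a$strand == "+", a$pos0, b$pos0)
      rv_pos <- ifelse(a$strand == "+", b$pos0, a$pos0)
      rv_len <- ifelse(a$strand == "+", len2[i], len1[i])
      ins <- rv_pos + rv_len - fw_pos
      ok <- a$ref == b$ref & a$strand != b$strand & fw_pos <= rv_pos &
        ins >= insert_range[1] & ins <= insert_range[2]
      if (any(ok)) {
        tot <- a$mm + b$mm
        tot[!ok] <- NA_integer_
        pick <- which.min(tot)
        sel1[[i]] <- h1[ii$a[pick]]; sel2[[i]] <- h2[ii$b[pick]]
        proper[i] <- TRUE
        next
      }
    }
    if (!is.null(h1)) sel1[[i]] <- h1[1L]
    if (!is.null(h2)) sel2[[i]] <- h2[1L]
  }
  fld <- function(sel, what, miss) {
    vapply(sel, function(x) if (is.null(x)) miss else x[[what]][1], miss)
  }
  rec <- function(sel, mate, qw, other) {
    mapped <- !vapply(sel, is.null, TRUE)
    data.frame(read_id = pairs$read_id, mate = mate,
               ref = fld(sel, "ref", NA_character_),
               pos = fld(sel, "pos0", NA_integer_),
               strand = fld(sel, "strand", NA_character_),
               qwidth = qw,
               mismatches = fld(sel, "mm", NA_integer_),
               mapped = mapped,
               n_best_hits = ifelse(mapped, fld(sel, "n_best", NA_integer_), 0L),
               proper_pair = proper & mapped,
               mate_ref = fld(other, "ref", NA_character_),
               mate_pos = fld(other, "pos0", NA_integer_),
               is_duplicate = FALSE, stringsAsFactors = FALSE)
  }
  res <- rbind(rec(sel1, 1L, len1, sel2), rec(sel2, 2L, len2, sel1))
  res <- res[order(match(res$read_id, pairs$read_id), res$mate), ]
  rownames(res) <- NULL
  res
}

#' Flag duplicate alignment records
#'
#' Records sharing `(ref, strand, pos, mate_pos)` are duplicates; the one
#' with the fewest mismatches survives (ties broken by `read_id`, then
#' mate). Survivors keep `is_duplicate = FALSE`; the rest are flagged and
#' excluded by downstream pileup construction.
#'
#' @param records alignment record data.frame.
#' @return the same records with `is_duplicate` filled in.
#' @export
remove_duplicates <- function(records) {
  if (!nrow(records)) return(records)
  dup <- logical(nrow(records))
  m <- which(records$mapped)
  if (length(m)) {
    key <- paste(records$ref[m], records$strand[m], records$pos[m],
                 ifelse(is.na(records$mate_pos[m]), ".",
                        records$mate_pos[m]))
    o <- m[order(key, records$mismatches[m], records$read_id[m],
                 records$mate[m])]
    ko <- key[match(o, m)]
    dup[o] <- duplicated(ko)
  }
  records$is_duplicate <- dup
  records
}
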