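# Strand-aware pileups and count-based genotype calling.
#
# The caller is deliberately simple and count-based: a site is typed
# homozygous for the majority base when that base carries strictly more
# than `hom_fraction` of the reads (default 0.80), heterozygous for the
# top two bases otherwise, provided the minor allele has at least
# `min_minor_reads` supporting reads and (by default) support on both
# strands; anything else is a no-call with a reason code. Sites below
# `min_depth` (default 8, the conventional minimum SNP detection depth)
# are no-calls. Overlapping mates count as two independent observations.

#' Build per-position, per-strand pileups from alignment records
#'
#' Duplicate-flagged and unmapped records are excluded. Read bases are
#' oriented to the reference strand; `N` read bases are not counted.
#'
#' @param records alignment record data.frame.
#' @param reads data.frame `read_id`, `mate`, `seq` (sequencing
#'   orientation).
#' @param reference named character vector (or `tr_reference`) supplying
#'   reference bases.
#' @return object of class `backmapr_pileups`: list with `columns` (one
#'   row per covered reference position: `ref`, `pos`, `ref_base`,
#'   per-base forward/reverse counts `A_f`, `A_r`, ..., `depth`) and
#'   `long` (one row per aligned base: `ref`, `pos`, `base`, `strand`,
#'   `read_id`, `mate`), used for supporting-read lookup and re-typing.
#' @export
build_pileups <- function(records, reads, reference) {
  if (inherits(reference, "tr_reference"))
    reference <- setNames(reference$sequence, reference$name)
  use <- records$mapped & !records$is_duplicate
  rec <- records[use, , drop = FALSE]
  key <- paste(reads$read_id, reads$mate)
  seqmap <- setNames(toupper(reads$seq), key)
  rs <- seqmap[paste(rec$read_id, rec$mate)]
  if (anyNA(rs)) stop("read_id referenced by records but absent from reads")
  oriented <- ifelse(rec$strand == "-", revcomp(rs), rs)
  n <- nrow(rec)
  if (!n) {
    cols <- data.table::data.table(ref = character(0), pos = integer(0),
                                   ref_base = character(0))
    long <- data.table::data.table(ref = character(0), pos = integer(0),
                                   base = character(0), strand = character(0),
                                   read_id = character(0), mate = integer(0))
    return(structure(list(columns = cols, long = long),
                     class = "backmapr_pileups"))
  }
  qw <- rec$qwidth
  long <- data.table::data.table(
    ref = rep(rec$ref, qw),
    pos = unlist(lapply(seq_len(n), function(i) rec$pos[i] + 0:(qw[i] - 1L)),
                 use.names = FALSE),
    base = unlist(strsplit(oriented, "", fixed = TRUE), use.names = FALSE),
    strand = rep(rec$strand, qw),
    read_id = rep(rec$read_id, qw),
    mate = rep(rec$mate, qw))
  long <- long[base != "N"]
  counts <- long[, .N, by = .(ref, pos, base, strand)]
  counts[, col := paste0(base, "_", ifelse(strand == "+", "f", "r"))]
  wide <- data.table::dcast(counts, ref + pos ~ col, value.var = "N",
                            fill = 0L)
  for (cn in paste0(rep(BASES, each = 2), "_", c("f", "r")))
    if (!cn %in% names(wide)) wide[, (cn) := 0L]
  cnt_cols <- paste0(rep(BASES, each = 2), "_", c("f", "r"))
  data.table::setcolorder(wide, c("ref", "pos", cnt_cols))
  wide[, depth := rowSums(.SD), .SDcols = cnt_cols]
  wide[, ref_base := toupper(substr(reference[ref], pos + 1L, pos + 1L))]
  data.table::setcolorder(wide, c("ref", "pos", "ref_base"))
  data.table::setorder(wide, ref, pos)
  structure(list(columns = wide, long = long), class = "backmapr_pileups")
}

#' @export
print.backmapr_pileups <- function(x, ...) {
  cat("pileups over", nrow(x$columns), "covered positions on",
      length(unique(x$columns$ref)), "reference sequence(s)\n")
  invisible(x)
}

#' Extract one pileup column with supporting reads
#'
#' @param pileups a `backmapr_pileups` object.
#' @param ref,pos reference name and 0-based position.
#' @return list with `site`, `ref_base`, `counts` (4 x 2 matrix, bases x
#'   strands), `depth` and `supporting_reads` (list of read ids per
#'   observed base).
#' @export
pileup_column <- function(pileups, ref, pos) {
  col <- pileups$columns[pileups$columns$ref == ref &
                           pileups$columns$pos == pos, ]
  sub <- pileups$long[pileups$long$ref == ref & pileups$long$pos == pos, ]
  counts <- matrix(0L, 4, 2, dimnames = list(BASES, c("f", "r")))
  for (b in BASES) {
    counts[b, "f"] <- sub[base == b & strand == "+", .N]
    counts[b, "r"] <- sub[base == b & strand == "-", .N]
  }
  list(site = list(ref = ref, pos = pos),
       ref_base = if (nrow(col)) col$ref_base else NA_character_,
       counts = counts, depth = sum(counts),
       supporting_reads = split(sub$read_id, sub$base))
}

# vectorised genotype rule on a columns table; adds a1, a2, zygosity,
# reason, af_minor, both_strand_support
genotype_columns <- function(cols, min_depth = 8L, hom_fraction = 0.80,
                             min_minor_reads = 2L,
                             require_both_strands = TRUE) {
  n <- nrow(cols)
  fwd <- as.matrix(cols[, paste0(BASES, "_f"), with = FALSE])
  rev <- as.matrix(cols[, paste0(BASES, "_r"), with = FALSE])
  tot <- fwd + rev
  depth <- rowSums(tot)
  a1 <- a2 <- rep(NA_character_, n)
  zyg <- rep("no_call", n)
  reason <- rep(NA_character_, n)
  af2 <- rep(NA_real_, n)
  both <- rep(NA, n)
  for (i in seq_len(n)) {
    d <- depth[i]
    if (d < min_depth) { reason[i] <- "low_depth"; next }
    o <- order(-tot[i, ], BASES)  # count desc, lexicographic tie-break
    maj <- o[1]; sec <- o[2]; thd <- o[3]
    if (tot[i, maj] / d > hom_fraction) {
      a1[i] <- a2[i] <- BASES[maj]; zyg[i] <- "hom"
      af2[i] <- tot[i, sec] / d
      both[i] <- fwd[i, maj] > 0L && rev[i, maj] > 0L
      next
    }
    if (tot[i, thd] >= min_minor_reads) { reason[i] <- "ambiguous"; next }
    minor_ok <- tot[i, sec] >= min_minor_reads
    minor_both <- fwd[i, sec] > 0L && rev[i, sec] > 0L
    if (!minor_ok || (require_both_strands && !minor_both)) {
      reason[i] <- "ambiguous"; next
    }
    al <- sort(BASES[c(maj, sec)])
    a1[i] <- al[1]; a2[i] <- al[2]; zyg[i] <- "het"
    af2[i] <- tot[i, sec] / d
    both[i] <- minor_both
  }
  cbind(as.data.frame(cols[, .(ref, pos, ref_base)]),
        data.frame(depth = depth, a1 = a1, a2 = a2, zygosity = zyg,
                   reason = reason, af_minor = af2,
                   both_strand_support = both, stringsAsFactors = FALSE))
}

#' Call the genotype of one pileup column
#'
#' Implements the count-based rule: no-call below `min_depth`; homozygous
#' for the majority base when its fraction strictly exceeds
#' `hom_fraction`; otherwise heterozygous for the top two bases provided
#' the minor allele has at least `min_minor_reads` reads and, if
#' `require_both_strands`, at least one read on each strand; tri-allelic
#' columns (third base at or above `min_minor_reads`) and failed minor
#' alleles are no-calls with reason `"ambiguous"`. Ties are broken in
#' lexicographic base order.
#'
#' @param col a pileup column from [pileup_column()], or a 4 x 2 counts
#'   matrix (bases x strands f/r).
#' @param min_depth minimum depth to attempt a call (default 8).
#' @param hom_fraction homozygous majority fraction threshold, exceeded
#'   strictly (default 0.80).
#' @param min_minor_reads minimum minor-allele reads for a het call
#'   (default 2).
#' @param require_both_strands require minor-allele support on both
#'   strands (default TRUE).
#' @return list with `genotype` (two alleles or NULL), `zygosity`
#'   (`"hom"`, `"het"` or `"no_call"`), `reason`, `depth`.
#' @export
call_genotype <- function(col, min_depth = 8L, hom_fraction = 0.80,
                          min_minor_reads = 2L,
                          require_both_strands = TRUE) {
  counts <- if (is.matrix(col)) col else col$counts
  dt <- data.table::as.data.table(
    c(list(ref = "x", pos = 0L, ref_base = NA_character_),
      setNames(as.list(as.integer(counts[BASES, "f"])),
               paste0(BASES, "_f")),
      setNames(as.list(as.integer(counts[BASES, "r"])),
               paste0(BASES, "_r"))))
  g <- genotype_columns(dt, min_depth, hom_fraction, min_minor_reads,
                        require_both_strands)
  list(genotype = if (g$zygosity == "no_call") NULL else c(g$a1, g$a2),
       zygosity = g$zygosity, reason = g$reason, depth = g$depth)
}

#' Call variants from pileups
#'
#' Emits one record per site whose called genotype differs from
#' homozygous-reference. No-call columns are never emitted. Columns whose
#' reference base is N (spacers) are skipped.
#'
#' @param pileups `backmapr_pileups` object.
#' @param min_depth,hom_fraction,min_minor_reads,require_both_strands
#'   genotyping thresholds, see [call_genotype()].
#' @param stage provenance label stored on each call (default
#'   `"initial_TR"`).
#' @return data.frame of variant calls: `ref`, `pos` (0-based), `ref_base`,
#'   `a1`, `a2` (alleles, lexicographically sorted), `zygosity`, `depth`,
#'   `af_minor`, `both_strand_support`, `stage`, plus a list column
#'   `supporting` of read ids supporting each non-reference allele.
#' @export
call_variants <- function(pileups, min_depth = 8L, hom_fraction = 0.80,
                          min_minor_reads = 2L, require_both_strands = TRUE,
                          stage = "initial_TR") {
  cols <- pileups$columns[!is.na(ref_base) & ref_base %in% BASES]
  if (!nrow(cols)) return(empty_calls(stage))
  g <- genotype_columns(cols, min_depth, hom_fraction, min_minor_reads,
                        require_both_strands)
  is_var <- g$zygosity == "hom" & g$a1 != g$ref_base |
    g$zygosity == "het"
  g <- g[is_var & g$zygosity != "no_call", , drop = FALSE]
  if (!nrow(g)) return(empty_calls(stage))
  g$stage <- stage
  # supporting = reads carrying a non-reference allele at the site;
  # covering = every read observing the site (the re-typing substrate)
  sup <- cov <- vector("list", nrow(g))
  lk <- pileups$long
  for (i in seq_len(nrow(g))) {
    alts <- setdiff(unique(c(g$a1[i], g$a2[i])), g$ref_base[i])
    sub <- lk[ref == g$ref[i] & pos == g$pos[i]]
    sup[[i]] <- sort(unique(sub$read_id[sub$base %in% alts]))
    cov[[i]] <- sort(unique(sub$read_id))
  }
  g$supporting <- sup
  g$covering <- cov
  rownames(g) <- NULL
  g
}

empty_calls <- function(stage = "initial_TR") {
  out <- data.frame(ref = character(0), pos = integer(0),
                    ref_base = character(0), depth = integer(0),
                    a1 = character(0), a2 = character(0),
                    zygosity = character(0), reason = character(0),
                    af_minor = numeric(0), both_strand_support = logical(0),
                    stage = character(0), stringsAsFactors = FALSE)
  out$supporting <- list()
  out$covering <- list()
  out
}
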