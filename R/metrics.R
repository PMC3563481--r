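# Capture QC and validation metrics: coverage tracks, on-target
# statistics, enrichment factor, coverage ROC AUC, strand bias, replicate
# coverage correlation, genotype concordance and variant-set overlap.

#' Per-base coverage from alignment records
#'
#' @param records deduplicated alignment records (unmapped and
#'   duplicate-flagged rows are ignored).
#' @param genome_lengths named integer vector of reference lengths.
#' @return object of class `coverage_track`: list with `depth` (named
#'   list of per-chromosome integer vectors, index 1 = position 0),
#'   `total_mapped_bases` and `genome_size`.
#' @export
coverage_track <- function(records, genome_lengths) {
  use <- records$mapped & !records$is_duplicate
  rec <- records[use, , drop = FALSE]
  depth <- lapply(names(genome_lengths), function(ch) {
    L <- as.integer(genome_lengths[[ch]])
    d <- integer(L + 1L)
    sel <- rec$ref == ch
    if (any(sel)) {
      s <- pmax(rec$pos[sel], 0L) + 1L
      e <- pmin(rec$pos[sel] + rec$qwidth[sel], L) + 1L
      for (i in seq_along(s)) {
        d[s[i]] <- d[s[i]] + 1L
        d[e[i]] <- d[e[i]] - 1L
      }
    }
    cumsum(d)[seq_len(L)]
  })
  names(depth) <- names(genome_lengths)
  structure(list(depth = depth,
                 total_mapped_bases = sum(rec$qwidth),
                 genome_size = sum(as.numeric(genome_lengths))),
            class = "coverage_track")
}

# depths at target / non-target positions from a coverage_track
split_depths <- function(track, targets) {
  on <- integer(0); off_mask <- list()
  for (ch in names(track$depth)) {
    d <- track$depth[[ch]]
    mask <- logical(length(d))
    iv <- targets[targets$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(iv)))
      mask[(iv$start[j] + 1L):iv$end[j]] <- TRUE
    on <- c(on, d[mask])
    off_mask[[ch]] <- d[!mask]
  }
  list(on = on, off = unlist(off_mask, use.names = FALSE))
}

#' Exact coverage ROC AUC from on- and off-target depth multisets
#'
#' Rank-statistic formulation: the probability that a random on-target
#' base is deeper than a random off-target base, counting ties as one
#' half. Exact (Wilcoxon/Mann-Whitney), not a trapezoid approximation.
#'
#' @param depths_on,depths_off numeric vectors of per-base depths; both
#'   must be non-empty.
#' @return AUC in \[0, 1\].
#' @export
coverage_auc <- function(depths_on, depths_off) {
  n1 <- length(depths_on); n2 <- length(depths_off)
  if (!n1 || !n2) stop("both depth multisets must be non-empty")
  r <- rank(c(depths_on, depths_off))
  n1 <- as.numeric(n1); n2 <- as.numeric(n2)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Strand bias as percentage deviation from balance
#'
#' `|forward_fraction - 0.5| * 2 * 100`: 0% means perfectly balanced,
#' 100% means all reads on one strand.
#'
#' @param forward,reverse read or base counts per strand.
#' @return percentage in \[0, 100\]; `NA` at zero depth.
#' @export
strand_bias <- function(forward, reverse) {
  tot <- forward + reverse
  ifelse(tot > 0, abs(forward / tot - 0.5) * 2 * 100, NA_real_)
}

#' Summarise capture enrichment QC
#'
#' A read is on-target when its alignment span overlaps any target
#' interval by at least one base. The enrichment factor is the on-target
#' read fraction divided by the target's share of the genome (1 for
#' uniform unenriched coverage). Completeness is the fraction of target
#' bases covered at or above each depth threshold.
#'
#' @param records deduplicated alignment records.
#' @param targets non-overlapping target intervals (genome coordinates).
#' @param genome_lengths named integer vector of chromosome lengths.
#' @param depth_thresholds completeness thresholds (default
#'   `c(1, 2, 5, 8, 15, 20, 30)`).
#' @return object of class `enrichment_summary`: list with
#'   `pct_on_target_reads`, `adoc` (average depth over target bases),
#'   `completeness` (named vector), `ef`, `auc`, `strand_bias`
#'   (per-target percentages), `n_reads_mapped`, `target_length`,
#'   `genome_size`.
#' @export
summarize_enrichment <- function(records, targets, genome_lengths,
                                 depth_thresholds = c(1, 2, 5, 8, 15, 20,
                                                      30)) {
  if (is.null(targets) || !nrow(targets)) stop("empty target set")
  use <- records$mapped & !records$is_duplicate
  rec <- records[use, , drop = FALSE]
  on_read <- logical(nrow(rec))
  for (ch in unique(targets$chrom)) {
    iv <- targets[targets$chrom == ch, , drop = FALSE]
    sel <- rec$ref == ch
    if (!any(sel)) next
    ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    q <- IRanges::IRanges(start = rec$pos[sel] + 1L,
                          width = rec$qwidth[sel])
    on_read[sel] <- IRanges::overlapsAny(q, ir)
  }
  track <- coverage_track(rec, genome_lengths)
  sp <- split_depths(track, targets)
  tlen <- intervals_length(targets)
  gsize <- track$genome_size
  on_frac <- if (nrow(rec)) mean(on_read) else 0
  comp <- vapply(depth_thresholds, function(t) mean(sp$on >= t), 0)
  names(comp) <- paste0(depth_thresholds, "x")
  sb <- vapply(seq_len(nrow(targets)), function(j) {
    iv <- targets[j, ]
    sel <- rec$ref == iv$chrom & rec$pos < iv$end &
      rec$pos + rec$qwidth > iv$start
    strand_bias(sum(rec$strand[sel] == "+"), sum(rec$strand[sel] == "-"))
  }, 0)
  structure(list(pct_on_target_reads = 100 * on_frac,
                 adoc = mean(sp$on),
                 completeness = comp,
                 ef = on_frac / (tlen / gsize),
                 auc = coverage_auc(sp$on, sp$off),
                 strand_bias = sb,
                 n_reads_mapped = nrow(rec),
                 target_length = tlen,
                 genome_size = gsize),
            class = "enrichment_summary")
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat(sprintf(paste0("enrichment summary: %.1f%% reads on target, ",
                     "ADoC %.1fx, EF %.1f, AUC %.3f\n"),
              x$pct_on_target_reads, x$adoc, x$ef, x$auc))
  cat("completeness:",
      paste(names(x$completeness),
            sprintf("%.1f%%", 100 * x$completeness), collapse = ", "),
      "\n")
  invisible(x)
}

#' Pearson correlation matrix of replicate coverage tracks
#'
#' @param tracks list of `coverage_track` objects over the same genome.
#' @param targets optional intervals restricting the compared positions.
#' @return symmetric matrix of Pearson r (diagonal 1); pairs involving a
#'   zero-variance track are `NA`.
#' @export
coverage_correlation_matrix <- function(tracks, targets = NULL) {
  vecs <- lapply(tracks, function(tr) {
    if (is.null(targets)) {
      unlist(tr$depth, use.names = FALSE)
    } else {
      split_depths(tr, targets)$on
    }
  })
  len <- unique(lengths(vecs))
  if (length(len) != 1L) stop("tracks cover different position sets")
  n <- length(vecs)
  m <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (stats::sd(vecs[[i]]) == 0 || stats::sd(vecs[[j]]) == 0)
      m[i, j] <- NA_real_
    else m[i, j] <- stats::cor(vecs[[i]], vecs[[j]])
  }
  dimnames(m) <- list(names(tracks), names(tracks))
  m
}

call_key <- function(calls) paste(calls$ref, calls$pos)

#' Genotype concordance between two call sets
#'
#' Overlap is the set of sites called non-reference in both sets;
#' concordance is the fraction of overlapping sites with identical
#' unordered genotypes.
#'
#' @param calls_a,calls_b variant call data.frames in the same coordinate
#'   system.
#' @return list with `overlap_count`, `concordance_rate` (fraction in
#'   \[0, 1\]; `NA` when the overlap is empty) and `discordant`
#'   (data.frame of disagreeing sites, for replicate-validation
#'   filtering).
#' @export
genotype_concordance <- function(calls_a, calls_b) {
  ka <- call_key(calls_a); kb <- call_key(calls_b)
  shared <- intersect(ka, kb)
  ia <- match(shared, ka); ib <- match(shared, kb)
  gt_a <- paste(calls_a$a1[ia], calls_a$a2[ia])  # alleles stored sorted
  gt_b <- paste(calls_b$a1[ib], calls_b$a2[ib])
  conc <- gt_a == gt_b
  disc <- data.frame(ref = calls_a$ref[ia][!conc],
                     pos = calls_a$pos[ia][!conc],
                     genotype_a = gt_a[!conc], genotype_b = gt_b[!conc],
                     stringsAsFactors = FALSE)
  list(overlap_count = length(shared),
       concordance_rate = if (length(shared)) mean(conc) else NA_real_,
       discordant = disc)
}

#' Venn-style overlap of 2-3 variant sets
#'
#' Sets are compared by `(chrom, pos, alt)` keys. Reports every
#' membership region count, pairwise overlap fractions with both the
#' `min(|A|,|B|)` and the union denominator, and (when `known` is given)
#' a known/unknown split per region.
#'
#' @param sets named list of 2-3 variant call data.frames (or character
#'   vectors of precomputed keys).
#' @param known optional call data.frame or key vector of known sites.
#' @return list with `region_counts`, `pairwise` (data.frame), and
#'   optionally `known_split`.
#' @export
variant_set_overlap <- function(sets, known = NULL) {
  keyify <- function(x) {
    if (is.character(x)) return(unique(x))
    alt <- ifelse(x$a2 == x$ref_base, x$a1, x$a2)
    unique(paste(x$ref, x$pos, alt))
  }
  keys <- lapply(sets, keyify)
  n <- length(keys)
  if (n < 2L || n > 3L) stop("variant_set_overlap takes 2 or 3 sets")
  nm <- names(keys) %||% paste0("set", seq_len(n))
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  member <- matrix(member, ncol = n)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1, , drop = FALSE]
  region_counts <- apply(combos, 1, function(cm) {
    sum(apply(member, 1, function(row) all(row == cm)))
  })
  names(region_counts) <- apply(combos, 1, function(cm)
    paste(ifelse(unlist(cm), nm, paste0("not_", nm)), collapse = "&"))
  pw <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    inter <- length(intersect(keys[[i]], keys[[j]]))
    pw[[length(pw) + 1L]] <- data.frame(
      a = nm[i], b = nm[j], intersection = inter,
      frac_min = inter / min(length(keys[[i]]), length(keys[[j]])),
      frac_union = inter / length(union(keys[[i]], keys[[j]])),
      stringsAsFactors = FALSE)
  }
  out <- list(region_counts = region_counts, pairwise = do.call(rbind, pw),
              set_sizes = setNames(lengths(keys), nm))
  if (!is.null(known)) {
    kk <- keyify(known)
    out$known_split <- data.frame(
      set = nm,
      known = vapply(keys, function(k) sum(k %in% kk), 0L),
      unknown = vapply(keys, function(k) sum(!k %in% kk), 0L),
      stringsAsFactors = FALSE)
  }
  out
}

#' Write per-target coverage as bedGraph
#'
#' Adjacent equal-depth positions are run-length collapsed. With
#' `targets` supplied only in-target spans are written.
#'
#' @param track `coverage_track` object.
#' @param path output path.
#' @param targets optional intervals restricting the output.
#' @export
write_bedgraph <- function(track, path, targets = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph name=backmapr_coverage", con)
  for (ch in names(track$depth)) {
    d <- track$depth[[ch]]
    mask <- if (is.null(targets)) rep(TRUE, length(d)) else {
      m <- logical(length(d))
      iv <- targets[targets$chrom == ch, , drop = FALSE]
      for (j in seq_len(nrow(iv))) m[(iv$start[j] + 1L):iv$end[j]] <- TRUE
      m
    }
    d[!mask] <- NA_integer_
    r <- rle(d)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- !is.na(r$values) & r$values > 0L
    if (any(keep))
      writeLines(paste(ch, starts[keep], ends[keep], r$values[keep],
                       sep = "\t"), con)
  }
  invisible(path)
}
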