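# Read-backmapping: the cleanup step that makes target-region-only
# variant calling trustworthy. Candidate SNPs called against the TR
# reference may be artifacts of force-mapped reads (reads whose true
# locus is absent from the TR reference). Only the reads supporting the
# candidate SNPs (plus their mates) are remapped to the whole genome;
# reads that map better or equally well somewhere else are dropped, and
# each candidate is re-typed from the reads that remain uniquely mapped
# over its (lifted) genomic position.

#' Extract the reads covering candidate SNPs (and their mates)
#'
#' Every read observing a selected candidate site is extracted exactly
#' once, even when it covers several variants; mates come along whether
#' or not they were mapped. Extracting the full covering set (not just
#' the reads carrying the alternate allele) is what makes the later
#' re-typing unbiased. By default only heterozygous calls trigger
#' extraction (heterozygous candidates are the force-mapping artifact
#' mode); set `include_hom = TRUE` to extract for homozygous
#' non-reference calls too.
#'
#' @param variants variant call data.frame with `covering` (and
#'   `supporting`) list columns, as produced by [call_variants()].
#' @param pairs original read pairs (`read_id`, `seq1`, `seq2`).
#' @param include_hom also extract reads for homozygous calls (default
#'   FALSE).
#' @return list with `pairs` (extracted read pairs, ordered by read id)
#'   and `no_read_variants` (integer row indices of selected variants
#'   that had no recorded reads and cannot be re-typed; a warning is
#'   issued for these).
#' @export
extract_snp_supporting_reads <- function(variants, pairs,
                                         include_hom = FALSE) {
  sel <- if (include_hom) seq_len(nrow(variants))
         else which(variants$zygosity == "het")
  readsets <- variants$covering %||% variants$supporting
  empty <- sel[vapply(readsets[sel], length, 1L) == 0L]
  if (length(empty))
    warning(length(empty), " variant(s) have no recorded reads and ",
            "cannot be re-typed")
  ids <- sort(unique(unlist(readsets[sel], use.names = FALSE)))
  out <- pairs[pairs$read_id %in% ids, , drop = FALSE]
  out <- out[order(out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  list(pairs = out, no_read_variants = empty)
}

#' Map extracted reads back to the whole genome
#'
#' Standard paired mapping against the full genome followed by duplicate
#' removal, exactly as in the conventional whole-genome pipeline.
#'
#' @param extracted_pairs read pairs from
#'   [extract_snp_supporting_reads()].
#' @param whole_genome named character vector (or [ref_index()]) of the
#'   full genome.
#' @param max_mismatches,insert_range as in [map_pairs()].
#' @return deduplicated alignment records.
#' @export
backmap_reads <- function(extracted_pairs, whole_genome,
                          max_mismatches = 5L, insert_range = c(100, 400)) {
  recs <- map_pairs(extracted_pairs, whole_genome, max_mismatches,
                    insert_range)
  remove_duplicates(recs)
}

#' Per-variant surviving reads after the uniqueness-over-SNP filter
#'
#' A read survives for a variant if and only if its single best whole-
#' genome placement (`n_best_hits == 1`) covers the variant's genomic
#' position. A read with any equal-best placement elsewhere is removed
#' for all variants; a uniquely mapped read whose best placement shifted
#' away from the site no longer covers it and is likewise removed for
#' that variant.
#'
#' @param bm_records backmapped alignment records (deduplicated).
#' @param sites data.frame with `chrom` and `pos` (0-based genome
#'   coordinates), one row per variant.
#' @return list (length `nrow(sites)`) of character vectors of surviving
#'   read ids.
#' @export
unique_over_snp_filter <- function(bm_records, sites) {
  ok <- bm_records$mapped & !bm_records$is_duplicate &
    bm_records$n_best_hits == 1L
  rec <- bm_records[ok, , drop = FALSE]
  lapply(seq_len(nrow(sites)), function(i) {
    cov <- rec$ref == sites$chrom[i] & rec$pos <= sites$pos[i] &
      sites$pos[i] < rec$pos + rec$qwidth
    sort(unique(rec$read_id[cov]))
  })
}

#' Re-type candidate SNPs after backmapping
#'
#' Re-runs the genotype rule at each candidate's genomic position using
#' only the uniquely mapped surviving reads. Candidates that re-type
#' homozygous-reference, fall below the depth threshold
#' (`low_depth_after_backmap`) or become uncallable are eliminated;
#' candidates whose genotype is confirmed are retained; a changed
#' non-reference genotype is reported as `genotype_changed` and kept with
#' its new genotype.
#'
#' @param variants initial variant calls (TR coordinates).
#' @param sites lifted genome coordinates for `variants` (data.frame
#'   `chrom`, `pos`, aligned row-wise with `variants`).
#' @param surviving list of surviving read ids per variant, from
#'   [unique_over_snp_filter()].
#' @param bm_pileups `backmapr_pileups` built from the backmapped
#'   records against the whole genome.
#' @param no_read_variants row indices of variants extracted with no
#'   supporting reads (eliminated with reason `no_reads`).
#' @param min_depth,hom_fraction,min_minor_reads,require_both_strands
#'   genotyping thresholds; must equal the initial calling stage's.
#' @return list with `calls` (final variant calls, genome coordinates,
#'   `stage = "post_backmap"`) and `report` (a `backmap_report`: per-
#'   variant verdicts plus run totals).
#' @export
retype_after_backmap <- function(variants, sites, surviving, bm_pileups,
                                 no_read_variants = integer(0),
                                 min_depth = 8L, hom_fraction = 0.80,
                                 min_minor_reads = 2L,
                                 require_both_strands = TRUE) {
  n <- nrow(variants)
  verdict <- character(n)
  reason <- rep(NA_character_, n)
  final_a1 <- final_a2 <- rep(NA_character_, n)
  final_depth <- integer(n)
  n_support <- vapply(variants$supporting, length, 1L)
  n_lost <- integer(n)
  lk <- bm_pileups$long
  keep_rows <- list()
  for (i in seq_len(n)) {
    if (i %in% no_read_variants) {
      verdict[i] <- "eliminated"; reason[i] <- "no_reads"; next
    }
    ids <- surviving[[i]]
    lost <- setdiff(variants$supporting[[i]], ids)
    n_lost[i] <- length(lost)
    sub <- lk[ref == sites$chrom[i] & pos == sites$pos[i] & read_id %in% ids]
    counts <- matrix(0L, 4, 2, dimnames = list(BASES, c("f", "r")))
    if (nrow(sub)) {
      tab <- sub[, .N, by = .(base, strand)]
      for (j in seq_len(nrow(tab)))
        if (tab$base[j] %in% BASES)
          counts[tab$base[j], ifelse(tab$strand[j] == "+", "f", "r")] <-
            tab$N[j]
    }
    g <- call_genotype(counts, min_depth, hom_fraction, min_minor_reads,
                       require_both_strands)
    final_depth[i] <- g$depth
    if (g$zygosity == "no_call") {
      verdict[i] <- "eliminated"
      reason[i] <- if (identical(g$reason, "low_depth"))
        "low_depth_after_backmap" else g$reason
      next
    }
    ref_base <- variants$ref_base[i]
    if (g$zygosity == "hom" && g$genotype[1] == ref_base) {
      verdict[i] <- "eliminated"; reason[i] <- "hom_reference"; next
    }
    final_a1[i] <- g$genotype[1]; final_a2[i] <- g$genotype[2]
    same <- g$zygosity == variants$zygosity[i] &&
      identical(sort(c(g$genotype[1], g$genotype[2])),
                sort(c(variants$a1[i], variants$a2[i])))
    verdict[i] <- if (same) "retained" else "genotype_changed"
    keep_rows[[length(keep_rows) + 1L]] <- i
  }
  keep <- unlist(keep_rows) %||% integer(0)
  calls <- if (length(keep)) {
    data.frame(ref = sites$chrom[keep], pos = sites$pos[keep],
               ref_base = variants$ref_base[keep],
               depth = final_depth[keep],
               a1 = final_a1[keep], a2 = final_a2[keep],
               zygosity = ifelse(final_a1[keep] == final_a2[keep],
                                 "hom", "het"),
               reason = NA_character_, af_minor = NA_real_,
               both_strand_support = NA, stage = "post_backmap",
               stringsAsFactors = FALSE)
  } else empty_calls("post_backmap")[, setdiff(names(empty_calls()),
                                               "supporting")]
  per_variant <- data.frame(
    tr_ref = variants$ref, tr_pos = variants$pos,
    chrom = sites$chrom, pos = sites$pos,
    initial_zygosity = variants$zygosity,
    initial_a1 = variants$a1, initial_a2 = variants$a2,
    n_supporting_reads = n_support, n_reads_lost = n_lost,
    final_a1 = final_a1, final_a2 = final_a2,
    final_depth = final_depth, verdict = verdict, reason = reason,
    stringsAsFactors = FALSE)
  totals <- list(
    initial = n,
    retained = sum(verdict == "retained"),
    genotype_changed = sum(verdict == "genotype_changed"),
    eliminated = sum(verdict == "eliminated"),
    elimination_fraction = if (n) sum(verdict == "eliminated") / n else 0)
  report <- structure(list(per_variant = per_variant, totals = totals),
                      class = "backmap_report")
  list(calls = calls, report = report)
}

#' @export
print.backmap_report <- function(x, ...) {
  t <- x$totals
  cat("read-backmapping report: ", t$initial, " candidate variant(s); ",
      t$retained, " retained, ", t$genotype_changed, " genotype changed, ",
      t$eliminated, " eliminated (",
      sprintf("%.1f%%", 100 * t$elimination_fraction), ")\n", sep = "")
  invisible(x)
}

#' Write a backmap report as TSV + JSON
#' @param report `backmap_report` object.
#' @param tsv_path,json_path output paths.
#' @export
write_backmap_report <- function(report, tsv_path, json_path) {
  utils::write.table(report$per_variant, tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$totals, json_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(tsv_path)
}

#' Probe-uniqueness screen for one candidate SNP
#'
#' Maps the reference k-mer centred on the candidate (the SNP position
#' plus `flank` reference bases on each side, taken from the TR
#' reference) to the whole genome. A multi-locus placement flags the
#' candidate as suspect. This screen is weaker than read-backmapping (a
#' probe can be unique while individual reads are not) and never
#' eliminates a variant on its own.
#'
#' @param tr_pos candidate position in TR coordinates (0-based).
#' @param trref `tr_reference` object.
#' @param whole_genome genome or [ref_index()].
#' @param flank flanking reference bases on each side (default 25).
#' @param max_mismatches mapping budget for the probe (default 5).
#' @return list with `status` (`"unique"` or `"multi_locus"`),
#'   `n_best_hits`, `clipped` (TRUE when the probe was truncated at a
#'   block edge) and the probe records.
#' @export
probe_backmap <- function(tr_pos, trref, whole_genome, flank = 25L,
                          max_mismatches = 5L) {
  tab <- trref$table
  i <- findInterval(tr_pos, tab$tr_start)
  if (i == 0L || tr_pos >= tab$tr_end[i])
    stop("tr_pos is not inside a TR block")
  lo <- max(tr_pos - flank, tab$tr_start[i])
  hi <- min(tr_pos + flank, tab$tr_end[i] - 1L)
  clipped <- (lo > tr_pos - flank) || (hi < tr_pos + flank)
  probe <- substr(trref$sequence, lo + 1L, hi + 1L)
  rec <- map_read(probe, whole_genome, max_mismatches,
                  read_id = paste0("probe_", tr_pos))
  nb <- if (rec$mapped[1]) rec$n_best_hits[1] else 0L
  list(status = if (nb > 1L) "multi_locus" else "unique",
       n_best_hits = nb, clipped = clipped, records = rec)
}
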