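# End-to-end orchestration of the two analysis modes:
#  - tr_backmap: build the concatenated TR reference, map reads to it,
#    call variants, backmap the SNP-supporting reads to the whole genome,
#    re-type, and report (the fast two-step strategy);
#  - wg: conventional whole-genome mapping and calling, restricted to the
#    targets (the reference strategy the two-step mode is validated
#    against).

default_thresholds <- function() {
  list(pad = 50L, spacer_len = 50L, max_mismatches = 5L,
       insert_range = c(100, 400), min_depth = 8L, hom_fraction = 0.80,
       min_minor_reads = 2L, require_both_strands = TRUE)
}

check_inputs <- function(genome, targets, pairs) {
  if (!nrow(pairs)) stop("no input reads")
  if (is.null(targets) || !nrow(targets)) stop("no target intervals")
  stopifnot(is.character(genome), !is.null(names(genome)))
}

#' Run the two-step TR + read-backmapping pipeline
#'
#' Stages: pad-and-merge targets, build the TR reference, map pairs to
#' it, remove duplicates, call initial variants, extract the
#' SNP-supporting reads (plus mates), backmap them to the whole genome,
#' filter to uniquely mapped reads over each site, re-type, and lift all
#' surviving calls to genome coordinates. Thresholds in the re-typing
#' stage equal the initial stage's.
#'
#' @param genome named character vector of chromosome sequences.
#' @param targets capture target intervals (genome coordinates).
#' @param pairs read pairs (`read_id`, `seq1`, `seq2`).
#' @param pad target padding for the greater-TR construction (default
#'   50; use 49 for strict read-length-minus-one extension).
#' @param spacer_len N spacer length between TR blocks (default 50; a
#'   warning is issued if any read is longer).
#' @param max_mismatches,insert_range mapping parameters.
#' @param min_depth,hom_fraction,min_minor_reads,require_both_strands
#'   genotyping thresholds.
#' @param include_hom also backmap homozygous non-reference calls
#'   (default FALSE: heterozygous candidates are the force-mapping
#'   artifact mode; homozygous calls pass through unchanged).
#' @param filter_to_targets restrict final calls to the (unpadded)
#'   target intervals (default TRUE).
#' @param out_dir optional directory; when given, every intermediate
#'   artefact is written (TR FASTA + transform table, SAM files,
#'   extracted FASTQ, VCFs, QC report, stage log).
#' @return list of class `backmapr_run`: `final_calls` (genome
#'   coordinates, stage `post_backmap`), `initial_calls` (TR
#'   coordinates), `removed_calls`, `report` (`backmap_report`),
#'   `enrichment` (`enrichment_summary`), `tr_reference`, `counts`
#'   (per-stage read/variant accounting).
#' @export
run_tr_backmap <- function(genome, targets, pairs, pad = 50L,
                           spacer_len = 50L, max_mismatches = 5L,
                           insert_range = c(100, 400), min_depth = 8L,
                           hom_fraction = 0.80, min_minor_reads = 2L,
                           require_both_strands = TRUE,
                           include_hom = FALSE, filter_to_targets = TRUE,
                           out_dir = NULL) {
  check_inputs(genome, targets, pairs)
  read_len <- max(nchar(pairs$seq1), nchar(pairs$seq2))
  if (read_len > spacer_len)
    warning("read length ", read_len, " exceeds spacer length ",
            spacer_len, "; reads may align across block junctions")
  merged <- pad_and_merge(targets, pad, chrom_lengths = nchar(genome))
  trref <- build_tr_reference(genome, merged, spacer_len)
  tr_recs <- map_pairs(pairs, trref, max_mismatches, insert_range)
  tr_recs <- remove_duplicates(tr_recs)
  reads <- pairs_to_reads(pairs)
  pl <- build_pileups(tr_recs, reads, trref)
  initial <- call_variants(pl, min_depth, hom_fraction, min_minor_reads,
                           require_both_strands, stage = "initial_TR")
  ex <- extract_snp_supporting_reads(initial, pairs,
                                     include_hom = include_hom)
  sel <- if (include_hom) seq_len(nrow(initial))
         else which(initial$zygosity == "het")
  passthrough <- setdiff(seq_len(nrow(initial)), sel)
  gpos <- if (nrow(initial)) tr_to_genome(initial$pos, trref)
          else data.frame(chrom = character(0), pos = integer(0))
  wg_idx <- ref_index(genome)
  bm <- if (nrow(ex$pairs)) {
    backmap_reads(ex$pairs, wg_idx, max_mismatches, insert_range)
  } else empty_records()
  bm_pl <- build_pileups(bm, pairs_to_reads(ex$pairs), genome)
  sites_sel <- data.frame(chrom = gpos$chrom[sel], pos = gpos$pos[sel])
  surv <- unique_over_snp_filter(bm, sites_sel)
  rt <- retype_after_backmap(initial[sel, , drop = FALSE], sites_sel,
                             surv, bm_pl,
                             no_read_variants = match(
                               intersect(ex$no_read_variants, sel),
                               sel),
                             min_depth, hom_fraction, min_minor_reads,
                             require_both_strands)
  final <- rt$calls
  if (length(passthrough)) {
    pt <- initial[passthrough, , drop = FALSE]
    pt$ref <- gpos$chrom[passthrough]
    pt$pos <- gpos$pos[passthrough]
    pt$stage <- "post_backmap"
    pt$supporting <- NULL
    final <- rbind(final, pt[, names(final), drop = FALSE])
  }
  final <- final[order(match(final$ref, names(genome)), final$pos), ,
                 drop = FALSE]
  rownames(final) <- NULL
  if (filter_to_targets && nrow(final))
    final <- final[in_intervals(final$ref, final$pos, targets), ,
                   drop = FALSE]
  removed <- rt$report$per_variant
  removed <- removed[removed$verdict == "eliminated", , drop = FALSE]
  enr <- summarize_enrichment(lift_records(tr_recs, trref), targets,
                              nchar(genome))
  counts <- list(n_pairs_in = nrow(pairs),
                 n_reads_tr_mapped = sum(tr_recs$mapped),
                 n_reads_tr_after_dedup = sum(tr_recs$mapped &
                                                !tr_recs$is_duplicate),
                 n_initial_variants = nrow(initial),
                 n_extracted_pairs = nrow(ex$pairs),
                 n_final_variants = nrow(final))
  params <- list(mode = "tr_backmap", pad = pad, spacer_len = spacer_len,
                 max_mismatches = max_mismatches,
                 insert_range = insert_range, min_depth = min_depth,
                 hom_fraction = hom_fraction,
                 min_minor_reads = min_minor_reads,
                 require_both_strands = require_both_strands,
                 include_hom = include_hom,
                 filter_to_targets = filter_to_targets)
  out <- structure(list(final_calls = final, initial_calls = initial,
                        removed_calls = removed, report = rt$report,
                        enrichment = enr, tr_reference = trref,
                        counts = counts, params = params,
                        mode = "tr_backmap"),
                   class = "backmapr_run")
  if (!is.null(out_dir)) write_run(out, genome, pairs, tr_recs, bm,
                                   ex$pairs, out_dir)
  out
}

# lift TR-space alignment records to genome coordinates for QC purposes;
# records overhanging a spacer are clipped to their block
lift_records <- function(records, trref) {
  use <- which(records$mapped)
  if (!length(use)) return(records[0, , drop = FALSE])
  tab <- trref$table
  rec <- records[use, , drop = FALSE]
  i <- findInterval(rec$pos, tab$tr_start)
  ok <- i > 0L & rec$pos < tab$tr_end[i]
  rec <- rec[ok, , drop = FALSE]; i <- i[ok]
  width <- pmin(rec$pos + rec$qwidth, tab$tr_end[i]) - rec$pos
  rec$qwidth <- as.integer(width)
  rec$ref <- tab$chrom[i]
  rec$pos <- tab$genome_start[i] + (rec$pos - tab$tr_start[i])
  rec$mate_ref <- NA_character_; rec$mate_pos <- NA_integer_
  rec
}

pairs_to_reads <- function(pairs) {
  data.frame(read_id = rep(pairs$read_id, 2L),
             mate = rep(c(1L, 2L), each = nrow(pairs)),
             seq = c(pairs$seq1, pairs$seq2), stringsAsFactors = FALSE)
}

write_run <- function(run, genome, pairs, tr_recs, bm_recs, ex_pairs,
                      out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  if (!is.null(run$tr_reference)) {
    write_tr_reference(run$tr_reference, p("tr_reference.fa"),
                       p("transform_table.tsv"))
    write_sam(tr_recs, pairs_to_reads(pairs),
              setNames(nchar(run$tr_reference$sequence),
                       run$tr_reference$name), p("tr_alignments.sam"))
    if (nrow(ex_pairs))
      write_fastq_pair(ex_pairs, p("extracted_1.fastq"),
                       p("extracted_2.fastq"))
    if (nrow(bm_recs))
      write_sam(bm_recs, pairs_to_reads(ex_pairs), nchar(genome),
                p("backmapped.sam"))
    write_vcf(run$initial_calls, p("initial_tr.vcf"))
    rm <- run$removed_calls
    if (nrow(rm)) {
      rmc <- data.frame(ref = rm$chrom, pos = rm$pos,
                        ref_base = NA_character_, depth = rm$final_depth,
                        a1 = rm$initial_a1, a2 = rm$initial_a2,
                        zygosity = rm$initial_zygosity,
                        stage = "initial_TR", stringsAsFactors = FALSE)
      # recover ref_base from the initial calls via TR coordinates
      rmc$ref_base <- run$initial_calls$ref_base[
        match(paste(rm$tr_ref, rm$tr_pos),
              paste(run$initial_calls$ref, run$initial_calls$pos))]
      write_vcf(rmc, p("removed.vcf"), filter = "backmap_removed")
    }
    write_backmap_report(run$report, p("backmap_report.tsv"),
                         p("backmap_report.json"))
  }
  write_vcf(run$final_calls, p("final.vcf"), contigs = nchar(genome))
  jsonlite::write_json(run$counts, p("stage_counts.json"),
                       auto_unbox = TRUE)
  if (!is.null(run$params))
    jsonlite::write_json(run$params, p("resolved_params.json"),
                         auto_unbox = TRUE)
  invisible(out_dir)
}

#' Run the conventional whole-genome pipeline
#'
#' Maps all pairs to the whole genome, removes duplicates, calls
#' variants, and restricts the calls to the target intervals.
#'
#' @inheritParams run_tr_backmap
#' @return list of class `backmapr_run` with `final_calls` (genome
#'   coordinates, stage `wg`), `enrichment`, `counts`.
#' @export
run_wg <- function(genome, targets, pairs, max_mismatches = 5L,
                   insert_range = c(100, 400), min_depth = 8L,
                   hom_fraction = 0.80, min_minor_reads = 2L,
                   require_both_strands = TRUE, filter_to_targets = TRUE,
                   out_dir = NULL) {
  check_inputs(genome, targets, pairs)
  recs <- map_pairs(pairs, genome, max_mismatches, insert_range)
  recs <- remove_duplicates(recs)
  pl <- build_pileups(recs, pairs_to_reads(pairs), genome)
  calls <- call_variants(pl, min_depth, hom_fraction, min_minor_reads,
                         require_both_strands, stage = "wg")
  if (filter_to_targets && nrow(calls))
    calls <- calls[in_intervals(calls$ref, calls$pos, targets), ,
                   drop = FALSE]
  rownames(calls) <- NULL
  enr <- summarize_enrichment(recs, targets, nchar(genome))
  counts <- list(n_pairs_in = nrow(pairs),
                 n_reads_mapped = sum(recs$mapped),
                 n_reads_after_dedup = sum(recs$mapped &
                                             !recs$is_duplicate),
                 n_final_variants = nrow(calls))
  params <- list(mode = "wg", max_mismatches = max_mismatches,
                 insert_range = insert_range, min_depth = min_depth,
                 hom_fraction = hom_fraction,
                 min_minor_reads = min_minor_reads,
                 require_both_strands = require_both_strands,
                 filter_to_targets = filter_to_targets)
  out <- structure(list(final_calls = calls, initial_calls = NULL,
                        removed_calls = NULL, report = NULL,
                        enrichment = enr, tr_reference = NULL,
                        counts = counts, params = params, mode = "wg"),
                   class = "backmapr_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sam(recs, pairs_to_reads(pairs), nchar(genome),
              file.path(out_dir, "wg_alignments.sam"))
    write_vcf(calls, file.path(out_dir, "final.vcf"),
              contigs = nchar(genome))
    jsonlite::write_json(counts, file.path(out_dir, "stage_counts.json"),
                         auto_unbox = TRUE)
    jsonlite::write_json(params, file.path(out_dir,
                                           "resolved_params.json"),
                         auto_unbox = TRUE)
    write_bedgraph(coverage_track(recs, nchar(genome)),
                   file.path(out_dir, "coverage.bedGraph"),
                   targets = targets)
  }
  out
}

#' @export
print.backmapr_run <- function(x, ...) {
  cat("backmapr ", x$mode, " run: ", x$counts$n_pairs_in, " read pairs, ",
      nrow(x$final_calls), " final variant call(s)\n", sep = "")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Compare the two analysis modes
#'
#' Delegates to [variant_set_overlap()] and [genotype_concordance()];
#' reports mode-exclusive calls split by membership in an optional
#' known-sites list.
#'
#' @param calls_tr_backmap,calls_wg final call sets in genome
#'   coordinates.
#' @param known optional known-sites call data.frame or key vector.
#' @return list with `overlap` (from [variant_set_overlap()]) and
#'   `concordance` (from [genotype_concordance()]).
#' @export
compare_modes <- function(calls_tr_backmap, calls_wg, known = NULL) {
  list(overlap = variant_set_overlap(list(tr_backmap = calls_tr_backmap,
                                          wg = calls_wg), known = known),
       concordance = genotype_concordance(calls_tr_backmap, calls_wg))
}
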