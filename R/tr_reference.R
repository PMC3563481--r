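# Construction of the concatenated target-region (TR) reference and the
# exact coordinate liftover between TR and genome coordinates.
#
# The TR reference is a single sequence made of "greater target regions":
# each capture target padded on both sides (so reads partially overlapping
# a target still map), overlapping padded targets merged, and the merged
# blocks concatenated with a run of N bases between them. The spacer length
# should be at least the read length so that no read can align across a
# block junction without incurring more N-mismatches than any sensible
# mismatch budget allows.

#' Pad capture targets and merge overlapping or abutting results
#'
#' Each target is extended by `pad` bases on both sides (clipped at
#' chromosome bounds when `chrom_lengths` is supplied), then overlapping or
#' directly abutting intervals on the same chromosome are merged.
#'
#' @param targets interval data.frame (`chrom`, `start`, `end`; 0-based
#'   half-open).
#' @param pad non-negative integer number of bases added on each side.
#'   Use 49 to make reads of length 50 that overlap a target by a single
#'   base mappable; 50 is the conventional exome padding.
#' @param chrom_lengths optional named integer vector of chromosome
#'   lengths. When supplied, padded intervals are clipped to
#'   `[0, chrom_length]` and any input interval lying off its chromosome is
#'   rejected.
#' @return sorted, strictly non-overlapping interval data.frame.
#' @export
pad_and_merge <- function(targets, pad, chrom_lengths = NULL) {
  stopifnot(is.data.frame(targets), pad >= 0)
  targets <- genomic_intervals(targets$chrom, targets$start, targets$end)
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(targets$chrom, names(chrom_lengths))
    if (length(unknown))
      stop("target on unknown chromosome: ", unknown[1])
    lim <- chrom_lengths[targets$chrom]
    bad <- which(targets$end > lim)
    if (length(bad))
      stop("interval off chromosome at row ", bad[1], ": ",
           targets$chrom[bad[1]], ":", targets$start[bad[1]], "-",
           targets$end[bad[1]])
  }
  pad <- as.integer(pad)
  start <- pmax(targets$start - pad, 0L)
  end <- targets$end + pad
  if (!is.null(chrom_lengths))
    end <- pmin(end, as.integer(chrom_lengths[targets$chrom]))
  chrom_order <- if (!is.null(chrom_lengths)) names(chrom_lengths)
                 else sort(unique(targets$chrom))
  out <- list()
  for (ch in chrom_order) {
    sel <- targets$chrom == ch
    if (!any(sel)) next
    ir <- IRanges::reduce(IRanges::IRanges(start = start[sel] + 1L,
                                           end = end[sel]))
    out[[ch]] <- data.frame(chrom = ch,
                            start = IRanges::start(ir) - 1L,
                            end = IRanges::end(ir),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the concatenated TR reference with N spacers
#'
#' @param genome named character vector of chromosome sequences.
#' @param merged non-overlapping intervals, as produced by
#'   [pad_and_merge()].
#' @param spacer_len number of N bases between consecutive blocks
#'   (default 50). Should be at least the read length.
#' @param name sequence name of the single TR record (default `"TR"`).
#' @return an object of class `tr_reference`: a list with `sequence`
#'   (single concatenated string), `table` (the transform table: columns
#'   `tr_start`, `tr_end`, `chrom`, `genome_start`), `spacer_len`, `name`
#'   and `targets` (the merged input intervals).
#' @export
build_tr_reference <- function(genome, merged, spacer_len = 50L, name = "TR") {
  stopifnot(is.character(genome), !is.null(names(genome)))
  spacer_len <- as.integer(spacer_len)
  stopifnot(spacer_len >= 0L)
  merged <- genomic_intervals(merged$chrom, merged$start, merged$end)
  unknown <- setdiff(merged$chrom, names(genome))
  if (length(unknown)) stop("interval on unknown chromosome: ", unknown[1])
  lim <- nchar(genome)[merged$chrom]
  bad <- which(merged$end > lim)
  if (length(bad))
    stop("interval exceeds chromosome sequence: ", merged$chrom[bad[1]],
         ":", merged$start[bad[1]], "-", merged$end[bad[1]])
  # chromosome-major (genome order), coordinate-minor block order
  merged <- merged[order(match(merged$chrom, names(genome)), merged$start), ,
                   drop = FALSE]
  widths <- merged$end - merged$start
  n <- nrow(merged)
  tr_start <- cumsum(c(0L, head(widths, -1L) + spacer_len))
  blocks <- substr(genome[merged$chrom], merged$start + 1L, merged$end)
  sequence <- paste(blocks, collapse = strrep("N", spacer_len))
  table <- data.frame(tr_start = tr_start,
                      tr_end = tr_start + widths,
                      chrom = merged$chrom,
                      genome_start = merged$start,
                      stringsAsFactors = FALSE)
  structure(list(sequence = sequence, table = table,
                 spacer_len = spacer_len, name = name,
                 targets = merged),
            class = "tr_reference")
}

#' @export
print.tr_reference <- function(x, ...) {
  cat("TR reference '", x$name, "': ", nrow(x$table), " blocks, ",
      nchar(x$sequence), " bp total (", sum(x$table$tr_end - x$table$tr_start),
      " bp non-spacer), spacer ", x$spacer_len, " N\n", sep = "")
  invisible(x)
}

#' Lift TR coordinates to genome coordinates
#'
#' @param tr_pos integer vector of 0-based TR positions.
#' @param table transform table (from a `tr_reference` or
#'   [read_transform_table()]).
#' @return data.frame with columns `chrom` and `pos` (0-based).
#'   Positions falling inside a spacer raise an error of class
#'   `backmapr_spacer_error`: an alignment there should not exist.
#' @export
tr_to_genome <- function(tr_pos, table) {
  if (inherits(table, "tr_reference")) table <- table$table
  tr_pos <- as.integer(tr_pos)
  if (any(tr_pos < 0L)) stop("negative TR position")
  i <- findInterval(tr_pos, table$tr_start)
  if (any(i == 0L)) stop("TR position before first block")
  in_spacer <- tr_pos >= table$tr_end[i]
  if (any(in_spacer)) {
    p <- tr_pos[in_spacer][1]
    stop(structure(class = c("backmapr_spacer_error", "error", "condition"),
                   list(message = paste0("TR position ", p,
                                         " falls in a spacer (or beyond the ",
                                         "last block)"),
                        call = sys.call(-1))))
  }
  data.frame(chrom = table$chrom[i],
             pos = table$genome_start[i] + (tr_pos - table$tr_start[i]),
             stringsAsFactors = FALSE)
}

#' Lift genome coordinates to TR coordinates
#'
#' Exact inverse of [tr_to_genome()] on block interiors; genome positions
#' outside every block return `NA` (not in target), not an error.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based genome positions.
#' @param table transform table.
#' @return integer vector of TR positions, `NA` where not in target.
#' @export
genome_to_tr <- function(chrom, pos, table) {
  if (inherits(table, "tr_reference")) table <- table$table
  pos <- as.integer(pos)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  unknown <- setdiff(chrom, table$chrom)
  if (length(unknown)) stop("unknown chromosome: ", unknown[1])
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    blk <- table[table$chrom == ch, , drop = FALSE]
    blk <- blk[order(blk$genome_start), , drop = FALSE]
    sel <- which(chrom == ch)
    i <- findInterval(pos[sel], blk$genome_start)
    ok <- i > 0L
    width <- blk$tr_end - blk$tr_start
    ok[ok] <- pos[sel][ok] < blk$genome_start[i[ok]] + width[i[ok]]
    out[sel[ok]] <- blk$tr_start[i[ok]] +
      (pos[sel][ok] - blk$genome_start[i[ok]])
  }
  out
}

#' Write a TR reference to disk
#'
#' Writes the single-record FASTA, the tab-separated transform table
#' (`tr_start`, `tr_end`, `chrom`, `genome_start`) and a JSON sidecar with
#' the build parameters.
#'
#' @param trref `tr_reference` object.
#' @param fasta_path,table_path,json_path output paths; `json_path`
#'   defaults to `<table_path>.json`.
#' @export
write_tr_reference <- function(trref, fasta_path, table_path,
                               json_path = paste0(table_path, ".json")) {
  write_genome_fasta(setNames(trref$sequence, trref$name), fasta_path)
  utils::write.table(trref$table, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(name = trref$name, spacer_len = trref$spacer_len,
                            n_blocks = nrow(trref$table),
                            total_length = nchar(trref$sequence)),
                       json_path, auto_unbox = TRUE)
  invisible(fasta_path)
}

#' Read a transform table written by [write_tr_reference()]
#' @param path tab-separated table path.
#' @return transform table data.frame.
#' @export
read_transform_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
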