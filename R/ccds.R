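# Ingest of the CCDS (Consensus Coding Sequence) flat file into BED-style
# exon intervals. The CCDS release file is tab-separated with a header
# line starting "#chromosome" and carries, per CCDS record, the list of
# coding exon spans in an inclusive bracketed form, e.g.
# "[100-199, 300-349]". Coordinates in the file are 0-based inclusive;
# they are converted to half-open on ingest.

#' Convert a CCDS flat file to BED-style exon intervals
#'
#' Emits one interval per exon sub-interval of each retained CCDS record.
#' Duplicate `(chrom, start, end)` lines are retained (downstream merging
#' is the job of [pad_and_merge()]).
#'
#' @param path path to a CCDS flat file (tab-separated, header line
#'   beginning `#chromosome`). Alternatively pass the file content via
#'   `text`.
#' @param text character vector of file lines (overrides `path`).
#' @param status_filter retain only records whose `ccds_status` is one of
#'   these values (default `"Public"`, the conventional choice); `NULL`
#'   disables status filtering.
#' @return interval data.frame; attribute `n_skipped` counts records
#'   skipped because their `cds_locations` field could not be parsed (a
#'   warning summarises the count).
#' @export
ccds_to_bed <- function(path = NULL, text = NULL, status_filter = "Public") {
  lines <- if (!is.null(text)) text else readLines(path)
  if (!length(lines)) stop("empty CCDS input")
  header <- lines[1]
  if (!startsWith(header, "#chromosome"))
    stop("not a CCDS flat file: header must begin '#chromosome'")
  cols <- strsplit(sub("^#", "", header), "\t")[[1]]
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  get <- function(rec, name) {
    i <- match(name, cols)
    if (is.na(i) || i > length(rec)) NA_character_ else rec[i]
  }
  acc <- vector("list", length(fields)); k <- 0L
  n_skipped <- 0L
  for (rec in fields) {
    status <- get(rec, "ccds_status")
    if (!is.null(status_filter) && !(status %in% status_filter)) next
    loc <- get(rec, "cds_locations")
    chrom <- get(rec, "chromosome")
    if (is.na(loc) || is.na(chrom) || !grepl("^\\[.*\\]$", loc)) {
      n_skipped <- n_skipped + 1L
      next
    }
    spans <- strsplit(gsub("\\[|\\]|\\s", "", loc), ",", fixed = TRUE)[[1]]
    m <- regmatches(spans, regexec("^(\\d+)-(\\d+)$", spans))
    if (!length(spans) || any(lengths(m) != 3L)) {
      n_skipped <- n_skipped + 1L
      next
    }
    s <- as.integer(vapply(m, `[`, "", 2L))
    e <- as.integer(vapply(m, `[`, "", 3L)) + 1L  # inclusive -> half-open
    k <- k + 1L
    acc[[k]] <- data.frame(chrom = chrom, start = s, end = e,
                           stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L)
    warning("skipped ", n_skipped,
            " CCDS record(s) with unparseable cds_locations")
  acc <- acc[seq_len(k)]
  if (!k)
    return(structure(genomic_intervals(character(0), integer(0), integer(0)),
                     n_skipped = n_skipped))
  res <- do.call(rbind, acc)
  res <- genomic_intervals(res$chrom, res$start, res$end)
  attr(res, "n_skipped") <- n_skipped
  res
}
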