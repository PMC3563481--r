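# Minimal VCFv4.2 writer/reader for this package's variant calls.
# POS is 1-based on write (the calls themselves are 0-based internally).

#' Write variant calls as VCF
#'
#' @param calls variant call data.frame (from [call_variants()] or the
#'   backmapping stage); positions 0-based, written 1-based.
#' @param path output path.
#' @param contigs optional named integer vector of contig lengths for
#'   `##contig` header lines.
#' @param filter character vector (recycled) for the FILTER column;
#'   default `"PASS"`.
#' @param sample_name genotype column name (default `"SAMPLE"`).
#' @export
write_vcf <- function(calls, path, contigs = NULL, filter = "PASS",
                      sample_name = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=backmapr",
           if (!is.null(contigs))
             paste0("##contig=<ID=", names(contigs), ",length=",
                    as.integer(contigs), ">"),
           "##INFO=<ID=STAGE,Number=1,Type=String,Description=\"Calling stage\">",
           "##FILTER=<ID=backmap_removed,Description=\"Eliminated by read-backmapping\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_name, sep = "\t"))
  if (!nrow(calls)) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  alts <- mapply(function(a1, a2, ref) {
    paste(setdiff(unique(c(a1, a2)), ref), collapse = ",")
  }, calls$a1, calls$a2, calls$ref_base, USE.NAMES = FALSE)
  gt <- mapply(function(a1, a2, ref, alt) {
    alt_alleles <- strsplit(alt, ",", fixed = TRUE)[[1]]
    code <- function(a) if (a == ref) "0" else match(a, alt_alleles)
    paste(code(a1), code(a2), sep = "/")
  }, calls$a1, calls$a2, calls$ref_base, alts, USE.NAMES = FALSE)
  lines <- paste(calls$ref, calls$pos + 1L, ".", calls$ref_base, alts, ".",
                 rep_len(filter, nrow(calls)),
                 paste0("STAGE=", calls$stage),
                 "GT:DP", paste0(gt, ":", calls$depth), sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()]
#'
#' @param path VCF path.
#' @return variant call data.frame (0-based `pos`; alleles in `a1`/`a2`,
#'   lexicographically sorted; `filter` and `stage` columns preserved).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(empty_calls())
  f <- strsplit(body, "\t", fixed = TRUE)
  getf <- function(i) vapply(f, `[`, "", i)
  ref_base <- getf(4); alt <- getf(5)
  gt <- sub(":.*$", "", getf(10))
  dp <- suppressWarnings(as.integer(sub("^[^:]*:", "", getf(10))))
  stage <- sub("^.*STAGE=([^;]*).*$", "\\1", getf(8))
  al <- mapply(function(g, r, a) {
    alleles <- c(r, strsplit(a, ",", fixed = TRUE)[[1]])
    idx <- as.integer(strsplit(g, "[/|]")[[1]]) + 1L
    sort(alleles[idx])
  }, gt, ref_base, alt, SIMPLIFY = FALSE)
  out <- data.frame(ref = getf(1), pos = as.integer(getf(2)) - 1L,
                    ref_base = ref_base, depth = dp,
                    a1 = vapply(al, `[`, "", 1L),
                    a2 = vapply(al, `[`, "", 2L),
                    zygosity = ifelse(vapply(al, `[`, "", 1L) ==
                                        vapply(al, `[`, "", 2L),
                                      "hom", "het"),
                    reason = NA_character_, af_minor = NA_real_,
                    both_strand_support = NA, stage = stage,
                    filter = getf(7), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
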