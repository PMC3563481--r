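# Deterministic synthetic data: genomes with paralogous decoy loci,
# capture targets, planted variants, and paired-end reads with
# enrichment, per-base errors and optional exact-copy duplicates. Every
# artefact regenerates byte-identically from (seed, parameters), and a
# machine-readable truth table accompanies each stage.
#
# The paralog mechanism is the point: a duplicated segment with tunable
# divergence sits outside the capture targets but is co-captured (as a
# homologous fragment would hybridise to the same probes), so target-
# region-only mapping force-maps its reads onto the in-target copy and
# calls spurious heterozygous SNPs at the divergence positions --
# exactly the artifact class that read-backmapping removes.

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

mutate_bases <- function(chars, idx) {
  vapply(idx, function(i) sample(setdiff(BASES, chars[i]), 1L), "")
}

#' Generate a synthetic genome, optionally with a diverged paralog
#'
#' The paralog is created by copying a donor span to a destination locus
#' and mutating each copied base independently at the divergence rate.
#' Every divergence position (reference-vs-paralog difference; these are
#' not sample variants) is recorded.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param paralog optional list with `chrom`, `start`, `end` (donor span,
#'   0-based half-open), `dest_chrom`, `dest_start`, `divergence` (per-
#'   base mutation probability in \[0, 1\]).
#' @param seed RNG seed; the same (seed, parameters) regenerate the same
#'   genome byte-for-byte.
#' @return list with `genome` (named character vector), `paralog_map`
#'   (data.frame of donor/destination positions and bases at divergence
#'   sites; zero rows without divergence) and `paralog` (the resolved
#'   spec).
#' @export
generate_genome <- function(chrom_lengths, paralog = NULL, seed = 1L) {
  set.seed(seed)
  genome <- vapply(chrom_lengths, random_dna, "")
  names(genome) <- names(chrom_lengths)
  pm <- data.frame(donor_chrom = character(0), donor_pos = integer(0),
                   dest_chrom = character(0), dest_pos = integer(0),
                   donor_base = character(0), dest_base = character(0),
                   stringsAsFactors = FALSE)
  if (!is.null(paralog)) {
    stopifnot(paralog$divergence >= 0, paralog$divergence <= 1)
    span <- paralog$end - paralog$start
    if (paralog$end > chrom_lengths[[paralog$chrom]])
      stop("paralog donor span exceeds chromosome ", paralog$chrom)
    if (paralog$dest_start + span > chrom_lengths[[paralog$dest_chrom]])
      stop("paralog destination span exceeds chromosome ",
           paralog$dest_chrom)
    donor <- substr(genome[[paralog$chrom]], paralog$start + 1L,
                    paralog$end)
    chars <- strsplit(donor, "", fixed = TRUE)[[1]]
    div <- which(runif(span) < paralog$divergence)
    new_chars <- chars
    if (length(div)) new_chars[div] <- mutate_bases(chars, div)
    dest <- genome[[paralog$dest_chrom]]
    substr(dest, paralog$dest_start + 1L,
           paralog$dest_start + span) <- paste(new_chars, collapse = "")
    genome[[paralog$dest_chrom]] <- dest
    if (length(div))
      pm <- data.frame(donor_chrom = paralog$chrom,
                       donor_pos = paralog$start + div - 1L,
                       dest_chrom = paralog$dest_chrom,
                       dest_pos = paralog$dest_start + div - 1L,
                       donor_base = chars[div], dest_base = new_chars[div],
                       stringsAsFactors = FALSE)
  }
  list(genome = genome, paralog_map = pm, paralog = paralog)
}

#' Plant heterozygous and homozygous SNPs into sample haplotypes
#'
#' Sites are drawn uniformly from the target intervals, avoiding `avoid`
#' positions (typically paralog divergence sites) and each other, at
#' least `margin` bases from interval edges. Two haplotype sequences per
#' chromosome realise the genotypes.
#'
#' @param genome named character vector.
#' @param targets interval data.frame.
#' @param n_het,n_hom numbers of heterozygous / homozygous-alt SNPs.
#' @param seed RNG seed.
#' @param avoid optional data.frame `chrom`, `pos` of forbidden sites.
#' @param margin minimum distance from interval edges (default 0).
#' @return list with `haplotypes` (list `A`, `B` of named character
#'   vectors) and `truth` (data.frame `chrom`, `pos`, `ref`, `alt`,
#'   `zygosity`, `gt`, `hap`).
#' @export
plant_variants <- function(genome, targets, n_het, n_hom, seed = 1L,
                           avoid = NULL, margin = 0L) {
  set.seed(seed)
  cand <- do.call(rbind, lapply(seq_len(nrow(targets)), function(j) {
    lo <- targets$start[j] + margin
    hi <- targets$end[j] - margin - 1L
    if (hi < lo) return(NULL)
    data.frame(chrom = targets$chrom[j], pos = lo:hi,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(avoid) && nrow(avoid)) {
    bad <- paste(cand$chrom, cand$pos) %in% paste(avoid$chrom, avoid$pos)
    cand <- cand[!bad, , drop = FALSE]
  }
  n <- n_het + n_hom
  if (nrow(cand) < n)
    stop("insufficient eligible target positions for ", n, " variants")
  pick <- cand[sample(nrow(cand), n), , drop = FALSE]
  pick <- pick[order(match(pick$chrom, names(genome)), pick$pos), ,
               drop = FALSE]
  zyg <- rep(c("het", "hom"), c(n_het, n_hom))
  zyg <- sample(zyg)  # interleave het/hom over positions
  ref <- substr(genome[pick$chrom], pick$pos + 1L, pick$pos + 1L)
  alt <- mutate_bases(ref, seq_len(n))
  hap <- ifelse(zyg == "hom", "AB", sample(c("A", "B"), n, replace = TRUE))
  hapA <- genome; hapB <- genome
  for (i in seq_len(n)) {
    ch <- pick$chrom[i]; p <- pick$pos[i]
    if (grepl("A", hap[i]))
      substr(hapA[[ch]], p + 1L, p + 1L) <- alt[i]
    if (grepl("B", hap[i]))
      substr(hapB[[ch]], p + 1L, p + 1L) <- alt[i]
  }
  gt <- ifelse(zyg == "hom", paste(alt, alt),
               paste(pmin(ref, alt), pmax(ref, alt)))
  truth <- data.frame(chrom = pick$chrom, pos = pick$pos, ref = ref,
                      alt = alt, zygosity = zyg, gt = gt, hap = hap,
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(haplotypes = list(A = hapA, B = hapB), truth = truth)
}

apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0)
    return(list(seqs = seqs, n_err = integer(length(seqs))))
  n_err <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    idx <- which(runif(length(chars)) < error_rate)
    if (length(idx)) {
      chars[idx] <- mutate_bases(chars, idx)
      seqs[i] <- paste(chars, collapse = "")
      n_err[i] <- length(idx)
    }
  }
  list(seqs = seqs, n_err = n_err)
}

#' Simulate enriched paired-end reads from sample haplotypes
#'
#' Fragments are drawn uniformly over each capture interval (any start
#' whose fragment overlaps the interval) at `mean_depth_on`, and
#' genome-wide at `mean_depth_off`, each from a uniformly chosen
#' haplotype and a uniformly chosen strand; per-base substitution errors
#' are applied at `error_rate`. The capture set may include loci outside
#' the analysis targets (e.g. a paralog span) to emulate
#' cross-hybridisation of homologous fragments.
#'
#' @param haplotypes list `A`, `B` of named character vectors.
#' @param capture intervals attracting enriched coverage.
#' @param mean_depth_on,mean_depth_off mean per-base depth inside capture
#'   intervals / genome-wide background.
#' @param read_len read length (default 50).
#' @param insert_mean,insert_sd outer insert size distribution (default
#'   200 +/- 20, truncated at `read_len`).
#' @param error_rate per-base substitution error probability (default
#'   0.01).
#' @param seed RNG seed.
#' @param duplicate_rate fraction of fragments duplicated as exact
#'   copies (default 0), for duplicate-removal tests.
#' @return list with `pairs` (`read_id`, `seq1`, `seq2`), `truth`
#'   (per-read origin: chromosome, fragment span, haplotype, strand flip,
#'   error counts, `origin` on/off, `dup_of`) and `params`.
#' @export
simulate_reads <- function(haplotypes, capture, mean_depth_on,
                           mean_depth_off = 0, read_len = 50L,
                           insert_mean = 200L, insert_sd = 20L,
                           error_rate = 0.01, seed = 1L,
                           duplicate_rate = 0) {
  set.seed(seed)
  stopifnot(read_len <= insert_mean)
  glen <- nchar(haplotypes$A)
  frag <- list(chrom = character(0), start = integer(0), origin = character(0))
  add <- function(ch, s, origin) {
    frag$chrom <<- c(frag$chrom, ch)
    frag$start <<- c(frag$start, s)
    frag$origin <<- c(frag$origin, origin)
  }
  for (j in seq_len(nrow(capture))) {
    L <- capture$end[j] - capture$start[j]
    span <- L + insert_mean - 1L
    n_frag <- round(mean_depth_on * span / (2 * read_len))
    if (n_frag <= 0) next
    s <- capture$start[j] - insert_mean + 1L +
      sample.int(span, n_frag, replace = TRUE) - 1L
    add(rep(capture$chrom[j], n_frag), s, rep("on", n_frag))
  }
  if (mean_depth_off > 0) {
    for (ch in names(glen)) {
      n_off <- round(mean_depth_off * glen[[ch]] / (2 * read_len))
      if (n_off <= 0) next
      s <- sample.int(glen[[ch]], n_off, replace = TRUE) - 1L
      add(rep(ch, n_off), s, rep("off", n_off))
    }
  }
  n <- length(frag$start)
  if (!n)
    return(list(pairs = data.frame(read_id = character(0),
                                   seq1 = character(0),
                                   seq2 = character(0)),
                truth = NULL, params = NULL))
  ins <- pmax(as.integer(round(rnorm(n, insert_mean, insert_sd))),
              read_len)
  start <- pmin(pmax(frag$start, 0L), glen[frag$chrom] - ins)
  start <- pmax(start, 0L)
  ins <- pmin(ins, glen[frag$chrom] - start)
  hap <- sample(c("A", "B"), n, replace = TRUE)
  flip <- sample(c(FALSE, TRUE), n, replace = TRUE)
  hseq <- ifelse(hap == "A", haplotypes$A[frag$chrom],
                 haplotypes$B[frag$chrom])
  left <- substr(hseq, start + 1L, start + read_len)
  right <- revcomp(substr(hseq, start + ins - read_len + 1L, start + ins))
  seq1 <- ifelse(flip, right, left)
  seq2 <- ifelse(flip, left, right)
  e1 <- apply_errors(seq1, error_rate)
  e2 <- apply_errors(seq2, error_rate)
  read_id <- sprintf("frag%06d", seq_len(n))
  truth <- data.frame(read_id = read_id, chrom = frag$chrom,
                      frag_start = start, frag_end = start + ins,
                      hap = hap, flipped = flip,
                      n_err1 = e1$n_err, n_err2 = e2$n_err,
                      origin = frag$origin, dup_of = NA_character_,
                      stringsAsFactors = FALSE)
  pairs <- data.frame(read_id = read_id, seq1 = e1$seqs, seq2 = e2$seqs,
                      stringsAsFactors = FALSE)
  if (duplicate_rate > 0) {
    n_dup <- round(n * duplicate_rate)
    if (n_dup > 0) {
      src <- sample.int(n, n_dup, replace = FALSE)
      dup_ids <- sprintf("frag%06d", n + seq_len(n_dup))
      pairs <- rbind(pairs,
                     data.frame(read_id = dup_ids,
                                seq1 = pairs$seq1[src],
                                seq2 = pairs$seq2[src],
                                stringsAsFactors = FALSE))
      dt <- truth[src, ]
      dt$read_id <- dup_ids
      dt$dup_of <- read_id[src]
      truth <- rbind(truth, dt)
    }
  }
  rownames(pairs) <- rownames(truth) <- NULL
  list(pairs = pairs, truth = truth,
       params = list(mean_depth_on = mean_depth_on,
                     mean_depth_off = mean_depth_off,
                     read_len = read_len, insert_mean = insert_mean,
                     insert_sd = insert_sd, error_rate = error_rate,
                     seed = seed, duplicate_rate = duplicate_rate))
}

scenario_seeds <- c(CLEAN = 101L, PARALOG95 = 202L, IDENTICAL_DUP = 303L,
                    LOWDEPTH = 404L)

#' Materialise a canonical test scenario
#'
#' Scenarios (each with a fixed documented seed, overridable):
#' * `CLEAN` - two 30 kb chromosomes, 8 kb of targets, no paralogy,
#'   15 het + 10 hom SNPs, 30x on-target, 1% error.
#' * `PARALOG95` - 200 kb over two chromosomes; a 5 kb in-target span on
#'   chr1 duplicated at 95% identity to an off-target chr2 locus that is
#'   co-captured; 20 het + 10 hom SNPs, 30x, 1% error. Target-region-only
#'   calling produces false-positive heterozygous calls at divergence
#'   sites.
#' * `IDENTICAL_DUP` - as PARALOG95 but zero divergence: every read from
#'   the duplicated span has two equal-best whole-genome placements.
#' * `LOWDEPTH` - CLEAN-like at the 8x calling boundary.
#'
#' @param name scenario name.
#' @param seed optional seed override (default: the scenario's fixed
#'   seed).
#' @return list bundle: `name`, `seed`, `genome`, `genome_lengths`,
#'   `targets`, `capture`, `paralog_map`, `truth_variants`,
#'   `haplotypes`, `reads` (pairs + per-read truth), `params`.
#' @export
synth_scenario <- function(name = c("CLEAN", "PARALOG95", "IDENTICAL_DUP",
                                    "LOWDEPTH"),
                           seed = NULL) {
  name <- match.arg(name)
  seed <- as.integer(seed %||% scenario_seeds[[name]])
  cfg <- switch(
    name,
    CLEAN = list(chrom_lengths = c(chr1 = 30000L, chr2 = 30000L),
                 targets = genomic_intervals(
                   c("chr1", "chr1", "chr2", "chr2"),
                   c(4000L, 15000L, 6000L, 20000L),
                   c(6000L, 17000L, 8000L, 22000L)),
                 paralog = NULL, n_het = 15L, n_hom = 10L,
                 depth_on = 30, depth_off = 0.3),
    PARALOG95 = list(chrom_lengths = c(chr1 = 120000L, chr2 = 80000L),
                     targets = genomic_intervals(
                       c("chr1", "chr1", "chr1"),
                       c(10000L, 29000L, 60000L),
                       c(14000L, 36000L, 64000L)),
                     paralog = list(chrom = "chr1", start = 30000L,
                                    end = 35000L, dest_chrom = "chr2",
                                    dest_start = 40000L,
                                    divergence = 0.05),
                     n_het = 20L, n_hom = 10L,
                     depth_on = 30, depth_off = 0.3),
    IDENTICAL_DUP = list(chrom_lengths = c(chr1 = 60000L, chr2 = 40000L),
                         targets = genomic_intervals(
                           "chr1", 19000L, 26000L),
                         paralog = list(chrom = "chr1", start = 20000L,
                                        end = 25000L, dest_chrom = "chr2",
                                        dest_start = 10000L,
                                        divergence = 0),
                         n_het = 8L, n_hom = 4L,
                         depth_on = 30, depth_off = 0.3),
    LOWDEPTH = list(chrom_lengths = c(chr1 = 20000L),
                    targets = genomic_intervals(
                      c("chr1", "chr1"), c(4000L, 12000L),
                      c(6000L, 14000L)),
                    paralog = NULL, n_het = 10L, n_hom = 5L,
                    depth_on = 8, depth_off = 0.1))
  g <- generate_genome(cfg$chrom_lengths, cfg$paralog, seed = seed)
  avoid <- if (nrow(g$paralog_map))
    data.frame(chrom = g$paralog_map$donor_chrom,
               pos = g$paralog_map$donor_pos) else NULL
  pv <- plant_variants(g$genome, cfg$targets, cfg$n_het, cfg$n_hom,
                       seed = seed + 1L, avoid = avoid, margin = 100L)
  capture <- cfg$targets
  if (!is.null(cfg$paralog)) {
    span <- cfg$paralog$end - cfg$paralog$start
    capture <- rbind(capture,
                     genomic_intervals(cfg$paralog$dest_chrom,
                                       cfg$paralog$dest_start,
                                       cfg$paralog$dest_start + span))
  }
  reads <- simulate_reads(pv$haplotypes, capture,
                          mean_depth_on = cfg$depth_on,
                          mean_depth_off = cfg$depth_off,
                          read_len = 50L, insert_mean = 200L,
                          insert_sd = 20L, error_rate = 0.01,
                          seed = seed + 2L)
  list(name = name, seed = seed, genome = g$genome,
       genome_lengths = cfg$chrom_lengths, targets = cfg$targets,
       capture = capture, paralog_map = g$paralog_map,
       truth_variants = pv$truth, haplotypes = pv$haplotypes,
       reads = reads, params = cfg)
}

#' Materialise all canonical scenarios
#' @param names subset of scenario names (default all four).
#' @return named list of scenario bundles.
#' @export
standard_fixtures <- function(names = c("CLEAN", "PARALOG95",
                                        "IDENTICAL_DUP", "LOWDEPTH")) {
  setNames(lapply(names, synth_scenario), names)
}

#' Write a scenario bundle to disk
#'
#' Writes genome FASTA, target and capture BED, truth VCF-like table,
#' paralog-map BED, paired FASTQ and a JSON manifest (seed, parameters).
#'
#' @param scenario bundle from [synth_scenario()].
#' @param dir output directory (created if needed).
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_genome_fasta(scenario$genome, p("genome.fa"))
  write_bed(scenario$targets, p("targets.bed"))
  write_bed(scenario$capture, p("capture.bed"))
  tv <- scenario$truth_variants
  truth_calls <- data.frame(ref = tv$chrom, pos = tv$pos,
                            ref_base = tv$ref, depth = NA_integer_,
                            a1 = vapply(strsplit(tv$gt, " "), `[`, "", 1L),
                            a2 = vapply(strsplit(tv$gt, " "), `[`, "", 2L),
                            zygosity = tv$zygosity, stage = "truth",
                            stringsAsFactors = FALSE)
  write_vcf(truth_calls, p("truth.vcf"),
            contigs = scenario$genome_lengths)
  if (nrow(scenario$paralog_map))
    utils::write.table(scenario$paralog_map, p("paralog_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_fastq_pair(scenario$reads$pairs, p("reads_1.fastq"),
                   p("reads_2.fastq"))
  jsonlite::write_json(list(name = scenario$name, seed = scenario$seed,
                            params = scenario$reads$params),
                       p("manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
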