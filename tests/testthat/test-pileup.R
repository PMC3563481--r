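test_that("build_pileups produces one column per covered base", {
  set.seed(30)
  genome <- rand_genome(c(chr1 = 200L))
  read <- substr(genome["chr1"], 11, 60)
  rec <- map_read(read, genome, 0, read_id = "r1")
  reads <- data.frame(read_id = "r1", mate = 1L, seq = read)
  pl <- build_pileups(rec, reads, genome)
  expect_equal(nrow(pl$columns), 50L)
  expect_equal(unique(pl$columns$depth), 1L)
  expect_equal(pl$columns$pos, 10:59)
  expect_equal(pl$columns$ref_base,
               strsplit(read, "")[[1]])

  # reads referenced but absent error
  expect_error(build_pileups(rec, reads[0, ], genome), "absent")
})

test_that("overlapping mates count as two observations", {
  set.seed(30)
  genome <- rand_genome(c(chr1 = 200L))
  frag <- substr(genome["chr1"], 51, 130)  # insert 80 < 2x50: mates overlap
  pairs <- data.frame(read_id = "p", seq1 = substr(frag, 1, 50),
                      seq2 = revcomp(substr(frag, 31, 80)))
  rec <- map_pairs(pairs, genome, 0, c(60, 100))
  pl <- build_pileups(rec, pairs_to_reads_test(pairs), genome)
  overlap_cols <- pl$columns[pl$columns$pos %in% 80:99, ]
  expect_equal(unique(overlap_cols$depth), 2L)
})

test_that("pileup counts equal a brute-force recount", {
  set.seed(31)
  genome <- rand_genome(c(chr1 = 800L))
  starts <- sample(0:550, 20, replace = TRUE)
  pairs <- data.frame(
    read_id = sprintf("r%02d", 1:20),
    seq1 = substring(genome["chr1"], starts + 1, starts + 50),
    seq2 = revcomp(substring(genome["chr1"], starts + 151, starts + 200)))
  rec <- remove_duplicates(map_pairs(pairs, genome, 2, c(100, 400)))
  reads <- pairs_to_reads_test(pairs)
  pl <- build_pileups(rec, reads, genome)
  cols <- pl$columns
  for (p in sample(cols$pos, 25)) {
    want <- oracle_recount(rec, reads, "chr1", p)
    row <- cols[cols$pos == p, ]
    got <- counts_mat(row$A_f, row$A_r, row$C_f, row$C_r, row$G_f,
                      row$G_r, row$T_f, row$T_r)
    expect_equal(got, want)
  }
})

test_that("call_genotype applies the depth/fraction/strand rules", {
  # clear homozygote: 9/10 = 0.9 > 0.8
  g <- call_genotype(counts_mat(A_f = 5, A_r = 4, C_f = 1))
  expect_equal(g$zygosity, "hom")
  expect_equal(g$genotype, c("A", "A"))

  # boundary of the strictly-greater-than-80% rule: 8/10 is het
  g2 <- call_genotype(counts_mat(A_f = 4, A_r = 4, C_f = 1, C_r = 1))
  expect_equal(g2$zygosity, "het")
  expect_equal(g2$genotype, c("A", "C"))

  # depth boundary: 7 reads no-call, 8 reads callable
  g7 <- call_genotype(counts_mat(A_f = 4, A_r = 3))
  expect_equal(g7$zygosity, "no_call")
  expect_equal(g7$reason, "low_depth")
  g8 <- call_genotype(counts_mat(A_f = 4, A_r = 4))
  expect_equal(g8$zygosity, "hom")

  # minor allele below min_minor_reads: ambiguous, not het
  g3 <- call_genotype(counts_mat(A_f = 4, A_r = 3, C_f = 1, G_f = 1))
  expect_equal(g3$zygosity, "no_call")
  expect_equal(g3$reason, "ambiguous")

  # minor allele on one strand only fails the both-strand rule
  g4 <- call_genotype(counts_mat(A_f = 4, A_r = 2, C_f = 2))
  expect_equal(g4$zygosity, "no_call")
  expect_true(call_genotype(counts_mat(A_f = 4, A_r = 2, C_f = 2),
                            require_both_strands = FALSE)$zygosity ==
                "het")

  # tri-allelic columns are rejected as ambiguous
  g5 <- call_genotype(counts_mat(A_f = 3, A_r = 3, C_f = 1, C_r = 2,
                                 G_f = 2, G_r = 1))
  expect_equal(g5$zygosity, "no_call")
  expect_equal(g5$reason, "ambiguous")

  # deterministic lexicographic tie-break at equal counts
  g6 <- call_genotype(counts_mat(T_f = 3, T_r = 2, G_f = 2, G_r = 3))
  expect_equal(g6$genotype, c("G", "T"))
})

test_that("call_variants reports only non-reference genotypes", {
  genome <- c(chr1 = strrep("A", 200))
  # all-reference coverage yields no calls
  starts <- seq(0L, 120L, by = 10L)
  pairs <- data.frame(
    read_id = sprintf("c%02d", seq_along(starts)),
    seq1 = substring(genome["chr1"], starts + 1, starts + 30),
    seq2 = revcomp(substring(genome["chr1"], starts + 51, starts + 80)))
  rec <- map_pairs(pairs, genome, 1, c(40, 120))
  pl <- build_pileups(rec, pairs_to_reads_test(pairs), genome)
  expect_equal(nrow(call_variants(pl)), 0L)
})

test_that("planted genotypes are recovered exactly at 30x, 1% error", {
  set.seed(32)
  genome <- rand_genome(c(chr1 = 12000L))
  targets <- genomic_intervals("chr1", 2000, 8000)
  pv <- plant_variants(genome, targets, n_het = 12, n_hom = 8, seed = 33,
                       margin = 150)
  sim <- simulate_reads(pv$haplotypes, targets, mean_depth_on = 30,
                        mean_depth_off = 0, error_rate = 0.01, seed = 34)
  rec <- remove_duplicates(map_pairs(sim$pairs, genome, 5, c(100, 400)))
  pl <- build_pileups(rec, pairs_to_reads_test(sim$pairs), genome)
  calls <- call_variants(pl, stage = "wg")
  calls <- calls[in_target_test(calls, targets), ]
  expect_equal(nrow(calls), 20L)
  truth_key <- paste(pv$truth$chrom, pv$truth$pos, pv$truth$gt)
  call_key <- paste(calls$ref, calls$pos, paste(calls$a1, calls$a2))
  expect_setequal(call_key, truth_key)
})

test_that("genotype calls are invariant under read reordering", {
  set.seed(35)
  genome <- rand_genome(c(chr1 = 3000L))
  targets <- genomic_intervals("chr1", 500, 2500)
  pv <- plant_variants(genome, targets, 5, 3, seed = 36, margin = 100)
  sim <- simulate_reads(pv$haplotypes, targets, 25, 0, error_rate = 0.01,
                        seed = 37)
  perm <- sample(nrow(sim$pairs))
  rec1 <- remove_duplicates(map_pairs(sim$pairs, genome, 5, c(100, 400)))
  rec2 <- remove_duplicates(map_pairs(sim$pairs[perm, ], genome, 5,
                                      c(100, 400)))
  pl1 <- build_pileups(rec1, pairs_to_reads_test(sim$pairs), genome)
  pl2 <- build_pileups(rec2, pairs_to_reads_test(sim$pairs[perm, ]),
                       genome)
  c1 <- call_variants(pl1)
  c2 <- call_variants(pl2)
  key <- function(x) paste(x$ref, x$pos, x$a1, x$a2, x$zygosity)
  expect_setequal(key(c1), key(c2))
})

test_that("raising min_depth never increases the variant count", {
  set.seed(38)
  genome <- rand_genome(c(chr1 = 4000L))
  targets <- genomic_intervals("chr1", 500, 3500)
  pv <- plant_variants(genome, targets, 8, 4, seed = 39, margin = 100)
  sim <- simulate_reads(pv$haplotypes, targets, 15, 0, error_rate = 0.01,
                        seed = 40)
  rec <- remove_duplicates(map_pairs(sim$pairs, genome, 5, c(100, 400)))
  pl <- build_pileups(rec, pairs_to_reads_test(sim$pairs), genome)
  n_calls <- vapply(c(2L, 5L, 8L, 12L, 16L, 25L), function(md)
    nrow(call_variants(pl, min_depth = md)), 1L)
  expect_true(all(diff(n_calls) <= 0L))
})

test_that("variant calls round-trip through VCF", {
  skip_if_not_installed("VariantAnnotation")
  calls <- data.frame(
    ref = c("chr1", "chr1", "chr2"), pos = c(10L, 99L, 5L),
    ref_base = c("A", "C", "G"), depth = c(30L, 12L, 22L),
    a1 = c("A", "T", "C"), a2 = c("G", "T", "T"),
    zygosity = c("het", "hom", "het"), stage = "post_backmap",
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".vcf")
  write_vcf(calls, f, contigs = c(chr1 = 200L, chr2 = 100L))
  back <- read_vcf(f)
  expect_equal(back[, c("ref", "pos", "ref_base", "a1", "a2",
                        "zygosity")],
               calls[, c("ref", "pos", "ref_base", "a1", "a2",
                         "zygosity")])
  # independent reader agreement
  v <- VariantAnnotation::readVcf(f)
  expect_equal(unname(BiocGenerics::start(v)), calls$pos + 1L)
  expect_equal(as.character(SummarizedExperiment::seqnames(v)),
               calls$ref)
  gt <- VariantAnnotation::geno(v)$GT[, 1]
  expect_equal(unname(gt), c("0/1", "1/1", "1/2"))
})
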