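test_that("coverage_auc matches closed forms and hand enumeration", {
  expect_equal(coverage_auc(c(10, 10), c(0, 0)), 1.0)
  expect_equal(coverage_auc(c(3, 7, 7, 3), c(3, 7, 7, 3)), 0.5)
  # 4 cross-pairs: 3>2, 3>0, 1>0 win; 1<2 loses -> 3/4
  expect_equal(coverage_auc(c(3, 1), c(2, 0)), 0.75)
  expect_error(coverage_auc(numeric(0), c(1)), "non-empty")
})

test_that("coverage_auc is invariant under monotone depth transforms", {
  set.seed(61)
  on <- rpois(300, 20); off <- rpois(500, 2)
  a <- coverage_auc(on, off)
  expect_equal(coverage_auc(sqrt(on), sqrt(off)), a)
  expect_equal(coverage_auc(3 * on + 7, 3 * off + 7), a)
})

test_that("strand_bias hits the documented boundary values", {
  expect_equal(strand_bias(50, 50), 0)
  expect_equal(strand_bias(55, 45), 10)
  expect_equal(strand_bias(100, 0), 100)
  expect_true(is.na(strand_bias(0, 0)))
})

test_that("coverage correlation is 1 for affine copies, NA at zero var", {
  tr <- structure(list(depth = list(c1 = c(3L, 5L, 9L, 2L, 7L)),
                       total_mapped_bases = 26, genome_size = 5),
                  class = "coverage_track")
  tr2 <- tr; tr2$depth$c1 <- 2L * tr$depth$c1 + 5L
  flat <- tr; flat$depth$c1 <- rep(4L, 5)
  m <- coverage_correlation_matrix(list(a = tr, b = tr2, c = flat))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m["a", "b"], 1)
  expect_true(is.na(m["a", "c"]))
  expect_equal(m, t(m))
})

test_that("replicate coverage tracks correlate like the direct formula", {
  set.seed(62)
  genome <- rand_genome(c(chr1 = 4000L))
  targets <- genomic_intervals("chr1", 500, 3500)
  hap <- list(A = genome, B = genome)
  tracks <- lapply(c(63, 64), function(s) {
    sim <- simulate_reads(hap, targets, 12, 0, error_rate = 0.01,
                          seed = s)
    rec <- remove_duplicates(map_pairs(sim$pairs, genome, 5,
                                       c(100, 400)))
    coverage_track(rec, nchar(genome))
  })
  m <- coverage_correlation_matrix(tracks, targets = targets)
  x <- tracks[[1]]$depth$chr1[501:3500]
  y <- tracks[[2]]$depth$chr1[501:3500]
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(m[1, 2], r_direct)
})

test_that("a hand-worked 10-read instance yields every QC field", {
  # chr of 1000 bases, one 100-base target at 200; 8 reads of length 50
  # inside the target (4 forward, 4 reverse), 2 outside
  rec <- data.frame(
    read_id = sprintf("h%02d", 1:10), mate = 1L, ref = "chr1",
    pos = c(200L, 210L, 220L, 230L, 240L, 250L, 250L, 250L, 600L, 700L),
    strand = c("+", "+", "+", "-", "-", "-", "+", "-", "+", "-"),
    qwidth = 50L, mismatches = 0L, mapped = TRUE, n_best_hits = 1L,
    proper_pair = FALSE, mate_ref = NA_character_, mate_pos = NA_integer_,
    is_duplicate = FALSE, stringsAsFactors = FALSE)
  targets <- genomic_intervals("chr1", 200, 300)
  s <- summarize_enrichment(rec, targets, c(chr1 = 1000L))
  expect_equal(s$pct_on_target_reads, 80)
  # ADoC: 8 reads x 50 bases all inside [200,300) -> 400/100
  expect_equal(s$adoc, 4)
  expect_equal(s$ef, 0.8 / (100 / 1000))
  expect_equal(unname(s$completeness["1x"]), 1.0)
  # depth >= 5 holds on [240,280): 40 of 100 target bases
  expect_equal(unname(s$completeness["5x"]), 0.4)
  expect_equal(s$strand_bias, 0)  # 4 forward vs 4 reverse on target
  expect_equal(s$n_reads_mapped, 10)
  expect_error(summarize_enrichment(rec, targets[0, ], c(chr1 = 1000L)),
               "empty target")
})

test_that("uniform unenriched reads give EF near 1 and AUC near 0.5", {
  set.seed(65)
  genome <- rand_genome(c(chr1 = 10000L))
  targets <- genomic_intervals("chr1", 2000, 3000)  # 10% of genome
  hap <- list(A = genome, B = genome)
  efs <- vapply(1:20, function(s) {
    sim <- simulate_reads(hap, genomic_intervals("chr1", 0, 10000),
                          mean_depth_on = 3, mean_depth_off = 0,
                          error_rate = 0, seed = 1000 + s)
    rec <- remove_duplicates(map_pairs(sim$pairs, genome, 3,
                                       c(100, 400)))
    summarize_enrichment(rec, targets, nchar(genome))$ef
  }, 0)
  # EF of an unenriched simulation is 1 within 3 standard errors
  expect_lt(abs(mean(efs) - 1), 3 * stats::sd(efs) / sqrt(length(efs)))
})

test_that("completeness is non-increasing in the depth threshold", {
  set.seed(66)
  genome <- rand_genome(c(chr1 = 6000L))
  targets <- genomic_intervals("chr1", 1000, 5000)
  sim <- simulate_reads(list(A = genome, B = genome), targets, 10, 0.5,
                        error_rate = 0, seed = 67)
  rec <- remove_duplicates(map_pairs(sim$pairs, genome, 3, c(100, 400)))
  s <- summarize_enrichment(rec, targets, nchar(genome))
  expect_true(all(diff(s$completeness) <= 0))
  expect_true(s$auc >= 0 && s$auc <= 1)
})

test_that("genotype concordance is unordered, symmetric and counted", {
  a <- data.frame(ref = "c", pos = 1:10, ref_base = "A",
                  a1 = c(rep("A", 5), rep("C", 5)),
                  a2 = c(rep("C", 5), rep("C", 5)),
                  stringsAsFactors = FALSE)
  b <- a
  expect_equal(genotype_concordance(a, b)$concordance_rate, 1)
  # alleles are compared unordered: A/C equals C/A
  b2 <- b
  b2$a1[1] <- "A"; b2$a2[1] <- "C"
  expect_equal(genotype_concordance(a, b2)$concordance_rate, 1)
  # 2 planted discordances out of 10 shared sites
  b3 <- b
  b3$a1[3] <- "G"; b3$a2[3] <- "G"
  b3$a1[8] <- "A"; b3$a2[8] <- "T"
  gc <- genotype_concordance(a, b3)
  expect_equal(gc$overlap_count, 10L)
  expect_equal(gc$concordance_rate, 0.8)
  expect_equal(nrow(gc$discordant), 2L)
  gc_rev <- genotype_concordance(b3, a)
  expect_equal(gc_rev$concordance_rate, gc$concordance_rate)
  expect_equal(gc_rev$overlap_count, gc$overlap_count)
})

test_that("variant set overlap enumerates venn regions and known split", {
  mk <- function(pos, alt) data.frame(ref = "c", pos = pos,
                                      ref_base = "A", a1 = "A", a2 = alt,
                                      stringsAsFactors = FALSE)
  A <- mk(1:5, "C"); B <- mk(3:7, "C"); C <- mk(c(1, 5, 9), "C")
  ov <- variant_set_overlap(list(A = A, B = B, C = C))
  rc <- ov$region_counts
  # exhaustive enumeration: A only {2}, B only {6,7}, C only {9},
  # A&B only {3,4}, A&C only {1}, B&C only {}, A&B&C {5}
  expect_equal(unname(rc["A&not_B&not_C"]), 1L)
  expect_equal(unname(rc["not_A&B&not_C"]), 2L)
  expect_equal(unname(rc["not_A&not_B&C"]), 1L)
  expect_equal(unname(rc["A&B&not_C"]), 2L)
  expect_equal(unname(rc["A&not_B&C"]), 1L)
  expect_equal(unname(rc["not_A&B&C"]), 0L)
  expect_equal(unname(rc["A&B&C"]), 1L)
  expect_equal(sum(rc), 8L)  # union size {1..7, 9}

  # identical sets put all mass in the triple intersection
  ov2 <- variant_set_overlap(list(x = A, y = A, z = A))
  expect_equal(unname(ov2$region_counts["x&y&z"]), 5L)
  expect_equal(sum(ov2$region_counts), 5L)

  # disjoint sets have empty intersections
  ov3 <- variant_set_overlap(list(p = mk(1:3, "C"), q = mk(10:12, "C")))
  expect_equal(unname(ov3$region_counts["p&q"]), 0L)
  expect_equal(ov3$pairwise$intersection, 0L)

  # pairwise fractions use min and union denominators
  ovAB <- variant_set_overlap(list(A = A, B = B))
  expect_equal(ovAB$pairwise$frac_min, 3 / 5)
  expect_equal(ovAB$pairwise$frac_union, 3 / 7)

  # known/unknown split against a supplied list
  ovk <- variant_set_overlap(list(A = A, B = B), known = mk(c(1, 3), "C"))
  expect_equal(ovk$known_split$known, c(2L, 1L))
  expect_equal(ovk$known_split$unknown, c(3L, 4L))
})

test_that("bedGraph output run-length encodes the coverage profile", {
  rec <- data.frame(
    read_id = c("b1", "b2"), mate = 1L, ref = "chr1",
    pos = c(10L, 30L), strand = "+", qwidth = 40L, mismatches = 0L,
    mapped = TRUE, n_best_hits = 1L, proper_pair = FALSE,
    mate_ref = NA_character_, mate_pos = NA_integer_,
    is_duplicate = FALSE, stringsAsFactors = FALSE)
  tr <- coverage_track(rec, c(chr1 = 100L))
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  lines <- readLines(f)[-1]
  got <- read.table(text = lines, sep = "\t")
  # spans: [10,30) depth 1, [30,50) depth 2, [50,70) depth 1
  expect_equal(got$V2, c(10L, 30L, 50L))
  expect_equal(got$V3, c(30L, 50L, 70L))
  expect_equal(got$V4, c(1L, 2L, 1L))
})
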