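test_that("map_read places exact, mismatched and multi-locus reads", {
  set.seed(21)
  genome <- rand_genome(c(chr1 = 1000L))
  read <- substr(genome["chr1"], 101, 130)
  r <- map_read(read, genome, 2)
  expect_equal(r$pos, 100L)
  expect_equal(r$strand, "+")
  expect_equal(r$mismatches, 0L)
  expect_equal(r$n_best_hits, 1L)

  # reverse-strand placement
  r2 <- map_read(revcomp(read), genome, 2)
  expect_equal(r2$pos, 100L)
  expect_equal(r2$strand, "-")

  # a segment duplicated at two loci yields two equal-best records
  dup <- c(chr1 = paste0(substr(genome["chr1"], 1, 500),
                         substr(genome["chr1"], 101, 130),
                         substr(genome["chr1"], 501, 900)))
  r3 <- map_read(read, dup, 2)
  expect_equal(nrow(r3), 2L)
  expect_equal(r3$n_best_hits, c(2L, 2L))
  expect_equal(r3$pos, c(100L, 500L))

  expect_false(map_read(strrep("A", 30), genome, 0)$mapped)
  expect_error(map_read("", genome, 2), "empty read")
})

test_that("builtin aligner equals the all-offsets brute-force oracle", {
  set.seed(22)
  for (inst in 1:10) {
    genome <- rand_genome(c(c1 = 700L, c2 = 300L))
    ridx <- ref_index(genome)
    for (j in 1:10) {
      src <- sample(names(genome), 1)
      rl <- sample(c(21L, 30L, 50L), 1)
      s <- sample(nchar(genome[src]) - rl, 1)
      chars <- strsplit(substr(genome[src], s + 1, s + rl), "")[[1]]
      ne <- sample(0:2, 1)
      if (ne > 0) {
        at <- sample(rl, ne)
        chars[at] <- vapply(chars[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      }
      read <- paste(chars, collapse = "")
      if (runif(1) < 0.5) read <- revcomp(read)
      got <- map_read(read, ridx, 2)
      exp <- oracle_map(read, genome, 2)
      if (is.null(exp)) {
        expect_false(got$mapped[1])
      } else {
        expect_equal(got[, c("ref", "pos", "strand", "mismatches")], exp,
                     ignore_attr = TRUE)
        expect_equal(got$n_best_hits, rep(nrow(exp), nrow(exp)))
      }
    }
  }
})

test_that("N in the reference counts as a mismatch (spacer penalty)", {
  genome <- c(chr1 = paste0(strrep("A", 40), strrep("N", 20),
                            strrep("A", 40)))
  # a poly-A read overlapping the N block only maps where the overlap is
  # within budget; with budget 0 it must stay off the Ns entirely
  r0 <- map_read(strrep("A", 30), genome, 0)
  expect_true(all(r0$pos + 30 <= 40 | r0$pos >= 60))
  # a read continuing past a TR block edge cannot map across the spacer
  set.seed(28)
  g <- rand_genome(c(g = 200L))
  tr <- build_tr_reference(g, genomic_intervals(c("g", "g"), c(0, 120),
                                                c(40, 160)),
                           spacer_len = 50)
  junction_read <- substr(g["g"], 21, 70)  # 20 bases in-block, 30 beyond
  expect_false(map_read(junction_read, tr, 5)$mapped)
})

test_that("map_pairs prefers proper pairs and handles unmapped mates", {
  set.seed(23)
  genome <- rand_genome(c(chr1 = 2000L))
  frag <- substr(genome["chr1"], 501, 700)  # insert 200
  p <- data.frame(read_id = "p1", seq1 = substr(frag, 1, 50),
                  seq2 = revcomp(substr(frag, 151, 200)))
  rec <- map_pairs(p, genome, 3, c(100, 400))
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$proper_pair))
  expect_equal(sort(rec$pos), c(500L, 650L))
  expect_equal(rec$mate_pos[rec$mate == 1], 650L)
  expect_equal(sort(rec$strand), c("+", "-"))

  # one unalignable mate: the mapped mate keeps the link, mate unmapped
  p2 <- data.frame(read_id = "p2", seq1 = substr(frag, 1, 50),
                   seq2 = strrep("T", 50))
  rec2 <- map_pairs(p2, genome, 0, c(100, 400))
  expect_true(rec2$mapped[rec2$mate == 1])
  expect_false(rec2$mapped[rec2$mate == 2])
  expect_false(any(rec2$proper_pair))
  expect_true(is.na(rec2$mate_ref[rec2$mate == 1]))
})

test_that("paralog pairs force-map onto the homolog with mismatches", {
  toy <- toy_paralog_genome()
  # fragment drawn from the chr2 (diverged, off-target) copy spanning
  # both divergence positions
  frag <- substr(toy$genome["chr2"], toy$core_start_chr2 + 1,
                 toy$core_start_chr2 + 200)
  pair <- data.frame(read_id = "fp", seq1 = substr(frag, 21, 70),
                     seq2 = revcomp(substr(frag, 101, 150)))
  # TR reference holds only the chr1 copy: both mates force-map there
  tr_genome <- c(tr = substr(toy$genome["chr1"], 301, 800))
  rec <- map_pairs(pair, tr_genome, 5, c(50, 400))
  expect_true(all(rec$mapped))
  # mate 1 covers divergence position 50 (1 mismatch); mate 2 covers
  # position 120 (1 mismatch)
  expect_equal(rec$mismatches, c(1L, 1L))
  # against the whole genome the same pair maps to chr2 with 0 mismatches
  rec_wg <- map_pairs(pair, toy$genome, 5, c(50, 400))
  expect_equal(rec_wg$ref, c("chr2", "chr2"))
  expect_equal(rec_wg$mismatches, c(0L, 0L))
})

test_that("remove_duplicates keeps one record per placement signature", {
  set.seed(24)
  genome <- rand_genome(c(chr1 = 3000L))
  starts <- c(100L, 100L, 100L, 400L, 400L)
  pairs <- data.frame(
    read_id = sprintf("r%02d", 1:5),
    seq1 = substring(genome["chr1"], starts + 1, starts + 50),
    seq2 = revcomp(substring(genome["chr1"], starts + 151, starts + 200)))
  # r4/r5 share a position but different mate -> give r5 a shifted mate
  pairs$seq2[5] <- revcomp(substr(genome["chr1"], 561, 610))
  rec <- remove_duplicates(map_pairs(pairs, genome, 3, c(100, 400)))
  surv <- rec[!rec$is_duplicate & rec$mate == 1, ]
  expect_equal(sort(surv$read_id), c("r01", "r04", "r05"))

  # generator-planted duplicates: survivor count equals originals
  sc <- simulate_reads(
    list(A = genome, B = genome),
    genomic_intervals("chr1", 500, 2500),
    mean_depth_on = 10, mean_depth_off = 0, error_rate = 0,
    seed = 77, duplicate_rate = 0.3)
  n_orig <- sum(is.na(sc$truth$dup_of))
  rec2 <- remove_duplicates(map_pairs(sc$pairs, genome, 3, c(100, 400)))
  surv2 <- unique(rec2$read_id[rec2$mapped & !rec2$is_duplicate &
                                 rec2$mate == 1])
  expect_equal(length(surv2), n_orig)
})

test_that("identical inputs give byte-identical SAM output", {
  set.seed(25)
  genome <- rand_genome(c(chr1 = 1500L))
  starts <- sample(0:1200, 20)
  pairs <- data.frame(
    read_id = sprintf("q%02d", 1:20),
    seq1 = substring(genome["chr1"], starts + 1, starts + 50),
    seq2 = revcomp(substring(genome["chr1"], starts + 151,
                             starts + 200)))
  reads <- data.frame(read_id = rep(pairs$read_id, 2),
                      mate = rep(1:2, each = 20),
                      seq = c(pairs$seq1, pairs$seq2))
  f1 <- tempfile(); f2 <- tempfile()
  rec_a <- remove_duplicates(map_pairs(pairs, genome, 3, c(100, 400)))
  rec_b <- remove_duplicates(map_pairs(pairs, genome, 3, c(100, 400)))
  write_sam(rec_a, reads, c(chr1 = 1500L), f1)
  write_sam(rec_b, reads, c(chr1 = 1500L), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("SAM round-trips through write_sam/read_sam", {
  set.seed(26)
  genome <- rand_genome(c(chr1 = 900L, chr2 = 600L))
  starts <- sample(0:600, 8)
  pairs <- data.frame(
    read_id = sprintf("s%02d", 1:8),
    seq1 = substring(genome["chr1"], starts + 1, starts + 40),
    seq2 = revcomp(substring(genome["chr1"], starts + 111, starts + 150)))
  pairs$seq2[8] <- strrep("T", 40)  # one unmapped mate
  rec <- remove_duplicates(map_pairs(pairs, genome, 2, c(80, 300)))
  reads <- data.frame(read_id = rep(pairs$read_id, 2),
                      mate = rep(1:2, each = 8),
                      seq = c(pairs$seq1, pairs$seq2))
  f <- tempfile()
  write_sam(rec, reads, nchar(genome), f)
  back <- read_sam(f)
  expect_equal(back$ref_lengths, nchar(genome))
  cols <- c("read_id", "mate", "ref", "pos", "strand", "qwidth",
            "mismatches", "mapped", "proper_pair", "mate_ref", "mate_pos",
            "is_duplicate")
  ord <- function(d) {
    d <- d[order(d$read_id, d$mate), cols]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(back$records), ord(rec))
  # sequences come back in sequencing orientation
  key <- paste(back$reads$read_id, back$reads$mate)
  expect_equal(setNames(back$reads$seq, key)[paste(reads$read_id,
                                                   reads$mate)],
               setNames(reads$seq, paste(reads$read_id, reads$mate)))
})

test_that("package SAM parses identically through Rsamtools", {
  skip_if_not_installed("Rsamtools")
  set.seed(27)
  genome <- rand_genome(c(chr1 = 800L))
  starts <- sample(0:550, 6)
  pairs <- data.frame(
    read_id = sprintf("x%02d", 1:6),
    seq1 = substring(genome["chr1"], starts + 1, starts + 50),
    seq2 = revcomp(substring(genome["chr1"], starts + 151, starts + 200)))
  rec <- map_pairs(pairs, genome, 2, c(100, 400))
  reads <- data.frame(read_id = rep(pairs$read_id, 2),
                      mate = rep(1:2, each = 6),
                      seq = c(pairs$seq1, pairs$seq2))
  f <- tempfile(fileext = ".sam")
  write_sam(rec, reads, nchar(genome), f)
  bam <- Rsamtools::asBam(f, tempfile(), overwrite = TRUE)
  sb <- Rsamtools::scanBam(bam)[[1]]
  ord <- order(sb$qname, !bitwAnd(sb$flag, 64L))
  rec_ord <- rec[order(rec$read_id, rec$mate), ]
  expect_equal(sb$pos[ord], rec_ord$pos + 1L)
  expect_equal(as.character(sb$rname[ord]), rec_ord$ref)
  expect_equal(as.character(sb$strand[ord]),
               ifelse(rec_ord$strand == "+", "+", "-"))
})

test_that("FASTQ pairs round-trip with identifiers preserved", {
  pairs <- data.frame(read_id = c("a1", "a2"),
                      seq1 = c("ACGTACGTAC", "TTGGCCAATT"),
                      seq2 = c("GGGGCCCCAA", "ACACACACGT"))
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq_pair(pairs, f1, f2)
  expect_equal(read_fastq_pair(f1, f2), pairs)
})
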