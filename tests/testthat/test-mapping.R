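test_that("the k-mer index covers every circular position exactly once", {
  g <- build_genome(list(replicon("pX", 10000)), seed = 1)
  idx <- index_reference(g, mapping_params(kmer_size = 15))
  st <- arseq:::index_stats(idx)
  expect_identical(st$n_positions, 10000)  # one entry per circular position
  # a k-mer spanning the origin is findable
  s <- g$replicons$pX$sequence
  wrap_kmer <- paste0(substr(s, 9996, 10000), substr(s, 1, 10))
  hit <- arseq:::kmer_positions(idx, wrap_kmer)
  expect_true(9995 %in% hit$pos)
})

test_that("k-mers inside a duplicated segment index at least two positions", {
  g <- dup_genome()
  idx <- index_reference(g, mapping_params())
  s <- g$replicons$pDUP$sequence
  for (off in c(1500, 2000, 3500)) {
    km <- substr(s, off + 1, off + 15)
    expect_gte(nrow(arseq:::kmer_positions(idx, km)), 2)
  }
})

test_that("degenerate references are rejected or skipped", {
  expect_error(index_reference(structure(list(replicons = list(),
                                              copy_weights = numeric(0)),
                                         class = "genome_model")),
               "empty genome")
  g <- build_genome(list(replicon("ok", 3000), replicon("tiny", 10)), seed = 1)
  expect_warning(index_reference(g), "shorter than k")
})

test_that("exact reads map uniquely with perfect identity and strand symmetry", {
  g <- test_genome(seed = 21)
  idx <- index_reference(g)
  s <- g$replicons$chr$sequence
  read <- substr(s, 5001, 5150)
  rec <- map_read(read, idx)
  expect_equal(nrow(rec), 1)
  expect_identical(rec$replicon, "chr")
  expect_equal(rec$start, 5000)
  expect_equal(rec$end, 5150)
  expect_identical(rec$strand, "+")
  expect_equal(rec$identity, 1.0)
  expect_equal(rec$aligned_fraction, 1.0)
  expect_equal(rec$n_hits, 1L)
  expect_equal(rec$score, 150)
  # reverse complement maps to the same locus on the other strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  rec2 <- map_read(rc, idx)
  expect_equal(rec2$start, rec$start)
  expect_equal(rec2$end, rec$end)
  expect_identical(rec2$strand, "-")
})

test_that("reads below the similarity fraction are discarded", {
  g <- test_genome(seed = 22)
  idx <- index_reference(g)
  s <- g$replicons$chr$sequence
  read <- strsplit(substr(s, 7001, 7150), "")[[1]]
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  # 18 substitutions clustered in the first 36 bases: identity 132/150 = 0.88,
  # while the clean 3' end still provides exact seeds
  for (p in seq(1, 36, by = 2)) read[p] <- flip(read[p])
  expect_equal(nrow(map_read(paste(read, collapse = ""), idx)), 0)
  # 12 substitutions: identity 138/150 = 0.92 passes
  read2 <- strsplit(substr(s, 7001, 7150), "")[[1]]
  for (p in seq(1, 24, by = 2)) read2[p] <- flip(read2[p])
  rec <- map_read(paste(read2, collapse = ""), idx)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$identity, 138 / 150)
})

test_that("reads from a duplicated segment are reported at all copies", {
  g <- dup_genome()
  idx <- index_reference(g)
  s <- g$replicons$pDUP$sequence
  read <- substr(s, 2001, 2150)  # interior to the [1000,4000)->7000 duplication
  rec <- map_read(read, idx)
  expect_gte(nrow(rec), 2)
  expect_true(all(rec$n_hits >= 2))
  expect_setequal(rec$start, c(2000, 8000))
})

test_that("alignments crossing the circular origin are reported modulo length", {
  g <- build_genome(list(replicon("pX", 5000)), seed = 31)
  idx <- index_reference(g)
  s <- g$replicons$pX$sequence
  read <- paste0(substr(s, 4951, 5000), substr(s, 1, 100))  # wraps the origin
  rec <- map_read(read, idx)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$start, 4950)
  expect_equal(rec$end, 5100)  # start + span; end > L denotes the wrap
  expect_equal(rec$identity, 1.0)
})

test_that("no emitted alignment violates the identity or length-fraction filters", {
  g <- test_genome(seed = 23)
  la <- make_library_a(g, test_library_config(), seed = 24)
  idx <- index_reference(g)
  # high error rate so that the filter actually bites: at 8% substitutions
  # a 150 bp read carries ~12 errors, and identity < 0.9 (>= 16 errors)
  # happens often enough that a visible share of mates must be dropped
  rd <- simulate_reads(la, 400, substitution_rate = 0.08, seed = 25)
  al <- map_library(rd, idx)
  expect_true(all(al$alignments$identity >= 0.9))
  expect_true(all(al$alignments$aligned_fraction >= 0.8))
  mapped_mates <- length(unique(paste(al$alignments$pair_id,
                                      al$alignments$mate)))
  expect_lt(mapped_mates, 780)
})

test_that("mapper placements and scores match the exhaustive oracle", {
  set.seed(99)
  refseq <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                  collapse = "")
  g <- build_genome(list(replicon("ref", 1500, sequence = refseq)), seed = 1)
  idx <- index_reference(g)
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  cases <- list()
  for (i in 1:8) {
    start <- sample(200:1200, 1)
    len <- sample(40:60, 1)
    rd <- strsplit(substr(refseq, start + 1, start + len), "")[[1]]
    if (i %% 2 == 0) rd[5] <- flip(rd[5])               # substitution
    if (i %% 4 == 0) rd <- rd[-20]                      # deletion in read
    if (i == 7) rd <- append(rd, "A", after = 30)       # insertion in read
    rd <- paste(rd, collapse = "")
    if (i %% 3 == 0) {
      rd <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rd)))
    }
    cases[[i]] <- rd
  }
  for (rd in cases) {
    got <- map_read(rd, idx)
    got <- got[order(got$strand, got$start), ]
    want <- oracle_map_read(rd, refseq)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$strand, want$strand)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$score, want$score)
  }
})

test_that("paired mapping is concordant and truthful on simulated reads", {
  g <- test_genome(seed = 26)
  la <- make_library_a(g, test_library_config(), seed = 27)
  idx <- index_reference(g)
  # error-free reads from unique regions: everything concordant and unique
  rd0 <- simulate_reads(la, 300, substitution_rate = 0, seed = 28)
  al0 <- map_library(rd0, idx)
  expect_equal(al0$stats$concordant_pairs, 300)
  expect_equal(al0$stats$multimapped_pairs, 0)
  # truth check at 0.5% substitutions: >= 99% of uniquely mapped mates at
  # their true coordinates
  rd <- simulate_reads(la, 500, substitution_rate = 0.005, seed = 29)
  al <- map_library(rd, idx)
  a <- al$alignments[al$alignments$n_hits == 1, ]
  tr <- rd$truth
  key <- match(a$pair_id, tr$pair_id)
  true_start <- ifelse(a$mate == 1, tr$m1_start[key], tr$m2_start[key])
  true_rep <- tr$replicon[key]
  ok <- a$replicon == true_rep & (a$start %% 1e9) == true_start
  expect_gte(mean(ok), 0.99)
})

test_that("read pairs from a duplicated segment are all flagged multi-mapped", {
  g <- dup_genome()
  # confine fragments to the duplicated segment via a dedicated library
  clones <- data.frame(replicon = "pDUP",
                       start = as.integer(seq(1100, 2300, length.out = 40)),
                       length = 1600L, carries_ars = FALSE, stage = "A")
  clones$end <- clones$start + clones$length
  lib <- structure(list(stage = "A", clones = clones, genome = g),
                   class = "clone_library")
  rd <- simulate_reads(lib, 60, substitution_rate = 0, seed = 30)
  idx <- index_reference(g)
  al <- map_library(rd, idx)
  expect_equal(al$stats$multimapped_pairs, 60)
})

test_that("alignment tables and SAM records are written with metadata", {
  g <- test_genome(seed = 71)
  la <- make_library_a(g, test_library_config(), seed = 72)
  rd <- simulate_reads(la, 40, seed = 73)
  idx <- index_reference(g)
  al <- map_library(rd, idx)
  tsv <- tempfile(fileext = ".tsv")
  write_alignments_tsv(al, tsv, seed = 73)
  lines <- readLines(tsv)
  expect_match(lines[1], "^# arseq")
  df <- read.delim(tsv, comment.char = "#")
  expect_true(all(c("pair_id", "identity", "n_hits", "cigar") %in% names(df)))
  js <- tempfile(fileext = ".json")
  write_mapping_stats_json(al, js, seed = 73)
  st <- jsonlite::read_json(js)
  expect_equal(st$total_pairs, 40)
  sam <- tempfile(fileext = ".sam")
  write_alignments_sam(al, sam)
  sl <- readLines(sam)
  expect_match(sl[1], "^@HD")
  expect_equal(sum(grepl("^@SQ", sl)), 3)
})
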