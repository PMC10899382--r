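# Hand-built alignment sets exercise the composition/coverage arithmetic
# directly; pipeline-level behaviour is covered in test-pipeline.R.

two_rep_lengths <- c(X = 5000L, Y = 4000L)

make_pairs <- function(n_x_unique, n_y_unique, n_multi) {
  n <- n_x_unique + n_y_unique + n_multi
  ids <- sprintf("p%03d", seq_len(n))
  rep_assign <- c(rep("X", n_x_unique), rep("Y", n_y_unique),
                  rep("X", n_multi))
  pairs <- data.frame(pair_id = ids, mapped = TRUE, concordant = TRUE,
                      multi = c(rep(FALSE, n_x_unique + n_y_unique),
                                rep(TRUE, n_multi)),
                      replicon = rep_assign, insert = 400,
                      n_combos = c(rep(1L, n_x_unique + n_y_unique),
                                   rep(2L, n_multi)),
                      stringsAsFactors = FALSE)
  # unique pairs: one placement; multi pairs: one placement on each replicon
  n_uni <- n_x_unique + n_y_unique
  plc_unique <- if (n_uni > 0) {
    data.frame(pair_id = ids[seq_len(n_uni)],
               replicon = rep_assign[seq_len(n_uni)],
               start1 = 100, end1 = 250, start2 = 350, end2 = 500,
               insert = 400, score = 300, stringsAsFactors = FALSE)
  } else NULL
  if (n_multi > 0) {
    mids <- ids[(n_x_unique + n_y_unique + 1):n]
    plc_multi <- rbind(
      data.frame(pair_id = mids, replicon = "X", start1 = 100, end1 = 250,
                 start2 = 350, end2 = 500, insert = 400, score = 300,
                 stringsAsFactors = FALSE),
      data.frame(pair_id = mids, replicon = "Y", start1 = 600, end1 = 750,
                 start2 = 850, end2 = 1000, insert = 400, score = 300,
                 stringsAsFactors = FALSE))
    plc <- rbind(plc_unique, plc_multi)
  } else plc <- plc_unique
  aln <- data.frame(read_index = seq_len(n), replicon = rep_assign,
                    start = 100, end = 250, strand = "+", score = 150,
                    identity = 1, aligned_fraction = 1,
                    n_hits = ifelse(pairs$multi, 2L, 1L), cigar = "150M",
                    mate = 1L, pair_id = ids, stringsAsFactors = FALSE)
  manual_alignment_set(pairs, plc, aln, two_rep_lengths)
}

test_that("composition excludes multi-mapped pairs from both sides of the ratio", {
  al <- make_pairs(90, 10, 5)
  cm <- compute_composition(al, policy = "exclude_multimapped")
  expect_equal(attr(cm, "counted_pairs"), 100)
  expect_equal(cm$percent[cm$replicon == "X"], 90)
  expect_equal(cm$percent[cm$replicon == "Y"], 10)
  expect_equal(sum(cm$percent), 100, tolerance = 1e-12)
})

test_that("include_all composition distributes multi-mapped pairs fractionally", {
  al <- make_pairs(90, 10, 5)
  cm <- compute_composition(al, policy = "include_all")
  # each multi pair contributes 1/2 to X and 1/2 to Y
  expect_equal(cm$pairs[cm$replicon == "X"], 92.5)
  expect_equal(cm$pairs[cm$replicon == "Y"], 12.5)
  expect_equal(sum(cm$percent), 100, tolerance = 1e-12)
})

test_that("a single-source library yields a 100% composition row", {
  al <- make_pairs(25, 0, 0)
  cm <- compute_composition(al)
  expect_equal(cm$percent[cm$replicon == "X"], 100)
  expect_equal(cm$percent[cm$replicon == "Y"], 0)
})

test_that("an all-multi-mapped library has no exclude-policy composition", {
  al <- make_pairs(0, 0, 5)
  expect_error(compute_composition(al, policy = "exclude_multimapped"),
               "empty composition")
  cm <- compute_composition(al, policy = "include_all")
  expect_equal(sum(cm$percent), 100, tolerance = 1e-12)
})

test_that("coverage depth follows interval arithmetic", {
  aln <- data.frame(read_index = 1:2, replicon = "X",
                    start = c(100, 200), end = c(250, 350), strand = "+",
                    score = 150, identity = 1, aligned_fraction = 1,
                    n_hits = 1L, cigar = "150M", mate = 1L,
                    pair_id = c("p1", "p2"), stringsAsFactors = FALSE)
  pairs <- data.frame(pair_id = c("p1", "p2"), mapped = FALSE,
                      concordant = FALSE, multi = FALSE,
                      replicon = NA_character_, insert = NA_real_,
                      n_combos = 0L, stringsAsFactors = FALSE)
  al <- manual_alignment_set(pairs, data.frame(), aln, two_rep_lengths)
  cv <- compute_coverage(al)
  d <- cv$X
  expect_true(all(d[101:200] == 1))
  expect_true(all(d[201:250] == 2))
  expect_true(all(d[251:350] == 1))
  expect_true(all(d[c(1:100, 351:5000)] == 0))
  expect_true(all(cv$Y == 0))
  # conservation: total depth equals total aligned bases
  expect_equal(sum(d), sum(aln$end - aln$start))
  expect_equal(attr(cv, "total_aligned_bases"), 300)
})

test_that("coverage handles origin-wrapping alignments and the multimap policy", {
  aln <- data.frame(read_index = 1:2, replicon = "X",
                    start = c(4950, 10), end = c(5100, 160), strand = "+",
                    score = 150, identity = 1, aligned_fraction = 1,
                    n_hits = c(1L, 3L), cigar = "150M", mate = 1L,
                    pair_id = c("p1", "p2"), stringsAsFactors = FALSE)
  pairs <- data.frame(pair_id = c("p1", "p2"), mapped = FALSE,
                      concordant = FALSE, multi = c(FALSE, TRUE),
                      replicon = NA_character_, insert = NA_real_,
                      n_combos = 0L, stringsAsFactors = FALSE)
  al <- manual_alignment_set(pairs, data.frame(), aln, two_rep_lengths)
  cv_all <- compute_coverage(al, policy = "include_all")
  expect_equal(sum(cv_all$X), 300)
  expect_true(all(cv_all$X[4951:5000] == 1))  # wrapped tail
  expect_true(all(cv_all$X[1:10] == 1))       # wrapped head alone
  expect_true(all(cv_all$X[11:100] == 2))     # wrapped head + second mate
  cv_uni <- compute_coverage(al, policy = "exclude_multimapped")
  expect_equal(sum(cv_uni$X), 150)
  expect_equal(attr(cv_uni, "total_aligned_bases"), 150)
})

test_that("bedGraph output round-trips the depth vector", {
  aln <- data.frame(read_index = 1L, replicon = "Y", start = 7, end = 19,
                    strand = "+", score = 12, identity = 1,
                    aligned_fraction = 1, n_hits = 1L, cigar = "12M",
                    mate = 1L, pair_id = "p1", stringsAsFactors = FALSE)
  pairs <- data.frame(pair_id = "p1", mapped = FALSE, concordant = FALSE,
                      multi = FALSE, replicon = NA_character_,
                      insert = NA_real_, n_combos = 0L)
  al <- manual_alignment_set(pairs, data.frame(), aln, two_rep_lengths)
  cv <- compute_coverage(al)
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(cv, f, seed = 1)
  lines <- readLines(f)
  expect_match(lines[1], "^# arseq")
  body <- read.delim(f, header = FALSE, skip = 2)
  expect_equal(body$V2, 7)
  expect_equal(body$V3, 19)
  expect_equal(body$V4, 1)
})
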