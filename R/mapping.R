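#' Mapping parameters
#'
#' The score scheme and filters used throughout: match score 1, mismatch
#' cost 2, indel cost 3; alignments must cover at least `length_fraction`
#' of the read and reach at least `similarity_fraction` identity
#' (matches / aligned columns) to be reported.  Alignment is end-to-end on
#' the read (no soft clipping), so the fraction filters are defined on the
#' read itself.
#'
#' @param match_score,mismatch_cost,indel_cost Alignment score scheme
#'   (score = matches * match_score - mismatches * mismatch_cost -
#'   gap columns * indel_cost).
#' @param length_fraction Minimum aligned fraction of the read.
#' @param similarity_fraction Minimum identity over aligned columns.
#' @param kmer_size Seed k-mer size (>= 8, <= 31).
#' @param max_hits Maximum number of co-optimal placements reported per
#'   read; reads with more remain flagged multi-mapped (`n_hits` carries
#'   the true co-optimal count) but further placements are not emitted.
#' @param band Half-width of the alignment band around a seed diagonal;
#'   bounds the number of indels an alignment can absorb.
#' @return An object of class `mapping_params`.
#' @export
mapping_params <- function(match_score = 1L, mismatch_cost = 2L,
                           indel_cost = 3L, length_fraction = 0.8,
                           similarity_fraction = 0.9, kmer_size = 15L,
                           max_hits = 10L, band = 16L) {
  stopifnot(length_fraction > 0, length_fraction <= 1,
            similarity_fraction > 0, similarity_fraction <= 1,
            kmer_size >= 8L, kmer_size <= 31L, max_hits >= 1L, band >= 1L)
  structure(list(match_score = as.integer(match_score),
                 mismatch_cost = as.integer(mismatch_cost),
                 indel_cost = as.integer(indel_cost),
                 length_fraction = length_fraction,
                 similarity_fraction = similarity_fraction,
                 kmer_size = as.integer(kmer_size),
                 max_hits = as.integer(max_hits),
                 band = as.integer(band)),
            class = "mapping_params")
}

#' Index a reference genome for mapping
#'
#' Builds an exact k-mer table over all replicons.  References are
#' circular: k-mers spanning the origin are indexed by appending the first
#' `k - 1` bases, so a replicon of length L contributes exactly L k-mer
#' positions.  Replicons shorter than k are skipped with a warning.
#'
#' @param genome A `genome_model`, or a path to a reference FASTA.
#' @param params A [mapping_params()].
#' @return An object of class `reference_index`.
#' @export
index_reference <- function(genome, params = mapping_params()) {
  if (is.character(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    seqs <- as.character(ss)
    nms <- sub("\\s.*$", "", names(ss))
  } else {
    stopifnot(inherits(genome, "genome_model"))
    seqs <- vapply(genome$replicons, `[[`, "", "sequence")
    nms <- names(genome$replicons)
  }
  if (!length(seqs)) stop("empty genome: nothing to index")
  short <- nchar(seqs) < params$kmer_size
  if (any(short)) {
    warning("replicon(s) shorter than k skipped: ",
            paste(nms[short], collapse = ", "))
  }
  xp <- .cpp_build_index(nms, unname(seqs), params$kmer_size)
  structure(list(ptr = xp, replicon = nms,
                 lengths = stats::setNames(nchar(seqs), nms),
                 params = params),
            class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  info <- .cpp_index_info(x$ptr)
  cat(sprintf("reference_index: %d replicon(s), k=%d, %g k-mer positions\n",
              length(x$replicon), info$k, info$n_positions))
  invisible(x)
}

# Index statistics (used by tests): total and per-replicon indexed positions.
index_stats <- function(index) {
  info <- .cpp_index_info(index$ptr)
  list(k = info$k, n_positions = info$n_positions,
       per_replicon = stats::setNames(info$positions_per_replicon,
                                      info$replicon))
}

# Positions of one exact k-mer in the index (forward strand).
kmer_positions <- function(index, kmer) {
  df <- .cpp_kmer_positions(index$ptr, kmer)
  df$replicon <- index$replicon[df$replicon_index]
  df
}

#' Map a single read
#'
#' Seed k-mers are looked up on both strands, candidate loci are extended
#' by banded end-to-end alignment under the configured score scheme, and
#' all co-optimal placements that pass the length-fraction and
#' similarity-fraction filters are returned with `n_hits` set to the
#' co-optimal count.
#'
#' @param seq Nucleotide string (length >= k).
#' @param index A [index_reference()] result.
#' @param params A [mapping_params()]; defaults to the index's.
#' @return A data.frame of alignment records with columns `replicon`,
#'   `start`, `end` (0-based half-open; `end` may exceed the replicon
#'   length when the alignment wraps the circular origin), `strand`,
#'   `score`, `identity`, `aligned_fraction`, `n_hits`, `cigar`.  Zero rows
#'   when no placement passes the filters.
#' @export
map_read <- function(seq, index, params = index$params) {
  stopifnot(inherits(index, "reference_index"), is.character(seq),
            length(seq) == 1L)
  if (nchar(seq) < params$kmer_size) stop("read shorter than seed k-mer")
  res <- map_reads_raw(seq, index, params)
  res$read_index <- NULL
  res
}

# Map a character vector of reads; returns one data.frame with read_index.
map_reads_raw <- function(reads, index, params) {
  raw <- .cpp_map_reads(index$ptr, reads,
                        params$match_score, params$mismatch_cost,
                        params$indel_cost, params$length_fraction,
                        params$similarity_fraction, params$max_hits,
                        params$band)
  data.frame(read_index = raw$read_index,
             replicon = index$replicon[raw$replicon_index],
             start = raw$start, end = raw$end, strand = raw$strand,
             score = raw$score,
             identity = ifelse(raw$aligned_cols > 0,
                               raw$matches / raw$aligned_cols, 0),
             aligned_fraction = rep(1.0, length(raw$read_index)),
             n_hits = raw$n_hits, cigar = raw$cigar,
             stringsAsFactors = FALSE)
}

#' Map a paired-end read set
#'
#' Both mates are mapped independently, then paired: a pair is concordant
#' when there is a combination of mate placements on the same replicon, on
#' opposite strands, whose implied insert size lies within
#' `insert_mean +/- 4 * insert_sd` (insert computed on the circular
#' replicon).  A pair is flagged multi-mapped when either mate has more
#' than one co-optimal placement.
#'
#' @param reads A `read_pair_set`.
#' @param index A [index_reference()] result.
#' @param params A [mapping_params()].
#' @param insert_mean,insert_sd Expected insert size; default taken from
#'   the read set.
#' @return An object of class `alignment_set`: list with
#'   * `alignments`: per-mate alignment records (`pair_id`, `mate`, plus
#'     the [map_read()] columns),
#'   * `pairs`: one row per input pair (`pair_id`, `mapped`, `concordant`,
#'     `multi`, `replicon`, `insert`, `n_combos`),
#'   * `placements`: all concordant placement combinations (long form,
#'     used for fractional multi-map assignment),
#'   * `stats`: totals (pairs, mapped, concordant, multi-mapped).
#' @export
map_library <- function(reads, index, params = index$params,
                        insert_mean = reads$insert_mean,
                        insert_sd = reads$insert_sd) {
  stopifnot(inherits(reads, "read_pair_set"),
            inherits(index, "reference_index"))
  n <- length(reads$mate1)
  pair_ids <- if (!is.null(reads$truth) && nrow(reads$truth) == n) {
    reads$truth$pair_id
  } else sprintf("pair%06d", seq_len(n))

  a1 <- map_reads_raw(reads$mate1, index, params)
  a2 <- map_reads_raw(reads$mate2, index, params)
  a1$mate <- rep(1L, nrow(a1)); a2$mate <- rep(2L, nrow(a2))
  aln <- rbind(a1, a2)
  aln$pair_id <- pair_ids[aln$read_index]

  lens <- index$lengths
  lo <- insert_mean - 4 * insert_sd
  hi <- insert_mean + 4 * insert_sd

  s1 <- split(seq_len(nrow(a1)), a1$read_index)
  s2 <- split(seq_len(nrow(a2)), a2$read_index)

  pairs <- data.frame(pair_id = pair_ids, mapped = rep(FALSE, n),
                      concordant = rep(FALSE, n), multi = rep(FALSE, n),
                      replicon = rep(NA_character_, n),
                      insert = rep(NA_real_, n), n_combos = rep(0L, n),
                      stringsAsFactors = FALSE)
  plc <- vector("list", n)
  for (i in seq_len(n)) {
    r1 <- s1[[as.character(i)]]
    r2 <- s2[[as.character(i)]]
    if (is.null(r1) && is.null(r2)) next
    pairs$mapped[i] <- !is.null(r1) && !is.null(r2)
    nh1 <- if (!is.null(r1)) a1$n_hits[r1[1]] else 0L
    nh2 <- if (!is.null(r2)) a2$n_hits[r2[1]] else 0L
    pairs$multi[i] <- max(nh1, nh2) > 1L
    if (!pairs$mapped[i]) next
    combos <- NULL
    for (j in r1) for (k in r2) {
      if (a1$replicon[j] != a2$replicon[k]) next
      if (a1$strand[j] == a2$strand[k]) next
      L <- lens[[a1$replicon[j]]]
      if (a1$strand[j] == "+") {
        fs <- a1$start[j]; re <- a2$end[k]
      } else {
        fs <- a2$start[k]; re <- a1$end[j]
      }
      ins <- (re - fs) %% L
      if (ins == 0) ins <- L
      if (ins < lo || ins > hi) next
      combos <- rbind(combos, data.frame(
        pair_id = pair_ids[i], replicon = a1$replicon[j],
        start1 = a1$start[j], end1 = a1$end[j],
        start2 = a2$start[k], end2 = a2$end[k],
        insert = ins, score = a1$score[j] + a2$score[k],
        stringsAsFactors = FALSE))
    }
    if (!is.null(combos) && nrow(combos)) {
      pairs$concordant[i] <- TRUE
      pairs$n_combos[i] <- nrow(combos)
      best <- which.max(combos$score)
      pairs$replicon[i] <- combos$replicon[best]
      pairs$insert[i] <- combos$insert[best]
      plc[[i]] <- combos
    }
  }
  placements <- do.call(rbind, plc)
  if (is.null(placements)) {
    placements <- data.frame(pair_id = character(0), replicon = character(0),
                             start1 = numeric(0), end1 = numeric(0),
                             start2 = numeric(0), end2 = numeric(0),
                             insert = numeric(0), score = numeric(0))
  }
  stats <- list(total_pairs = n,
                mapped_pairs = sum(pairs$mapped),
                concordant_pairs = sum(pairs$concordant),
                multimapped_pairs = sum(pairs$multi))
  structure(list(alignments = aln, pairs = pairs, placements = placements,
                 stats = stats, replicon_lengths = lens),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "alignment_set: %d pairs, %d mapped, %d concordant, %d multi-mapped\n",
    s$total_pairs, s$mapped_pairs, s$concordant_pairs, s$multimapped_pairs))
  invisible(x)
}

#' Write alignments and mapping statistics
#'
#' `write_alignments_tsv()` writes the per-mate alignment table as headered
#' TSV; `write_mapping_stats_json()` writes the pair-level statistics;
#' `write_alignments_sam()` emits minimal SAM-compatible records (mandatory
#' fields only, `@SQ` from the index).
#'
#' @param aln An `alignment_set`.
#' @param path Output path.
#' @param seed,hash Optional header metadata.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(aln, path, seed = NA, hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, hash), con)
  cols <- c("pair_id", "mate", "replicon", "start", "end", "strand",
            "score", "identity", "aligned_fraction", "n_hits", "cigar")
  utils::write.table(aln$alignments[, cols], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignments_tsv
#' @export
write_mapping_stats_json <- function(aln, path, seed = NA, hash = NA) {
  out <- c(aln$stats, list(arseq_version =
                             as.character(utils::packageVersion("arseq")),
                           seed = seed, config = hash))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_alignments_tsv
#' @export
write_alignments_sam <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (nm in names(aln$replicon_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm,
                       as.integer(aln$replicon_lengths[[nm]])), con)
  }
  a <- aln$alignments
  if (nrow(a)) {
    flag <- ifelse(a$strand == "-", 16L, 0L) +
      ifelse(a$mate == 1L, 64L, 128L) + 1L
    mapq <- ifelse(a$n_hits > 1L, 0L, 60L)
    L <- aln$replicon_lengths[a$replicon]
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                       a$pair_id, flag, a$replicon,
                       as.integer(a$start %% L) + 1L, mapq, a$cigar), con)
  }
  invisible(path)
}
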