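#' Simulate paired-end reads from a clone library
#'
#' Clones are sampled uniformly; a sequencing insert is placed uniformly
#' within the genomic fragment (the vector backbone is never emitted), mate
#' 1 is read from the insert 5' end on the fragment strand and mate 2 is
#' the reverse complement of the insert 3' end.  Substitution errors are
#' applied per base at the configured rate; indel errors are not modelled.
#' Truth coordinates (genome coordinates of both mates) are retained for
#' mapper validation.
#'
#' @param library A `clone_library`.
#' @param n_pairs Number of read pairs.
#' @param read_length Read length in bases; must not exceed the shortest
#'   fragment.
#' @param substitution_rate Per-base substitution probability.
#' @param insert_mean,insert_sd Insert size distribution (normal, rounded,
#'   clamped to `[read_length, fragment length]`).
#' @param seed Integer seed.
#' @return An object of class `read_pair_set`: list with `mate1`, `mate2`
#'   (character vectors), `truth` (data.frame with the source clone and the
#'   0-based genome coordinates of each mate), and the simulation
#'   parameters.
#' @export
simulate_reads <- function(library, n_pairs, read_length = 150L,
                           substitution_rate = 0.005,
                           insert_mean = 400L, insert_sd = 40L, seed = 1L) {
  stopifnot(inherits(library, "clone_library"), n_pairs >= 0,
            substitution_rate >= 0, substitution_rate < 1)
  read_length <- as.integer(read_length)
  clones <- library$clones
  if (n_pairs > 0 && !nrow(clones)) stop("library has no clones")
  if (n_pairs > 0 && read_length > min(clones$length)) {
    stop("read_length must not exceed the shortest fragment")
  }
  if (insert_mean < read_length) stop("insert_mean must be >= read_length")
  genome <- library$genome

  res <- with_seed(seed, {
    if (n_pairs == 0) {
      list(mate1 = character(0), mate2 = character(0),
           truth = data.frame(pair_id = character(0), clone = integer(0),
                              replicon = character(0),
                              insert_start = integer(0), insert_end = integer(0),
                              m1_start = integer(0), m1_end = integer(0),
                              m2_start = integer(0), m2_end = integer(0)))
    } else {
      ci <- sample.int(nrow(clones), n_pairs, replace = TRUE)
      flen <- clones$length[ci]
      ins <- as.integer(round(rnorm(n_pairs, insert_mean, insert_sd)))
      ins <- pmax(read_length, pmin(ins, flen))
      off <- as.integer(floor(runif(n_pairs) * (flen - ins + 1L)))
      g1 <- clones$start[ci] + off              # insert start, genome coords
      g2 <- g1 + ins                            # insert end
      L <- replicon_lengths(genome)[clones$replicon[ci]]
      m1 <- character(n_pairs); m2 <- character(n_pairs)
      # vectorised extraction on an origin-extended copy of each replicon
      s1 <- g1 %% L
      s2 <- (g2 - read_length) %% L
      for (nm in unique(clones$replicon[ci])) {
        sel <- clones$replicon[ci] == nm
        sq <- genome$replicons[[nm]]$sequence
        ext <- paste0(sq, substr(sq, 1L, read_length))
        m1[sel] <- substring(ext, s1[sel] + 1L, s1[sel] + read_length)
        m2[sel] <- substring(ext, s2[sel] + 1L, s2[sel] + read_length)
      }
      m2 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(m2)))
      if (substitution_rate > 0) {
        m1 <- add_substitutions(m1, substitution_rate)
        m2 <- add_substitutions(m2, substitution_rate)
      }
      truth <- data.frame(
        pair_id = sprintf("pair%06d", seq_len(n_pairs)),
        clone = ci, replicon = clones$replicon[ci],
        insert_start = as.integer(g1 %% L), insert_len = ins,
        m1_start = as.integer(g1 %% L),
        m1_end = as.integer(g1 %% L) + read_length,
        m2_start = as.integer((g2 - read_length) %% L),
        m2_end = as.integer((g2 - read_length) %% L) + read_length,
        row.names = NULL)
      list(mate1 = m1, mate2 = m2, truth = truth)
    }
  })
  structure(list(mate1 = res$mate1, mate2 = res$mate2, truth = res$truth,
                 read_length = read_length,
                 substitution_rate = substitution_rate,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 stage = library$stage, seed = seed),
            class = "read_pair_set")
}

# Vectorised substitution errors: each base replaced, with probability
# `rate`, by a base drawn uniformly from the three alternatives.
add_substitutions <- function(reads, rate) {
  if (!length(reads)) return(reads)
  rl <- nchar(reads[1])
  mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                nrow = rl)
  hit <- which(runif(length(mat)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    repl <- sample(bases, length(hit), replace = TRUE)
    same <- repl == mat[hit]
    while (any(same)) {  # redraw until the substitution changes the base
      repl[same] <- sample(bases, sum(same), replace = TRUE)
      same <- repl == mat[hit]
    }
    mat[hit] <- repl
  }
  apply(mat, 2, paste, collapse = "")
}

#' @export
print.read_pair_set <- function(x, ...) {
  cat(sprintf("read_pair_set: %d pairs, %d bp reads, substitution rate %g (stage %s)\n",
              length(x$mate1), x$read_length, x$substitution_rate,
              x$stage %||% "?"))
  invisible(x)
}

#' Write / read paired FASTQ
#'
#' Reads are written as standard 4-line FASTQ records with a fixed quality
#' character (`I`); base qualities are not modelled because the mapper
#' scores sequence only.
#'
#' @param reads A `read_pair_set`.
#' @param prefix Output prefix; files `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` are produced, plus `<prefix>_truth.json` with the
#'   truth sidecar.
#' @return Character vector of the two FASTQ paths, invisibly.
#' @export
write_fastq_pair <- function(reads, prefix) {
  stopifnot(inherits(reads, "read_pair_set"))
  write_one <- function(seqs, ids, path) {
    if (length(seqs)) {
      ss <- Biostrings::DNAStringSet(seqs)
      names(ss) <- ids
      Biostrings::writeXStringSet(
        ss, path, format = "fastq",
        qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
    } else {
      file.create(path)
    }
    path
  }
  ids <- if (length(reads$mate1)) reads$truth$pair_id else character(0)
  p1 <- write_one(reads$mate1, paste0(ids, "/1"), paste0(prefix, "_R1.fastq"))
  p2 <- write_one(reads$mate2, paste0(ids, "/2"), paste0(prefix, "_R2.fastq"))
  jsonlite::write_json(reads$truth, paste0(prefix, "_truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(c(p1, p2))
}

#' @rdname write_fastq_pair
#' @param r1,r2 Paths to the two mate FASTQ files.
#' @param read_length,insert_mean,insert_sd Metadata to attach (used for
#'   pairing during mapping).
#' @export
read_fastq_pair <- function(r1, r2, insert_mean = 400L, insert_sd = 40L,
                            read_length = NULL) {
  rd <- function(p) {
    if (file.size(p) == 0) return(Biostrings::DNAStringSet())
    Biostrings::readDNAStringSet(p, format = "fastq")
  }
  s1 <- rd(r1); s2 <- rd(r2)
  if (length(s1) != length(s2)) stop("mate files have different read counts")
  m1 <- as.character(s1); m2 <- as.character(s2)
  structure(list(mate1 = unname(m1), mate2 = unname(m2),
                 truth = NULL,
                 read_length = read_length %||%
                   (if (length(m1)) nchar(m1[1]) else 0L),
                 substitution_rate = NA_real_,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 stage = NA_character_, seed = NA_integer_),
            class = "read_pair_set")
}
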