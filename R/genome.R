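#' Describe one circular replicon of a synthetic genome
#'
#' A replicon descriptor holds everything `build_genome()` needs to realise
#' one circular chromosome or plasmid: its length, optional fixed sequence,
#' annotated ORFs, designated ARS loci (intervals whose full inclusion in a
#' cloned fragment confers autonomous replication), and verbatim internal
#' duplications such as the tandem repeat found on large cyanobacterial
#' plasmids.
#'
#' All coordinates are 0-based, half-open, on the forward strand.
#'
#' @param name Unique replicon identifier.
#' @param length Replicon length in bases.
#' @param is_chromosome Logical flag.
#' @param sequence Optional nucleotide string over A/C/G/T of length
#'   `length`; when `NULL` a random sequence is generated by
#'   [build_genome()].
#' @param orfs `data.frame` with columns `id`, `start`, `end`, `strand`
#'   (or `NULL`).
#' @param ars_loci `data.frame` with columns `id`, `start`, `end`
#'   (or `NULL`).
#' @param duplications `data.frame` with columns `src_start`, `src_end`,
#'   `dst_start` (or `NULL`); the destination segment is overwritten with a
#'   byte-identical copy of the source segment.
#' @return An object of class `replicon_spec`.
#' @export
replicon <- function(name, length, is_chromosome = FALSE, sequence = NULL,
                     orfs = NULL, ars_loci = NULL, duplications = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  length <- as.integer(length)
  stopifnot(length > 0L)
  empty_iv <- function(cols) {
    stats::setNames(as.data.frame(rep(list(integer(0)), length(cols))), cols)
  }
  orfs <- if (is.null(orfs)) {
    data.frame(id = character(0), start = integer(0), end = integer(0),
               strand = character(0))
  } else as.data.frame(orfs)
  ars_loci <- if (is.null(ars_loci)) {
    data.frame(id = character(0), start = integer(0), end = integer(0))
  } else as.data.frame(ars_loci)
  duplications <- if (is.null(duplications)) {
    empty_iv(c("src_start", "src_end", "dst_start"))
  } else as.data.frame(duplications)

  check_iv <- function(start, end, what) {
    if (any(!(start >= 0 & start < end & end <= length))) {
      stop(sprintf("%s intervals must satisfy 0 <= start < end <= length on '%s'",
                   what, name))
    }
  }
  if (nrow(orfs)) check_iv(orfs$start, orfs$end, "ORF")
  if (nrow(ars_loci)) check_iv(ars_loci$start, ars_loci$end, "ARS locus")
  if (nrow(duplications)) {
    dl <- duplications$src_end - duplications$src_start
    check_iv(duplications$src_start, duplications$src_end, "duplication source")
    check_iv(duplications$dst_start, duplications$dst_start + dl,
             "duplication destination")
    for (i in seq_len(nrow(duplications))) {
      s1 <- duplications$src_start[i]; e1 <- duplications$src_end[i]
      s2 <- duplications$dst_start[i]; e2 <- s2 + dl[i]
      if (s1 < e2 && s2 < e1) {
        stop("duplication source and destination overlap on '", name, "'")
      }
    }
  }
  if (!is.null(sequence)) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (nchar(sequence) != length) stop("sequence length must equal `length`")
    if (grepl("[^ACGTacgt]", sequence)) stop("sequence must be over A/C/G/T")
    sequence <- toupper(sequence)
  }
  structure(
    list(name = name, length = length, is_chromosome = isTRUE(is_chromosome),
         sequence = sequence, orfs = orfs, ars_loci = ars_loci,
         duplications = duplications),
    class = "replicon_spec")
}

#' Build a multi-replicon genome model
#'
#' Realises a set of [replicon()] descriptors into a genome: random
#' sequences are drawn for replicons without a fixed sequence, internal
#' duplications are applied by copying the source bytes over the
#' destination, and relative per-cell copy weights are attached.  The copy
#' weights model per-cell replicon abundance (chromosome vs high-copy
#' plasmids) and drive fragment-library sampling.
#'
#' @param replicons List of [replicon()] objects.
#' @param copy_weights Positive numeric vector, one per replicon (default
#'   all 1).
#' @param seed Integer seed for the random sequences.
#' @return An object of class `genome_model`: a list with elements
#'   `replicons` (named list, each with a realised `sequence`) and
#'   `copy_weights` (named numeric).
#' @examples
#' g <- build_genome(list(
#'   replicon("chr", 5000, is_chromosome = TRUE),
#'   replicon("pX", 3000, ars_loci = data.frame(id = "ars1", start = 500, end = 1500))
#' ), seed = 1)
#' replicon_lengths(g)
#' @export
build_genome <- function(replicons, copy_weights = NULL, seed = 1L) {
  if (inherits(replicons, "replicon_spec")) replicons <- list(replicons)
  stopifnot(length(replicons) >= 1L,
            all(vapply(replicons, inherits, TRUE, "replicon_spec")))
  nms <- vapply(replicons, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("replicon names must be unique")
  if (is.null(copy_weights)) copy_weights <- rep(1, length(replicons))
  stopifnot(length(copy_weights) == length(replicons), all(copy_weights > 0))
  reps <- with_seed(seed, {
    lapply(replicons, function(r) {
      if (is.null(r$sequence)) r$sequence <- random_dna(r$length)
      if (nrow(r$duplications)) {
        for (i in seq_len(nrow(r$duplications))) {
          src <- substr(r$sequence, r$duplications$src_start[i] + 1L,
                        r$duplications$src_end[i])
          dl <- nchar(src)
          substr(r$sequence, r$duplications$dst_start[i] + 1L,
                 r$duplications$dst_start[i] + dl) <- src
        }
      }
      r
    })
  })
  names(reps) <- nms
  structure(list(replicons = reps,
                 copy_weights = stats::setNames(as.numeric(copy_weights), nms)),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model with", length(x$replicons), "replicon(s)\n")
  for (r in x$replicons) {
    cat(sprintf("  %s: %d bp%s, %d ORF(s), %d ARS locus/loci, weight %.3g\n",
                r$name, r$length, if (r$is_chromosome) " (chromosome)" else "",
                nrow(r$orfs), nrow(r$ars_loci), x$copy_weights[[r$name]]))
  }
  invisible(x)
}

#' @rdname build_genome
#' @param genome A `genome_model`.
#' @export
replicon_lengths <- function(genome) {
  vapply(genome$replicons, `[[`, integer(1), "length")
}

#' Write genome model artifacts to disk
#'
#' `write_genome_fasta()` writes the realised sequences as FASTA;
#' `write_genome_gff3()` writes all ORF annotations as GFF3 (1-based,
#' closed intervals); `write_ars_bed()` writes the designated ARS loci as
#' BED (0-based, half-open).
#'
#' @param genome A `genome_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(genome$replicons, `[[`, "", "sequence"))
  names(seqs) <- names(genome$replicons)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

genome_granges <- function(genome, table, extra = list()) {
  rows <- do.call(rbind, lapply(genome$replicons, function(r) {
    tb <- r[[table]]
    if (!nrow(tb)) return(NULL)
    tb$replicon <- r$name
    tb
  }))
  if (is.null(rows)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    seqnames = rows$replicon,
    ranges = IRanges::IRanges(start = rows$start + 1L, end = rows$end),
    strand = if ("strand" %in% names(rows)) rows$strand else "*")
  names(gr) <- rows$id
  gr
}

#' @rdname write_genome_fasta
#' @export
write_genome_gff3 <- function(genome, path) {
  gr <- genome_granges(genome, "orfs")
  if (length(gr)) {
    gr$type <- "gene"
    gr$ID <- names(gr)
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
write_ars_bed <- function(genome, path) {
  gr <- genome_granges(genome, "ars_loci")
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

# Collected ORF annotations as one data.frame (0-based half-open).
genome_orfs <- function(genome) {
  out <- do.call(rbind, lapply(genome$replicons, function(r) {
    if (!nrow(r$orfs)) return(NULL)
    data.frame(replicon = r$name, r$orfs, row.names = NULL)
  }))
  if (is.null(out)) {
    out <- data.frame(replicon = character(0), id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0))
  }
  rownames(out) <- NULL
  out
}
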