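#' Per-replicon read-pair composition
#'
#' Computes the percentage of concordantly mapped pairs assigned to each
#' replicon, the screen's primary readout.  Under
#' `policy = "exclude_multimapped"` (how the before/after composition was
#' analysed), pairs with any multi-mapped mate are dropped from both
#' numerator and denominator.  Under `policy = "include_all"` each pair is
#' distributed fractionally, `1 / n` to each of its `n` concordant
#' placement combinations, so percentages still sum to 100.
#'
#' Composition counts pairs, not mates; single-mate mappings contribute to
#' coverage but not composition.
#'
#' @param aln An `alignment_set` from [map_library()].
#' @param genome A `genome_model` fixing the replicon universe (replicons
#'   with zero pairs are reported with 0), or `NULL` to use the mapping
#'   index's replicons.
#' @param policy `"exclude_multimapped"` or `"include_all"`.
#' @return An object of class `composition_table`: data.frame with columns
#'   `replicon`, `pairs`, `percent`, plus attributes `policy`, `stage`,
#'   `counted_pairs`.
#' @export
compute_composition <- function(aln, genome = NULL,
                                policy = c("exclude_multimapped",
                                           "include_all")) {
  stopifnot(inherits(aln, "alignment_set"))
  policy <- match.arg(policy)
  reps <- if (inherits(genome, "genome_model")) names(genome$replicons)
          else names(aln$replicon_lengths)
  counts <- stats::setNames(numeric(length(reps)), reps)
  p <- aln$pairs
  if (policy == "exclude_multimapped") {
    keep <- p$concordant & !p$multi
    tab <- table(p$replicon[keep])
    counts[names(tab)] <- as.numeric(tab)
  } else {
    pl <- aln$placements
    keep_ids <- p$pair_id[p$concordant]
    pl <- pl[pl$pair_id %in% keep_ids, , drop = FALSE]
    if (nrow(pl)) {
      w <- 1 / table(pl$pair_id)[pl$pair_id]
      agg <- tapply(as.numeric(w), pl$replicon, sum)
      counts[names(agg)] <- as.numeric(agg)
    }
  }
  denom <- sum(counts)
  if (denom == 0) stop("empty composition: no counted pairs under policy '",
                       policy, "'")
  out <- data.frame(replicon = reps, pairs = as.numeric(counts),
                    percent = 100 * as.numeric(counts) / denom,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, policy = policy, counted_pairs = denom,
            class = c("composition_table", "data.frame"))
}

#' Per-base coverage tracks
#'
#' Depth is incremented over every aligned mate interval (both mates,
#' including mates of non-concordant pairs).  `include_all` counts every
#' emitted placement of multi-mapped mates (the view used to inspect
#' duplicated regions); `exclude_multimapped` counts uniquely mapped mates
#' only.  Intervals wrapping the circular origin are split.
#'
#' @param aln An `alignment_set`.
#' @param genome A `genome_model` or `NULL` (replicon universe from the
#'   index).
#' @param policy `"include_all"` or `"exclude_multimapped"`.
#' @return An object of class `coverage_set`: named list of integer depth
#'   vectors (one per replicon, length = replicon length), with attributes
#'   `policy` and `total_aligned_bases` (sum over the whole library under
#'   the policy).
#' @export
compute_coverage <- function(aln, genome = NULL,
                             policy = c("include_all",
                                        "exclude_multimapped")) {
  stopifnot(inherits(aln, "alignment_set"))
  policy <- match.arg(policy)
  lens <- aln$replicon_lengths
  a <- aln$alignments
  if (policy == "exclude_multimapped") a <- a[a$n_hits == 1L, , drop = FALSE]
  tracks <- lapply(lens, function(L) integer(L))
  for (nm in names(lens)) {
    rows <- which(a$replicon == nm)
    if (!length(rows)) next
    L <- lens[[nm]]
    st <- a$start[rows] %% L
    en <- st + (a$end[rows] - a$start[rows])
    wrap <- en > L
    # difference-array accumulation of [start, end) increments
    starts <- c(st[!wrap], st[wrap], rep(0L, sum(wrap)))
    ends <- c(en[!wrap], rep(L, sum(wrap)), en[wrap] - L)
    delta <- tabulate(starts + 1L, nbins = L + 1L) -
      tabulate(ends + 1L, nbins = L + 1L)
    tracks[[nm]] <- as.integer(cumsum(delta[seq_len(L)]))
  }
  total <- sum(a$end - a$start)
  structure(tracks, policy = policy, total_aligned_bases = total,
            class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat(sprintf("coverage_set (%s): %d replicon(s), %g aligned bases\n",
              attr(x, "policy"), length(x), attr(x, "total_aligned_bases")))
  for (nm in names(x)) {
    cat(sprintf("  %s: mean depth %.2f, max %d\n", nm, mean(x[[nm]]),
                max(x[[nm]])))
  }
  invisible(x)
}

#' Write composition / coverage artifacts
#'
#' @param x A `composition_table` or `coverage_set`.
#' @param path Output path (for bedGraph, one file for all replicons).
#' @param stage Optional stage label written into the TSV.
#' @param seed,hash Optional header metadata.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(x, path, stage = NA, seed = NA, hash = NA) {
  stopifnot(inherits(x, "composition_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, hash), con)
  df <- data.frame(stage = stage, as.data.frame(x),
                   policy = attr(x, "policy"))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_composition_tsv
#' @export
write_bedgraph <- function(x, path, seed = NA, hash = NA) {
  stopifnot(inherits(x, "coverage_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, hash), con)
  writeLines("track type=bedGraph name=coverage", con)
  for (nm in names(x)) {
    r <- rle(x[[nm]])
    en <- cumsum(r$lengths)           # 0-based half-open runs
    st <- en - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%d", nm, st[keep], en[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}
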