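#' Windowed enrichment profile of the selected over the starting library
#'
#' Coverage tracks are normalised to depth per million aligned bases of
#' their library, averaged per window, and compared as
#' `log2((covC + eps) / (covA + eps))` with a pseudocount `eps` on the
#' per-million scale.  Windows empty in both libraries therefore score 0.
#'
#' @param covC,covA `coverage_set` objects from [compute_coverage()] for the
#'   selected (C) and starting (A) libraries, built on the same genome.
#' @param replicon Replicon name to profile.
#' @param window Window size in bases (last window may be short).
#' @param eps Pseudocount, in depth-per-million units.
#' @return An object of class `enrichment_profile`: data.frame with columns
#'   `start`, `end`, `score`, `covC_norm`, `covA_norm`, plus attributes
#'   `replicon` and `window`.
#' @export
enrichment_profile <- function(covC, covA, replicon, window = 200L,
                               eps = 1) {
  stopifnot(inherits(covC, "coverage_set"), inherits(covA, "coverage_set"))
  if (!replicon %in% names(covC) || !replicon %in% names(covA)) {
    stop("replicon '", replicon, "' absent from a coverage set")
  }
  dC <- covC[[replicon]]; dA <- covA[[replicon]]
  if (length(dC) != length(dA)) {
    stop("coverage tracks disagree on replicon length; were they built on ",
         "the same genome?")
  }
  nC <- dC * 1e6 / max(attr(covC, "total_aligned_bases"), 1)
  nA <- dA * 1e6 / max(attr(covA, "total_aligned_bases"), 1)
  L <- length(dC)
  win_id <- (seq_len(L) - 1L) %/% window
  mC <- tapply(nC, win_id, mean)
  mA <- tapply(nA, win_id, mean)
  starts <- as.integer(sort(unique(win_id))) * window
  out <- data.frame(start = starts,
                    end = pmin(starts + window, L),
                    covC_norm = as.numeric(mC), covA_norm = as.numeric(mA),
                    score = log2((as.numeric(mC) + eps) /
                                 (as.numeric(mA) + eps)),
                    row.names = NULL)
  structure(out, replicon = replicon, window = as.integer(window), eps = eps,
            class = c("enrichment_profile", "data.frame"))
}

#' Call candidate autonomous-replication regions
#'
#' Maximal runs of windows with enrichment score at or above `threshold`
#' are merged (tolerating gaps of one window), and each merged region
#' retains only the ORFs that lie fully inside it and whose every base
#' reaches depth `min_depth` in the selected library ("full-length ORF
#' present in the selected reads").  Regions with no such ORF are dropped.
#'
#' @param profile An [enrichment_profile()].
#' @param covC The selected library's `coverage_set` (raw depth used for the
#'   full-coverage rule).
#' @param orfs ORF annotations: data.frame with columns `replicon`, `id`,
#'   `start`, `end` (0-based half-open), e.g. from a `genome_model`.
#' @param min_depth Minimum per-base depth for an ORF to count as fully
#'   covered.
#' @param threshold Enrichment threshold in log2 units.
#' @return data.frame of class `ars_candidates` with columns `replicon`,
#'   `start`, `end`, `mean_enrichment`, `covered_orfs` (comma-separated
#'   ids), `n_orfs`.  Zero rows when nothing qualifies.
#' @export
call_ars_candidates <- function(profile, covC, orfs, min_depth = 5L,
                                threshold = 2) {
  stopifnot(inherits(profile, "enrichment_profile"),
            inherits(covC, "coverage_set"))
  rep_nm <- attr(profile, "replicon")
  depth <- covC[[rep_nm]]
  orfs <- orfs[orfs$replicon == rep_nm, , drop = FALSE]
  empty <- data.frame(replicon = character(0), start = integer(0),
                      end = integer(0), mean_enrichment = numeric(0),
                      covered_orfs = character(0), n_orfs = integer(0))
  class(empty) <- c("ars_candidates", "data.frame")
  hot <- is.finite(profile$score) & profile$score >= threshold
  if (!any(hot)) return(empty)
  # merge hot windows, tolerating single-window gaps
  idx <- which(hot)
  grp <- cumsum(c(1, diff(idx) > 2))
  out <- NULL
  for (g in unique(grp)) {
    wins <- idx[grp == g]
    reg_start <- profile$start[min(wins)]
    reg_end <- profile$end[max(wins)]
    mean_enr <- mean(profile$score[seq(min(wins), max(wins))])
    if (nrow(orfs)) {
      inside <- orfs$start >= reg_start & orfs$end <= reg_end
      covered <- vapply(which(inside), function(o) {
        all(depth[(orfs$start[o] + 1L):orfs$end[o]] >= min_depth)
      }, TRUE)
      ids <- orfs$id[inside][covered]
    } else ids <- character(0)
    if (!length(ids)) next
    out <- rbind(out, data.frame(
      replicon = rep_nm, start = reg_start, end = reg_end,
      mean_enrichment = mean_enr,
      covered_orfs = paste(ids, collapse = ","),
      n_orfs = length(ids), stringsAsFactors = FALSE))
  }
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  class(out) <- c("ars_candidates", "data.frame")
  out
}

#' Write candidate regions
#'
#' BED output is 0-based half-open; GFF3 output is 1-based closed.
#'
#' @param cands An `ars_candidates` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates_bed <- function(cands, path) {
  gr <- candidates_granges(cands)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_candidates_bed
#' @export
write_candidates_gff3 <- function(cands, path) {
  gr <- candidates_granges(cands)
  if (length(gr)) {
    gr$type <- "region"
    gr$ID <- names(gr)
    gr$covered_orfs <- cands$covered_orfs
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

candidates_granges <- function(cands) {
  if (!nrow(cands)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    cands$replicon,
    IRanges::IRanges(start = cands$start + 1L, end = cands$end),
    score = cands$mean_enrichment)
  names(gr) <- sprintf("ars_candidate_%d", seq_len(nrow(cands)))
  gr
}

#' @rdname write_candidates_bed
#' @param profile An `enrichment_profile` to dump alongside scores.
#' @param seed,hash Optional header metadata.
#' @export
write_enrichment_tsv <- function(profile, path, seed = NA, hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, hash), con)
  df <- data.frame(replicon = attr(profile, "replicon"),
                   as.data.frame(profile))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
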