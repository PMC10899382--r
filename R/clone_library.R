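#' Configuration of the fragment clone libraries
#'
#' Defaults mirror the screen that motivated the package: 1.5-2.5 kbp
#' genomic fragments, 2.5e4 clones in the starting library (A), 6.3e3
#' surviving the host-transformation bottleneck (B), and 456 recovered
#' after plasmid re-isolation in the secondary host (C).
#' `background_fraction_b` is the share of Library B drawn from the bulk
#' genome rather than from replicating plasmids; it models chromosomally
#' integrated clones plus genomic carry-over in the extracted DNA.
#'
#' @param fragment_min,fragment_max Fragment length bounds (bases).
#' @param n_clones_a,n_clones_b,n_clones_c Clone counts per stage.
#' @param background_fraction_b Fraction in `[0, 1]`.
#' @return An object of class `library_config`.
#' @export
library_config <- function(fragment_min = 1500L, fragment_max = 2500L,
                           n_clones_a = 25000L, n_clones_b = 6300L,
                           n_clones_c = 456L, background_fraction_b = 0.5) {
  fragment_min <- as.integer(fragment_min); fragment_max <- as.integer(fragment_max)
  stopifnot(fragment_min > 0L, fragment_min <= fragment_max,
            n_clones_a >= n_clones_b, n_clones_b >= n_clones_c, n_clones_c >= 0,
            background_fraction_b >= 0, background_fraction_b <= 1)
  structure(list(fragment_min = fragment_min, fragment_max = fragment_max,
                 n_clones_a = as.integer(n_clones_a),
                 n_clones_b = as.integer(n_clones_b),
                 n_clones_c = as.integer(n_clones_c),
                 background_fraction_b = background_fraction_b),
            class = "library_config")
}

# Does each fragment [start, start+len) fully contain some ARS locus of its
# replicon?  Fragments live on circular replicons and may wrap the origin.
fragment_carries_ars <- function(rep_spec, start, len) {
  if (!nrow(rep_spec$ars_loci)) return(rep(FALSE, length(start)))
  L <- rep_spec$length
  out <- len >= L  # a fragment spanning the whole circle contains everything
  for (i in seq_len(nrow(rep_spec$ars_loci))) {
    a <- rep_spec$ars_loci$start[i]
    b <- rep_spec$ars_loci$end[i]
    out <- out | circular_contains(start, start + len, a, b, L)
  }
  out
}

new_clone_library <- function(stage, clones, genome) {
  structure(list(stage = stage, clones = clones, genome = genome),
            class = "clone_library")
}

#' @export
print.clone_library <- function(x, ...) {
  cat(sprintf("clone_library stage %s: %d clone(s), %.1f%% ARS-bearing\n",
              x$stage, nrow(x$clones),
              if (nrow(x$clones)) 100 * mean(x$clones$carries_ars) else 0))
  print(table(x$clones$replicon))
  invisible(x)
}

#' Draw the starting fragment library (stage A)
#'
#' Fragments model random digestion of bulk genomic DNA: the source
#' replicon is chosen proportional to copy weight times length, fragment
#' length is uniform on `[fragment_min, fragment_max]`, and the start is
#' uniform on the circular replicon (fragments may wrap the origin).
#' Replicons shorter than `fragment_min` cannot yield a fragment and are
#' excluded from sampling with a warning.
#'
#' @param genome A `genome_model` from [build_genome()].
#' @param config A [library_config()].
#' @param seed Integer seed.
#' @return A `clone_library` (stage "A") whose `clones` data.frame has
#'   columns `replicon`, `start`, `end` (0-based half-open; `end` may
#'   exceed the replicon length when the fragment wraps the origin),
#'   `length`, `carries_ars`, `stage`.
#' @export
make_library_a <- function(genome, config = library_config(), seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "library_config"))
  lens <- replicon_lengths(genome)
  eligible <- lens >= config$fragment_min
  if (!any(eligible)) stop("no replicon is long enough to yield a fragment")
  if (any(!eligible)) {
    warning("replicon(s) shorter than fragment_min excluded from sampling: ",
            paste(names(lens)[!eligible], collapse = ", "))
  }
  w <- genome$copy_weights[eligible] * lens[eligible]
  n <- config$n_clones_a
  clones <- with_seed(seed, {
    rep_idx <- sample(names(lens)[eligible], n, replace = TRUE, prob = w / sum(w))
    len <- sample(seq(config$fragment_min, config$fragment_max), n, replace = TRUE)
    # fragment length is capped by the replicon size on short replicons
    len <- pmin(len, lens[rep_idx])
    start <- floor(runif(n) * lens[rep_idx])
    carries <- logical(n)
    for (nm in unique(rep_idx)) {
      sel <- rep_idx == nm
      carries[sel] <- fragment_carries_ars(genome$replicons[[nm]],
                                           start[sel], len[sel])
    }
    data.frame(replicon = rep_idx, start = as.integer(start),
               end = as.integer(start + len), length = as.integer(len),
               carries_ars = carries, stage = "A", row.names = NULL)
  })
  new_clone_library("A", clones, genome)
}

#' Pass a clone library through a selection bottleneck
#'
#' Models the two bottlenecks of the screen.  `A -> B` (host
#' transformation): a fraction `1 - background_fraction_b` of the
#' `n_clones_b` survivors is drawn (with replacement) from ARS-bearing
#' clones, which persist as replicating plasmids; the remaining
#' `background_fraction_b` share is drawn from the bulk library, modelling
#' chromosomally integrated material and genomic carry-over in the
#' extracted DNA.  `B -> C` (plasmid re-isolation in the secondary host):
#' `n_clones_c` clones are drawn only from ARS-bearing survivors, so stage
#' C is pure by construction.
#'
#' @param library A `clone_library` at the preceding stage.
#' @param target_stage `"B"` or `"C"`.
#' @param config A [library_config()].
#' @param seed Integer seed.
#' @return A `clone_library` at `target_stage`.
#' @export
apply_selection <- function(library, target_stage = c("B", "C"),
                            config = library_config(), seed = 1L) {
  stopifnot(inherits(library, "clone_library"))
  target_stage <- match.arg(target_stage)
  from <- library$stage
  if (!(identical(from, "A") && target_stage == "B") &&
      !(identical(from, "B") && target_stage == "C")) {
    stop("only stage transitions A->B and B->C are defined")
  }
  clones <- library$clones
  ars_rows <- which(clones$carries_ars)
  picked <- with_seed(seed, {
    if (target_stage == "B") {
      n <- config$n_clones_b
      n_bg <- round(config$background_fraction_b * n)
      if (!length(ars_rows)) n_bg <- n  # nothing replicates; all carry-over
      n_ars <- n - n_bg
      idx <- integer(0)
      if (n_ars > 0) {
        idx <- c(idx, ars_rows[sample.int(length(ars_rows), n_ars, replace = TRUE)])
      }
      if (n_bg > 0) idx <- c(idx, sample.int(nrow(clones), n_bg, replace = TRUE))
      idx[sample.int(length(idx))]  # shuffle
    } else {
      if (config$n_clones_c == 0L) {
        integer(0)
      } else {
        if (!length(ars_rows)) {
          stop("empty selection: no ARS-bearing clone available for stage C")
        }
        ars_rows[sample.int(length(ars_rows), config$n_clones_c,
                            replace = TRUE)]
      }
    }
  })
  out <- clones[picked, , drop = FALSE]
  out$stage <- rep(target_stage, nrow(out))
  rownames(out) <- NULL
  new_clone_library(target_stage, out, library$genome)
}
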