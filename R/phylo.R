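#' Pairwise p-distances with pairwise deletion
#'
#' For each sequence pair, alignment columns where either sequence carries
#' a gap (`-`) or an ambiguous residue are excluded (pairwise deletion);
#' the p-distance is the fraction of remaining columns that differ.  Only
#' the 20 canonical amino acids count as unambiguous; `X`, `B`, `Z`, `U`,
#' `O`, `*` and `.` all trigger deletion.
#'
#' @param msa Named character vector of aligned sequences (equal lengths),
#'   or a `Biostrings::AAStringSet`, or a path to an aligned FASTA file.
#' @return List with `p` (symmetric matrix of p-distances) and `sites`
#'   (matrix of per-pair usable-site counts).
#' @examples
#' pairwise_p_distance(c(a = "ACDEF", b = "ACDEY"))$p["a", "b"]  # 0.2
#' @export
pairwise_p_distance <- function(msa) {
  msa <- as_msa(msa)
  n <- length(msa)
  stopifnot(n >= 2L)
  ids <- names(msa)
  rows <- strsplit(toupper(msa), "", fixed = TRUE)
  len <- unique(lengths(rows))
  if (length(len) != 1L) stop("aligned sequences must have equal length")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ok <- lapply(rows, function(r) r %in% aa)
  p <- matrix(0, n, n, dimnames = list(ids, ids))
  sites <- matrix(len, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      use <- ok[[i]] & ok[[j]]
      ns <- sum(use)
      if (ns == 0L) {
        stop("no usable sites for pair '", ids[i], "' / '", ids[j],
             "' after pairwise deletion")
      }
      mism <- sum(rows[[i]][use] != rows[[j]][use])
      p[i, j] <- p[j, i] <- mism / ns
      sites[i, j] <- sites[j, i] <- ns
    }
  }
  list(p = p, sites = sites)
}

as_msa <- function(msa) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa)) {
    msa <- Biostrings::readAAStringSet(msa)
  }
  if (methods::is(msa, "XStringSet")) {
    msa <- stats::setNames(as.character(msa), sub("\\s.*$", "", names(msa)))
  }
  stopifnot(is.character(msa))
  if (is.null(names(msa))) names(msa) <- paste0("seq", seq_along(msa))
  msa
}

#' Poisson correction of a proportion of differing sites
#'
#' Converts an observed proportion of differing sites into the expected
#' number of substitutions per site under a Poisson model of substitution:
#' `d = -ln(1 - p)`.  Monotone increasing and always `>= p`.
#'
#' @param p Proportion(s) in `[0, 1)`.
#' @return Distance(s), same length as `p`.
#' @examples
#' poisson_correct(0.5)  # log(2)
#' @export
poisson_correct <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p >= 1)) {
    stop("undefined distance: p must lie in [0, 1)")
  }
  -log(1 - p)
}

#' Poisson-corrected distance matrix from an alignment
#'
#' Convenience wrapper: [pairwise_p_distance()] followed by
#' [poisson_correct()].
#'
#' @inheritParams pairwise_p_distance
#' @return Symmetric numeric matrix of distances (substitutions per site)
#'   with a `sites` attribute carrying the usable-site counts.
#' @export
poisson_distance <- function(msa) {
  pd <- pairwise_p_distance(msa)
  d <- poisson_correct(pd$p)
  attr(d, "sites") <- pd$sites
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration on the Q-criterion.  At each step the
#' pair minimising `Q(i, j) = (n - 2) d(i, j) - r_i - r_j` is joined (ties
#' broken by the smallest `(i, j)` index pair); branch lengths to the new
#' node follow the usual three-point formulas and negative estimates are
#' clamped to zero.  The final three lineages are joined at a trifurcating
#' root, so the result is an unrooted tree.  Exact on additive matrices.
#' Branch lengths are serialized at full double precision (well above the
#' six significant digits the Newick output guarantees).
#'
#' @param dm Symmetric distance matrix with row/column names (e.g. from
#'   [poisson_distance()]), or a `dist` object.
#' @return An object of class `nj_tree`: list with `newick` (string,
#'   branch lengths at 8 significant digits) and `labels`.
#' @examples
#' d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' nj_tree(d)$newick
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 3L) stop("at least 3 taxa are required")
  if (any(!is.finite(dm)) || any(dm < 0)) stop("invalid distance matrix")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  labels <- rownames(dm) %||% paste0("t", seq_len(n))
  # `node` holds the growing Newick fragment for each active lineage
  node <- labels
  D <- dm
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # smallest (i, j), i < j, in row-major scan order on ties
    best <- c(NA_integer_, NA_integer_); bq <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        if (Q[i, j] < bq - 1e-12) {
          bq <- Q[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    merged <- sprintf("(%s:%s,%s:%s)", node[i], fmt(vi), node[j], fmt(vj))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    node <- c(node[keep], merged)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
  }
  # trifurcating root over the last three lineages
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", node[1], fmt(v1),
                    node[2], fmt(v2), node[3], fmt(v3))
  structure(list(newick = newick, labels = labels), class = "nj_tree")
}

#' @export
print.nj_tree <- function(x, ...) {
  cat("nj_tree over", length(x$labels), "taxa\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Write tree / distance matrix artifacts
#'
#' @param tree An `nj_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "nj_tree"))
  writeLines(tree$newick, path)
  invisible(path)
}

#' @rdname write_newick
#' @param d Distance matrix (e.g. from [poisson_distance()]).
#' @param format `"tsv"` (headered, tab-separated) or `"phylip"` (square
#'   PHYLIP).
#' @export
write_distance_matrix <- function(d, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "phylip") {
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d))) {
      writeLines(paste(c(sprintf("%-10s", rownames(d)[i]),
                         sprintf("%.6f", d[i, ])), collapse = "  "), con)
    }
  } else {
    df <- data.frame(id = rownames(d), as.data.frame(d),
                     check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
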