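# Shared fixtures: all test data is generated in code.

# Desk-scale three-replicon genome: one chromosome, one plasmid carrying a
# single ARS locus that fully contains one ORF, one ARS-free control
# plasmid.
test_genome <- function(seed = 5, ars = TRUE) {
  reps <- list(
    replicon("chr", 20000, is_chromosome = TRUE),
    replicon("pARS", 8000,
             orfs = data.frame(id = "repX", start = 3100, end = 4500,
                               strand = "+"),
             ars_loci = if (ars) {
               data.frame(id = "ars1", start = 3000, end = 4600)
             } else NULL),
    replicon("pCTL", 8000)
  )
  build_genome(reps, seed = seed)
}

# Library bottlenecks scaled down 10x from the screen's 25000/6300/456.
test_library_config <- function(n_clones_a = 2500, n_clones_b = 630,
                                n_clones_c = 46, ...) {
  library_config(n_clones_a = n_clones_a, n_clones_b = n_clones_b,
                 n_clones_c = n_clones_c, ...)
}

# Genome with a tandem byte-identical duplication (the multi-mapping case).
dup_genome <- function(seed = 11) {
  build_genome(list(
    replicon("pDUP", 12000,
             duplications = data.frame(src_start = 1000, src_end = 4000,
                                       dst_start = 7000))
  ), seed = seed)
}

# Exhaustive alignment oracle, independent of the mapper: full
# (unbanded, unseeded) glocal dynamic programming over every position of
# the reference and both strands, under the same score scheme
# (match +1, mismatch -mismatch_cost, gap column -indel_cost).  Returns
# all co-optimal placements as (strand, start, end, score).
oracle_map_read <- function(read, ref, match = 1, mismatch = 2, indel = 3) {
  revcomp <- function(x) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
  }
  one_strand <- function(rd) {
    r <- strsplit(rd, "", fixed = TRUE)[[1]]
    s <- strsplit(ref, "", fixed = TRUE)[[1]]
    m <- length(r); w <- length(s)
    dp <- matrix(0, m + 1, w + 1)
    mv <- matrix(0L, m + 1, w + 1)
    dp[1, ] <- 0
    for (i in 1:m) {
      dp[i + 1, 1] <- -indel * i
      mv[i + 1, 1] <- 2L
      sub <- ifelse(s == r[i], match, -mismatch)
      for (j in 1:w) {
        sd <- dp[i, j] + sub[j]
        su <- dp[i, j + 1] - indel
        sl <- dp[i + 1, j] - indel
        if (sd >= su && sd >= sl) {
          dp[i + 1, j + 1] <- sd; mv[i + 1, j + 1] <- 1L
        } else if (su >= sl) {
          dp[i + 1, j + 1] <- su; mv[i + 1, j + 1] <- 2L
        } else {
          dp[i + 1, j + 1] <- sl; mv[i + 1, j + 1] <- 3L
        }
      }
    }
    best <- max(dp[m + 1, ])
    ends <- which(dp[m + 1, ] == best) - 1L
    res <- NULL
    for (e in ends) {
      i <- m; j <- e
      repeat {
        if (i == 0) break
        mm <- mv[i + 1, j + 1]
        if (mm == 1L) { i <- i - 1; j <- j - 1 }
        else if (mm == 2L) { i <- i - 1 }
        else { j <- j - 1 }
      }
      res <- rbind(res, data.frame(start = j, end = e, score = best))
    }
    unique(res)
  }
  fwd <- one_strand(read)
  rev <- one_strand(revcomp(read))
  out <- rbind(
    if (!is.null(fwd)) cbind(strand = "+", fwd),
    if (!is.null(rev)) cbind(strand = "-", rev))
  best <- max(out$score)
  out <- out[out$score == best, , drop = FALSE]
  out[order(out$strand, out$start), , drop = FALSE]
}

# Build a minimal alignment_set by hand (documented structure) for
# composition/coverage arithmetic tests.
manual_alignment_set <- function(pairs, placements, alignments,
                                 replicon_lengths) {
  structure(list(alignments = alignments, pairs = pairs,
                 placements = placements,
                 stats = list(total_pairs = nrow(pairs),
                              mapped_pairs = sum(pairs$mapped),
                              concordant_pairs = sum(pairs$concordant),
                              multimapped_pairs = sum(pairs$multi)),
                 replicon_lengths = replicon_lengths),
            class = "alignment_set")
}

# Least-squares branch lengths for a fixed unrooted topology given a
# distance matrix; returns the residual sum of squares.  Used as the
# exhaustive-topology oracle at n = 5.
ls_fit_rss <- function(tree, d) {
  # tree: ape "phylo"; d: symmetric matrix with matching tip labels
  n <- length(tree$tip.label)
  E <- nrow(tree$edge)
  pairs <- t(combn(n, 2))
  X <- matrix(0, nrow(pairs), E)
  y <- numeric(nrow(pairs))
  # edges on the path between two tips, via node paths to the root
  anc_path <- function(node) {
    path <- integer(0)
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (!length(e)) break
      path <- c(path, e)
      node <- tree$edge[e, 1]
    }
    path
  }
  paths <- lapply(seq_len(n), anc_path)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    eij <- c(setdiff(paths[[i]], paths[[j]]), setdiff(paths[[j]], paths[[i]]))
    X[r, eij] <- 1
    y[r] <- d[tree$tip.label[i], tree$tip.label[j]]
  }
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# Parse an nj_tree's Newick with ape and return path-length (cophenetic)
# matrix ordered by label.
nj_cophenetic <- function(tree) {
  ph <- ape::read.tree(text = tree$newick)
  cm <- ape::cophenetic.phylo(ph)
  cm[order(rownames(cm)), order(colnames(cm))]
}

# Unrooted topology equality via Robinson-Foulds distance.
same_topology <- function(newick1, newick2) {
  t1 <- ape::unroot(ape::read.tree(text = newick1))
  t2 <- ape::unroot(ape::read.tree(text = newick2))
  isTRUE(all.equal(ape::dist.topo(t1, t2)[1], 0, check.attributes = FALSE))
}
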