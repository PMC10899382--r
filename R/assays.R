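#' Simulate a droplet digital PCR assay
#'
#' Each droplet is positive for a channel independently with probability
#' `1 - exp(-lambda)`, the zero-truncation of a Poisson partition of
#' template molecules over droplets.  Target and reference channels are
#' treated as independent (two-probe design; dual positivity carries no
#' extra information under this model).
#'
#' @param true_lambda_target,true_lambda_reference True mean copies per
#'   droplet for the two channels (non-negative).
#' @param n_droplets Number of droplets (>= 1).
#' @param seed Integer seed.
#' @return An object of class `droplet_assay` with the positive counts and
#'   the simulation truth.
#' @examples
#' a <- simulate_droplets(0.341, 0.01, 20000, seed = 7)
#' a$n_positive_target / a$n_droplets  # about 1 - exp(-0.341)
#' @export
simulate_droplets <- function(true_lambda_target, true_lambda_reference,
                              n_droplets, seed = 1L) {
  stopifnot(true_lambda_target >= 0, true_lambda_reference >= 0,
            n_droplets >= 1)
  n_droplets <- as.integer(n_droplets)
  counts <- with_seed(seed, {
    c(t = rbinom(1L, n_droplets, 1 - exp(-true_lambda_target)),
      r = rbinom(1L, n_droplets, 1 - exp(-true_lambda_reference)))
  })
  structure(list(n_droplets = n_droplets,
                 n_positive_target = unname(counts["t"]),
                 n_positive_reference = unname(counts["r"]),
                 true_lambda_target = true_lambda_target,
                 true_lambda_reference = true_lambda_reference),
            class = "droplet_assay")
}

#' Simulate a flow-cytometry fluorescence histogram
#'
#' Each cell's fluorescence is `copies * unit_signal * noise` where `noise`
#' is lognormal with unit mean and coefficient of variation `cv`; the
#' standard population (one chromosome copy per cell, e.g. cells starved to
#' a single chromosome) is simulated with `standard = TRUE`.  Fluorescence
#' is binned on a fixed grid of width `unit_signal / 10`.
#'
#' @param copies Integer vector of possible chromosome copy numbers per
#'   cell (positive).
#' @param probs Probabilities for `copies` (default uniform).
#' @param n_cells Number of cells (>= 1).
#' @param cv Coefficient of variation of the multiplicative noise (> 0).
#' @param standard If `TRUE`, all cells carry one copy.
#' @param unit_signal Fluorescence units per chromosome copy.
#' @param seed Integer seed.
#' @return An object of class `fluorescence_histogram`: list with
#'   `bin_edges`, `counts`, `label`.
#' @export
simulate_fcm <- function(copies, probs = NULL, n_cells = 10000L, cv = 0.1,
                         standard = FALSE, unit_signal = 100, seed = 1L) {
  stopifnot(n_cells >= 1, cv > 0, unit_signal > 0)
  if (standard) {
    copies <- 1L
    probs <- 1
  }
  copies <- as.integer(copies)
  stopifnot(all(copies >= 1))
  if (is.null(probs)) probs <- rep(1 / length(copies), length(copies))
  stopifnot(length(probs) == length(copies), all(probs >= 0), sum(probs) > 0)
  sdlog <- sqrt(log(1 + cv^2))
  fl <- with_seed(seed, {
    cp <- copies[sample.int(length(copies), n_cells, replace = TRUE,
                            prob = probs)]
    noise <- exp(rnorm(n_cells, -sdlog^2 / 2, sdlog))  # unit-mean lognormal
    cp * unit_signal * noise
  })
  bw <- unit_signal / 10
  edges <- seq(0, (floor(max(fl) / bw) + 1) * bw, by = bw)
  counts <- as.integer(table(cut(fl, edges, right = FALSE)))
  structure(list(bin_edges = edges, counts = counts,
                 label = if (standard) "standard" else "sample"),
            class = "fluorescence_histogram")
}

#' @export
print.fluorescence_histogram <- function(x, ...) {
  cat(sprintf("fluorescence_histogram (%s): %d cells in %d bins\n",
              x$label, sum(x$counts), length(x$counts)))
  invisible(x)
}

#' Write droplet counts / histograms as TSV
#'
#' @param x A `droplet_assay` or `fluorescence_histogram`.
#' @param path Output path.
#' @param seed,hash Optional header metadata.
#' @return `path`, invisibly.
#' @export
write_assay_tsv <- function(x, path, seed = NA, hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, hash), con)
  if (inherits(x, "droplet_assay")) {
    df <- data.frame(channel = c("target", "reference"),
                     n_droplets = x$n_droplets,
                     n_positive = c(x$n_positive_target,
                                    x$n_positive_reference))
  } else if (inherits(x, "fluorescence_histogram")) {
    df <- data.frame(bin_start = head(x$bin_edges, -1),
                     bin_end = x$bin_edges[-1],
                     count = x$counts, label = x$label)
  } else stop("unsupported object")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
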