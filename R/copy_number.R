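#' Poisson estimate of copies per droplet
#'
#' In droplet digital PCR, template molecules partition over droplets
#' approximately Poisson, so the mean copies per droplet is recovered from
#' the fraction of positive droplets as `lambda = -ln(1 - p)` with
#' `p = n_positive / n_droplets`.  The standard error follows by the delta
#' method: `se = sqrt(p / ((1 - p) * n))`.
#'
#' @param n_positive Number of positive droplets.
#' @param n_droplets Total droplets (>= 1).
#' @return List with `lambda`, `se`, `p_hat`, `n_droplets`.
#' @examples
#' estimate_lambda(2000, 20000)$lambda  # -log(0.9)
#' @export
estimate_lambda <- function(n_positive, n_droplets) {
  stopifnot(n_droplets >= 1, n_positive >= 0, n_positive <= n_droplets)
  if (n_positive == n_droplets) {
    stop("saturated assay: every droplet positive; lambda is unbounded")
  }
  p <- n_positive / n_droplets
  list(lambda = -log(1 - p),
       se = sqrt(p / ((1 - p) * n_droplets)),
       p_hat = p, n_droplets = n_droplets)
}

#' Target/reference concentration ratio with uncertainty
#'
#' Computes the plasmid-per-chromosome ratio as the ratio of the two
#' Poisson-corrected concentrations.  The standard error propagates the two
#' (independent) delta-method errors:
#' `se = ratio * sqrt((se_t/lambda_t)^2 + (se_r/lambda_r)^2)`.
#'
#' @param target,reference Either a length-2 vector `c(n_positive,
#'   n_droplets)` or a `droplet_assay` (in which case `reference` is
#'   ignored and both channels are taken from it).
#' @return An object of class `ddpcr_result`: list with `lambda_target`,
#'   `lambda_reference`, `ratio`, `ratio_se`, `n_droplets`.
#' @examples
#' a <- simulate_droplets(0.341, 0.01, 1e5, seed = 1)
#' ratio_with_ci(a)$ratio  # close to 34.1
#' @export
ratio_with_ci <- function(target, reference = NULL) {
  if (inherits(target, "droplet_assay")) {
    reference <- c(target$n_positive_reference, target$n_droplets)
    target <- c(target$n_positive_target, target$n_droplets)
  }
  stopifnot(length(target) == 2L, length(reference) == 2L)
  lt <- estimate_lambda(target[1], target[2])
  lr <- estimate_lambda(reference[1], reference[2])
  if (lr$lambda == 0) {
    stop("undefined ratio: reference concentration estimate is zero")
  }
  ratio <- lt$lambda / lr$lambda
  se <- if (lt$lambda > 0) {
    ratio * sqrt((lt$se / lt$lambda)^2 + (lr$se / lr$lambda)^2)
  } else {
    # null target: uncertainty driven by the target channel alone
    lt$se / lr$lambda
  }
  structure(list(lambda_target = lt$lambda, lambda_reference = lr$lambda,
                 ratio = ratio, ratio_se = se,
                 n_droplets = c(target = target[2], reference = reference[2])),
            class = "ddpcr_result")
}

#' @export
print.ddpcr_result <- function(x, ...) {
  cat(sprintf("ddpcr_result: ratio %.3g +/- %.2g (lambda_t %.4g, lambda_r %.4g)\n",
              x$ratio, x$ratio_se, x$lambda_target, x$lambda_reference))
  invisible(x)
}

#' Chromosome copies per cell from fluorescence histograms
#'
#' The unit signal is the modal fluorescence of a one-copy-per-cell
#' standard population (modal bin refined by three-point parabolic peak
#' interpolation); the sample's ploidy range is the sample
#' fluorescence at the `quantiles` divided by the unit signal, rounded to
#' the nearest integers and clamped to at least 1.
#'
#' @param sample,standard `fluorescence_histogram` objects.
#' @param quantiles Lower/upper quantiles of the sample distribution used
#'   as the copy range.
#' @return An object of class `ploidy_estimate`: list with `copies_min`,
#'   `copies_max`, `unit_signal`, `method = "fcm"`.
#' @export
ploidy_from_histogram <- function(sample, standard,
                                  quantiles = c(0.05, 0.95)) {
  stopifnot(inherits(sample, "fluorescence_histogram"),
            inherits(standard, "fluorescence_histogram"),
            sum(sample$counts) > 0, sum(standard$counts) > 0,
            length(quantiles) == 2L, quantiles[1] <= quantiles[2])
  unit <- histogram_mode(standard)
  q <- histogram_quantile(sample, quantiles)
  if (q[1] < unit / 2) {
    stop("degenerate sample: lower quantile below half the unit signal")
  }
  cmin <- max(1L, as.integer(round(q[1] / unit)))
  cmax <- max(1L, as.integer(round(q[2] / unit)))
  structure(list(copies_min = cmin, copies_max = cmax,
                 unit_signal = unit, method = "fcm"),
            class = "ploidy_estimate")
}

#' @rdname ploidy_from_histogram
#' @param copies_min,copies_max Directly asserted ploidy bounds (used when
#'   the chromosome copy range is known rather than re-estimated).
#' @export
ploidy_asserted <- function(copies_min, copies_max) {
  stopifnot(copies_min >= 1, copies_max >= copies_min)
  structure(list(copies_min = as.integer(copies_min),
                 copies_max = as.integer(copies_max),
                 unit_signal = NA_real_, method = "asserted"),
            class = "ploidy_estimate")
}

# Mode of a binned distribution: modal bin refined by parabolic (3-point)
# peak interpolation, which removes most of the bin-granularity error.
histogram_mode <- function(h) {
  mid <- (head(h$bin_edges, -1) + h$bin_edges[-1]) / 2
  b <- which.max(h$counts)
  if (b == 1L || b == length(h$counts)) return(mid[b])
  c0 <- h$counts[b]
  cm <- h$counts[b - 1L]; cp <- h$counts[b + 1L]
  denom <- cm - 2 * c0 + cp
  if (denom == 0) return(mid[b])
  delta <- 0.5 * (cm - cp) / denom
  width <- h$bin_edges[b + 1L] - h$bin_edges[b]
  mid[b] + max(-0.5, min(0.5, delta)) * width
}

# Quantiles of a binned distribution (linear interpolation within the bin).
histogram_quantile <- function(h, probs) {
  cw <- cumsum(h$counts)
  n <- cw[length(cw)]
  vapply(probs, function(p) {
    tgt <- p * n
    b <- which(cw >= tgt)[1]
    below <- if (b > 1) cw[b - 1] else 0
    frac <- if (h$counts[b] > 0) (tgt - below) / h$counts[b] else 0
    h$bin_edges[b] + frac * (h$bin_edges[b + 1] - h$bin_edges[b])
  }, numeric(1))
}

#' Per-cell plasmid copy range
#'
#' Combines a plasmid-per-chromosome ratio with a chromosome-ploidy range
#' into per-cell plasmid copy bounds:
#' `(floor(ratio * copies_min), floor(ratio * copies_max))`.  Truncation
#' (floor) is the rounding rule; a small epsilon guards against binary
#' floating-point representation of decimal ratios (so 8.7 x 10 floors to
#' 87, not 86).
#'
#' @param ratio Plasmid-per-chromosome ratio (>= 0), e.g. from
#'   [ratio_with_ci()].
#' @param ploidy A `ploidy_estimate` (from [ploidy_from_histogram()] or
#'   [ploidy_asserted()]).
#' @return Integer vector `c(per_cell_min, per_cell_max)`.
#' @examples
#' per_cell_copy_range(34.1, ploidy_asserted(2, 6))  # 68 204
#' @export
per_cell_copy_range <- function(ratio, ploidy) {
  stopifnot(ratio >= 0, inherits(ploidy, "ploidy_estimate"))
  f <- function(x) as.integer(floor(x + 1e-9))
  c(per_cell_min = f(ratio * ploidy$copies_min),
    per_cell_max = f(ratio * ploidy$copies_max))
}

#' Assemble a copy-number report table
#'
#' One row per strain/plasmid combination: the ddPCR ratio, the ploidy
#' range, and the derived per-cell plasmid copy range.
#'
#' @param labels Character vector of row labels.
#' @param ratios Numeric vector of plasmid-per-chromosome ratios.
#' @param ratio_ses Optional numeric vector of ratio standard errors
#'   (displayed, never asserted).
#' @param ploidies List of `ploidy_estimate` objects, one per row.
#' @return data.frame with columns `label`, `chromosome_copies`, `ratio`,
#'   `ratio_se`, `plasmid_copies_min`, `plasmid_copies_max`.
#' @export
copy_number_report <- function(labels, ratios, ploidies, ratio_ses = NA) {
  stopifnot(length(labels) == length(ratios),
            length(ploidies) == length(ratios))
  ratio_ses <- rep_len(ratio_ses, length(ratios))
  rows <- lapply(seq_along(labels), function(i) {
    rng <- per_cell_copy_range(ratios[i], ploidies[[i]])
    data.frame(label = labels[i],
               chromosome_copies = sprintf("%d-%d", ploidies[[i]]$copies_min,
                                           ploidies[[i]]$copies_max),
               ratio = ratios[i], ratio_se = ratio_ses[i],
               plasmid_copies_min = rng[["per_cell_min"]],
               plasmid_copies_max = rng[["per_cell_max"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
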