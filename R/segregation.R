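#' Simulate generational plasmid segregation
#'
#' A population of cells each starts with `initial_copies` plasmid copies.
#' Every generation the copies are replicated (doubled) and each of the
#' `2n` copies is assigned independently to one of the two daughters with
#' probability 1/2; one daughter per cell is tracked, i.e. the retained
#' copy number is `Binomial(2n, 1/2)`.  Plasmid-free cells are an absorbing
#' state.  With `selection_on = TRUE` plasmid-free cells are removed after
#' each division and the population is renormalised to `n_cells` by
#' resampling survivors, mirroring growth on selective medium; with
#' selection off the plasmid-free fraction can only grow, mirroring the
#' progressive loss of reporter fluorescence on antibiotic-free medium, and
#' low-copy plasmids are lost faster than high-copy ones.
#'
#' @param initial_copies Starting plasmid copies per cell (>= 0).
#' @param generations Number of generations to simulate.
#' @param selection_on Logical; remove plasmid-free cells each generation.
#' @param n_cells Number of cells tracked.
#' @param seed Integer seed.
#' @return An object of class `segregation_trajectory`: list with
#'   `fraction_plasmid_free` (length `generations + 1`, starting at
#'   generation 0), `mean_copies` among all tracked cells, and the
#'   parameters.
#' @examples
#' tr <- simulate_segregation(8, 20, selection_on = FALSE, n_cells = 1000, seed = 1)
#' tr$fraction_plasmid_free
#' @export
simulate_segregation <- function(initial_copies, generations,
                                 selection_on = FALSE, n_cells = 10000L,
                                 seed = 1L) {
  stopifnot(initial_copies >= 0, generations >= 0, n_cells >= 1)
  initial_copies <- as.integer(initial_copies)
  n_cells <- as.integer(n_cells)
  res <- with_seed(seed, {
    copies <- rep(initial_copies, n_cells)
    frac <- numeric(generations + 1L)
    meanc <- numeric(generations + 1L)
    frac[1] <- mean(copies == 0L)
    meanc[1] <- mean(copies)
    if (generations > 0) {
      for (g in seq_len(generations)) {
        copies <- rbinom(length(copies), 2L * copies, 0.5)
        frac[g + 1L] <- mean(copies == 0L)
        meanc[g + 1L] <- mean(copies)
        if (selection_on) {
          keep <- copies > 0L
          if (!any(keep)) {
            copies <- integer(0)
            if (g < generations) {
              frac[(g + 2L):(generations + 1L)] <- 1
              meanc[(g + 2L):(generations + 1L)] <- 0
              break
            }
          } else {
            surv <- copies[keep]
            copies <- surv[sample.int(length(surv), n_cells, replace = TRUE)]
          }
        }
      }
    }
    list(frac = frac, meanc = meanc)
  })
  structure(list(initial_copies = initial_copies, generations = generations,
                 selection_on = selection_on, n_cells = n_cells, seed = seed,
                 fraction_plasmid_free = res$frac,
                 mean_copies = res$meanc),
            class = "segregation_trajectory")
}

#' @export
print.segregation_trajectory <- function(x, ...) {
  cat(sprintf(
    "segregation_trajectory: %d initial copies, %d generations, selection %s\n",
    x$initial_copies, x$generations, if (x$selection_on) "on" else "off"))
  cat("final plasmid-free fraction:",
      x$fraction_plasmid_free[length(x$fraction_plasmid_free)], "\n")
  invisible(x)
}

#' @rdname write_assay_tsv
#' @export
write_trajectory_tsv <- function(x, path, seed = NA, hash = NA) {
  stopifnot(inherits(x, "segregation_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, hash), con)
  df <- data.frame(generation = seq_along(x$fraction_plasmid_free) - 1L,
                   fraction_plasmid_free = x$fraction_plasmid_free,
                   mean_copies = x$mean_copies)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
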