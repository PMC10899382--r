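# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state.  All simulators funnel their `seed` argument through here so that
# results are bit-reproducible and side-effect free.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (abs(seed) >= 2^31) stop("seed must fit in a 32-bit integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation: one global seed fans out to per-stage
# seeds via a polynomial hash of the stage name, so any stage can be re-run
# independently and reproducibly.  Result is always in [0, 2^31 - 2].
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h * 2654435) %% 2147483647)
}

# Extract the subsequence [start, end) from a circular sequence (0-based,
# half-open; end may exceed the sequence length to denote origin wrap).
circular_substr <- function(seq, start, end) {
  L <- nchar(seq)
  stopifnot(end > start, end - start <= L)
  s <- (start %% L) + 1L
  e_lin <- s + (end - start) - 1L
  if (e_lin <= L) {
    substr(seq, s, e_lin)
  } else {
    paste0(substr(seq, s, L), substr(seq, 1L, e_lin - L))
  }
}

# Is circular interval [a, b) fully contained in circular interval [s, e)?
# All 0-based; b and e may exceed L (wrap representation).  Vectorised over
# any argument.
circular_contains <- function(s, e, a, b, L) {
  len_outer <- e - s
  len_inner <- b - a
  off <- (a - s) %% L
  (len_inner <= len_outer) & (off + len_inner <= len_outer)
}

# Split a possibly wrapping 0-based half-open interval into non-wrapping
# pieces on [0, L).  Returns a matrix with columns start, end.
split_circular_interval <- function(start, end, L) {
  start <- start %% L
  span <- end %% L + (end %/% L) * L - start  # keep original span
  span <- if (span <= 0) span + L else span
  end <- start + span
  if (end <= L) {
    cbind(start = start, end = end)
  } else {
    rbind(cbind(start = start, end = L), cbind(start = 0, end = end - L))
  }
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Header comment written at the top of text outputs (TSV/BED/bedGraph/GFF3).
output_header <- function(seed = NA, config_hash = NA, prefix = "#") {
  ver <- as.character(utils::packageVersion("arseq"))
  sprintf("%s arseq %s seed=%s config=%s", prefix, ver,
          as.character(seed), as.character(config_hash))
}

# Stable hash of an R object (used for config fingerprints in file headers).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x, control = "all"), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
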