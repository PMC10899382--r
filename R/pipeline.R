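#' Pipeline run configuration
#'
#' Bundles everything [run_pipeline()] needs: the genome description, the
#' library bottleneck configuration, per-stage read counts, mapping
#' parameters, candidate-caller thresholds, and one global seed.  Per-stage
#' seeds are derived deterministically from the global seed by hashing the
#' stage name, so any stage can be regenerated independently.
#'
#' @param replicons List of [replicon()] descriptors.
#' @param copy_weights Per-replicon copy weights (default all 1).
#' @param library A [library_config()].
#' @param mapping A [mapping_params()].
#' @param n_pairs Read pairs simulated per stage (named vector with
#'   entries `A`, `B`, `C`, or one number used for all stages).
#' @param read_length,substitution_rate,insert_mean,insert_sd Read
#'   simulation parameters.
#' @param window,eps,min_depth,threshold ARS caller parameters (see
#'   [enrichment_profile()] and [call_ars_candidates()]).
#' @param coverage_policy Coverage policy used for candidate calling.
#' @param seed Global seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(replicons, copy_weights = NULL,
                       library = library_config(),
                       mapping = mapping_params(),
                       n_pairs = c(A = 2000L, B = 2000L, C = 2000L),
                       read_length = 150L, substitution_rate = 0.005,
                       insert_mean = 400L, insert_sd = 40L,
                       window = 200L, eps = 1, min_depth = 5L, threshold = 2,
                       coverage_policy = c("include_all",
                                           "exclude_multimapped"),
                       seed = 1L) {
  coverage_policy <- match.arg(coverage_policy)
  if (length(n_pairs) == 1L) {
    n_pairs <- stats::setNames(rep(as.integer(n_pairs), 3), c("A", "B", "C"))
  }
  stopifnot(all(c("A", "B", "C") %in% names(n_pairs)))
  structure(list(replicons = replicons, copy_weights = copy_weights,
                 library = library, mapping = mapping,
                 n_pairs = n_pairs, read_length = as.integer(read_length),
                 substitution_rate = substitution_rate,
                 insert_mean = as.integer(insert_mean),
                 insert_sd = as.integer(insert_sd),
                 window = as.integer(window), eps = eps,
                 min_depth = as.integer(min_depth), threshold = threshold,
                 coverage_policy = coverage_policy,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' A thin front end over [run_config()]: scalar fields map 1:1, replicons
#' are listed under `replicons:` with optional `orfs`, `ars_loci` and
#' `duplications` tables.
#'
#' @param path Path to a YAML document.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  reps <- lapply(y$replicons, function(r) {
    as_df <- function(x) if (is.null(x)) NULL else
      do.call(rbind, lapply(x, as.data.frame))
    replicon(r$name, r$length,
             is_chromosome = isTRUE(r$is_chromosome),
             sequence = r$sequence,
             orfs = as_df(r$orfs), ars_loci = as_df(r$ars_loci),
             duplications = as_df(r$duplications))
  })
  args <- y[setdiff(names(y), c("replicons", "library", "mapping"))]
  args$replicons <- reps
  if (!is.null(y$library)) args$library <- do.call(library_config, y$library)
  if (!is.null(y$mapping)) args$mapping <- do.call(mapping_params, y$mapping)
  if (!is.null(args$n_pairs)) args$n_pairs <- unlist(args$n_pairs)
  do.call(run_config, args)
}

#' Run the full in-silico screen
#'
#' Chains the whole pipeline: genome realisation, Library A, the two
#' selection bottlenecks, read simulation per stage, mapping, per-stage
#' composition, coverage, enrichment profiling of C over A on every
#' replicon, and ARS candidate calling.  Artifacts are written into a
#' deterministic directory layout (`genome/`, `libraries/`, `reads/`,
#' `alignments/`, `composition/`, `candidates/`, `logs/`) and a
#' machine-readable `summary.json`.  Every stage draws its seed
#' deterministically from the global seed, so reruns (including partial
#' reruns after deleting a stage directory) are byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results: `genome`,
#'   `libraries`, `alignments`, `composition` (per stage), `coverage`
#'   (per stage), `candidates`, `summary_path`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  hash <- config_hash(unclass(config))
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste(format(Sys.time(), "%H:%M:%S"), msg))
    if (!quiet) message(msg)
  }
  dirs <- file.path(out_dir, c("genome", "libraries", "reads", "alignments",
                               "composition", "candidates", "logs"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  on.exit(writeLines(log_lines, file.path(out_dir, "logs", "run.log")))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say("stage %s FAILED: %s", name, conditionMessage(e))
      writeLines(log_lines, file.path(out_dir, "logs", "run.log"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  say("building genome (%d replicons)", length(config$replicons))
  genome <- run_stage("genome", {
    g <- build_genome(config$replicons, config$copy_weights,
                      seed = derive_seed(config$seed, "genome"))
    write_genome_fasta(g, file.path(out_dir, "genome", "genome.fasta"))
    write_genome_gff3(g, file.path(out_dir, "genome", "orfs.gff3"))
    write_ars_bed(g, file.path(out_dir, "genome", "ars_loci.bed"))
    g
  })

  say("sampling libraries A -> B -> C")
  libs <- run_stage("libraries", {
    la <- make_library_a(genome, config$library,
                         seed = derive_seed(config$seed, "library_A"))
    lb <- apply_selection(la, "B", config$library,
                          seed = derive_seed(config$seed, "library_B"))
    lc <- apply_selection(lb, "C", config$library,
                          seed = derive_seed(config$seed, "library_C"))
    for (l in list(la, lb, lc)) {
      utils::write.table(
        l$clones, file.path(out_dir, "libraries",
                            sprintf("library_%s.tsv", l$stage)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(A = la, B = lb, C = lc)
  })

  index <- index_reference(genome, config$mapping)
  stages <- c("A", "B", "C")
  alns <- list(); comps <- list(); covs <- list()
  for (st in stages) {
    say("stage %s: simulating %d pairs, mapping", st, config$n_pairs[[st]])
    res <- run_stage(paste0("reads_map_", st), {
      rd <- simulate_reads(libs[[st]], config$n_pairs[[st]],
                           read_length = config$read_length,
                           substitution_rate = config$substitution_rate,
                           insert_mean = config$insert_mean,
                           insert_sd = config$insert_sd,
                           seed = derive_seed(config$seed,
                                              paste0("reads_", st)))
      write_fastq_pair(rd, file.path(out_dir, "reads", paste0("stage_", st)))
      al <- map_library(rd, index, config$mapping)
      write_alignments_tsv(al, file.path(out_dir, "alignments",
                                         sprintf("stage_%s.tsv", st)),
                           seed = config$seed, hash = hash)
      write_mapping_stats_json(al, file.path(out_dir, "alignments",
                                             sprintf("stage_%s_stats.json",
                                                     st)),
                               seed = config$seed, hash = hash)
      # a stage sequenced at zero depth has no composition (null experiment)
      cm <- tryCatch(compute_composition(al, genome, "exclude_multimapped"),
                     error = function(e) NULL)
      if (!is.null(cm)) {
        write_composition_tsv(cm, file.path(out_dir, "composition",
                                            sprintf("stage_%s.tsv", st)),
                              stage = st, seed = config$seed, hash = hash)
      }
      cv <- compute_coverage(al, genome, config$coverage_policy)
      write_bedgraph(cv, file.path(out_dir, "composition",
                                   sprintf("stage_%s.bedGraph", st)),
                     seed = config$seed, hash = hash)
      list(al = al, cm = cm, cv = cv)
    })
    alns[[st]] <- res$al; comps[st] <- list(res$cm); covs[[st]] <- res$cv
  }

  say("calling ARS candidates (C vs A)")
  cands <- run_stage("candidates", {
    orfs <- genome_orfs(genome)
    out <- NULL
    for (nm in names(genome$replicons)) {
      prof <- enrichment_profile(covs$C, covs$A, nm,
                                 window = config$window, eps = config$eps)
      write_enrichment_tsv(prof,
                           file.path(out_dir, "candidates",
                                     sprintf("enrichment_%s.tsv", nm)),
                           seed = config$seed, hash = hash)
      cc <- call_ars_candidates(prof, covs$C, orfs,
                                min_depth = config$min_depth,
                                threshold = config$threshold)
      out <- rbind(out, as.data.frame(cc))
    }
    out <- out %||% data.frame()
    cc <- structure(out, class = c("ars_candidates", "data.frame"))
    write_candidates_bed(cc, file.path(out_dir, "candidates",
                                       "candidates.bed"))
    write_candidates_gff3(cc, file.path(out_dir, "candidates",
                                        "candidates.gff3"))
    cc
  })

  summary <- list(
    arseq_version = as.character(utils::packageVersion("arseq")),
    seed = config$seed, config = hash,
    composition = lapply(comps, function(cm) {
      if (is.null(cm)) return(NULL)
      stats::setNames(as.list(cm$percent), cm$replicon)
    }),
    mapping_stats = lapply(alns, `[[`, "stats"),
    candidates = if (nrow(cands)) cands else list())
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(genome = genome, libraries = libs, alignments = alns,
                 composition = comps, coverage = covs, candidates = cands,
                 summary_path = summary_path))
}
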