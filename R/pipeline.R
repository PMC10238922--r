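#' Configuration of a full simulation-to-scan run
#'
#' Bundles every parameter of the pipeline (cross simulation, pooling,
#' pooled sequencing, BSA scan) with one root seed. Stage seeds for the
#' population, the read simulation and the null threshold are derived
#' deterministically from the root seed, so a config reproduces a run
#' exactly.
#'
#' @param genome A [genome_spec()].
#' @param qtl A [qtl_model()].
#' @param n_lines,n_generations,n_animals_per_line Cross design (defaults:
#'   200 F5 lines, 20 animals each).
#' @param pool_size Lines per extreme pool (default 40).
#' @param mean_depth,error_rate Pooled sequencing model.
#' @param params A [bsa_params()].
#' @param seed Root seed (integer).
#' @return An object of class `bsa_config`.
#' @export
bsa_config <- function(genome = default_genome(), qtl = qtl_model(),
                       n_lines = 200, n_generations = 4,
                       n_animals_per_line = 20, pool_size = 40,
                       mean_depth = 20, error_rate = 0.001,
                       params = bsa_params(), seed = 1) {
  stopifnot(inherits(genome, "genome_spec"), inherits(qtl, "qtl_model"),
            inherits(params, "bsa_params"))
  stop_if_not_scalar_count(n_lines, "n_lines", min = 2L)
  stop_if_not_scalar_count(seed, "seed", min = 0L)
  if (2L * pool_size > n_lines) stop("pools larger than the population", call. = FALSE)
  structure(list(genome = genome, qtl = qtl, n_lines = as.integer(n_lines),
                 n_generations = as.integer(n_generations),
                 n_animals_per_line = as.integer(n_animals_per_line),
                 pool_size = as.integer(pool_size), mean_depth = mean_depth,
                 error_rate = error_rate, params = params,
                 seed = as.integer(seed)),
            class = "bsa_config")
}

# root seed -> named stage seeds (documented splitting rule: three draws
# from a sample.int stream seeded with the root seed)
stage_seeds <- function(seed) {
  withr::with_seed(seed, stats::setNames(child_seeds(3L),
                                         c("population", "reads", "threshold")))
}

config_to_list <- function(config) {
  g <- config$genome
  list(
    genome = list(
      chromosomes = lapply(seq_len(nrow(g$chromosomes)), function(i)
        as.list(g$chromosomes[i, ])),
      marker_spacing_bp = if (is.na(g$marker_spacing_bp)) NULL else
        g$marker_spacing_bp,
      markers = if (is.na(g$marker_spacing_bp))
        list(chrom = g$markers$chrom, pos = g$markers$pos) else NULL
    ),
    qtl = unclass(config$qtl),
    n_lines = config$n_lines, n_generations = config$n_generations,
    n_animals_per_line = config$n_animals_per_line,
    pool_size = config$pool_size, mean_depth = config$mean_depth,
    error_rate = config$error_rate,
    bsa = unclass(config$params),
    seed = config$seed
  )
}

list_to_config <- function(x) {
  chroms <- do.call(rbind, lapply(x$genome$chromosomes, as.data.frame))
  genome <- if (!is.null(x$genome$markers)) {
    genome_spec(chroms, markers = data.frame(chrom = x$genome$markers$chrom,
                                             pos = x$genome$markers$pos))
  } else {
    genome_spec(chroms, marker_spacing_bp = x$genome$marker_spacing_bp)
  }
  bsa_config(
    genome = genome, qtl = do.call(qtl_model, x$qtl),
    n_lines = x$n_lines, n_generations = x$n_generations,
    n_animals_per_line = x$n_animals_per_line, pool_size = x$pool_size,
    mean_depth = x$mean_depth, error_rate = x$error_rate,
    params = do.call(bsa_params, x$bsa), seed = x$seed
  )
}

#' Write / read a run configuration as YAML
#'
#' The file stores every tunable of [bsa_config()]; reading it back rebuilds
#' an equivalent configuration (lossless round trip).
#'
#' @param config A [bsa_config()].
#' @param path `.yaml` file.
#' @return `path`, invisibly (writer); a `bsa_config` (reader).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  list_to_config(yaml::read_yaml(path))
}

run_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline: simulate, pool, sequence, scan, report
#'
#' Executes the whole flow under one seeded configuration and writes, into
#' `out_dir`: `config.yaml`, `genotypes.tsv`, `phenotypes.csv`,
#' `pool_counts.tsv`, `pool_counts.vcf`, `track.tsv` (smoothed frequencies
#' plus log-odds ratio), `qtl_intervals.tsv`, `qtl_intervals.bed`,
#' `thresholds.json` and `summary.json`. Identical configurations give
#' byte-identical text outputs. The summary records the stage seeds and all
#' parameters, so it documents the run completely.
#'
#' @param config A [bsa_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with `population`, `pools`, `counts`, `result`
#'   (the [bsa_scan()] output) and `summary`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "bsa_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(config$seed)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("simulate: %d lines, %d selfing generations, %d animals/line (seed %d)",
      config$n_lines, config$n_generations, config$n_animals_per_line,
      seeds[["population"]])
  pop <- run_stage("simulate", simulate_ril_population(
    config$genome, config$qtl, config$n_lines, config$n_generations,
    config$n_animals_per_line, seed = seeds[["population"]]))

  say("pool: 2 x %d extreme lines", config$pool_size)
  pools <- run_stage("pool", select_pools(
    pop, pool_spec(config$pool_size, "lowest", "anterior"),
    pool_spec(config$pool_size, "highest", "posterior")))

  say("sequence: mean depth %g, error rate %g (seed %d)", config$mean_depth,
      config$error_rate, seeds[["reads"]])
  counts <- run_stage("sequence", simulate_pool_counts(
    pop, pools, config$mean_depth, config$error_rate, seed = seeds[["reads"]]))

  say("scan: window %d bp, min coverage > %d, alpha %g, %d null draws (seed %d)",
      config$params$window_bp, config$params$min_coverage, config$params$alpha,
      config$params$n_null_draws, seeds[["threshold"]])
  result <- run_stage("scan", bsa_scan(counts, config$params,
                                       seed = seeds[["threshold"]]))

  say("report: writing %s", out_dir)
  run_stage("report", {
    write_config(config, file.path(out_dir, "config.yaml"))
    write_genotypes(pop, file.path(out_dir, "genotypes.tsv"))
    write_phenotypes(pop, file.path(out_dir, "phenotypes.csv"))
    write_pool_counts(counts, file.path(out_dir, "pool_counts.tsv"))
    write_pool_vcf(counts, file.path(out_dir, "pool_counts.vcf"))
    write_track(result$track, file.path(out_dir, "track.tsv"))
    data.table::fwrite(data.table::as.data.table(result$intervals),
                       file.path(out_dir, "qtl_intervals.tsv"), sep = "\t")
    write_bed(result$intervals, file.path(out_dir, "qtl_intervals.bed"))
    write_thresholds(result$thresholds, file.path(out_dir, "thresholds.json"))
  })

  pm <- line_means(pop)
  summary <- list(
    config = config_to_list(config),
    stage_seeds = as.list(seeds),
    pool_means = list(pool1 = unname(mean(pm[pools$pool1])),
                      pool2 = unname(mean(pm[pools$pool2]))),
    thresholds = unclass(result$thresholds),
    n_sites = nrow(counts), n_track_positions = nrow(result$track),
    intervals = result$intervals
  )
  run_stage("report", jsonlite::write_json(
    summary, file.path(out_dir, "summary.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE))

  invisible(list(population = pop, pools = pools, counts = counts,
                 result = result, summary = summary))
}
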