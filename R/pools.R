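#' Specification of an extreme-phenotype pool
#'
#' @param pool_size Lines per pool, >= 1.
#' @param selection Take the lines with the `"lowest"` or `"highest"` mean
#'   phenotype.
#' @param label Pool label used in output files and VCF sample names.
#' @return An object of class `pool_spec`.
#' @export
pool_spec <- function(pool_size = 40, selection = c("lowest", "highest"),
                      label = NULL) {
  stop_if_not_scalar_count(pool_size, "pool_size", min = 1L)
  selection <- match.arg(selection)
  label <- label %||% if (selection == "lowest") "anterior" else "posterior"
  structure(list(pool_size = as.integer(pool_size), selection = selection,
                 label = label),
            class = "pool_spec")
}

#' Select the two extreme-phenotype pools
#'
#' Lines are ranked by mean phenotype (ties broken deterministically by line
#' id); the `pool_size` lowest lines form pool 1 and the `pool_size` highest
#' form pool 2, emulating the 40-line anterior / 40-line posterior pools of
#' the mapped cross. Pools are always disjoint.
#'
#' @param pop A phenotyped [ril_population()].
#' @param spec_low,spec_high [pool_spec()]s for the low and high pool.
#' @return A named list of two character vectors of line ids (`pool1` =
#'   lowest, `pool2` = highest) with the pool labels as an attribute.
#' @export
select_pools <- function(pop,
                         spec_low = pool_spec(40, "lowest", "anterior"),
                         spec_high = pool_spec(40, "highest", "posterior")) {
  stopifnot(inherits(spec_low, "pool_spec"), inherits(spec_high, "pool_spec"))
  if (spec_low$selection != "lowest" || spec_high$selection != "highest") {
    stop("`spec_low` must select lowest, `spec_high` highest", call. = FALSE)
  }
  means <- line_means(pop)
  n <- length(means)
  if (spec_low$pool_size + spec_high$pool_size > n) {
    stop("pools larger than the population", call. = FALSE)
  }
  ord <- order(means, pop$line_ids)
  pool1 <- pop$line_ids[ord[seq_len(spec_low$pool_size)]]
  pool2 <- pop$line_ids[ord[seq(n - spec_high$pool_size + 1L, n)]]
  structure(list(pool1 = pool1, pool2 = pool2),
            labels = c(spec_low$label, spec_high$label))
}

#' Default alternating assignment of variant parental origin
#'
#' Ascertained variants alternate between JU1242-origin and CB4932-origin
#' along the marker map, so both allele-frequency rules of the scan are
#' exercised.
#'
#' @param n Number of sites.
#' @return Character vector in `{"JU1242", "CB4932"}`.
#' @export
alternating_origins <- function(n) {
  rep_len(c("JU1242", "CB4932"), n)
}

#' Simulate pooled read counts for one pool
#'
#' Per site, the true pool B-allele (JU1242) frequency is the summed B dosage
#' of the pooled lines divided by `2 * pool_size` (equal DNA contribution per
#' line). Sequencing depth is Poisson with the given mean; a symmetric
#' per-read error rate moves the sampled frequency towards 0.5; the variant
#' read count is binomial at the frequency of the ascertained variant allele
#' (the B frequency for JU1242-origin variants, its complement for
#' CB4932-origin variants).
#'
#' @param pop A [ril_population()].
#' @param line_ids Lines in the pool.
#' @param mean_depth Mean sequencing coverage (20 in the emulated design).
#' @param error_rate Per-read error probability in `[0, 0.5)`.
#' @param origins Variant parental origin per site; defaults to
#'   [alternating_origins()].
#' @param seed Optional integer seed.
#' @return Tibble with `chrom`, `pos`, `origin`, `read_var`, `read_tot`.
#' @export
simulate_pool_reads <- function(pop, line_ids, mean_depth = 20,
                                error_rate = 0.001, origins = NULL,
                                seed = NULL) {
  stopifnot(inherits(pop, "ril_population"))
  if (length(line_ids) == 0L) stop("empty pool", call. = FALSE)
  if (mean_depth <= 0) stop("`mean_depth` must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("`error_rate` must lie in [0, 0.5)", call. = FALSE)
  }
  idx <- match(line_ids, pop$line_ids)
  if (anyNA(idx)) stop("unknown line id in pool", call. = FALSE)
  ns <- n_markers(pop$genome)
  origins <- origins %||% alternating_origins(ns)
  if (!all(origins %in% c("JU1242", "CB4932"))) {
    stop("origins must be JU1242 or CB4932", call. = FALSE)
  }
  f <- colSums(pop$geno[idx, , drop = FALSE]) / (2 * length(idx))
  fobs <- f * (1 - error_rate) + (1 - f) * error_rate
  p <- ifelse(origins == "JU1242", fobs, 1 - fobs)
  maybe_with_seed(seed, {
    depth <- stats::rpois(ns, mean_depth)
    rv <- integer(ns)
    nz <- depth > 0L
    rv[nz] <- stats::rbinom(sum(nz), depth[nz], p[nz])
    tibble::tibble(chrom = pop$genome$markers$chrom,
                   pos = pop$genome$markers$pos,
                   origin = origins, read_var = rv, read_tot = depth)
  })
}

#' Simulate the full two-pool count table
#'
#' Convenience wrapper producing the `pool_counts` table consumed by
#' [bsa_scan()]: one row per marker with variant origin and the
#' variant/total read counts of both pools.
#'
#' @inheritParams simulate_pool_reads
#' @param pools Result of [select_pools()] (list with `pool1`, `pool2`).
#' @return A `pool_counts` tibble with columns `chrom`, `pos`, `origin`,
#'   `var1`, `tot1`, `var2`, `tot2`.
#' @export
simulate_pool_counts <- function(pop, pools, mean_depth = 20,
                                 error_rate = 0.001, origins = NULL,
                                 seed = NULL) {
  maybe_with_seed(seed, {
    r1 <- simulate_pool_reads(pop, pools$pool1, mean_depth, error_rate, origins)
    r2 <- simulate_pool_reads(pop, pools$pool2, mean_depth, error_rate, origins)
    pool_counts(tibble::tibble(
      chrom = r1$chrom, pos = r1$pos, origin = r1$origin,
      var1 = r1$read_var, tot1 = r1$read_tot,
      var2 = r2$read_var, tot2 = r2$read_tot
    ), labels = attr(pools, "labels") %||% c("pool1", "pool2"))
  })
}

#' Validate and class a pool count table
#'
#' @param x Data frame with columns `chrom`, `pos`, `origin`, `var1`, `tot1`,
#'   `var2`, `tot2` (counts of the ascertained variant allele and total
#'   coverage, per pool).
#' @param labels Character vector of two pool labels.
#' @return A `pool_counts` tibble (positions sorted within chromosome).
#' @export
pool_counts <- function(x, labels = c("pool1", "pool2")) {
  x <- tibble::as_tibble(x)
  need <- c("chrom", "pos", "origin", "var1", "tot1", "var2", "tot2")
  if (!all(need %in% names(x))) {
    stop("pool_counts needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  cnt <- as.matrix(x[, c("var1", "tot1", "var2", "tot2")])
  if (any(cnt < 0) || any(x$var1 > x$tot1) || any(x$var2 > x$tot2)) {
    stop("counts must satisfy 0 <= var <= tot", call. = FALSE)
  }
  x <- x[order(match(x$chrom, unique(x$chrom)), x$pos), need]
  structure(x, class = c("pool_counts", class(tibble::tibble()))) -> out
  attr(out, "pool_labels") <- labels
  out
}
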