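#' Parameters of the BSA scan
#'
#' Defaults reproduce the published analysis: 40 RILs per pool, pseudocount
#' 1e-6 in the odds, a 200 bp sliding window advanced 1 bp at a time,
#' coverage strictly greater than 10 required in both pools, a genome-wide
#' significance level of 0.001 calibrated from one million null draws, and a
#' fixation tolerance of 0.02 on the smoothed pool frequency.
#'
#' @param n_rils_per_pool Lines per pool; pool frequencies are converted to
#'   line counts `m = f * n_rils_per_pool` inside the statistic.
#' @param pseudocount Added to numerator and denominator of each odds to keep
#'   the statistic finite at fixation.
#' @param window_bp Sliding-window width in bp.
#' @param step_bp Window step in bp (used by the exhaustive smoothing mode).
#' @param min_coverage Sites are kept only when coverage is strictly greater
#'   than this in both pools.
#' @param alpha Two-sided genome-wide significance level.
#' @param n_null_draws Monte Carlo draws for the null threshold (>= 1000).
#' @param fixation_eps Smoothed frequency within `fixation_eps` of 1 counts
#'   as fixed when flagging fixed sub-intervals.
#' @param smoothing One of `"unique"` (default: one emitted window per
#'   distinct SNP content, equivalent to the step-1 scan after removing
#'   duplicate windows) or `"exhaustive"` (every anchor, spaced `step_bp`).
#' @return An object of class `bsa_params`.
#' @export
bsa_params <- function(n_rils_per_pool = 40, pseudocount = 1e-6,
                       window_bp = 200, step_bp = 1, min_coverage = 10,
                       alpha = 0.001, n_null_draws = 1e6,
                       fixation_eps = 0.02,
                       smoothing = c("unique", "exhaustive")) {
  smoothing <- match.arg(smoothing)
  if (pseudocount <= 0) stop("`pseudocount` must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  stop_if_not_scalar_count(n_rils_per_pool, "n_rils_per_pool")
  stop_if_not_scalar_count(window_bp, "window_bp")
  stop_if_not_scalar_count(step_bp, "step_bp")
  stop_if_not_scalar_count(min_coverage, "min_coverage", min = 0L)
  stop_if_not_scalar_count(n_null_draws, "n_null_draws", min = 1000L)
  structure(list(n_rils_per_pool = as.integer(n_rils_per_pool),
                 pseudocount = pseudocount, window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp),
                 min_coverage = as.integer(min_coverage), alpha = alpha,
                 n_null_draws = as.integer(n_null_draws),
                 fixation_eps = fixation_eps, smoothing = smoothing),
            class = "bsa_params")
}

#' JU1242 allele frequency from allelic depths
#'
#' For a variant ascertained in JU1242 the frequency is `read_var /
#' read_tot`; for a variant ascertained in CB4932 it is `1 - read_var /
#' read_tot`, so the track always reports the JU1242 allele.
#'
#' @param read_var Reads carrying the ascertained variant allele.
#' @param read_tot Total reads (> 0; zero-coverage sites must be filtered
#'   out beforehand).
#' @param origin `"JU1242"` or `"CB4932"`, recycled as needed.
#' @return JU1242 allele frequency in `[0, 1]` (vectorized).
#' @export
ju1242_frequency <- function(read_var, read_tot, origin) {
  if (any(read_tot <= 0)) {
    stop("`read_tot` must be positive (filter zero-coverage sites first)",
         call. = FALSE)
  }
  if (any(read_var < 0) || any(read_var > read_tot)) {
    stop("need 0 <= read_var <= read_tot", call. = FALSE)
  }
  if (!all(origin %in% c("JU1242", "CB4932"))) {
    stop("`origin` must be JU1242 or CB4932", call. = FALSE)
  }
  f <- read_var / read_tot
  ifelse(origin == "JU1242", f, 1 - f)
}

#' Coverage filter
#'
#' Keeps sites whose total coverage is strictly greater than `min_coverage`
#' in both pools ("higher than ten" at the default).
#'
#' @param counts A [pool_counts()] table.
#' @param min_coverage Strict lower bound on per-pool coverage.
#' @return The filtered `pool_counts` table (possibly empty).
#' @export
filter_by_coverage <- function(counts, min_coverage = 10) {
  keep <- counts$tot1 > min_coverage & counts$tot2 > min_coverage
  counts[keep, ]
}

#' Per-site JU1242 frequencies for both pools
#'
#' @param counts A [pool_counts()] table with positive coverage everywhere
#'   (apply [filter_by_coverage()] first).
#' @return Tibble with `chrom`, `pos`, `freq_pool1`, `freq_pool2`.
#' @export
pool_frequencies <- function(counts) {
  tibble::tibble(
    chrom = counts$chrom, pos = counts$pos,
    freq_pool1 = ju1242_frequency(counts$var1, counts$tot1, counts$origin),
    freq_pool2 = ju1242_frequency(counts$var2, counts$tot2, counts$origin)
  )
}

# smoothing of one chromosome; mat = numeric matrix of per-site values
smooth_one_chrom <- function(pos, mat, window_bp, step_bp, mode) {
  if (mode == "unique") {
    # window content only changes where a SNP enters (anchor = pos - w + 1)
    # or leaves (anchor = pos + 1); one representative (leftmost) anchor per
    # distinct content reproduces the step-1 scan without duplicate windows
    anchors <- sort(unique(pmax(c(pos - window_bp + 1L, pos + 1L), 1L)))
  } else {
    anchors <- seq.int(max(1L, min(pos) - window_bp + 1L), max(pos), by = step_bp)
  }
  i1 <- findInterval(anchors - 1L, pos) + 1L       # first SNP with p >= anchor
  i2 <- findInterval(anchors + window_bp - 1L, pos) # last SNP with p < anchor + w
  keep <- i2 >= i1                                  # drop empty windows
  if (mode == "unique") {
    keep <- keep & !duplicated(paste(i1, i2))
  }
  anchors <- anchors[keep]; i1 <- i1[keep]; i2 <- i2[keep]
  cs <- apply(rbind(0, mat), 2L, cumsum)
  n_snps <- i2 - i1 + 1L
  means <- (cs[i2 + 1L, , drop = FALSE] - cs[i1, , drop = FALSE]) / n_snps
  list(pos = anchors + (window_bp - 1L) %/% 2L, means = means, n_snps = n_snps)
}

#' Sliding-window smoothing of allele-frequency tracks
#'
#' Windows are 1-based and half-open, `[anchor, anchor + window_bp)`; each
#' emitted window reports the unweighted mean of the SNP values it contains
#' at the window midpoint (floored), and windows containing no SNP are
#' skipped. The default `"unique"` mode emits one window per distinct SNP
#' content, which is the step-1 scan with duplicate adjacent windows removed;
#' `"exhaustive"` emits every anchor spaced `step_bp` apart.
#'
#' All numeric columns other than `pos` are smoothed jointly on the same
#' windows, so the two pool tracks stay aligned position for position.
#'
#' @param freqs Tibble with `chrom`, `pos` and one or more numeric value
#'   columns (typically `freq_pool1`, `freq_pool2`), sorted by position
#'   within chromosome.
#' @param window_bp Window width in bp.
#' @param step_bp Anchor spacing for the exhaustive mode.
#' @param mode `"unique"` or `"exhaustive"`.
#' @return A frequency track tibble: `chrom`, `pos` (window midpoint), the
#'   smoothed value columns and `n_snps` per window.
#' @export
smooth_frequencies <- function(freqs, window_bp = 200, step_bp = 1,
                               mode = c("unique", "exhaustive")) {
  mode <- match.arg(mode)
  if (nrow(freqs) == 0L) stop("no data: empty frequency table", call. = FALSE)
  val_cols <- setdiff(names(freqs)[vapply(freqs, is.numeric, logical(1))], "pos")
  if (length(val_cols) == 0L) stop("no numeric value columns to smooth", call. = FALSE)
  out <- lapply(split(freqs, factor(freqs$chrom, levels = unique(freqs$chrom))),
                function(d) {
    sm <- smooth_one_chrom(d$pos, as.matrix(d[, val_cols, drop = FALSE]),
                           window_bp, step_bp, mode)
    res <- tibble::tibble(chrom = rep(d$chrom[1], length(sm$pos)), pos = sm$pos)
    for (j in seq_along(val_cols)) res[[val_cols[j]]] <- sm$means[, j]
    res$n_snps <- sm$n_snps
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pseudocounted log-odds-ratio statistic
#'
#' The pool frequencies are converted to line counts `m_i = f_i *
#' n_rils_per_pool` and compared as
#' `log(((m1 + eps) / (n - m1 + eps)) / ((m2 + eps) / (n - m2 + eps)))`
#' with natural logarithm (the base only rescales statistic and threshold
#' together, so interval calls are base-invariant). The pseudocount `eps`
#' keeps the statistic finite when a pool is fixed: at `f1 = 1, f2 = 0`,
#' `n = 40`, `eps = 1e-6` the value is `2 * log(4.0000001e7) ~ 35.01`.
#'
#' @param f1,f2 JU1242 allele frequencies in `[0, 1]` (vectorized; in the
#'   genome scan `f1` is the high/posterior pool and `f2` the low/anterior
#'   pool, so positive values mean JU1242 enrichment in the high pool).
#' @param n_rils_per_pool Lines per pool.
#' @param pseudocount Pseudocount `eps`.
#' @return Numeric vector of log-odds ratios.
#' @export
log_odds_ratio <- function(f1, f2, n_rils_per_pool = 40, pseudocount = 1e-6) {
  tol <- 1e-9 # windowed means may overshoot [0, 1] by floating-point error
  if (any(f1 < -tol | f1 > 1 + tol) || any(f2 < -tol | f2 > 1 + tol)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  f1 <- pmin(pmax(f1, 0), 1)
  f2 <- pmin(pmax(f2, 0), 1)
  lor_m(f1 * n_rils_per_pool, f2 * n_rils_per_pool, n_rils_per_pool, pseudocount)
}

# log-odds ratio on the line-count (m) scale
lor_m <- function(m1, m2, n, eps) {
  log((m1 + eps) / (n - m1 + eps)) - log((m2 + eps) / (n - m2 + eps))
}

#' Monte Carlo significance threshold for the log-odds-ratio scan
#'
#' Under the null of no linkage both pools draw their JU1242 line counts
#' independently from `Binomial(n_rils_per_pool, 1/2)`; the statistic is
#' computed for `n_null_draws` such pairs and the empirical `alpha/2` and
#' `1 - alpha/2` quantiles give the two-sided genome-wide thresholds
#' (the null is symmetric under pool swap, so they are near-mirror images).
#'
#' The alternative `null = "pool_and_reads"` additionally resamples each
#' pool's frequency through Poisson sequencing depth and binomial read
#' sampling, giving a null that also accounts for finite coverage; it is not
#' the default.
#'
#' @param params A [bsa_params()] (uses `n_rils_per_pool`, `pseudocount`,
#'   `alpha`, `n_null_draws`, and for the read-aware null `min_coverage`).
#' @param seed Optional integer seed.
#' @param null `"pool_binomial"` (default) or `"pool_and_reads"`.
#' @param mean_depth Mean coverage for the read-aware null.
#' @return An object of class `bsa_threshold`: list with `threshold_low`,
#'   `threshold_high`, `alpha`, `n_draws`, `null`.
#' @export
simulate_threshold <- function(params = bsa_params(), seed = NULL,
                               null = c("pool_binomial", "pool_and_reads"),
                               mean_depth = 20) {
  null <- match.arg(null)
  n <- params$n_rils_per_pool
  eps <- params$pseudocount
  nd <- params$n_null_draws
  maybe_with_seed(seed, {
    m1 <- stats::rbinom(nd, n, 0.5)
    m2 <- stats::rbinom(nd, n, 0.5)
    if (null == "pool_and_reads") {
      d1 <- stats::rpois(nd, mean_depth)
      d2 <- stats::rpois(nd, mean_depth)
      keep <- d1 > params$min_coverage & d2 > params$min_coverage
      m1 <- stats::rbinom(sum(keep), d1[keep], m1[keep] / n) / d1[keep] * n
      m2 <- stats::rbinom(sum(keep), d2[keep], m2[keep] / n) / d2[keep] * n
    }
    draws <- lor_m(m1, m2, n, eps)
    q <- stats::quantile(draws, c(params$alpha / 2, 1 - params$alpha / 2),
                         names = FALSE, type = 1)
    structure(list(threshold_low = q[1], threshold_high = q[2],
                   alpha = params$alpha, n_draws = length(draws), null = null),
              class = "bsa_threshold")
  })
}

#' @export
print.bsa_threshold <- function(x, ...) {
  cat(sprintf("<bsa_threshold> [%.4f, %.4f] at alpha = %g (%s, %d draws)\n",
              x$threshold_low, x$threshold_high, x$alpha, x$null, x$n_draws))
  invisible(x)
}

#' Call QTL intervals from a log-odds-ratio track
#'
#' Maximal runs of consecutive emitted positions with `lor >
#' threshold_high` (JU1242 enriched in pool 2) or `lor < threshold_low`
#' (enriched in pool 1) become candidate intervals. Within each interval the
#' longest sub-run where the favored pool's smoothed JU1242 frequency is
#' within `fixation_eps` of fixation is reported (`fixed_start`/`fixed_end`,
#' `NA` when absent), mirroring the fixed region observed over a strong QTL.
#'
#' @param track Tibble with `chrom`, `pos`, `lor`, `freq_pool1`,
#'   `freq_pool2` (as produced by [bsa_scan()]).
#' @param threshold_low,threshold_high Thresholds from
#'   [simulate_threshold()] (or a `bsa_threshold` passed as
#'   `threshold_low`).
#' @param fixation_eps Fixation tolerance on the smoothed frequency.
#' @return Tibble of intervals: `chrom`, `start`, `end` (1-based inclusive,
#'   emitted positions), `direction` (`"pool2"` or `"pool1"`: the pool with
#'   elevated JU1242 frequency), `n_positions`, `peak_pos`, `peak_lor`,
#'   `fixed`, `fixed_start`, `fixed_end`.
#' @export
call_qtl_intervals <- function(track, threshold_low, threshold_high = NULL,
                               fixation_eps = 0.02) {
  if (inherits(threshold_low, "bsa_threshold")) {
    threshold_high <- threshold_low$threshold_high
    threshold_low <- threshold_low$threshold_low
  }
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), direction = character(),
                          n_positions = integer(), peak_pos = integer(),
                          peak_lor = numeric(), fixed = logical(),
                          fixed_start = integer(), fixed_end = integer())
  if (nrow(track) == 0L) return(empty)
  out <- list(empty)
  for (ch in unique(track$chrom)) {
    d <- track[track$chrom == ch, ]
    state <- ifelse(d$lor > threshold_high, 1L,
                    ifelse(d$lor < threshold_low, -1L, 0L))
    r <- rle(state)
    stop_at <- cumsum(r$lengths)
    start_at <- stop_at - r$lengths + 1L
    for (k in which(r$values != 0L)) {
      i <- start_at[k]:stop_at[k]
      dir <- if (r$values[k] == 1L) "pool2" else "pool1"
      fav <- if (dir == "pool2") d$freq_pool2[i] else d$freq_pool1[i]
      pk <- i[which.max(abs(d$lor[i]))]
      fx <- fav >= 1 - fixation_eps
      fs <- fe <- NA_integer_
      if (any(fx)) {
        fr <- rle(fx)
        ends <- cumsum(fr$lengths)
        starts <- ends - fr$lengths + 1L
        best <- which(fr$values)[which.max(fr$lengths[fr$values])]
        fs <- d$pos[i[starts[best]]]
        fe <- d$pos[i[ends[best]]]
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = ch, start = d$pos[i[1]], end = d$pos[i[length(i)]],
        direction = dir, n_positions = length(i),
        peak_pos = d$pos[pk], peak_lor = d$lor[pk],
        fixed = any(fx), fixed_start = fs, fixed_end = fe)
    }
  }
  do.call(rbind, out)
}

#' Run the full BSA scan on a pool count table
#'
#' Applies, in order: the strict per-pool coverage filter, the JU1242
#' allele-frequency rules, sliding-window smoothing of the frequencies, the
#' pseudocounted log-odds-ratio statistic on the smoothed tracks (pool 2,
#' the high/posterior pool, versus pool 1), Monte Carlo calibration of the
#' two-sided genome-wide threshold, and interval calling.
#'
#' @param counts A [pool_counts()] table.
#' @param params A [bsa_params()].
#' @param thresholds Optional precomputed [simulate_threshold()] result
#'   (reuse across replicate scans with identical parameters).
#' @param seed Optional integer seed for the threshold simulation.
#' @return An object of class `bsa_result`: list with `track` (smoothed
#'   frequencies plus `lor`), `thresholds`, `intervals`, `params`.
#' @export
bsa_scan <- function(counts, params = bsa_params(), thresholds = NULL,
                     seed = NULL) {
  stopifnot(inherits(params, "bsa_params"))
  kept <- filter_by_coverage(counts, params$min_coverage)
  if (nrow(kept) == 0L) {
    stop("no data: no site passes the coverage filter", call. = FALSE)
  }
  freqs <- pool_frequencies(kept)
  track <- smooth_frequencies(freqs, params$window_bp, params$step_bp,
                              params$smoothing)
  track$lor <- log_odds_ratio(track$freq_pool2, track$freq_pool1,
                              params$n_rils_per_pool, params$pseudocount)
  thresholds <- thresholds %||% simulate_threshold(params, seed = seed)
  intervals <- call_qtl_intervals(track, thresholds,
                                  fixation_eps = params$fixation_eps)
  structure(list(track = track, thresholds = thresholds,
                 intervals = intervals, params = params),
            class = "bsa_result")
}

#' @export
print.bsa_result <- function(x, ...) {
  cat(sprintf("<bsa_result> %d smoothed positions on %d chromosome(s)\n",
              nrow(x$track), length(unique(x$track$chrom))))
  print(x$thresholds)
  if (nrow(x$intervals) == 0L) {
    cat("no significant intervals\n")
  } else {
    cat(sprintf("%d significant interval(s):\n", nrow(x$intervals)))
    print(x$intervals)
  }
  invisible(x)
}

#' Plot a BSA scan
#'
#' Log-odds ratio along the genome with the significance thresholds and the
#' called intervals; one panel row, chromosomes concatenated.
#'
#' @param x A `bsa_result`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.bsa_result <- function(x, ...) {
  tr <- x$track
  chroms <- unique(tr$chrom)
  offs <- stats::setNames(cumsum(c(0, vapply(chroms, function(ch)
    max(tr$pos[tr$chrom == ch]), numeric(1))))[seq_along(chroms)], chroms)
  gx <- tr$pos + offs[tr$chrom]
  plot(gx / 1e6, tr$lor, pch = ".", xlab = "genome position (Mb)",
       ylab = "log-odds ratio", ...)
  graphics::abline(h = c(x$thresholds$threshold_low,
                         x$thresholds$threshold_high), lty = 2)
  graphics::abline(v = offs[-1] / 1e6, col = "grey")
  if (nrow(x$intervals) > 0) {
    graphics::rect((x$intervals$start + offs[x$intervals$chrom]) / 1e6,
                   graphics::par("usr")[3],
                   (x$intervals$end + offs[x$intervals$chrom]) / 1e6,
                   graphics::par("usr")[4],
                   col = grDevices::adjustcolor("red", 0.15), border = NA)
  }
  invisible(x)
}
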