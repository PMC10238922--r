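# Independent oracles used by the tests. These deliberately recompute every
# quantity from first principles (closed forms, enumeration, pair counting)
# and share no code with the package internals they check.

# Haldane map function: recombination fraction for a distance in cM
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

# recombinant fraction among fully inbred selfing RILs (Haldane-Waddington)
ril_recomb <- function(r) 2 * r / (1 + 2 * r)

# brute-force sliding-window means: for each anchor, average the values of
# sites with anchor <= pos < anchor + window
brute_window_mean <- function(pos, vals, anchor, window) {
  inside <- pos >= anchor & pos < anchor + window
  if (!any(inside)) return(NULL)
  list(mean = mean(vals[inside]), n = sum(inside), idx = which(inside))
}

# exact null quantiles of the log-odds-ratio statistic by full enumeration of
# the 41 x 41 product-binomial outcome grid (for n RILs per pool)
exact_null_lor <- function(n = 40, alpha = 0.001, eps = 1e-6) {
  m <- 0:n
  lor <- outer(m, m, function(m1, m2) {
    log((m1 + eps) / (n - m1 + eps)) - log((m2 + eps) / (n - m2 + eps))
  })
  p <- outer(dbinom(m, n, 0.5), dbinom(m, n, 0.5))
  ord <- order(lor)
  v <- as.vector(lor)[ord]
  cdf <- cumsum(as.vector(p)[ord])
  qtl <- function(prob) v[which(cdf >= prob - 1e-12)[1]]
  u <- sort(unique(round(v, 12)))
  spacing_at <- function(x) {
    i <- which.min(abs(u - x))
    max(diff(u[max(1, i - 1):min(length(u), i + 1)]))
  }
  list(low = qtl(alpha / 2), high = qtl(1 - alpha / 2),
       spacing_at = spacing_at)
}

# Wilcoxon W by direct pair counting (Mann-Whitney with half ties)
brute_wilcoxon_W <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# mid-ranks by counting, without rank()
brute_midranks <- function(v) {
  vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
}

# Dunn Z statistics from first principles
brute_dunn_Z <- function(values, groups) {
  g <- sort(unique(as.character(groups)))
  N <- length(values)
  r <- brute_midranks(values)
  ties <- as.vector(table(values))
  C <- sum(ties^3 - ties) / (12 * (N - 1))
  V <- N * (N + 1) / 12 - C
  out <- list()
  for (i in seq_along(g)) for (j in seq_along(g)) if (i < j) {
    a <- groups == g[i]; b <- groups == g[j]
    z <- (mean(r[a]) - mean(r[b])) / sqrt(V * (1 / sum(a) + 1 / sum(b)))
    out[[paste(g[i], g[j], sep = "|")]] <- z
  }
  unlist(out)
}

# small single-chromosome genome for fast simulation tests
tiny_genome <- function(n_markers = 11, length_bp = 1e6, length_cM = 50) {
  genome_spec(data.frame(name = "chr1", length_bp = length_bp,
                         length_cM = length_cM),
              markers = data.frame(chrom = "chr1",
                                   pos = round(seq(1, length_bp,
                                                   length.out = n_markers))))
}

# two-marker genome whose markers recombine with probability r per meiosis
two_marker_genome <- function(r) {
  d <- -50 * log(1 - 2 * r)  # inverse Haldane, in cM
  genome_spec(data.frame(name = "chr1", length_bp = 1e6, length_cM = d),
              markers = data.frame(chrom = "chr1", pos = c(1L, 1000000L)))
}

# fraction of heterozygous marker calls per line
het_fraction <- function(dip) mean(dip$h1 != dip$h2)

# no-QTL model (both parental means equal)
flat_qtl <- function(chrom = "chr1", pos = 5e5) {
  qtl_model(chromosome = chrom, position_bp = pos, mean_AA = 5, mean_BB = 5,
            dominance_h = 0.5, residual_sd = 0.6)
}
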