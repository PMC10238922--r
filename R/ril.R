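#' QTL model for the simulated cross
#'
#' A single biallelic QTL with additive-plus-dominance action. Parental-origin
#' allele B (JU1242 by default) shifts the phenotype from `mean_AA` towards
#' `mean_BB`; heterozygotes sit at `mean_AA + dominance_h * (mean_BB -
#' mean_AA)`. The defaults reproduce the published cross: parental QR.pap
#' means 4.16 (CB4932) and 5.54 (JU1242) on the 0-27 V-cell scale, with the
#' JU1242 allele mostly dominant (h = 0.85 places heterozygotes near 5.33).
#' The residual standard deviation is a free calibration parameter (0.6 by
#' default); the published figures show only mean +/- s.d. bars.
#'
#' @param chromosome Chromosome carrying the QTL.
#' @param position_bp QTL position in bp (1-based).
#' @param mean_AA,mean_BB Genotype means on the phenotype scale.
#' @param dominance_h Dominance coefficient in `[0, 1]` (0 = A fully
#'   dominant, 1 = B fully dominant).
#' @param residual_sd Residual (within-line) standard deviation, > 0.
#' @return An object of class `qtl_model`.
#' @export
qtl_model <- function(chromosome = "chrIV", position_bp = 5200000,
                      mean_AA = 4.16, mean_BB = 5.54,
                      dominance_h = 0.85, residual_sd = 0.6) {
  if (residual_sd <= 0) stop("`residual_sd` must be > 0", call. = FALSE)
  if (dominance_h < 0 || dominance_h > 1) {
    stop("`dominance_h` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(chromosome = chromosome, position_bp = as.integer(position_bp),
         mean_AA = mean_AA, mean_BB = mean_BB,
         dominance_h = dominance_h, residual_sd = residual_sd),
    class = "qtl_model"
  )
}

#' Fully heterozygous F1 diplotype
#'
#' One haplotype from each parent at every marker: haplotype 1 carries the
#' A (CB4932) allele (code 0), haplotype 2 the B (JU1242) allele (code 1).
#'
#' @param genome A [genome_spec()].
#' @return An object of class `diplotype`: a list with integer vectors `h1`
#'   and `h2` over all markers (0 = A, 1 = B).
#' @export
f1_diplotype <- function(genome) {
  n <- n_markers(genome)
  structure(list(h1 = integer(n), h2 = rep(1L, n)), class = "diplotype")
}

#' Build a diplotype from explicit haplotypes
#'
#' @param h1,h2 Integer vectors of parental-origin codes (0 = A/CB4932,
#'   1 = B/JU1242), one entry per marker of the genome they refer to.
#' @return A `diplotype`. Pairs are unordered: `(h1, h2)` and `(h2, h1)`
#'   describe the same genotype.
#' @export
diplotype <- function(h1, h2) {
  if (length(h1) != length(h2)) stop("haplotype lengths differ", call. = FALSE)
  if (!all(c(h1, h2) %in% c(0L, 1L))) {
    stop("haplotype codes must be 0 (A) or 1 (B)", call. = FALSE)
  }
  structure(list(h1 = as.integer(h1), h2 = as.integer(h2)), class = "diplotype")
}

#' Simulate one gamete by meiosis
#'
#' Crossovers per chromosome are Poisson with mean `length_cM / 100`
#' (one crossover per Morgan on average) and breakpoints are uniform on the
#' genetic map, i.e. the Haldane model with no crossover interference: two
#' markers separated by d Morgans recombine with probability
#' `(1 - exp(-2 d)) / 2`.
#'
#' @param dip A [diplotype()].
#' @param genome A [genome_spec()].
#' @param seed Optional integer seed (the global RNG state is preserved).
#' @return Integer haplotype vector over all markers (0 = A, 1 = B), a mosaic
#'   of the two input haplotypes.
#' @export
simulate_gamete <- function(dip, genome, seed = NULL) {
  stopifnot(inherits(dip, "diplotype"), inherits(genome, "genome_spec"))
  if (length(dip$h1) != n_markers(genome)) {
    stop("diplotype and genome have different marker counts", call. = FALSE)
  }
  maybe_with_seed(seed, {
    hap <- integer(n_markers(genome))
    for (i in seq_len(nrow(genome$chromosomes))) {
      rows <- genome$index[[i]]
      L <- genome$chromosomes$length_cM[i]
      first <- sample.int(2L, 1L)
      k <- stats::rpois(1L, L / 100)
      if (k == 0L) {
        hap[rows] <- if (first == 1L) dip$h1[rows] else dip$h2[rows]
      } else {
        breaks <- sort(stats::runif(k, 0, L))
        seg <- findInterval(genome$markers$gpos[rows], breaks)
        use1 <- ((seg + first) %% 2L) == 1L
        out <- dip$h2[rows]
        out[use1] <- dip$h1[rows][use1]
        hap[rows] <- out
      }
    }
    hap
  })
}

#' Self-fertilize a founder for several generations
#'
#' Follows a single-individual descent: at each generation two independent
#' gametes of the current individual are united, emulating the transfer of a
#' single selfing hermaphrodite per line and generation. Starting from the
#' fully heterozygous F1, `n_generations = 4` yields an F5 individual with
#' expected per-marker heterozygosity `(1/2)^4 = 1/16`.
#'
#' @param founder Founder [diplotype()] (typically [f1_diplotype()]).
#' @param n_generations Number of selfing rounds, >= 1.
#' @param genome A [genome_spec()].
#' @param seed Optional integer seed.
#' @return The `diplotype` of one F(1 + n_generations) individual.
#' @export
self_to_generation <- function(founder, n_generations, genome, seed = NULL) {
  stop_if_not_scalar_count(n_generations, "n_generations", min = 1L)
  maybe_with_seed(seed, {
    dip <- founder
    for (g in seq_len(n_generations)) {
      dip <- diplotype(simulate_gamete(dip, genome),
                       simulate_gamete(dip, genome))
    }
    dip
  })
}

#' Construct a RIL population container
#'
#' @param genome A [genome_spec()].
#' @param geno Integer matrix, lines x markers, of B-allele dosages (0 = AA,
#'   1 = AB, 2 = BB).
#' @param line_ids Character vector of line identifiers.
#' @param n_generations Selfing generations the lines went through.
#' @param phenotypes Optional numeric matrix, lines x animals.
#' @return An object of class `ril_population`.
#' @export
ril_population <- function(genome, geno, line_ids = NULL, n_generations = NA,
                           phenotypes = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (ncol(geno) != n_markers(genome)) {
    stop("genotype matrix has wrong number of markers", call. = FALSE)
  }
  if (!all(geno %in% 0:2)) {
    stop("genotype dosages must be 0, 1 or 2", call. = FALSE)
  }
  line_ids <- line_ids %||% sprintf("RIL%03d", seq_len(nrow(geno)))
  structure(
    list(genome = genome, geno = geno, line_ids = line_ids,
         n_generations = n_generations, phenotypes = phenotypes),
    class = "ril_population"
  )
}

#' @export
print.ril_population <- function(x, ...) {
  cat(sprintf("<ril_population> %d lines x %d markers", nrow(x$geno), ncol(x$geno)))
  if (!is.null(x$phenotypes)) {
    cat(sprintf(", %d phenotyped animals/line", ncol(x$phenotypes)))
  }
  cat("\n")
  invisible(x)
}

# genotype dosage mean on the phenotype scale
qtl_class_mean <- function(dosage, qtl) {
  shift <- c(0, qtl$dominance_h, 1)[dosage + 1L]
  qtl$mean_AA + shift * (qtl$mean_BB - qtl$mean_AA)
}

# marker used to read the QTL genotype: nearest marker at or left of the
# QTL position (deterministic tie rule)
qtl_marker_column <- function(genome, qtl) {
  rows <- chrom_rows(genome, qtl$chromosome)
  pos <- genome$markers$pos[rows]
  j <- findInterval(qtl$position_bp, pos)
  if (j == 0L) {
    stop("QTL position precedes the first marker of its chromosome", call. = FALSE)
  }
  rows[j]
}

#' Assign per-animal phenotypes from a QTL model
#'
#' Each line's QTL genotype is read at the nearest marker at or to the left of
#' the QTL position. Every scored animal receives the genotype mean plus
#' independent Gaussian noise, then values are clamped to the bounded 0-27
#' V-cell scale.
#'
#' @param pop A [ril_population()].
#' @param qtl A [qtl_model()].
#' @param n_animals_per_line Animals scored per line (20 in the emulated
#'   study design), >= 1.
#' @param seed Optional integer seed.
#' @return The population with a `phenotypes` matrix (lines x animals).
#' @export
assign_phenotypes <- function(pop, qtl, n_animals_per_line = 20, seed = NULL) {
  stopifnot(inherits(pop, "ril_population"), inherits(qtl, "qtl_model"))
  stop_if_not_scalar_count(n_animals_per_line, "n_animals_per_line", min = 1L)
  col <- qtl_marker_column(pop$genome, qtl)
  mu <- qtl_class_mean(pop$geno[, col], qtl)
  n_lines <- nrow(pop$geno)
  maybe_with_seed(seed, {
    noise <- stats::rnorm(n_lines * n_animals_per_line, 0, qtl$residual_sd)
    ph <- matrix(rep(mu, n_animals_per_line) + noise,
                 nrow = n_lines, ncol = n_animals_per_line)
    pop$phenotypes <- pmin(pmax(ph, 0), 27)
    pop
  })
}

#' Simulate a phenotyped RIL population
#'
#' Runs `n_lines` independent single-descent selfing chains from the F1
#' (each line gets its own child seed derived from the root seed, so
#' populations are reproducible and lines are exchangeable), then phenotypes
#' every line under the QTL model. The defaults emulate the published cross:
#' 200 lines selfed to F5 (4 rounds), 20 animals scored per line.
#'
#' @param genome A [genome_spec()].
#' @param qtl A [qtl_model()].
#' @param n_lines Number of RILs, >= 2.
#' @param n_generations Selfing rounds from the F1 (4 = F5).
#' @param n_animals_per_line Animals scored per line.
#' @param seed Optional root seed; per-line child seeds are drawn from it.
#' @return A phenotyped [ril_population()].
#' @export
simulate_ril_population <- function(genome = default_genome(),
                                    qtl = qtl_model(),
                                    n_lines = 200, n_generations = 4,
                                    n_animals_per_line = 20, seed = NULL) {
  stop_if_not_scalar_count(n_lines, "n_lines", min = 2L)
  maybe_with_seed(seed, {
    seeds <- child_seeds(n_lines)
    founder <- f1_diplotype(genome)
    geno <- matrix(0L, nrow = n_lines, ncol = n_markers(genome))
    for (i in seq_len(n_lines)) {
      dip <- self_to_generation(founder, n_generations, genome, seed = seeds[i])
      geno[i, ] <- dip$h1 + dip$h2
    }
    pop <- ril_population(genome, geno, n_generations = n_generations)
    assign_phenotypes(pop, qtl, n_animals_per_line)
  })
}

#' Idealized chromosome-substitution (NIL) diplotype
#'
#' Homozygous for the donor parent along one chromosome and homozygous for
#' the recipient elsewhere, emulating a near-isogenic line built by repeated
#' backcrossing. Optionally, each background chromosome independently retains
#' a residual homozygous donor segment with probability `residual_rate`
#' (uniform random extent), mimicking incomplete background cleaning.
#'
#' @param genome A [genome_spec()].
#' @param donor_chromosome Name of the introgressed chromosome.
#' @param donor Which parent donates the chromosome: `"JU1242"` (B) or
#'   `"CB4932"` (A). The recipient background is the other parent.
#' @param residual_rate Per-background-chromosome probability of a leftover
#'   donor segment (default 0 = ideal NIL).
#' @param seed Optional integer seed (only used when `residual_rate > 0`).
#' @return A `diplotype`.
#' @export
simulate_introgression_line <- function(genome, donor_chromosome,
                                        donor = c("JU1242", "CB4932"),
                                        residual_rate = 0, seed = NULL) {
  donor <- match.arg(donor)
  rows <- chrom_rows(genome, donor_chromosome)
  donor_code <- if (donor == "JU1242") 1L else 0L
  hap <- rep(1L - donor_code, n_markers(genome))
  hap[rows] <- donor_code
  if (residual_rate > 0) {
    hap <- maybe_with_seed(seed, {
      for (ch in genome$chromosomes$name) {
        if (ch == donor_chromosome) next
        if (stats::runif(1) < residual_rate) {
          r <- genome$index[[ch]]
          ends <- sort(sample(seq_along(r), 2L))
          hap[r[ends[1]:ends[2]]] <- donor_code
        }
      }
      hap
    })
  }
  diplotype(hap, hap)
}

#' Per-line mean phenotypes
#'
#' @param pop A phenotyped [ril_population()].
#' @return Named numeric vector of line means.
#' @export
line_means <- function(pop) {
  if (is.null(pop$phenotypes)) stop("population has no phenotypes", call. = FALSE)
  stats::setNames(rowMeans(pop$phenotypes), pop$line_ids)
}
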