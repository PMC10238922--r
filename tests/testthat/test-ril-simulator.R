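test_that("gamete simulation honors degenerate limits and is reproducible", {
  g0 <- tiny_genome(n_markers = 5, length_cM = 0)
  f1 <- f1_diplotype(g0)
  # no recombination possible: each gamete is exactly one parental haplotype
  haps <- replicate(200, paste(simulate_gamete(f1, g0), collapse = ""))
  expect_true(all(haps %in% c("00000", "11111")))
  expect_gt(mean(haps == "11111"), 0.35) # both drawn with probability ~ 1/2
  expect_lt(mean(haps == "11111"), 0.65)

  g <- tiny_genome(n_markers = 7)
  hom <- diplotype(integer(7), integer(7))
  expect_identical(simulate_gamete(hom, g, seed = 1), integer(7))

  expect_identical(simulate_gamete(f1_diplotype(g), g, seed = 99),
                   simulate_gamete(f1_diplotype(g), g, seed = 99))
})

test_that("gamete recombinant fraction follows the Haldane map function", {
  d <- 20 # cM
  g <- genome_spec(data.frame(name = "chr1", length_bp = 1e6, length_cM = d),
                   markers = data.frame(chrom = "chr1", pos = c(1L, 1000000L)))
  f1 <- f1_diplotype(g)
  set.seed(11)
  rec <- replicate(10000, {
    h <- simulate_gamete(f1, g)
    h[1] != h[2]
  })
  r_expected <- haldane_r(d)
  se <- sqrt(r_expected * (1 - r_expected) / length(rec))
  expect_lt(abs(mean(rec) - r_expected), 3 * se)
})

test_that("selfing halves heterozygosity each generation", {
  g <- tiny_genome(n_markers = 11)
  f1 <- f1_diplotype(g)
  expect_error(self_to_generation(f1, 0, g), "n_generations")

  set.seed(21)
  het <- replicate(2000, het_fraction(self_to_generation(f1, 2, g)))
  se <- sd(het) / sqrt(length(het))
  expect_lt(abs(mean(het) - 0.25), 3 * se)
})

test_that("RIL recombinant fraction approaches the selfing-RIL closed form", {
  r <- 0.2
  g <- two_marker_genome(r)
  f1 <- f1_diplotype(g)
  set.seed(31)
  geno <- t(replicate(1500, {
    d <- self_to_generation(f1, 14, g)
    d$h1 + d$h2
  }))
  hom <- geno[, 1] != 1L & geno[, 2] != 1L
  rec <- geno[hom, 1] != geno[hom, 2]
  R <- ril_recomb(r)
  se <- sqrt(R * (1 - R) / sum(hom))
  expect_lt(abs(mean(rec) - R), 3 * se)
})

test_that("phenotype model reproduces genotype means, dominance and bounds", {
  g <- tiny_genome(n_markers = 5, length_bp = 1e6)
  qtl <- qtl_model(chromosome = "chr1", position_bp = 5e5, residual_sd = 1e-9)
  geno <- matrix(rep(c(0L, 1L, 2L), each = 5), nrow = 3, byrow = TRUE)
  pop <- ril_population(g, geno, line_ids = c("aa", "ab", "bb"))

  ph <- assign_phenotypes(pop, qtl, n_animals_per_line = 4, seed = 1)
  m <- unname(line_means(ph))
  expect_equal(m[1], 4.16, tolerance = 1e-6)
  expect_equal(m[2], 4.16 + 0.85 * (5.54 - 4.16), tolerance = 1e-6)
  expect_equal(m[3], 5.54, tolerance = 1e-6)

  # complete dominance: heterozygote sits exactly at the BB mean
  full_dom <- qtl_model(chromosome = "chr1", position_bp = 5e5,
                        dominance_h = 1, residual_sd = 1e-9)
  expect_equal(unname(line_means(assign_phenotypes(pop, full_dom, 4, seed = 1)))[2],
               5.54, tolerance = 1e-6)

  # the V-cell scale is bounded
  wild <- qtl_model(chromosome = "chr1", position_bp = 5e5,
                    mean_AA = -5, mean_BB = 40, residual_sd = 3)
  phw <- assign_phenotypes(pop, wild, 50, seed = 2)$phenotypes
  expect_true(all(phw >= 0 & phw <= 27))

  expect_error(assign_phenotypes(pop, qtl, n_animals_per_line = 0),
               "n_animals_per_line")
  expect_error(assign_phenotypes(pop, qtl_model(chromosome = "nope",
                                                position_bp = 1e5)),
               "not in genome")
})

test_that("simulated populations are Mendelian, bimodal and deterministic", {
  g <- default_genome(marker_spacing_bp = 500000)
  qtl <- qtl_model() # chrIV at 5.2 Mb, paper-calibrated means
  pop <- simulate_ril_population(g, qtl, n_lines = 200, seed = 5)
  expect_error(simulate_ril_population(g, qtl, n_lines = 1), "n_lines")

  # B-allele frequency ~ 0.5 across lines at every marker (no selection)
  bfreq <- colMeans(pop$geno) / 2
  se <- sqrt(0.5 * 0.5 / (2 * nrow(pop$geno))) # conservative binomial SE
  expect_lt(max(abs(bfreq - 0.5)), 5 * se)
  expect_lt(abs(mean(bfreq) - 0.5), 0.03)

  # line-mean distribution is a two-component mixture near the parental means
  m <- line_means(pop)
  expect_gt(mean(abs(m - 4.16) < 0.45), 0.25)
  expect_gt(mean(abs(m - 5.54) < 0.45), 0.25)
  expect_lt(mean(abs(m - (4.16 + 5.54) / 2) < 0.2), 0.15)

  pop2 <- simulate_ril_population(g, qtl, n_lines = 200, seed = 5)
  expect_identical(pop$geno, pop2$geno)
  expect_identical(pop$phenotypes, pop2$phenotypes)
})

test_that("introgression lines predict parental phenotypes at the QTL", {
  g <- default_genome(marker_spacing_bp = 500000)
  qtl <- qtl_model(residual_sd = 1e-9)
  mean_of <- function(dip) {
    pop <- ril_population(g, matrix(dip$h1 + dip$h2, nrow = 1),
                          line_ids = "NIL")
    unname(line_means(assign_phenotypes(pop, qtl, 4, seed = 1)))
  }
  # JU1242 chrIV in CB4932 background: posterior, like JU1242
  nil <- simulate_introgression_line(g, "chrIV", donor = "JU1242")
  expect_equal(mean_of(nil), 5.54, tolerance = 1e-6)
  # reciprocal swap recapitulates the CB4932 phenotype
  rev <- simulate_introgression_line(g, "chrIV", donor = "CB4932")
  expect_equal(mean_of(rev), 4.16, tolerance = 1e-6)
  # a donor chromosome without the QTL leaves the recipient phenotype
  off <- simulate_introgression_line(g, "chrV", donor = "JU1242")
  expect_equal(mean_of(off), 4.16, tolerance = 1e-6)

  expect_error(simulate_introgression_line(g, "chrZ"), "not in genome")
})
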