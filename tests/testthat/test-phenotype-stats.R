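test_that("Wilcoxon W honors exchange symmetry, extremes and complementarity", {
  x <- c(2, 2, 3, 3, 5)
  expect_equal(wilcoxon_rank_sum(x, x)$W, length(x)^2 / 2)

  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6, 7))$W, 0)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "nonempty")

  set.seed(41)
  for (i in 1:25) {
    a <- sample(0:8, sample(2:10, 1), replace = TRUE)
    b <- sample(0:8, sample(2:10, 1), replace = TRUE)
    wa <- wilcoxon_rank_sum(a, b)$W
    wb <- wilcoxon_rank_sum(b, a)$W
    expect_equal(wa + wb, length(a) * length(b))
    expect_equal(wa, brute_wilcoxon_W(a, b))
  }
})

test_that("Dunn Z is null for identical groups, antisymmetric and rank-based", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("g1", "g2"), each = 3)
  d <- dunn_test(v, g)
  expect_equal(d$comparisons$Z, 0)
  expect_equal(d$comparisons$p_adj, 1)

  set.seed(42)
  v <- c(rnorm(5), rnorm(6, 1), rnorm(4, 2))
  g <- rep(c("a", "b", "c"), c(5, 6, 4))
  d1 <- dunn_test(v, g)
  # relabeling so the lexicographic order reverses flips every Z sign
  g_rev <- c(a = "z3", b = "z2", c = "z1")[g]
  d2 <- dunn_test(v, g_rev)
  expect_equal(sort(d2$comparisons$Z), sort(-d1$comparisons$Z))

  # invariant under monotone transformation of the values
  d3 <- dunn_test(exp(v), g)
  expect_equal(d3$comparisons$Z, d1$comparisons$Z)

  # Bonferroni never shrinks and caps at 1
  expect_true(all(d1$comparisons$p_adj >= d1$comparisons$p_raw))
  expect_true(all(d1$comparisons$p_adj <= 1))

  expect_error(dunn_test(1:3, c("a", "a", "a")), "two groups")
})

test_that("Dunn Z matches a first-principles recomputation under ties", {
  set.seed(43)
  for (i in 1:20) {
    k <- sample(3:4, 1)
    n <- sample(3:6, k, replace = TRUE)
    v <- sample(0:5, sum(n), replace = TRUE)  # heavy ties
    g <- rep(paste0("grp", seq_len(k)), n)
    d <- dunn_test(v, g)
    oracle <- brute_dunn_Z(v, g)
    got <- setNames(d$comparisons$Z,
                    paste(d$comparisons$group_a, d$comparisons$group_b,
                          sep = "|"))
    expect_equal(got[names(oracle)], oracle, tolerance = 1e-12)
  }
})

test_that("compact letters cover the non-significance graph minimally", {
  pairs3 <- tibble::tibble(group_a = c("a1", "a1", "a2"),
                           group_b = c("a2", "a3", "a3"))

  all_ns <- transform(pairs3, p_adj = 0.9)
  expect_identical(unname(compact_letters(all_ns, 0.05)), rep("a", 3))

  all_sig <- transform(pairs3, p_adj = 0.001)
  expect_identical(unname(compact_letters(all_sig, 0.05)), c("a", "b", "c"))

  # exactly one non-significant pair: it shares a letter, the third is apart
  one_ns <- transform(pairs3, p_adj = c(0.8, 0.01, 0.01))
  lt <- compact_letters(one_ns, 0.05)
  expect_identical(unname(lt), c("a", "a", "b")) # minimal two-letter solution

  # random instances: sharing a letter <=> the pair is not significant
  set.seed(44)
  for (i in 1:30) {
    k <- sample(3:5, 1)
    gr <- paste0("g", seq_len(k))
    cmb <- utils::combn(gr, 2)
    cmp <- tibble::tibble(group_a = cmb[1, ], group_b = cmb[2, ],
                          p_adj = runif(ncol(cmb)))
    lt <- compact_letters(cmp, 0.5)
    share <- function(u, w) {
      length(intersect(strsplit(lt[[u]], "")[[1]],
                       strsplit(lt[[w]], "")[[1]])) > 0
    }
    for (j in seq_len(ncol(cmb))) {
      ns <- cmp$p_adj[j] >= 0.5
      expect_identical(share(cmp$group_a[j], cmp$group_b[j]), ns)
    }
    expect_true(all(nchar(lt) > 0)) # every group lettered
  }
})
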