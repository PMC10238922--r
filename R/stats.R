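#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum comparison as used for the parental phenotype
#' contrasts. The statistic is `W = (rank sum of x, mid-ranks under ties) -
#' n_x (n_x + 1) / 2`, i.e. the Mann-Whitney count of `(x, y)` pairs with
#' `x > y` plus half the tied pairs; it can be half-integer under ties. The
#' p-value uses the normal approximation with tie correction and continuity
#' correction by default (the convention of the original analysis
#' environment); `exact = TRUE` requests the exact distribution, available
#' for untied samples.
#'
#' Computation is delegated to [stats::wilcox.test()], whose `W` follows
#' exactly this convention with `x` the first-named group.
#'
#' @param x,y Numeric vectors (both nonempty); `x` is the first-named group.
#' @param exact Use the exact null distribution (falls back to the corrected
#'   normal approximation under ties).
#' @param correct Apply the continuity correction in the approximation.
#' @return List with `W` and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact = FALSE, correct = TRUE) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = correct))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' All values are pooled and mid-ranked; for each pair of groups (ordered
#' lexicographically) the standardized mean-rank difference is
#' `Z = (Rbar_a - Rbar_b) / sqrt((N (N + 1) / 12 - C) (1/n_a + 1/n_b))`
#' with the tie correction `C = sum(t^3 - t) / (12 (N - 1))` over tie groups
#' of size `t` (Dunn 1964). Raw p-values are Bonferroni-adjusted over all
#' `k (k - 1) / 2` pairs.
#'
#' `p_type = "two.sided"` (default) reports `2 * P(|Z| > z)`;
#' `"one.sided"` reports `P(Z > |z|)`, the convention of the `dunn.test`
#' package used in many published analyses (its adjusted p-values are half
#' the two-sided ones).
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`; every group must be
#'   nonempty and there must be at least two groups.
#' @param adjust Multiple-testing adjustment (only `"bonferroni"`).
#' @param p_type `"two.sided"` or `"one.sided"` raw p-values.
#' @return An object of class `dunn_result`: list with `comparisons`
#'   (tibble: `group_a`, `group_b`, `Z`, `p_raw`, `p_adj`), `mean_ranks`,
#'   `kruskal` (the [stats::kruskal.test()] result) and `p_type`.
#' @export
dunn_test <- function(values, groups, adjust = "bonferroni",
                      p_type = c("two.sided", "one.sided")) {
  adjust <- match.arg(adjust)
  p_type <- match.arg(p_type)
  if (length(values) != length(groups)) {
    stop("`values` and `groups` lengths differ", call. = FALSE)
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(tabulate(g) == 0L)) stop("empty group", call. = FALSE)

  N <- length(values)
  r <- rank(values)                       # mid-ranks
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  tie_sizes <- table(values)
  C <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  V <- N * (N + 1) / 12 - C

  lev <- levels(g)                        # lexicographic pair order
  pairs <- utils::combn(seq_along(lev), 2L)
  Z <- (rbar[pairs[1L, ]] - rbar[pairs[2L, ]]) /
    sqrt(V * (1 / n[pairs[1L, ]] + 1 / n[pairs[2L, ]]))
  Z <- as.vector(Z)
  p_raw <- if (p_type == "two.sided") 2 * stats::pnorm(-abs(Z)) else
    stats::pnorm(-abs(Z))
  p_adj <- stats::p.adjust(p_raw, method = adjust)

  structure(list(
    comparisons = tibble::tibble(group_a = lev[pairs[1L, ]],
                                 group_b = lev[pairs[2L, ]],
                                 Z = Z, p_raw = p_raw, p_adj = p_adj),
    mean_ranks = rbar,
    kruskal = stats::kruskal.test(values, g),
    p_type = p_type
  ), class = "dunn_result")
}

#' @export
print.dunn_result <- function(x, ...) {
  kw <- x$kruskal
  cat(sprintf("Kruskal-Wallis chi-squared = %.3f, df = %d, p = %.3g\n",
              unname(kw$statistic), unname(kw$parameter), kw$p.value))
  cat(sprintf("Dunn's test (Bonferroni, %s p-values):\n", x$p_type))
  d <- x$comparisons
  d$Z <- round(d$Z, 2)    # display rounding only
  print(d)
  invisible(x)
}

#' Compact letter display
#'
#' Assigns letters to groups so that two groups share a letter if and only
#' if their pairwise comparison is not significant at `level`, using the
#' insert-and-absorb algorithm: start from one letter covering all groups,
#' split every letter containing a significant pair, then absorb letters
#' whose group set is contained in another's.
#'
#' @param x A [dunn_test()] result, or a data frame with columns `group_a`,
#'   `group_b`, `p_adj` covering every pair.
#' @param level Significance level (pairs with `p_adj < level` are
#'   separated).
#' @return Named character vector: letter string per group (e.g. `"ab"`).
#' @export
compact_letters <- function(x, level = 0.05) {
  cmp <- if (inherits(x, "dunn_result")) x$comparisons else tibble::as_tibble(x)
  groups <- sort(unique(c(cmp$group_a, cmp$group_b)))
  sig <- cmp[cmp$p_adj < level, , drop = FALSE]

  cols <- list(groups)
  if (nrow(sig) > 0L) {
    for (s in seq_len(nrow(sig))) {
      a <- sig$group_a[s]; b <- sig$group_b[s]
      new_cols <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # dedupe identical letters and absorb subsets
      new_cols <- unique(lapply(new_cols, sort))
      keep <- vapply(seq_along(new_cols), function(i) {
        !any(vapply(seq_along(new_cols), function(j) {
          i != j && all(new_cols[[i]] %in% new_cols[[j]]) &&
            (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j)
        }, logical(1)))
      }, logical(1))
      cols <- new_cols[keep]
    }
  }
  # stable ordering: by first (alphabetically first) member
  cols <- cols[order(vapply(cols, function(col) match(col[1], groups), 1L))]
  letters_used <- letters[seq_along(cols)]
  out <- vapply(groups, function(grp) {
    paste(letters_used[vapply(cols, function(col) grp %in% col, logical(1))],
          collapse = "")
  }, character(1))
  stats::setNames(out, groups)
}
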