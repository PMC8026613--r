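# Statistical tests used across the analyses: Mann-Whitney U for group
# expression comparisons, Fisher/chi-squared for 2x2 association tables,
# and a genomic permutation test for community-TAD overlap.

#' Mann-Whitney U test
#'
#' Exact enumeration (via the null rank distribution) when
#' `min(n1, n2) <= 8` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction. The U
#' statistic is reported for `group1`. When all values across both groups
#' are identical, p = 1.
#'
#' @param group1,group2 numeric vectors (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return One-row tibble: `statistic` (U for group1), `p_value`, `method`
#'   (`exact`/`normal_approx`), `n1`, `n2`, `alternative`.
#' @export
mann_whitney_u <- function(group1, group2,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(group1) > 0, length(group2) > 0)
  ties <- anyDuplicated(c(group1, group2)) > 0
  if (diff(range(c(group1, group2))) == 0) {
    return(tibble(statistic = length(group1) * length(group2) / 2,
                  p_value = 1, method = "degenerate",
                  n1 = length(group1), n2 = length(group2),
                  alternative = alternative))
  }
  exact <- min(length(group1), length(group2)) <= 8 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(group1, group2, alternative = alternative,
                       exact = exact, correct = TRUE)
  )
  tibble(
    statistic = unname(res$statistic),
    p_value = min(1, res$p.value),
    method = if (exact) "exact" else "normal_approx",
    n1 = length(group1), n2 = length(group2),
    alternative = alternative
  )
}

#' Fisher or chi-squared test on a 2x2 table
#'
#' In `auto` mode the chi-squared test (without continuity correction) is
#' used when every expected cell is at least 5, and Fisher's exact test is
#' substituted otherwise (the `test` column records which ran). The odds
#' ratio is the cross-product ratio computed from the counts, with a 0.5
#' continuity correction applied when any cell is zero (`or_corrected`
#' flags it). A table with a zero margin yields p = 1 and a missing OR.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param prefer `"auto"` (default), `"fisher"` or `"chisq"`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (one-tailed variants apply to Fisher's test).
#' @return One-row tibble: counts `a`,`b`,`c`,`d`, `odds_ratio`,
#'   `log2_odds_ratio`, `or_corrected`, `test`, `p_value`, `alternative`.
#' @export
fisher_or_chisq <- function(tab, prefer = c("auto", "fisher", "chisq"),
                            alternative = c("two.sided", "less", "greater")) {
  prefer <- match.arg(prefer)
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  total <- sum(tab)
  zero_margin <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  corrected <- any(tab == 0) && !zero_margin
  or <- if (zero_margin) NA_real_ else if (corrected) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  if (zero_margin) {
    return(tibble(a = a, b = b, c = cc, d = d, odds_ratio = NA_real_,
                  log2_odds_ratio = NA_real_, or_corrected = FALSE,
                  test = "none", p_value = 1, alternative = alternative))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / total
  use_chisq <- switch(prefer,
                      auto = all(expected >= 5),
                      chisq = TRUE,
                      fisher = FALSE)
  if (use_chisq && alternative == "two.sided") {
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    test <- "chi_squared"
  } else {
    p <- stats::fisher.test(tab, alternative = alternative)$p.value
    test <- "fisher"
  }
  tibble(a = a, b = b, c = cc, d = d, odds_ratio = or,
         log2_odds_ratio = log2(or), or_corrected = corrected,
         test = test, p_value = min(1, p), alternative = alternative)
}

#' Benjamini-Hochberg adjustment helper
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values (`stats::p.adjust`, method "BH").
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")

#' Permutation test for genomic region overlap
#'
#' Observed statistic: the number of query regions overlapping at least one
#' reference region. The null distribution is obtained by re-placing each
#' query region uniformly at random within its own chromosome
#' (width-preserving, chromosome-preserving; `"circular"` instead applies a
#' single random shift per chromosome). The empirical p-value uses the +1
#' pseudocount convention, `(1 + #{null >= observed}) / (N + 1)`, so it is
#' never zero.
#'
#' @param query,reference interval tibbles (`chrom`, `start`, `end`).
#' @param genome tibble `chrom`, `length`.
#' @param n_perm number of permutations (default 1000, must be >= 1).
#' @param seed RNG seed (recorded in the output).
#' @param strategy `"uniform"` (default) or `"circular"`.
#' @return One-row tibble: `observed`, `null_mean`, `null_sd`, `z`,
#'   `p_value`, `n_perm`, `seed`, `strategy`.
#' @export
permutation_overlap_test <- function(query, reference, genome,
                                     n_perm = 1000L, seed = 1L,
                                     strategy = c("uniform", "circular")) {
  strategy <- match.arg(strategy)
  if (n_perm < 1) abort("n_perm must be >= 1")
  glen <- setNames(genome$length, genome$chrom)
  if (!all(query$chrom %in% names(glen))) {
    abort("query chromosome absent from genome table")
  }
  ref_gr <- gr_from_tbl(reference)
  count_overlap <- function(q) {
    sum(ov_count(gr_from_tbl(q), ref_gr) > 0)
  }
  observed <- count_overlap(query)
  widths <- query$end - query$start
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    if (strategy == "uniform") {
      start <- floor(runif(nrow(query)) * (glen[query$chrom] - widths + 1))
    } else {
      shift <- floor(runif(length(glen)) * glen)
      start <- (query$start + shift[query$chrom]) %% (glen[query$chrom] - widths)
    }
    count_overlap(tibble(chrom = query$chrom, start = start,
                         end = start + widths))
  }, numeric(1))
  sdv <- stats::sd(null)
  tibble(
    observed = observed,
    null_mean = mean(null),
    null_sd = sdv,
    z = if (isTRUE(sdv > 0)) (observed - mean(null)) / sdv else NA_real_,
    p_value = (1 + sum(null >= observed)) / (n_perm + 1),
    n_perm = n_perm, seed = seed, strategy = strategy
  )
}
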