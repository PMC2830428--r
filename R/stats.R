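# Exact statistical core: Fisher 2x2 exact test, Wilcoxon rank-sum test,
# fractions, contingency construction and the promoter-class ladder.

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with fixed margins, computed in log space so
#' large margins do not overflow.  The two-sided p-value uses the
#' point-probability rule: the sum of the probabilities of all tables
#' (with the observed margins) whose probability does not exceed the
#' observed table's, within a relative tolerance of 1e-7.
#'
#' @param x A 2x2 matrix of non-negative integer counts, or the count `a`
#'   when `b`, `cc`, `d` are given.
#' @param b,cc,d Remaining cell counts when `x` is scalar (row-wise:
#'   a, b / cc, d).
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`;
#'   one-sided alternatives refer to the upper-left cell `a`.
#' @return The p-value.
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))  # 34/70
#' @export
fisher_exact <- function(x, b = NULL, cc = NULL, d = NULL,
                         alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L))) stop("'x' must be a 2x2 matrix")
    a <- x[1, 1]; b <- x[1, 2]; cc <- x[2, 1]; d <- x[2, 2]
  } else {
    a <- x
  }
  cells <- c(a, b, cc, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells))) {
    stop("cell counts must be non-negative integers")
  }
  n <- sum(cells)
  if (n == 0) stop("all cells are zero")
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  k <- lo:hi
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  obs <- logp[k == a]
  p <- switch(alternative,
    two_sided = sum(exp(logp[logp <= obs + log1p(1e-7)])),
    greater = sum(exp(logp[k >= a])),
    less = sum(exp(logp[k <= a])))
  min(1, p)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sample location test on pooled midranks.  The statistic is the
#' rank sum of `x`.  With `mode = "auto"` the p-value is exact (full
#' enumeration of the rank-sum null distribution) when the pooled size is
#' at most 30 and there are no ties, and otherwise uses the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`
#'   (location of `x` relative to `y`).
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.  `"exact"`
#'   with ties present warns and falls back to the normal approximation.
#' @return A list with `statistic` (rank sum of `x`) and `p_value`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value  # 2/6 exactly
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "greater", "less"),
                              mode = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  ties <- anyDuplicated(c(x, y)) > 0L
  if (mode == "exact" && ties) {
    warning("cannot compute an exact p-value with ties; using normal approximation")
  }
  use_exact <- !ties && (mode == "exact" || (mode == "auto" && N <= 30L))
  if (use_exact) {
    p <- .wilcox_exact_p(W, m, n, alternative)
  } else {
    tie_sizes <- table(r)
    tie_term <- sum(tie_sizes^3 - tie_sizes) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(statistic = W, p_value = 1))
    mu <- m * (N + 1) / 2
    dev <- W - mu
    p <- switch(alternative,
      two_sided = {
        z <- (abs(dev) - 0.5) / sqrt(sigma2)
        min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
      },
      greater = stats::pnorm((dev - 0.5) / sqrt(sigma2), lower.tail = FALSE),
      less = stats::pnorm((dev + 0.5) / sqrt(sigma2)))
  }
  list(statistic = W, p_value = min(1, max(p, .Machine$double.xmin)))
}

# Exact null distribution of the rank sum: dynamic programming over the
# ranks 1..N counting subsets of size m by rank sum.
.wilcox_rank_sum_counts <- function(m, n) {
  N <- m + n
  wmax <- sum((n + 1):N)        # maximal rank sum of m elements
  # counts[j + 1, w + 1] = number of size-j subsets of 1..i with sum w
  counts <- matrix(0, nrow = m + 1L, ncol = wmax + 1L)
  counts[1L, 1L] <- 1
  for (i in seq_len(N)) {
    jmax <- min(i, m)
    for (j in jmax:1L) {
      w <- (i:wmax)
      counts[j + 1L, w + 1L] <- counts[j + 1L, w + 1L] + counts[j, w - i + 1L]
    }
  }
  counts[m + 1L, ]              # index w + 1 holds count for rank sum w
}

.wilcox_exact_p <- function(W, m, n, alternative) {
  counts <- .wilcox_rank_sum_counts(m, n)
  total <- sum(counts)
  w <- seq_along(counts) - 1L
  ple <- sum(counts[w <= W]) / total
  pge <- sum(counts[w >= W]) / total
  switch(alternative,
    two_sided = min(1, 2 * min(ple, pge)),
    greater = pge,
    less = ple)
}

#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` decimal
#' places (so 72.45 at one decimal is 72.5, not banker's 72.4).
#'
#' @param numerator,denominator Counts with
#'   `0 <= numerator <= denominator`, `denominator > 0`.
#' @param decimals Number of decimal places (default 1).
#' @return The rounded percentage.
#' @examples
#' fraction(14410, 14410 + 5226, decimals = 0)  # 73
#' @export
fraction <- function(numerator, denominator, decimals = 1L) {
  if (denominator <= 0) stop("denominator must be positive")
  if (numerator < 0 || numerator > denominator) {
    stop("numerator must be between 0 and denominator")
  }
  pct <- 100 * numerator / denominator
  scale <- 10^decimals
  floor(pct * scale + 0.5) / scale
}

#' Build a 2x2 contingency table from flags and two gene groups
#'
#' Rows are the two groups, columns are flag yes/no.  Genes with an
#' unknown flag (NA) are dropped; the number dropped is attached as
#' attribute `n_dropped`.
#'
#' @param flags Named logical vector (gene id -> flag; may contain NA).
#' @param group1,group2 Disjoint, non-empty character vectors of gene ids
#'   present in `names(flags)`.
#' @return A 2x2 integer matrix with dimnames.
#' @export
contingency_2x2 <- function(flags, group1, group2) {
  if (length(group1) == 0L || length(group2) == 0L) {
    stop("both groups must be non-empty")
  }
  if (length(intersect(group1, group2)) > 0L) {
    stop("groups must be disjoint")
  }
  f1 <- flags[group1]; f2 <- flags[group2]
  n_dropped <- sum(is.na(f1)) + sum(is.na(f2))
  f1 <- f1[!is.na(f1)]; f2 <- f2[!is.na(f2)]
  tab <- matrix(c(sum(f1), sum(!f1), sum(f2), sum(!f2)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("group1", "group2"), c("yes", "no")))
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Promoter-class comparison ladder
#'
#' Runs the fixed four-rung comparison used for every gene-level trait:
#' pooled AP vs SP, then AP2 vs SP, AP3_4 vs AP2 and AP5plus vs AP3_4.
#' Continuous traits (`kind = "rank_sum"`) use the Wilcoxon rank-sum test
#' and report group medians; boolean traits (`kind = "fisher"`) use
#' Fisher's exact test and report group percentages.  A rung with an
#' empty group is skipped with a warning.  Per-class summaries (median or
#' percentage per promoter class) are attached as attribute
#' `class_summary`.
#'
#' @param values Numeric trait (for `rank_sum`) or logical flag (for
#'   `fisher`), one element per gene; NA values are excluded per
#'   comparison.
#' @param classes Factor of promoter classes (levels
#'   [promoter_classes()]) aligned with `values`.
#' @param kind `"rank_sum"` or `"fisher"`.
#' @param alternative Sidedness passed to the underlying test
#'   (default two-sided).
#' @return A data.frame with one row per rung: `label`, `kind`, `n1`,
#'   `n2`, `summary1`, `summary2`, `statistic`, `p_value`, `p_display`.
#' @export
class_ladder <- function(values, classes, kind = c("rank_sum", "fisher"),
                         alternative = "two_sided") {
  kind <- match.arg(kind)
  if (length(values) != length(classes)) {
    stop("'values' and 'classes' must have the same length")
  }
  classes <- factor(classes, levels = promoter_classes())
  ok <- !is.na(values) & !is.na(classes)
  values <- values[ok]; classes <- classes[ok]
  pool <- function(lv) values[classes %in% lv]
  groups <- list(
    AP_vs_SP = list(g1 = pool(c("AP2", "AP3_4", "AP5plus")), g2 = pool("SP")),
    AP2_vs_SP = list(g1 = pool("AP2"), g2 = pool("SP")),
    AP3_4_vs_AP2 = list(g1 = pool("AP3_4"), g2 = pool("AP2")),
    AP5plus_vs_AP3_4 = list(g1 = pool("AP5plus"), g2 = pool("AP3_4")))
  summarize <- function(v) {
    if (kind == "rank_sum") stats::median(v) else 100 * mean(v)
  }
  rows <- lapply(names(groups), function(lab) {
    g1 <- groups[[lab]]$g1; g2 <- groups[[lab]]$g2
    if (length(g1) == 0L || length(g2) == 0L) {
      warning("rung ", lab, " skipped: empty class")
      return(NULL)
    }
    if (kind == "rank_sum") {
      res <- wilcoxon_rank_sum(g1, g2, alternative = alternative)
      stat <- res$statistic; p <- res$p_value
    } else {
      tab <- matrix(c(sum(g1), sum(!g1), sum(g2), sum(!g2)), 2L, byrow = TRUE)
      p <- fisher_exact(tab, alternative = alternative)
      stat <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])  # odds ratio
    }
    data.frame(label = lab, kind = kind,
               n1 = length(g1), n2 = length(g2),
               summary1 = summarize(g1), summary2 = summarize(g2),
               statistic = stat, p_value = p,
               p_display = format_pvalue(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(label = character(), kind = character(), n1 = integer(),
                      n2 = integer(), summary1 = numeric(), summary2 = numeric(),
                      statistic = numeric(), p_value = numeric(),
                      p_display = character(), stringsAsFactors = FALSE)
  }
  cls_summary <- data.frame(
    class = promoter_classes(),
    n = as.integer(table(classes)[promoter_classes()]),
    summary = vapply(promoter_classes(), function(cl) {
      v <- pool(cl)
      if (length(v) == 0L) NA_real_ else summarize(v)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(cls_summary) <- NULL
  attr(out, "class_summary") <- cls_summary
  out
}

#' Display form of a p-value
#'
#' P-values below 2.2e-16 (the smallest value conventionally printed by
#' test functions) are displayed as `"<2.2e-16"`; full precision is kept
#' in the stored numeric value.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 2.2e-16, "<2.2e-16", format(p, digits = 4, scientific = TRUE))
}
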