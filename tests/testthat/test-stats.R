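test_that("Fisher exact matches enumeration on worked tables", {
  # margins (4,4)/(4,4): masses 1,16,36,16,1 over 70; observed a=3 ->
  # qualifying tables a in {0,1,3,4} -> 34/70
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 34 / 70)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_error(fisher_exact(matrix(0L, 2, 2)), "zero")
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Fisher exact agrees with fisher.test and dhyper oracle", {
  set.seed(19)
  for (i in 1:150) {
    tab <- matrix(rpois(4, sample(c(3, 10, 40), 1L)), 2)
    if (sum(tab) == 0) next
    for (alt in c("two_sided", "greater", "less")) {
      mine <- fisher_exact(tab, alternative = alt)
      expect_equal(mine, fisher_oracle(tab[1, 1], tab[1, 2], tab[2, 1],
                                       tab[2, 2], alt), tolerance = 1e-12)
      ralt <- c(two_sided = "two.sided", greater = "greater", less = "less")[alt]
      expect_equal(mine, stats::fisher.test(tab, alternative = ralt)$p.value,
                   tolerance = 1e-9)
    }
    # hypergeometric symmetry: transpose has the same two-sided p
    expect_equal(fisher_exact(tab), fisher_exact(t(tab)), tolerance = 1e-12)
    # simultaneous row and column swap leaves p unchanged
    expect_equal(fisher_exact(tab), fisher_exact(tab[2:1, 2:1]), tolerance = 1e-12)
  }
})

test_that("Fisher exact stays finite and correct at large margins", {
  big <- matrix(c(212, 7079, 324, 7565), 2, byrow = TRUE)
  expect_equal(fisher_exact(big), stats::fisher.test(big)$p.value,
               tolerance = 1e-7)
  huge <- matrix(c(5000, 95000, 5500, 94500), 2, byrow = TRUE)
  p <- fisher_exact(huge)
  expect_true(is.finite(p) && p > 0 && p <= 1)
  expect_equal(p, stats::fisher.test(huge)$p.value, tolerance = 1e-6)
})

test_that("Wilcoxon exact p matches its worked examples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 2 / 6)
  expect_equal(wilcoxon_rank_sum(1, 2)$p_value, 1)
  # identical multisets: perfectly balanced ranks, p = 1 in either mode
  x <- c(1, 2, 3)
  expect_equal(suppressWarnings(wilcoxon_rank_sum(x, x, mode = "exact"))$p_value, 1)
  expect_equal(wilcoxon_rank_sum(x, x, mode = "normal")$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("Wilcoxon exact equals permutation enumeration and wilcox.test", {
  set.seed(23)
  for (i in 1:60) {
    m <- sample(1:5, 1L); n <- sample(1:5, 1L)
    v <- sample.int(1000, m + n)      # tie-free
    x <- v[seq_len(m)]; y <- v[-seq_len(m)]
    for (alt in c("two_sided", "greater", "less")) {
      mine <- wilcoxon_rank_sum(x, y, alternative = alt, mode = "exact")
      expect_equal(mine$p_value, wilcox_enum_oracle(x, y, alt), tolerance = 1e-12)
    }
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation is the standard corrected one and tracks exact", {
  set.seed(29)
  for (i in 1:60) {
    N <- sample(11:30, 1L)
    m <- sample(3:(N - 3), 1L)
    v <- sample.int(10000, N)
    x <- v[seq_len(m)]; y <- v[-seq_len(m)]
    pe <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
    pn <- wilcoxon_rank_sum(x, y, mode = "normal")$p_value
    # 0.039 is the worst case of the continuity-corrected approximation
    # over every statistic value with 10 < pooled n <= 30 (exhaustively
    # enumerated); typical gaps are far smaller and shrink with n
    expect_lt(abs(pe - pn), 0.039)
    expect_equal(pn, stats::wilcox.test(x, y, exact = FALSE,
                                        correct = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon p is invariant under strictly monotone transforms", {
  set.seed(37)
  x <- rlnorm(25); y <- rlnorm(40, 0.4)
  p0 <- wilcoxon_rank_sum(x, y)$p_value
  for (f in list(log, sqrt, function(v) 3 * v - 7, function(v) v^3)) {
    expect_equal(wilcoxon_rank_sum(f(x), f(y))$p_value, p0, tolerance = 1e-12)
  }
})

test_that("tie-corrected normal p matches wilcox.test with ties", {
  set.seed(41)
  for (i in 1:25) {
    x <- sample(1:8, 40, replace = TRUE)
    y <- sample(1:8, 55, replace = TRUE)
    mine <- wilcoxon_rank_sum(x, y)$p_value
    ref <- suppressWarnings(stats::wilcox.test(x, y))$p.value
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("percentages round half-up at the requested precision", {
  expect_equal(fraction(1, 8, decimals = 0), 13)   # 12.5 rounds up, not to even
  expect_equal(fraction(145, 1000, decimals = 1), 14.5)
  expect_equal(fraction(0, 10), 0)
  expect_equal(fraction(10, 10), 100)
  expect_error(fraction(1, 0), "positive")
  expect_error(fraction(5, 4), "between 0 and")
})

test_that("contingency tables recount group memberships exactly", {
  flags <- c(A = TRUE, B = FALSE, C = TRUE, D = FALSE)
  tab <- contingency_2x2(flags, c("A", "B"), c("C", "D"))
  expect_equal(unname(tab), matrix(c(1L, 1L, 1L, 1L), 2, byrow = TRUE),
               ignore_attr = TRUE)

  flags2 <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  extreme <- contingency_2x2(flags2, c("a", "b"), c("c", "d"))
  expect_equal(unname(extreme), matrix(c(2L, 0L, 0L, 2L), 2, byrow = TRUE),
               ignore_attr = TRUE)

  expect_error(contingency_2x2(flags, c("A"), c("A", "B")), "disjoint")
  expect_error(contingency_2x2(flags, character(), "A"), "non-empty")

  set.seed(43)
  ids <- sprintf("g%03d", 1:200)
  fl <- setNames(sample(c(TRUE, FALSE, NA), 200, replace = TRUE,
                        prob = c(.45, .45, .1)), ids)
  g1 <- sample(ids, 80); g2 <- setdiff(ids, g1)[1:80]
  tab <- contingency_2x2(fl, g1, g2)
  expect_equal(tab[1, 1], sum(fl[g1] %in% TRUE))
  expect_equal(tab[1, 2], sum(fl[g1] %in% FALSE))
  expect_equal(tab[2, 1], sum(fl[g2] %in% TRUE))
  expect_equal(tab[2, 2], sum(fl[g2] %in% FALSE))
  expect_equal(attr(tab, "n_dropped"), sum(is.na(fl[g1])) + sum(is.na(fl[g2])))
})

test_that("the class ladder has fixed rungs and detects planted effects", {
  set.seed(47)
  n <- 400
  classes <- factor(rep(promoter_classes(), each = n), levels = promoter_classes())
  shift <- rep(c(0, 0.5, 1, 1.5), each = n)
  values <- rnorm(4 * n) + shift
  lad <- class_ladder(values, classes, kind = "rank_sum")
  expect_equal(lad$label, c("AP_vs_SP", "AP2_vs_SP", "AP3_4_vs_AP2",
                            "AP5plus_vs_AP3_4"))
  expect_true(all(lad$p_value < 0.01))
  expect_true(all(lad$p_value > 0 & lad$p_value <= 1))
  cs <- attr(lad, "class_summary")
  expect_equal(cs$class, promoter_classes())
  expect_equal(cs$n, rep(n, 4))
  # rung order is fixed regardless of input order
  perm <- sample(length(values))
  expect_equal(class_ladder(values[perm], classes[perm], kind = "rank_sum")$label,
               lad$label)

  # fisher kind: planted monotone flag fractions light up every rung
  fracs <- rep(c(0.05, 0.10, 0.20, 0.40), each = 2000)
  fl <- runif(4 * 2000) < fracs
  fcl <- factor(rep(promoter_classes(), each = 2000), levels = promoter_classes())
  flad <- class_ladder(fl, fcl, kind = "fisher")
  expect_true(all(flad$p_value < 0.01))
  fs <- attr(flad, "class_summary")
  expect_true(all(diff(fs$summary) > 0))

  # an empty class skips its rungs (one warning per missing rung)
  sub <- classes %in% c("SP", "AP2")
  warns <- capture_warnings(
    short <- class_ladder(values[sub], droplevels(classes[sub]),
                          kind = "rank_sum"))
  expect_match(warns, "skipped", all = TRUE)
  expect_length(warns, 2L)
  expect_equal(short$label, c("AP_vs_SP", "AP2_vs_SP"))
})

test_that("p-value display floors at 2.2e-16 without losing precision", {
  expect_equal(format_pvalue(1e-20), "<2.2e-16")
  expect_equal(format_pvalue(0.04481), "4.481e-02")
  lad <- suppressWarnings(
    class_ladder(c(rnorm(50), rnorm(50, 10)),
                 factor(rep(c("SP", "AP2"), each = 50),
                        levels = promoter_classes()),
                 kind = "rank_sum"))
  expect_true(all(lad$p_value > 0))
})
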