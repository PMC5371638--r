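# Condition-level statistics: shell-distribution tests, KS, Kruskal-Wallis,
# ploidy calling and metaphase classification.

mkDist <- function(counts, condition = "c") {
  new("ShellDistribution", condition = condition,
      counts = stats::setNames(as.integer(counts),
                               c("I", "II", "III", "IV", "V")),
      n = as.integer(sum(counts)))
}

test_that("identical shell distributions give chi2 = 0, p = 1", {
  a <- mkDist(c(5, 10, 20, 10, 5))
  res <- compareShellDistributions(a, a)
  expect_equal(res$chi2$statistic, 0)
  expect_equal(res$chi2$p, 1)
  expect_false(res$significant_chi2)
  expect_false(res$significant_fisher)
})

test_that("maximally separated distributions are highly significant", {
  a <- mkDist(c(0, 0, 0, 0, 50))
  b <- mkDist(c(50, 0, 0, 0, 0))
  res <- suppressWarnings(compareShellDistributions(a, b))
  expect_lt(res$chi2$p, 0.001)
  expect_lt(min(res$fisher_per_shell), 0.001)
  expect_true(res$significant_chi2 && res$significant_fisher)
})

test_that("shells empty in both conditions are dropped with a warning", {
  a <- mkDist(c(10, 0, 15, 20, 5))
  b <- mkDist(c(5, 0, 25, 10, 10))
  expect_warning(res <- compareShellDistributions(a, b), "II")
  expect_equal(res$chi2$df, 3L)  # 4 retained shells - 1
})

test_that("shell counts sum to n and pooling is additive", {
  rd <- c(5, 25, 45, 65, 85, 99, 61, 80)
  sd1 <- shellDistribution(rd, "a")
  expect_equal(sum(sd1@counts), sd1@n)
  expect_equal(unname(sd1@counts["IV"]), 3L)  # 65, 80 upper-inclusive, 61
  pooled <- poolShellDistributions(sd1, sd1)
  expect_equal(pooled@counts, sd1@counts * 2L)
  expect_equal(pooled@n, 2L * sd1@n)
})

test_that("KS test behaves at the degenerate extremes", {
  x <- c(0.2, 0.5, 0.7, 0.9, 1.3, 1.8)
  same <- ksTwoSample(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  far <- ksTwoSample(x, x + 100)
  expect_equal(far$D, 1)
  expect_lt(far$p, 0.01)
  expect_error(ksTwoSample(x[1:4], x), "5")
})

test_that("Kruskal-Wallis agrees with the closed-form midrank statistic", {
  # independent oracle: the rank-sum formula with tie correction
  kwOracle <- function(groups) {
    v <- unlist(groups); g <- rep(seq_along(groups), lengths(groups))
    N <- length(v); r <- rank(v)
    H <- 12 / (N * (N + 1)) *
      sum(tapply(r, g, function(ri) length(ri) *
                   (mean(ri) - (N + 1) / 2)^2))
    ties <- table(v)
    H / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  withr::with_seed(17, {
    for (i in 1:20) {
      k <- sample(2:5, 1)
      groups <- lapply(seq_len(k), function(j)
        round(rnorm(sample(5:15, 1), mean = j), 1))  # rounded -> ties
      expect_equal(kruskalWallis(groups)$H, kwOracle(groups),
                   tolerance = 1e-9)
    }
  })
  expect_warning(res <- kruskalWallis(list(c(1, 1), c(1, 1))), "identical")
  expect_equal(res$p, 1)
  expect_lt(kruskalWallis(list(c(1, 2, 3), c(100, 101, 102)))$p, 0.05)
  expect_error(kruskalWallis(list(1:3)), "2 non-empty")
})

test_that("ploidy classes follow the copy-count rule", {
  calls <- callPloidy(c(2, 3, 4, 1, 0), chromosome = "19")
  expect_equal(as.character(calls$class),
               c("diploid", "aneuploid_gain", "aneuploid_gain", "loss",
                 "loss"))
  expect_equal(calls$qc_flag, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  s <- ploidySummary(calls)
  expect_equal(s$fraction_gain, 0.4)
  expect_equal(s$fraction_loss + s$fraction_diploid + s$fraction_gain, 1)
})

test_that("metaphase spreads classify by the 45-46 pseudo-diploid window", {
  expect_equal(as.character(classifyMetaphase(c(44, 45, 46, 47, 49))),
               c("loss", "pseudo_diploid", "pseudo_diploid", "gain", "gain"))
  expect_error(classifyMetaphase(-1), ">= 0")
})

test_that("median/IQR summaries use linear-interpolation quantiles", {
  x <- c(1, 2, 3, 4, 10)
  tab <- medianIQRTable(x, "a")
  expect_equal(tab$median, 3)
  expect_equal(tab$IQR, unname(diff(quantile(x, c(0.25, 0.75)))))
  two <- medianIQRTable(c(x, x + 50), rep(c("a", "b"), each = 5))
  expect_equal(nrow(two), 2L)
  expect_equal(two$median[two$condition == "b"], 53)
})
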