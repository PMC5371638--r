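# Condition-level comparisons: shell-distribution tests (chi-squared on the
# 2 x 5 table and per-shell Fisher's exact tests), Kolmogorov-Smirnov on raw
# distances, Kruskal-Wallis for volumes, interphase ploidy calling from
# territory counts, and metaphase chromosome-count classification.

#' Build a ShellDistribution from radial distances
#'
#' @param rd numeric vector of percent radial distances in [0, 100].
#' @param condition condition label.
#' @return a [ShellDistribution-class].
#' @examples
#' shellDistribution(c(10, 55, 61, 85, 85), "untreated")
#' @export
shellDistribution <- function(rd, condition = "condition") {
  counts <- table(shellOf(rd))
  new("ShellDistribution", condition = as.character(condition),
      counts = stats::setNames(as.integer(counts), names(counts)),
      n = length(rd))
}

#' Pool shell distributions across replicates
#'
#' @param ... `ShellDistribution` objects for the same condition.
#' @return a pooled [ShellDistribution-class] (counts are additive).
#' @export
poolShellDistributions <- function(...) {
  xs <- list(...)
  counts <- Reduce(`+`, lapply(xs, function(x) x@counts))
  new("ShellDistribution", condition = xs[[1]]@condition,
      counts = counts, n = sum(counts))
}

#' Compare two shell distributions
#'
#' Two complementary tests, both reported: a chi-squared test on the 2 x 5
#' condition-by-shell contingency table (shells empty in both conditions are
#' dropped with a warning), and per-shell Fisher's exact tests on the 2 x 2
#' table (in shell vs not in shell, condition A vs B). p < 0.05 is flagged
#' significant; the omnibus and per-shell routes are reported side by side
#' and disagreement between them is flagged rather than resolved.
#'
#' @param a,b [ShellDistribution-class] objects; both must have n > 0.
#' @param alpha significance level for the flags (default 0.05).
#' @return list with `chi2` (statistic, df, p), `fisher_per_shell` (named
#'   p-value vector), `significant_chi2`, `significant_fisher` (any shell),
#'   and `disagreement`.
#' @export
compareShellDistributions <- function(a, b, alpha = 0.05) {
  stopifnot(is(a, "ShellDistribution"), is(b, "ShellDistribution"))
  if (a@n == 0L || b@n == 0L) stop("both distributions must have n > 0")
  m <- rbind(a@counts, b@counts)
  empty <- colSums(m) == 0L
  mChi <- m
  if (any(empty)) {
    warning("shell(s) ", paste(names(which(empty)), collapse = ", "),
            " empty in both conditions; dropped from the chi-squared table")
    mChi <- m[, !empty, drop = FALSE]
  }
  if (identical(a@counts, b@counts)) {
    chi <- list(statistic = 0, df = ncol(mChi) - 1L, p = 1)
  } else {
    ct <- suppressWarnings(stats::chisq.test(mChi, correct = FALSE))
    chi <- list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                p = ct$p.value)
  }
  fisherP <- vapply(colnames(m), function(sh) {
    tab <- rbind(c(a@counts[sh], a@n - a@counts[sh]),
                 c(b@counts[sh], b@n - b@counts[sh]))
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  sigChi <- chi$p < alpha
  sigFisher <- any(fisherP < alpha)
  list(chi2 = chi, fisher_per_shell = fisherP,
       significant_chi2 = sigChi, significant_fisher = sigFisher,
       disagreement = sigChi != sigFisher)
}

#' Two-sample Kolmogorov-Smirnov test on raw distances
#'
#' Applied to unbinned distance samples (e.g. locus-to-lamina distances in
#' um for control vs knockdown). Requires at least 5 observations per group.
#'
#' @param x,y numeric vectors of distances.
#' @return list with `D` and `p`.
#' @export
ksTwoSample <- function(x, y) {
  if (length(x) < 5L || length(y) < 5L)
    stop("ksTwoSample requires at least 5 observations per group")
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based non-parametric ANOVA with midrank tie handling, as used for
#' comparing territory volumes across conditions or nuclear sub-shells.
#' Groups must be non-empty; if every value across all groups is identical
#' the test is undefined and `H = 0, p = 1` is returned with a warning.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return list with `H`, `df` and `p`.
#' @export
kruskalWallis <- function(groups) {
  if (length(groups) < 2L || any(vapply(groups, length, integer(1)) == 0L))
    stop("kruskalWallis requires >= 2 non-empty groups")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    warning("all values identical: Kruskal-Wallis undefined, returning p = 1")
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Call interphase ploidy from territory counts
#'
#' Copy number is the number of retained territory objects in a nucleus's
#' paint channel; class is `loss` (< 2 copies; 0 copies is additionally
#' flagged for QC as a possible hybridization failure), `diploid` (exactly
#' 2) or `aneuploid_gain` (> 2).
#'
#' @param copyCount integer vector, one entry per nucleus.
#' @param nucleusId,chromosome optional identifiers recycled along
#'   `copyCount`.
#' @return data.frame with columns `nucleus_id`, `chromosome`, `copy_count`,
#'   `class`, `qc_flag`.
#' @examples
#' callPloidy(c(2, 3, 2, 0))
#' @export
callPloidy <- function(copyCount, nucleusId = seq_along(copyCount),
                       chromosome = "") {
  copyCount <- as.integer(copyCount)
  if (any(copyCount < 0L)) stop("copy counts must be >= 0")
  cls <- ifelse(copyCount < 2L, "loss",
                ifelse(copyCount == 2L, "diploid", "aneuploid_gain"))
  data.frame(nucleus_id = nucleusId, chromosome = chromosome,
             copy_count = copyCount,
             class = factor(cls, levels = c("loss", "diploid",
                                            "aneuploid_gain")),
             qc_flag = copyCount == 0L)
}

#' Cohort ploidy summary
#'
#' @param calls data.frame from [callPloidy()].
#' @return data.frame of per-chromosome fractions of nuclei per class.
#' @export
ploidySummary <- function(calls) {
  out <- do.call(rbind, lapply(split(calls, calls$chromosome), function(d) {
    tab <- table(d$class) / nrow(d)
    data.frame(chromosome = d$chromosome[1], n_nuclei = nrow(d),
               fraction_loss = unname(tab["loss"]),
               fraction_diploid = unname(tab["diploid"]),
               fraction_gain = unname(tab["aneuploid_gain"]))
  }))
  rownames(out) <- NULL
  out
}

#' Classify a metaphase spread by chromosome count
#'
#' 45-46 chromosomes is pseudo-diploid, fewer than 45 is a loss, more than
#' 46 a gain.
#'
#' @param count integer vector of per-spread chromosome counts (>= 0).
#' @return factor with levels loss, pseudo_diploid, gain.
#' @examples
#' classifyMetaphase(c(44, 46, 47))
#' @export
classifyMetaphase <- function(count) {
  count <- as.integer(count)
  if (any(count < 0L)) stop("chromosome counts must be >= 0")
  cls <- ifelse(count < 45L, "loss",
                ifelse(count <= 46L, "pseudo_diploid", "gain"))
  factor(cls, levels = c("loss", "pseudo_diploid", "gain"))
}

#' Median / IQR summary per condition
#'
#' Median and interquartile range (Q3 - Q1, linear-interpolation quantiles)
#' of percent radial distances, grouped by condition — the shape of the
#' median/IQR summary tables reported alongside shell distributions.
#'
#' @param rd numeric vector of measurements.
#' @param condition grouping vector recycled along `rd`.
#' @return data.frame with columns `condition`, `n`, `median`, `IQR`.
#' @export
medianIQRTable <- function(rd, condition = "all") {
  condition <- rep_len(condition, length(rd))
  out <- do.call(rbind, lapply(split(rd, condition), function(x) {
    s <- .medianIQR(x)
    data.frame(n = length(x), median = s[["median"]], IQR = s[["IQR"]])
  }))
  data.frame(condition = rownames(out), out, row.names = NULL)
}
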