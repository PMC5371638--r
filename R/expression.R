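# Expression-side statistics: the deregulation filter (|FC| >= 2, p < 0.05),
# knockdown overlap set algebra, per-chromosome percent deregulation with
# the strict > 0.7% significance threshold, and the deregulation-vs-gene-
# density least-squares r^2.

#' Filter deregulated genes
#'
#' Splits a gene table into up- and downregulated sets using the standard
#' cutoffs: absolute linear fold change at least `fcCutoff` (inclusive) and
#' p-value strictly below `pCutoff`.
#'
#' @param table data.frame of gene records (see [readGeneTable()]).
#' @param fcCutoff absolute fold-change cutoff, inclusive (default 2.0).
#' @param pCutoff p-value cutoff, strict (default 0.05).
#' @return list with data.frames `up` and `down` (disjoint subsets of
#'   `table`).
#' @examples
#' tab <- data.frame(gene_id = c("a", "b", "c"), chromosome = "19",
#'                   fold_change = c(2.96, -1.99, -2.0),
#'                   p_value = c(0.01, 0.001, 0.05))
#' filterDeregulated(tab)$up$gene_id    # "a"
#' filterDeregulated(tab)$down$gene_id  # none: b below cutoff, c at p = 0.05
#' @export
filterDeregulated <- function(table, fcCutoff = 2.0, pCutoff = 0.05) {
  stopifnot(nrow(table) > 0L)
  pass <- abs(table$fold_change) >= fcCutoff & table$p_value < pCutoff
  list(up = table[pass & table$fold_change > 0, , drop = FALSE],
       down = table[pass & table$fold_change < 0, , drop = FALSE])
}

#' Overlap between two deregulated gene sets
#'
#' @param setA,setB character vectors of gene ids (de-duplicated
#'   internally).
#' @return list with counts `unique_to_a`, `unique_to_b`, `common`, `n_a`,
#'   `n_b`, and the id vectors `common_ids`.
#' @examples
#' overlapGenes(c("a", "b", "c"), c("b", "c", "d"))
#' @export
overlapGenes <- function(setA, setB) {
  a <- unique(as.character(setA)); b <- unique(as.character(setB))
  common <- intersect(a, b)
  list(unique_to_a = length(setdiff(a, b)),
       unique_to_b = length(setdiff(b, a)),
       common = length(common),
       n_a = length(a), n_b = length(b),
       common_ids = common)
}

#' Per-chromosome percent deregulation
#'
#' For each chromosome, percent deregulation is 100 times the number of
#' deregulated genes on that chromosome divided by its coding-gene count.
#' Chromosomes exceeding `threshold` percent (strictly) are flagged
#' significant.
#'
#' @param dereg data.frame of deregulated gene records (with `gene_id` and
#'   `chromosome` columns), e.g. the row-bound `up` and `down` sets from
#'   [filterDeregulated()].
#' @param annotation data.frame from [readAnnotation()]; every chromosome
#'   carrying a deregulated gene must appear in it.
#' @param threshold significance threshold in percent (default 0.7, strict).
#' @return data.frame with one row per annotated chromosome: `chromosome`,
#'   `n_deregulated`, `coding_genes`, `percent_dereg`, `significant`.
#' @export
percentDeregulation <- function(dereg, annotation, threshold = 0.7) {
  chrom <- normalizeChromosome(annotation$chromosome)
  unknown <- !dereg$chromosome %in% chrom
  if (any(unknown))
    stop("gene(s) on chromosome(s) absent from the annotation: ",
         paste(utils::head(dereg$gene_id[unknown], 5), collapse = ", "))
  counts <- table(factor(dereg$chromosome, levels = chrom))
  pct <- 100 * as.integer(counts) / annotation$coding_genes
  data.frame(chromosome = chrom,
             n_deregulated = as.integer(counts),
             coding_genes = annotation$coding_genes,
             percent_dereg = pct,
             significant = pct > threshold)
}

#' Correlation of deregulation with gene density
#'
#' Ordinary least-squares regression of per-chromosome percent deregulation
#' on gene density (coding genes per Mbp); reports the coefficient of
#' determination r^2 (the squared Pearson correlation).
#'
#' @param profile data.frame from [percentDeregulation()].
#' @param annotation data.frame from [readAnnotation()] supplying
#'   `gene_density` per chromosome.
#' @return list with `r_squared`, `slope`, `intercept`, `n`.
#' @export
densityCorrelation <- function(profile, annotation) {
  m <- merge(profile, annotation[, c("chromosome", "gene_density")],
             by = "chromosome")
  if (nrow(m) < 3L) stop("need >= 3 chromosomes for the regression")
  if (stats::var(m$gene_density) == 0 || stats::var(m$percent_dereg) == 0)
    stop("zero variance in gene density or percent deregulation")
  fit <- stats::lm(percent_dereg ~ gene_density, data = m)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = nrow(m))
}
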