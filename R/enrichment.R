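#' Map genes onto focal regions
#'
#' A gene is assigned to a region when its `[start, end]` interval overlaps
#' the region's confidence interval by at least one base pair (1-based
#' inclusive coordinates on both sides; a gene merely abutting the interval
#' end is not assigned).
#'
#' @param regions A `focal_regions` data frame with `ci_lo`/`ci_hi`.
#' @param genes Gene annotation data frame (see [read_gene_annotation]).
#' @return Data frame with one row per (region, gene) assignment: `region`
#'   (row index into `regions`), `chrom`, `direction`, `gene_symbol`,
#'   `driver_class`.
#' @export
map_genes_to_regions <- function(regions, genes) {
  if (nrow(regions) == 0L)
    return(data.frame(region = integer(), chrom = character(),
                      direction = character(), gene_symbol = character(),
                      driver_class = character(), stringsAsFactors = FALSE))
  # genes on chromosomes with no region simply match nothing; an error is
  # reserved for regions whose chromosome is absent from the annotation
  missing_chr <- setdiff(unique(regions$chrom), unique(genes$chrom))
  if (length(missing_chr))
    stop("no annotated genes on chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  gr_regions <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$ci_lo, regions$ci_hi))
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  ov <- GenomicRanges::findOverlaps(gr_regions, gr_genes, minoverlap = 1L)
  data.frame(region = S4Vectors::queryHits(ov),
             chrom = regions$chrom[S4Vectors::queryHits(ov)],
             direction = regions$direction[S4Vectors::queryHits(ov)],
             gene_symbol = genes$gene_symbol[S4Vectors::subjectHits(ov)],
             driver_class = as.character(
               genes$driver_class[S4Vectors::subjectHits(ov)]),
             stringsAsFactors = FALSE)
}

#' Build the driver 2x2 table from region-gene assignments
#'
#' Rows are region direction (gain, loss), columns driver class (oncogene,
#' TSG); each cell counts distinct driver genes assigned to regions of that
#' direction.
#'
#' @param mapping Output of [map_genes_to_regions].
#' @return 2x2 integer matrix.
#' @export
driver_contingency <- function(mapping) {
  drv <- mapping[mapping$driver_class %in% c("oncogene", "TSG"), , drop = FALSE]
  drv <- drv[!duplicated(drv[, c("direction", "gene_symbol")]), , drop = FALSE]
  tab <- table(factor(drv$direction, levels = c("gain", "loss")),
               factor(drv$driver_class, levels = c("oncogene", "TSG")))
  matrix(as.integer(tab), 2, 2,
         dimnames = list(c("gain", "loss"), c("oncogene", "TSG")))
}

#' Test the association of gains/losses with oncogenes/TSGs
#'
#' Two-sided Fisher's exact test on the 2x2 table of driver genes in gain
#' vs loss regions (minimum-likelihood two-sided convention: the p-value is
#' the sum of the probabilities of all tables with the same margins that are
#' no more probable than the observed one). The ratio fold is the ratio of
#' the two oncogene:TSG ratios, `(a/b) / (c/d)` for table `[[a,b],[c,d]]` —
#' numerically the sample odds ratio.
#'
#' @param table 2x2 matrix of non-negative integer counts, rows = (gain,
#'   loss) regions, columns = (oncogene, TSG).
#' @return List with `p_value`, `odds_ratio` (conditional MLE), `ratio_fold`
#'   (NA when a denominator cell is zero) and the input `table`.
#' @export
driver_contingency_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("cells must be non-negative integers")
  if (sum(table) == 0) stop("at least one margin must be nonzero")
  ft <- stats::fisher.test(table, alternative = "two.sided")
  fold <- if (table[1, 2] > 0 && table[2, 2] > 0 && table[2, 1] > 0)
    (table[1, 1] / table[1, 2]) / (table[2, 1] / table[2, 2])
  else NA_real_
  list(p_value = ft$p.value,
       odds_ratio = unname(ft$estimate),
       ratio_fold = fold,
       table = table)
}

#' Expression effect size of a focal region on its genes
#'
#' For a gain region, a sample is a carrier when it has a gain call at any
#' reduced site inside the region's confidence interval (symmetrically for
#' losses). The per-gene effect is the mean log2 expression difference,
#' oriented so that dosage-responsive genes have positive effect: carriers
#' minus non-carriers for gains, non-carriers minus carriers for losses.
#'
#' @param expression Numeric matrix of log2 expression, genes x samples,
#'   with dimnames.
#' @param calls List of tumor `call_track`s; names (or `sample_id`
#'   attributes) must match the expression columns.
#' @param region One-row slice of a `focal_regions` data frame.
#' @param genes Gene annotation; genes overlapping the region are analyzed.
#' @param min_group Minimum carriers and non-carriers required (default 2).
#' @return Data frame `gene_symbol`, `effect`, `n_carrier`, `n_noncarrier`;
#'   genes in the annotation but absent from the matrix are skipped.
#' @export
expression_effect_size <- function(expression, calls, region, genes,
                                   min_group = 2L) {
  stopifnot(nrow(region) == 1L)
  ids <- vapply(calls, function(ct) as.character(attr(ct, "sample_id")), "")
  common <- intersect(colnames(expression), ids)
  if (length(common) < 2L * min_group)
    stop("too few samples shared between calls and expression matrix")
  want <- as.character(region$direction)
  carrier <- vapply(calls[match(common, ids)], function(ct) {
    hit <- ct$chrom == region$chrom & ct$pos >= region$ci_lo &
      ct$pos <= region$ci_hi
    any(ct$state[hit] == want)
  }, TRUE)
  if (sum(carrier) < min_group || sum(!carrier) < min_group)
    stop(sprintf("region needs >= %d carriers and non-carriers (found %d / %d)",
                 min_group, sum(carrier), sum(!carrier)))
  mapped <- map_genes_to_regions(region, genes)
  sym <- intersect(mapped$gene_symbol, rownames(expression))
  eff <- vapply(sym, function(g) {
    d <- mean(expression[g, common[carrier]]) -
      mean(expression[g, common[!carrier]])
    if (want == "loss") -d else d
  }, 1.0)
  data.frame(gene_symbol = sym, effect = unname(eff),
             n_carrier = sum(carrier), n_noncarrier = sum(!carrier),
             stringsAsFactors = FALSE)
}

#' Compare expression effects of driver vs non-driver genes
#'
#' Two-sided Wilcoxon rank-sum test of the per-gene effect-size
#' distributions; for tiny groups the exact null enumeration is used
#' automatically.
#'
#' @param effects Numeric vector of per-gene effect sizes.
#' @param is_driver Logical vector, same length, TRUE for driver genes.
#' @return The two-sided p-value.
#' @export
compare_driver_effects <- function(effects, is_driver) {
  stopifnot(length(effects) == length(is_driver))
  if (sum(is_driver) < 3L || sum(!is_driver) < 3L)
    stop("need >= 3 genes in each group")
  stats::wilcox.test(effects[is_driver], effects[!is_driver],
                     alternative = "two.sided", exact = NULL)$p.value
}
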