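## Statistical layer: pooled-variance two-sided t tests, Bonferroni
## adjustment, delta-delta-Ct fold changes, box-plot summaries, and the
## significance-star convention.

#' Unpaired two-sided t test (pooled variance)
#'
#' Classic Student test between a sample of interest and its control:
#' pooled-variance statistic with `n1 + n2 - 2` degrees of freedom and a
#' two-sided p value. Welch's unequal-variance variant is available via
#' `varEqual = FALSE`. Degenerate inputs with zero pooled variance return
#' p = 1 when the means are equal and are an error otherwise.
#'
#' @param a,b numeric samples, each with at least 2 finite values.
#' @param varEqual pool the variances (default `TRUE`).
#' @param comparison optional label for the comparison.
#' @return data.frame with `statistic`, `p_value`, `df`, `n1`, `n2`,
#'   `comparison`.
#' @export
tTestTwoSided <- function(a, b, varEqual = TRUE, comparison = "a vs b") {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 finite values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(data.frame(statistic = 0, p_value = 1,
                        df = length(a) + length(b) - 2,
                        n1 = length(a), n2 = length(b),
                        comparison = comparison))
    }
    stop("zero variance with unequal means: degenerate test")
  }
  ht <- stats::t.test(a, b, var.equal = varEqual, alternative = "two.sided")
  data.frame(statistic = unname(ht$statistic),
             p_value = ht$p.value, df = unname(ht$parameter),
             n1 = length(a), n2 = length(b), comparison = comparison)
}

#' Bonferroni adjustment
#'
#' `adjusted_i = min(1, p_i * m)` with `m` the number of tests.
#'
#' @param pValues p values in `[0, 1]`.
#' @return Adjusted p values (same order).
#' @export
bonferroniAdjust <- function(pValues) {
  if (any(!is.finite(pValues)) || any(pValues < 0 | pValues > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pValues, method = "bonferroni")
}

#' Significance stars
#'
#' Maps p values to the star convention `* p < 0.05`, `** p < 0.01`,
#' `*** p < 0.001` (values at or above 0.05 give `"ns"`).
#'
#' @param p numeric p values.
#' @return character vector of star labels.
#' @export
significanceStars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Relative fold changes by the delta-delta-Ct method
#'
#' For each replicate, `dCt = Ct_gene - Ct_reference_gene`; per gene and
#' condition, `ddCt = mean dCt(condition) - mean dCt(reference condition)`;
#' the fold change is `2^-ddCt` (perfect amplification efficiency). Adding a
#' constant to every Ct (a plate shift) leaves all fold changes unchanged.
#'
#' @param ctTable data.frame with columns `gene`, `condition`, `replicate`,
#'   `ct`.
#' @param referenceGene housekeeping gene; must be measured in every
#'   (condition, replicate), otherwise an error lists the gaps.
#' @param referenceCondition baseline condition.
#' @return data.frame `gene`, `condition`, `delta_delta_ct`, `fold_change`
#'   for all non-reference genes.
#' @export
deltaDeltaCt <- function(ctTable, referenceGene = "Gapdh",
                         referenceCondition) {
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(ctTable)))
    stop("ctTable must have columns ", paste(need, collapse = ", "))
  if (!referenceCondition %in% ctTable$condition)
    stop("reference condition '", referenceCondition, "' not in table")
  ref <- ctTable[ctTable$gene == referenceGene, ]
  cells <- unique(ctTable[, c("condition", "replicate")])
  have <- paste(ref$condition, ref$replicate)
  gaps <- cells[!paste(cells$condition, cells$replicate) %in% have, ]
  if (nrow(gaps))
    stop("reference gene '", referenceGene, "' missing in: ",
         paste(paste(gaps$condition, "rep", gaps$replicate),
               collapse = "; "))
  refCt <- stats::setNames(ref$ct, paste(ref$condition, ref$replicate))
  tab <- ctTable[ctTable$gene != referenceGene, ]
  tab$d_ct <- tab$ct - refCt[paste(tab$condition, tab$replicate)]
  agg <- stats::aggregate(d_ct ~ gene + condition, tab, mean)
  base <- agg[agg$condition == referenceCondition, ]
  baseMap <- stats::setNames(base$d_ct, base$gene)
  agg$delta_delta_ct <- agg$d_ct - baseMap[agg$gene]
  agg$fold_change <- 2^(-agg$delta_delta_ct)
  agg[order(agg$gene, agg$condition),
      c("gene", "condition", "delta_delta_ct", "fold_change")]
}

#' Box-plot summary
#'
#' Five-number summary with the convention used for the figures: box limits
#' at the 25th and 75th percentiles (quartiles by linear interpolation
#' between order statistics), whiskers at the most extreme data points within
#' 1.5 interquartile ranges of the box, remaining points listed as outliers.
#'
#' @param values numeric sample (>= 1 value).
#' @return A list with `q1`, `median`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
boxSummary <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("need at least one finite value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  inWhisker <- values >= q[1] - 1.5 * iqr & values <= q[3] + 1.5 * iqr
  list(q1 = q[1], median = q[2], q3 = q[3],
       whisker_low = min(values[inWhisker]),
       whisker_high = max(values[inWhisker]),
       outliers = sort(values[!inWhisker]))
}
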