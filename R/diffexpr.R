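#' Per-feature log2 fold change for a within-cohort contrast
#'
#' Computes, for every feature, the log2 fold change of a post-fracture
#' timepoint (`2w` or `4w`) against the `0w` baseline within one cohort.
#' The default takes the log2 of the ratio of linear-scale group means
#' (intensities are stored as log2, so means are taken on `2^x`), which is
#' algebraically the form the contribution score uses; `method = "log"`
#' instead takes the difference of mean log2 values.
#'
#' @param se `SummarizedExperiment` from [mirna_experiment()].
#' @param cohort `"adult"` or `"aged"`.
#' @param timepoint `"2w"` or `"4w"` (contrasted against `"0w"`).
#' @param method `"linear"` (ratio of linear means, default) or `"log"`
#'   (difference of mean log2 values).
#' @return Named numeric vector of log2 fold changes, one per feature.
#' @export
compute_log2fc <- function(se, cohort, timepoint, method = c("linear", "log")) {
  method <- match.arg(method)
  cohort <- match.arg(cohort, COHORTS)
  timepoint <- match.arg(timepoint, c("2w", "4w"))
  if (method == "linear") {
    hi <- group_linear_means(se, cohort, timepoint)
    lo <- group_linear_means(se, cohort, "0w")
    bad <- which(hi <= 0 | lo <= 0)
    if (length(bad))
      stop_rcifh("non-positive linear group mean for feature %s",
                 names(hi)[bad[1]], class = "rcifh_domain_error")
    log2(hi / lo)
  } else {
    m <- SummarizedExperiment::assay(se, "log2")
    idx_hi <- group_columns(se, cohort, timepoint)
    idx_lo <- group_columns(se, cohort, "0w")
    for (idx in list(idx_hi, idx_lo))
      if (length(idx) < 2L)
        stop_rcifh("contrast group has fewer than 2 samples",
                   class = "rcifh_replicates_error")
    rowMeans(m[, idx_hi, drop = FALSE]) - rowMeans(m[, idx_lo, drop = FALSE])
  }
}

# vectorised two-sample t-test on the rows of two matrices.
# var_equal = TRUE gives the pooled-variance (Student) test, the form behind
# ordinary microarray linear-model t-statistics; FALSE gives Welch with
# Satterthwaite degrees of freedom. Features with zero variance in both
# groups and equal means get p = 1 by convention.
row_t_test <- function(x, y, var_equal = TRUE) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se2 <- sp2 * (1 / nx + 1 / ny)
    df <- rep.int(nx + ny - 2, nrow(x))
  } else {
    se2 <- vx / nx + vy / ny
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- (mx - my) / sqrt(se2)
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate & mx == my] <- 1
  p[degenerate & mx != my] <- 0
  data.frame(statistic = tstat, df = df, p_value = p)
}

#' Differential-expression screen for one cohort and contrast
#'
#' Tests every miRNA for differential expression between a post-fracture
#' timepoint and the 0-week baseline within one cohort, using a two-sample
#' t-test on the log2 intensities. A miRNA is flagged significant when
#' `p_value < alpha` and `|log2FC| >= min_abs_log2fc` (defaults 0.05 and 1).
#' All features are returned, not only the significant ones.
#'
#' @inheritParams compute_log2fc
#' @param alpha p-value cutoff for the significance flag.
#' @param min_abs_log2fc absolute log2-fold-change floor for the flag.
#' @param var_equal pooled-variance Student t (default) or Welch (`FALSE`).
#' @param fc_method passed to [compute_log2fc()].
#' @param adjust optional multiple-testing correction applied into a
#'   `p_adj` column (`"none"` default, or `"BH"`); the significance flag
#'   always uses the raw p-value.
#' @return data.frame with columns `feature_id`, `contrast`, `log2fc`,
#'   `p_value` (and `p_adj` if requested), `significant`, `direction`
#'   (`up` / `down` / `unchanged`).
#' @export
test_differential <- function(se, cohort, timepoint, alpha = 0.05,
                              min_abs_log2fc = 1, var_equal = TRUE,
                              fc_method = c("linear", "log"),
                              adjust = c("none", "BH")) {
  cohort <- match.arg(cohort, COHORTS)
  timepoint <- match.arg(timepoint, c("2w", "4w"))
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha > 1)
    stop_rcifh("alpha must be in (0, 1]", class = "rcifh_argument_error")
  m <- SummarizedExperiment::assay(se, "log2")
  idx_hi <- group_columns(se, cohort, timepoint)
  idx_lo <- group_columns(se, cohort, "0w")
  for (idx in list(idx_hi, idx_lo))
    if (length(idx) < 2L)
      stop_rcifh("group %s has fewer than 2 samples for the %s contrast",
                 cohort, timepoint, class = "rcifh_replicates_error")
  tt <- row_t_test(m[, idx_hi, drop = FALSE], m[, idx_lo, drop = FALSE],
                   var_equal = var_equal)
  fc <- compute_log2fc(se, cohort, timepoint, method = match.arg(fc_method))
  out <- data.frame(
    feature_id = rownames(m),
    contrast = paste0(cohort, "_", timepoint, "_vs_0w"),
    log2fc = unname(fc),
    p_value = tt$p_value,
    stringsAsFactors = FALSE
  )
  if (adjust == "BH") out$p_adj <- p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < alpha & abs(out$log2fc) >= min_abs_log2fc
  out$direction <- de_direction(out$log2fc)
  rownames(out) <- NULL
  out
}

de_direction <- function(log2fc) {
  ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", "unchanged"))
}

#' Read an externally supplied gene differential-expression table
#'
#' Gene tables (e.g. limma results for angiogenesis, chondrogenesis or
#' osteogenesis expression sets) carry one row per gene with its log2 fold
#' change and p-value. Genes are flagged significant at `p_value < alpha`
#' with no fold-change floor, and their direction is the sign of the fold
#' change.
#'
#' @param path TSV with columns `gene_id`, `log2fc`, `p_value` (a `log2FC`
#'   header is accepted as an alias).
#' @param alpha significance cutoff (default 0.05).
#' @return data.frame with columns `gene_id`, `log2fc`, `p_value`,
#'   `significant`, `direction`.
#' @export
read_gene_de_table <- function(path, alpha = 0.05) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  names(tab)[names(tab) == "log2FC"] <- "log2fc"
  miss <- setdiff(c("gene_id", "log2fc", "p_value"), names(tab))
  if (length(miss))
    stop_rcifh(
      "gene DE table %s is missing column(s) %s; expected header: gene_id, log2fc, p_value",
      path, paste(miss, collapse = ", "), class = "rcifh_format_error")
  data.frame(
    gene_id = as.character(tab$gene_id),
    log2fc = as.numeric(tab$log2fc),
    p_value = as.numeric(tab$p_value),
    significant = as.numeric(tab$p_value) < alpha,
    direction = de_direction(as.numeric(tab$log2fc)),
    stringsAsFactors = FALSE
  )
}
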