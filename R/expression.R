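#' Assemble a miRNA expression experiment
#'
#' Wraps a log2-scale feature-by-sample intensity matrix and its sample
#' annotations in a [SummarizedExperiment::SummarizedExperiment] with one
#' assay, `"log2"`. Sample annotations must give, for every sample, the
#' cohort (`adult` or `aged`), the post-fracture timepoint (`0w`, `2w` or
#' `4w`) and a replicate index.
#'
#' @param values numeric matrix, features x samples, log2-scale intensities
#'   with row and column names.
#' @param samples data.frame with columns `sample_id`, `cohort`, `timepoint`,
#'   `replicate`; `sample_id` must match `colnames(values)`.
#' @return A `SummarizedExperiment` with assay `log2` and the annotations in
#'   `colData`.
#' @export
mirna_experiment <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_rcifh("`values` must be a numeric matrix", class = "rcifh_format_error")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop_rcifh("feature ids (rownames) must be present and unique",
               class = "rcifh_format_error")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop_rcifh("sample ids (colnames) must be present and unique",
               class = "rcifh_format_error")
  if (any(!is.finite(values)))
    stop_rcifh("expression values must all be finite",
               class = "rcifh_format_error")
  need <- c("sample_id", "cohort", "timepoint", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop_rcifh("sample table is missing column(s): %s",
               paste(miss, collapse = ", "), class = "rcifh_format_error")
  if (!setequal(samples$sample_id, colnames(values)) ||
      nrow(samples) != ncol(values))
    stop_rcifh("sample table ids do not match expression matrix columns",
               class = "rcifh_format_error")
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  bad <- setdiff(unique(samples$cohort), COHORTS)
  if (length(bad))
    stop_rcifh("unknown cohort value(s): %s", paste(bad, collapse = ", "),
               class = "rcifh_format_error")
  bad <- setdiff(unique(samples$timepoint), TIMEPOINTS)
  if (length(bad))
    stop_rcifh("unknown timepoint value(s): %s", paste(bad, collapse = ", "),
               class = "rcifh_format_error")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = values),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id)
  )
}

#' Read a miRNA expression matrix and its sample table
#'
#' `read_expression()` reads the tab-separated pair written by
#' [write_simulation()] (or any files in the same layout): an expression TSV
#' whose first column holds feature ids and whose remaining columns are
#' samples, plus a sample-annotation TSV with columns `sample_id`, `cohort`,
#' `timepoint`, `replicate`.
#'
#' @param expr_path path to the expression TSV (log2-scale intensities).
#' @param samples_path path to the sample annotation TSV.
#' @return A `SummarizedExperiment`; see [mirna_experiment()].
#' @export
read_expression <- function(expr_path, samples_path) {
  expr <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(expr) < 2)
    stop_rcifh("expression table needs a feature-id column plus >=1 sample",
               class = "rcifh_format_error")
  values <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(expr[[1]])
  samples <- read.delim(samples_path, stringsAsFactors = FALSE)
  mirna_experiment(values, samples)
}

# sample mask for one cohort x timepoint group
group_columns <- function(se, cohort, timepoint) {
  cd <- SummarizedExperiment::colData(se)
  which(cd$cohort == cohort & cd$timepoint == timepoint)
}

# linear-scale group means per feature (intensities are stored as log2)
group_linear_means <- function(se, cohort, timepoint, min_n = 2L) {
  idx <- group_columns(se, cohort, timepoint)
  if (length(idx) < min_n)
    stop_rcifh("group %s/%s has %d sample(s); at least %d required",
               cohort, timepoint, length(idx), min_n,
               class = "rcifh_replicates_error")
  if (length(idx) == 2L)
    warning(sprintf("group %s/%s has only 2 replicates", cohort, timepoint),
            call. = FALSE)
  m <- SummarizedExperiment::assay(se, "log2")[, idx, drop = FALSE]
  rowMeans(2^m)
}
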