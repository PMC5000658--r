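#' Read a miRNA-target interaction table
#'
#' One row per miRNA-gene interaction with its evidence provenance:
#' `validated` marks wet-experiment support (e.g. a curated interaction
#' database) and `prediction_methods` holds a comma-joined list of
#' computational predictors supporting the pair. Method names are
#' canonicalised (lower-cased, trimmed, de-duplicated) on read.
#'
#' @param path TSV with columns `mirna_id`, `gene_id`, `validated` (0/1 or
#'   TRUE/FALSE), `prediction_methods` (comma-joined, may be empty).
#' @return data.frame with columns `mirna_id`, `gene_id`, `validated`
#'   (logical), `prediction_methods` (list column of character vectors).
#' @export
read_target_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(prediction_methods = "character"))
  miss <- setdiff(c("mirna_id", "gene_id", "validated", "prediction_methods"),
                  names(tab))
  if (length(miss))
    stop_rcifh("target table %s is missing column(s): %s", path,
               paste(miss, collapse = ", "), class = "rcifh_format_error")
  data.frame(
    mirna_id = as.character(tab$mirna_id),
    gene_id = as.character(tab$gene_id),
    validated = as_flag(tab$validated),
    prediction_methods = I(canonicalize_methods(tab$prediction_methods)),
    stringsAsFactors = FALSE
  )
}

# accepts 0/1, TRUE/FALSE or "yes"/"no" style flags
as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("1", "true", "yes", "t", "y")
  bad <- !out & !x %in% c("0", "false", "no", "f", "n")
  if (any(bad))
    stop_rcifh("unrecognised boolean flag value: %s", x[which(bad)[1]],
               class = "rcifh_format_error")
  out
}

# lower-case, trim, drop empties, de-duplicate; returns a list column
canonicalize_methods <- function(x) {
  if (is.list(x)) x <- vapply(x, paste, "", collapse = ",")
  lapply(strsplit(ifelse(is.na(x), "", x), ","), function(v) {
    v <- tolower(trimws(v))
    sort(unique(v[nzchar(v)]))
  })
}

#' Evidence filter for miRNA-target interactions
#'
#' Keeps an interaction when it is supported by at least one wet-experiment
#' (`validated`) or by at least two distinct prediction methods.
#'
#' @param interactions data.frame as returned by [read_target_table()] (the
#'   `prediction_methods` column may also be a plain comma-joined character
#'   vector; it is canonicalised first).
#' @return The input with logical column `kept_evidence` and a
#'   `reason_evidence` column (`""` when kept, `"insufficient_evidence"`
#'   otherwise).
#' @export
evidence_filter <- function(interactions) {
  methods <- canonicalize_methods(interactions$prediction_methods)
  n_methods <- lengths(methods)
  keep <- interactions$validated | n_methods >= 2L
  interactions$prediction_methods <- I(methods)
  interactions$n_methods <- n_methods
  interactions$kept_evidence <- keep
  interactions$reason_evidence <- ifelse(keep, "", "insufficient_evidence")
  interactions
}

#' Opposite-expression-direction filter
#'
#' A miRNA represses its targets, so a genuine interaction in fracture
#' healing should pair an up-regulated miRNA with a significantly
#' down-regulated target gene, or a down-regulated miRNA with a
#' significantly up-regulated one. The miRNA's direction comes from the
#' cohort/timepoint contrast being scored (`mirna_de`); the gene's direction
#' and significance come from one or more gene DE tables
#' ([read_gene_de_table()]). With `combine = "union"` (default) the rule may
#' hold in any supplied table; `"intersection"` requires it in all of them.
#' Genes absent from every table are treated as unchanged and dropped.
#'
#' @param interactions data.frame with `mirna_id`, `gene_id` (extra columns
#'   are carried through).
#' @param mirna_de data.frame from [test_differential()]; every interaction's
#'   miRNA must appear in it.
#' @param gene_de one gene DE data.frame or a (optionally named) list of them.
#' @param combine `"union"` or `"intersection"` across gene tables.
#' @return The input with logical column `kept_direction` and a
#'   `reason_direction` column (`""`, `"mirna_unchanged"` or
#'   `"gene_not_opposite"`).
#' @export
direction_filter <- function(interactions, mirna_de, gene_de,
                             combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  if (is.data.frame(gene_de)) gene_de <- list(gene_de)
  idx <- match(interactions$mirna_id, mirna_de$feature_id)
  if (anyNA(idx))
    stop_rcifh("miRNA %s is absent from the miRNA DE table",
               interactions$mirna_id[which(is.na(idx))[1]],
               class = "rcifh_lookup_error")
  mdir <- mirna_de$direction %||% de_direction(mirna_de$log2fc)
  mdir <- mdir[idx]
  gene_de <- lapply(gene_de, function(tab) {
    # raw (gene_id, log2fc, p_value) tables get the standard gene DE rule
    if (is.null(tab$direction)) tab$direction <- de_direction(tab$log2fc)
    if (is.null(tab$significant)) tab$significant <- tab$p_value < 0.05
    tab
  })
  per_table <- vapply(gene_de, function(tab) {
    g <- match(interactions$gene_id, tab$gene_id)
    gdir <- ifelse(is.na(g), "unchanged", tab$direction[g])
    gsig <- !is.na(g) & tab$significant[g]
    gsig & ((mdir == "up" & gdir == "down") | (mdir == "down" & gdir == "up"))
  }, logical(nrow(interactions)))
  per_table <- matrix(per_table, nrow = nrow(interactions))
  keep <- if (combine == "union") rowSums(per_table) > 0
          else rowSums(per_table) == length(gene_de)
  interactions$kept_direction <- keep
  interactions$reason_direction <-
    ifelse(keep, "", ifelse(mdir == "unchanged", "mirna_unchanged",
                            "gene_not_opposite"))
  interactions
}

#' Apply the full interaction filter cascade
#'
#' Composes [evidence_filter()] and [direction_filter()]; an interaction is
#' kept only if it passes both. The two filters are independent, so their
#' order does not matter.
#'
#' @inheritParams direction_filter
#' @inheritParams evidence_filter
#' @return The input with columns `kept_evidence`, `kept_direction`, `kept`
#'   and `reasons` (semicolon-joined machine-readable failure reasons, `""`
#'   for survivors).
#' @export
filter_target_interactions <- function(interactions, mirna_de, gene_de,
                                       combine = c("union", "intersection")) {
  out <- evidence_filter(interactions)
  out <- direction_filter(out, mirna_de, gene_de, combine = combine)
  out$kept <- out$kept_evidence & out$kept_direction
  reasons <- paste(out$reason_evidence, out$reason_direction, sep = ";")
  out$reasons <- gsub("^;|;$", "", reasons)
  out
}

#' Per-miRNA target lists from a filtered interaction table
#'
#' @param mirnas character vector of miRNA ids to report (a miRNA with no
#'   surviving interactions maps to an empty vector).
#' @param filtered data.frame from [filter_target_interactions()] (or any
#'   table with `mirna_id`, `gene_id` and logical `kept`).
#' @return Named list mapping each requested miRNA to its sorted, unique
#'   surviving target genes.
#' @export
interactions_for_mirna_set <- function(mirnas, filtered) {
  kept <- filtered[filtered$kept, c("mirna_id", "gene_id")]
  out <- lapply(stats::setNames(mirnas, mirnas), function(m) {
    sort(unique(kept$gene_id[kept$mirna_id == m]))
  })
  out
}
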