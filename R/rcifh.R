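#' Contribution of each miRNA to impaired fracture healing
#'
#' For every miRNA with a network-power record, computes the four
#' linear-scale group means (adult and aged cohorts at the chosen
#' post-fracture timepoint and at 0 weeks), the two within-cohort log2 fold
#' changes, and the contribution score
#'
#'   `rcifh = (adult_log2fc - aged_log2fc) * prn`
#'
#' A positive score means the miRNA promotes bone fracture healing; a
#' negative score means it impairs healing (its fold change is larger in
#' the aged cohort, so its repression of targets is stronger where healing
#' is impaired). Records are returned sorted by `|rcifh|` descending with
#' ties broken lexicographically by miRNA id.
#'
#' @param se `SummarizedExperiment` from [mirna_experiment()].
#' @param prn data.frame from [compute_prn()]; only its miRNAs are scored.
#' @param timepoint `"2w"` or `"4w"`.
#' @return data.frame with columns `mirna_id`, `timepoint`, `enh`, `enn`,
#'   `eah`, `ean` (linear-scale means: adult high/0w, aged high/0w),
#'   `adult_log2fc`, `aged_log2fc`, `prn`, `rcifh`, `rank`.
#' @export
compute_rcifh <- function(se, prn, timepoint = c("2w", "4w")) {
  timepoint <- match.arg(timepoint)
  means <- list(
    enh = group_linear_means(se, "adult", timepoint),
    enn = group_linear_means(se, "adult", "0w"),
    eah = group_linear_means(se, "aged", timepoint),
    ean = group_linear_means(se, "aged", "0w")
  )
  ids <- as.character(prn$mirna_id)
  missing <- setdiff(ids, rownames(se))
  if (length(missing))
    stop_rcifh("miRNA %s has a PRN record but no expression data",
               missing[1], class = "rcifh_lookup_error")
  for (nm in names(means)) {
    v <- means[[nm]][ids]
    if (any(v <= 0))
      stop_rcifh("non-positive %s group mean for miRNA %s", toupper(nm),
                 ids[which(v <= 0)[1]], class = "rcifh_domain_error")
    means[[nm]] <- v
  }
  adult_log2fc <- log2(means$enh / means$enn)
  aged_log2fc <- log2(means$eah / means$ean)
  out <- data.frame(
    mirna_id = ids,
    timepoint = timepoint,
    enh = unname(means$enh), enn = unname(means$enn),
    eah = unname(means$eah), ean = unname(means$ean),
    adult_log2fc = unname(adult_log2fc),
    aged_log2fc = unname(aged_log2fc),
    prn = prn$prn,
    stringsAsFactors = FALSE
  )
  out$rcifh <- (out$adult_log2fc - out$aged_log2fc) * out$prn
  out <- out[order(-abs(out$rcifh), out$mirna_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the top-scoring miRNAs
#'
#' Keeps the `k` records with the largest contribution score among those
#' passing an optional fold-change floor (applied to the larger of the two
#' cohort `|log2fc|` values). By default the magnitude `|rcifh|` is ranked,
#' since both strongly promoting and strongly impairing miRNAs are of
#' interest; `signed = TRUE` ranks by the signed value descending instead.
#' Ties are broken lexicographically by miRNA id.
#'
#' @param records data.frame from [compute_rcifh()].
#' @param k number of records to keep (all records if fewer).
#' @param min_abs_log2fc fold-change floor (default 0 = no floor).
#' @param signed rank by signed `rcifh` instead of `|rcifh|`.
#' @return The selected subset, re-ranked 1..n.
#' @export
select_top <- function(records, k = 100, min_abs_log2fc = 0, signed = FALSE) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0)
    stop_rcifh("k must be a positive number", class = "rcifh_argument_error")
  pass <- pmax(abs(records$adult_log2fc), abs(records$aged_log2fc)) >=
    min_abs_log2fc
  out <- records[pass, , drop = FALSE]
  key <- if (signed) -out$rcifh else -abs(out$rcifh)
  out <- out[order(key, out$mirna_id), , drop = FALSE]
  out <- head(out, n = k)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Pooled target genes of the selected miRNAs
#'
#' Unions the surviving target genes of the selected miRNAs (the gene list
#' handed to pathway enrichment) and annotates each gene with the miRNAs
#' targeting it and the regulation status its miRNAs' scores imply in the
#' aged cohort: a miRNA with a negative score is relatively up-regulated in
#' aged animals, so its targets are `inhibited`; a positive score implies
#' `activated` targets. A gene reached by miRNAs of both signs is `mixed`.
#'
#' @param selected data.frame from [select_top()] (or [compute_rcifh()]).
#' @param target_lists named list from [interactions_for_mirna_set()].
#' @return data.frame with columns `gene_id`, `mirna_ids` (comma-joined),
#'   `status` (`activated` / `inhibited` / `mixed`), sorted by `gene_id`.
#' @export
gather_top_targets <- function(selected, target_lists) {
  rows <- lapply(seq_len(nrow(selected)), function(i) {
    m <- selected$mirna_id[i]
    targets <- target_lists[[m]]
    if (is.null(targets) || !length(targets)) return(NULL)
    data.frame(gene_id = targets, mirna_id = m,
               status = if (selected$rcifh[i] >= 0) "activated" else "inhibited",
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  if (is.null(long))
    return(data.frame(gene_id = character(), mirna_ids = character(),
                      status = character(), stringsAsFactors = FALSE))
  split_rows <- split(long, long$gene_id)
  out <- data.frame(
    gene_id = names(split_rows),
    mirna_ids = vapply(split_rows, function(d)
      paste(sort(unique(d$mirna_id)), collapse = ","), ""),
    status = vapply(split_rows, function(d) {
      s <- unique(d$status)
      if (length(s) > 1) "mixed" else s
    }, ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$gene_id), , drop = FALSE]
}
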