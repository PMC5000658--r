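#' Read a GMT gene-set collection
#'
#' Standard GMT layout: one set per line, tab-separated — set name,
#' description, then member gene ids. Members are de-duplicated; sets empty
#' after de-duplication are dropped with a warning.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors (set name -> member genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 0L) < 3L
  if (any(short))
    warning(sprintf("dropping %d GMT line(s) with no members", sum(short)),
            call. = FALSE)
  fields <- fields[!short]
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop_rcifh("duplicate gene-set names in %s", path,
               class = "rcifh_format_error")
  sets[lengths(sets) > 0]
}

#' Over-representation analysis of a gene list
#'
#' One-sided Fisher's exact test (upper hypergeometric tail) of the overlap
#' between a query gene list and each gene set, within a background
#' universe: with universe size `N`, set size `K`, query size `n` and
#' overlap `k`, the p-value is `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' Query genes outside the universe are dropped (with a message); set
#' members are intersected with the universe. Sets are flagged significant
#' at raw `p < alpha`; Benjamini-Hochberg q-values are reported alongside.
#'
#' @param query character vector of gene ids.
#' @param gene_sets named list of character vectors ([read_gmt()]).
#' @param universe character vector of background gene ids.
#' @param alpha significance cutoff on the raw p-value (default 0.05).
#' @return data.frame sorted by ascending p-value with columns `set`, `k`
#'   (overlap), `K` (set size in universe), `n` (query size in universe),
#'   `N` (universe size), `p_value`, `q_value`, `significant`.
#' @export
enrich <- function(query, gene_sets, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (!length(universe))
    stop_rcifh("empty background universe", class = "rcifh_input_error")
  query <- unique(as.character(query))
  dropped <- setdiff(query, universe)
  if (length(dropped))
    message(sprintf("dropping %d query gene(s) outside the universe",
                    length(dropped)))
  query <- intersect(query, universe)
  if (!length(query))
    stop_rcifh("no query genes left after intersecting with the universe",
               class = "rcifh_input_error")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  out$q_value <- p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
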