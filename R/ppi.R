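#' Read a protein-protein interaction edge list
#'
#' Expects a BioGRID-style tab-separated edge list: one row per reported
#' interaction with the two gene symbols and an evidence-type label
#' (identifiers must already be harmonised to the gene ids used elsewhere).
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `evidence_type`.
#' @return data.frame with those three character columns.
#' @export
read_ppi_edges <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_a", "gene_b", "evidence_type"), names(tab))
  if (length(miss))
    stop_rcifh("PPI edge table %s is missing column(s): %s", path,
               paste(miss, collapse = ", "), class = "rcifh_format_error")
  for (col in c("gene_a", "gene_b", "evidence_type")) {
    v <- as.character(tab[[col]])
    bad <- which(is.na(v) | !nzchar(trimws(v)))
    if (length(bad))
      stop_rcifh("malformed PPI edge row at line %d: empty %s",
                 bad[1] + 1L, col, class = "rcifh_format_error")
    tab[[col]] <- v
  }
  tab[c("gene_a", "gene_b", "evidence_type")]
}

#' Build the experimentally supported PPI graph
#'
#' Retains only edges whose evidence type is in `experimental_types`
#' (wet-experiment support), removes self-loops, and collapses duplicate
#' and reversed edges into a single undirected edge.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `evidence_type`
#'   (see [read_ppi_edges()]).
#' @param experimental_types evidence labels counted as wet-experiment
#'   support (default `"experimental"`).
#' @return An undirected simple [igraph::graph] whose vertices are gene ids.
#' @export
build_ppi_graph <- function(edges, experimental_types = "experimental") {
  keep <- edges$evidence_type %in% experimental_types
  ab <- edges[keep & edges$gene_a != edges$gene_b,
              c("gene_a", "gene_b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(ab, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Network power (PRN) of each miRNA
#'
#' The network power of a miRNA is the sum, over its filtered target genes,
#' of each target's degree in the experimentally supported PPI graph —
#' i.e. the number of proteins directly connected to that target. Targets
#' absent from the graph contribute 0 (the sum is never renormalised by the
#' number of targets).
#'
#' @param target_lists named list mapping miRNA ids to character vectors of
#'   target gene ids (see [interactions_for_mirna_set()]).
#' @param graph undirected [igraph::graph] from [build_ppi_graph()].
#' @return data.frame with columns `mirna_id`, `n_targets`, `prn`.
#' @export
compute_prn <- function(target_lists, graph) {
  deg <- igraph::degree(graph)
  prn <- vapply(target_lists, function(targets) {
    targets <- unique(targets)
    sum(deg[intersect(targets, names(deg))])
  }, numeric(1))
  data.frame(
    mirna_id = names(target_lists),
    n_targets = lengths(lapply(target_lists, unique)),
    prn = unname(prn),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
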