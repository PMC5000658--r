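# Independent oracles and small fixture builders shared across tests.

# Brute-force network power: for each target, count its distinct partners
# by scanning the raw edge list. Deliberately avoids igraph so it is an
# independent route to the same quantity as compute_prn().
prn_oracle <- function(targets, edges, experimental_types = "experimental") {
  keep <- edges$evidence_type %in% experimental_types &
    edges$gene_a != edges$gene_b
  total <- 0L
  for (t in unique(targets)) {
    partners <- c(edges$gene_b[keep & edges$gene_a == t],
                  edges$gene_a[keep & edges$gene_b == t])
    total <- total + length(unique(partners))
  }
  total
}

# Exhaustive hypergeometric upper tail P(X >= k): enumerate every possible
# draw of n from a universe of N in which elements 1..K form the set.
hyper_tail_oracle <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

# random edge table including self-loops, duplicates and non-experimental
# rows, to exercise the graph builder
random_edge_table <- function(n_nodes, n_rows, frac_predicted = 0.2) {
  genes <- sprintf("g%02d", seq_len(n_nodes))
  data.frame(
    gene_a = sample(genes, n_rows, replace = TRUE),
    gene_b = sample(genes, n_rows, replace = TRUE),
    evidence_type = sample(c("experimental", "predicted"), n_rows,
                           replace = TRUE,
                           prob = c(1 - frac_predicted, frac_predicted)),
    stringsAsFactors = FALSE)
}

# Build a small expression experiment from per-group log2 means.
# group_means: named list keyed "<cohort>_<timepoint>" -> numeric vector of
# log2 means (one per feature). Replicates are mean + N(0, sd).
make_se <- function(group_means, feature_ids = NULL, n_rep = 3, sd = 0) {
  n_feat <- length(group_means[[1]])
  if (is.null(feature_ids)) feature_ids <- sprintf("f%03d", seq_len(n_feat))
  cols <- list(); ann <- list()
  for (key in names(group_means)) {
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    for (r in seq_len(n_rep)) {
      id <- sprintf("%s_r%d", key, r)
      cols[[id]] <- group_means[[key]] + rnorm(n_feat, 0, sd)
      ann[[id]] <- data.frame(sample_id = id, cohort = parts[1],
                              timepoint = parts[2], replicate = r,
                              stringsAsFactors = FALSE)
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- feature_ids
  mirna_experiment(values, do.call(rbind, ann))
}

fixture_path <- function(...) {
  system.file("extdata", "filter_fixture", ..., package = "rcifh",
              mustWork = TRUE)
}

# six-interaction toy table: 2 miRNAs; one row fails the evidence rule,
# one fails the direction rule, four survive (split 3/1)
toy_six_interactions <- function() {
  mirna_de <- data.frame(
    feature_id = c("mirA", "mirB"),
    log2fc = c(1.4, -1.1), p_value = c(0.01, 0.02),
    significant = TRUE, direction = c("up", "down"),
    stringsAsFactors = FALSE)
  gene_de <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    log2fc = c(-1, -1, -1, -1, 1, 1),
    p_value = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.30),
    stringsAsFactors = FALSE)
  gene_de$significant <- gene_de$p_value < 0.05
  gene_de$direction <- ifelse(gene_de$log2fc > 0, "up", "down")
  interactions <- data.frame(
    mirna_id = c("mirA", "mirA", "mirA", "mirA", "mirB", "mirB"),
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    validated = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    prediction_methods = c("", "", "", "m1", "", ""),
    stringsAsFactors = FALSE)
  list(interactions = interactions, mirna_de = mirna_de, gene_de = gene_de)
}
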