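#' Describe one planted miRNA effect
#'
#' A planted miRNA receives additive log2-scale expression shifts at 2 and 4
#' weeks post-fracture, separately per cohort, and its target genes can be
#' placed preferentially on high- or low-degree PPI nodes to control its
#' network power.
#'
#' @param mirna_id id of the planted miRNA.
#' @param adult_log2fc_2wk,aged_log2fc_2wk,adult_log2fc_4wk,aged_log2fc_4wk
#'   additive log2 fold changes relative to the 0-week baseline.
#' @param target_degree_bias `"none"` (uniform target placement), `"high"`
#'   (hub targets) or `"low"` (peripheral targets).
#' @return A list of class `planted_effect`.
#' @export
planted_effect <- function(mirna_id,
                           adult_log2fc_2wk = 0, aged_log2fc_2wk = 0,
                           adult_log2fc_4wk = 0, aged_log2fc_4wk = 0,
                           target_degree_bias = c("none", "high", "low")) {
  structure(list(
    mirna_id = as.character(mirna_id),
    adult_log2fc_2wk = adult_log2fc_2wk, aged_log2fc_2wk = aged_log2fc_2wk,
    adult_log2fc_4wk = adult_log2fc_4wk, aged_log2fc_4wk = aged_log2fc_4wk,
    target_degree_bias = match.arg(target_degree_bias)
  ), class = "planted_effect")
}

#' Configuration of a synthetic fracture-healing miRNA study
#'
#' Describes a two-cohort (adult, aged) by three-timepoint (0, 2, 4 weeks
#' post-fracture) miRNA microarray study with replicate noise, a planted set
#' of differentially expressed miRNAs, a miRNA-target map with controllable
#' evidence annotations, gene differential-expression tables for three
#' skeletal lineages, and a PPI graph — everything the scoring pipeline
#' consumes, with known ground truth.
#'
#' Defaults mirror a desk-scale version of a real design: 200 miRNAs, 1000
#' genes, 3 replicates per cohort-timepoint group, log2 intensities around 8
#' with 0.3 log2 units of replicate noise.
#'
#' @param n_mirnas,n_genes feature counts (planted miRNAs are included in
#'   `n_mirnas`).
#' @param replicates_per_group arrays per cohort x timepoint group (>= 2).
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-miRNA
#'   baseline log2 intensities.
#' @param replicate_sd i.i.d. Gaussian replicate noise, log2 units (> 0).
#' @param planted_mirnas list of [planted_effect()] objects.
#' @param targets_per_mirna length-2 range; each miRNA's target count is
#'   drawn uniformly from it.
#' @param frac_validated_evidence probability a background interaction
#'   carries wet-experiment support.
#' @param n_prediction_methods number of in-silico target predictors.
#' @param method_support_prob probability each predictor supports a
#'   background interaction.
#' @param ppi_model `list(type = "scale_free", m = ...)` (preferential
#'   attachment) or `list(type = "random", p = ...)` (Erdos-Renyi).
#' @param frac_decoy_edges non-experimental decoy edges emitted into the
#'   edge list, as a fraction of the experimental edge count (the graph
#'   builder must discard them).
#' @param n_gene_sets,gene_set_size random gene sets written to the
#'   synthetic GMT collection (plus one module of planted targets).
#' @param lineages names of the gene DE tables to generate.
#' @param seed integer; fixes all downstream randomness.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_mirnas = 200, n_genes = 1000,
                              replicates_per_group = 3,
                              baseline_log2_mean = 8, baseline_log2_sd = 1,
                              replicate_sd = 0.3,
                              planted_mirnas = list(),
                              targets_per_mirna = c(5, 15),
                              frac_validated_evidence = 0.3,
                              n_prediction_methods = 4,
                              method_support_prob = 0.3,
                              ppi_model = list(type = "scale_free", m = 2),
                              frac_decoy_edges = 0.1,
                              n_gene_sets = 20, gene_set_size = c(20, 60),
                              lineages = c("angiogenesis", "chondrogenesis",
                                           "osteogenesis"),
                              seed = 1) {
  cfg <- list(n_mirnas = n_mirnas, n_genes = n_genes,
              replicates_per_group = replicates_per_group,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              replicate_sd = replicate_sd,
              planted_mirnas = planted_mirnas,
              targets_per_mirna = targets_per_mirna,
              frac_validated_evidence = frac_validated_evidence,
              n_prediction_methods = n_prediction_methods,
              method_support_prob = method_support_prob,
              ppi_model = ppi_model, frac_decoy_edges = frac_decoy_edges,
              n_gene_sets = n_gene_sets, gene_set_size = gene_set_size,
              lineages = lineages, seed = seed)
  check_count <- function(field, min) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < min ||
        v != round(v))
      stop_rcifh("invalid configuration field `%s`: must be an integer >= %d",
                 field, min, class = "rcifh_config_error")
  }
  check_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop_rcifh("invalid configuration field `%s`: must be in [0, 1]",
                 field, class = "rcifh_config_error")
  }
  check_count("n_mirnas", 1); check_count("n_genes", 1)
  check_count("replicates_per_group", 2)
  check_count("n_prediction_methods", 0); check_count("n_gene_sets", 0)
  check_count("seed", -.Machine$integer.max)
  check_prob("frac_validated_evidence"); check_prob("method_support_prob")
  check_prob("frac_decoy_edges")
  if (!is.numeric(replicate_sd) || replicate_sd <= 0)
    stop_rcifh("invalid configuration field `replicate_sd`: must be > 0",
               class = "rcifh_config_error")
  for (field in c("targets_per_mirna", "gene_set_size")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 2 || any(v < 1) || v[1] > v[2])
      stop_rcifh("invalid configuration field `%s`: must be a range c(lo, hi)",
                 field, class = "rcifh_config_error")
  }
  if (!is.list(planted_mirnas) ||
      !all(vapply(planted_mirnas, inherits, TRUE, "planted_effect")))
    stop_rcifh("invalid configuration field `planted_mirnas`: must be a list of planted_effect objects",
               class = "rcifh_config_error")
  if (length(planted_mirnas) > n_mirnas)
    stop_rcifh("invalid configuration field `planted_mirnas`: more planted miRNAs than `n_mirnas`",
               class = "rcifh_config_error")
  if (anyDuplicated(vapply(planted_mirnas, `[[`, "", "mirna_id")))
    stop_rcifh("invalid configuration field `planted_mirnas`: duplicate miRNA ids",
               class = "rcifh_config_error")
  if (!is.list(ppi_model) || is.null(ppi_model$type) ||
      !ppi_model$type %in% c("scale_free", "random"))
    stop_rcifh("invalid configuration field `ppi_model`: type must be \"scale_free\" or \"random\"",
               class = "rcifh_config_error")
  structure(cfg, class = "simulation_config")
}

# independent degree-sum: scans the raw edge list rather than any graph
# object, so generator ground truth never depends on the ppi module
prn_edge_scan <- function(targets, edges) {
  keep <- edges$evidence_type == "experimental" & edges$gene_a != edges$gene_b
  a <- pmin(edges$gene_a[keep], edges$gene_b[keep])
  b <- pmax(edges$gene_a[keep], edges$gene_b[keep])
  pair <- unique(paste(a, b, sep = "\r"))
  ends <- unlist(strsplit(pair, "\r", fixed = TRUE))
  sum(ends %in% unique(targets))
}

#' Simulate a complete synthetic study
#'
#' Generates, from a [simulation_config()], every input the scoring pipeline
#' consumes: the log2 miRNA expression matrix with sample annotations, one
#' gene DE table per lineage, the annotated miRNA-target interaction table,
#' the PPI edge list, a synthetic GMT gene-set collection, and a ground
#' truth record (planted targets, their network power computed by an
#' independent edge-list scan, and the expected sign of each planted
#' miRNA's contribution score per timepoint).
#'
#' Planted miRNAs' interactions are annotated as experimentally validated
#' and their targets are written into the assigned lineage's gene DE table
#' with significant, opposite-direction fold changes, so the filter cascade
#' retains exactly the planted target sets.
#'
#' @param config a [simulation_config()].
#' @return A list of class `rcifh_simulation` with elements `se`
#'   (expression `SummarizedExperiment`), `gene_de` (named list of
#'   data.frames), `targets`, `ppi_edges`, `gene_sets`, `ground_truth`,
#'   `config`.
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  set.seed(config$seed)
  planted <- config$planted_mirnas
  planted_ids <- vapply(planted, `[[`, "", "mirna_id")
  n_bg <- config$n_mirnas - length(planted_ids)
  mirna_ids <- c(planted_ids,
                 sprintf("miR-sim-%0*d", nchar(as.character(max(n_bg, 1))),
                         seq_len(n_bg)))
  gene_ids <- sprintf("G%0*d", nchar(as.character(config$n_genes)),
                      seq_len(config$n_genes))

  ## --- PPI graph ----------------------------------------------------------
  g <- switch(config$ppi_model$type,
    scale_free = igraph::sample_pa(config$n_genes,
                                   m = config$ppi_model$m %||% 2,
                                   directed = FALSE),
    random = igraph::sample_gnp(config$n_genes,
                                p = config$ppi_model$p %||% 0.01)
  )
  igraph::V(g)$name <- gene_ids
  el <- igraph::as_edgelist(g)
  ppi_edges <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                          evidence_type = "experimental",
                          stringsAsFactors = FALSE)
  n_decoy <- round(config$frac_decoy_edges * nrow(ppi_edges))
  if (n_decoy > 0) {
    da <- sample(gene_ids, n_decoy, replace = TRUE)
    db <- sample(gene_ids, n_decoy, replace = TRUE)
    ppi_edges <- rbind(ppi_edges,
                       data.frame(gene_a = da, gene_b = db,
                                  evidence_type = "predicted",
                                  stringsAsFactors = FALSE))
  }
  deg <- igraph::degree(g)

  ## --- target map ---------------------------------------------------------
  hub_pool <- gene_ids[deg >= stats::quantile(deg, 0.9)]
  low_pool <- gene_ids[deg <= stats::quantile(deg, 0.25)]
  draw_targets <- function(bias, n_t) {
    pool <- switch(bias, high = hub_pool, low = low_pool, none = gene_ids)
    sample(pool, min(n_t, length(pool)))
  }
  rng <- config$targets_per_mirna
  n_targets <- sample(seq(rng[1], rng[2]), config$n_mirnas, replace = TRUE)
  biases <- c(vapply(planted, `[[`, "", "target_degree_bias"),
              rep("none", n_bg))
  target_rows <- vector("list", config$n_mirnas)
  method_names <- if (config$n_prediction_methods > 0)
    sprintf("pm%02d", seq_len(config$n_prediction_methods)) else character()
  for (i in seq_len(config$n_mirnas)) {
    tg <- draw_targets(biases[i], n_targets[i])
    is_planted <- i <= length(planted_ids)
    if (is_planted) {
      validated <- rep(TRUE, length(tg))
      methods <- rep("", length(tg))
    } else {
      validated <- runif(length(tg)) < config$frac_validated_evidence
      methods <- vapply(seq_along(tg), function(j) {
        supp <- method_names[runif(length(method_names)) <
                               config$method_support_prob]
        paste(supp, collapse = ",")
      }, "")
    }
    target_rows[[i]] <- data.frame(
      mirna_id = mirna_ids[i], gene_id = tg,
      validated = as.integer(validated), prediction_methods = methods,
      stringsAsFactors = FALSE)
  }
  targets <- do.call(rbind, target_rows)
  rownames(targets) <- NULL

  ## --- expression ---------------------------------------------------------
  reps <- config$replicates_per_group
  samples <- expand.grid(replicate = seq_len(reps), timepoint = TIMEPOINTS,
                         cohort = COHORTS, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  samples <- samples[, c("cohort", "timepoint", "replicate")]
  samples$sample_id <- sprintf("%s_%s_r%d", samples$cohort,
                               samples$timepoint, samples$replicate)
  baseline <- rnorm(config$n_mirnas, config$baseline_log2_mean,
                    config$baseline_log2_sd)
  effect_of <- function(i, cohort, timepoint) {
    if (i > length(planted) || timepoint == "0w") return(0)
    pe <- planted[[i]]
    key <- paste0(cohort, "_log2fc_", sub("w", "wk", timepoint))
    pe[[key]]
  }
  values <- matrix(0, config$n_mirnas, nrow(samples),
                   dimnames = list(mirna_ids, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    eff <- vapply(seq_len(config$n_mirnas), effect_of, 0,
                  cohort = samples$cohort[s], timepoint = samples$timepoint[s])
    values[, s] <- baseline + eff +
      rnorm(config$n_mirnas, 0, config$replicate_sd)
  }
  se <- mirna_experiment(values,
                         samples[, c("sample_id", "cohort", "timepoint",
                                     "replicate")])

  ## --- gene DE tables -----------------------------------------------------
  gene_de <- lapply(config$lineages, function(lin) {
    data.frame(gene_id = gene_ids,
               log2fc = rnorm(config$n_genes, 0, 1),
               p_value = runif(config$n_genes),
               stringsAsFactors = FALSE)
  })
  names(gene_de) <- config$lineages
  planted_lineage <- if (length(planted))
    config$lineages[(seq_along(planted) - 1L) %% length(config$lineages) + 1L]
  else character()
  planted_dir <- vapply(planted, function(pe) {
    effs <- c(pe$aged_log2fc_2wk, pe$aged_log2fc_4wk,
              pe$adult_log2fc_2wk, pe$adult_log2fc_4wk)
    nz <- effs[effs != 0]
    if (length(nz)) sign(nz[1]) else 0
  }, 0)
  for (i in seq_along(planted)) {
    if (planted_dir[i] == 0) next
    tg <- target_rows[[i]]$gene_id
    tab <- gene_de[[planted_lineage[i]]]
    j <- match(tg, tab$gene_id)
    tab$log2fc[j] <- -planted_dir[i] * runif(length(j), 1, 2)
    tab$p_value[j] <- runif(length(j), 1e-4, 0.01)
    gene_de[[planted_lineage[i]]] <- tab
  }

  ## --- gene sets ----------------------------------------------------------
  gene_sets <- list()
  if (config$n_gene_sets > 0) {
    sizes <- sample(seq(config$gene_set_size[1], config$gene_set_size[2]),
                    config$n_gene_sets, replace = TRUE)
    gene_sets <- lapply(sizes, function(sz)
      sample(gene_ids, min(sz, length(gene_ids))))
    names(gene_sets) <- sprintf("synthetic_set_%02d",
                                seq_len(config$n_gene_sets))
  }
  planted_targets_all <- unique(unlist(lapply(
    seq_along(planted), function(i) target_rows[[i]]$gene_id)))
  if (length(planted_targets_all))
    gene_sets$synthetic_planted_target_module <- sort(planted_targets_all)

  ## --- ground truth -------------------------------------------------------
  gt_planted <- lapply(seq_along(planted), function(i) {
    pe <- planted[[i]]
    tg <- sort(unique(target_rows[[i]]$gene_id))
    sign_at <- function(tp) {
      diff <- effect_of(i, "adult", tp) - effect_of(i, "aged", tp)
      if (diff == 0) 0 else sign(diff)
    }
    list(mirna_id = pe$mirna_id,
         target_degree_bias = pe$target_degree_bias,
         lineage = planted_lineage[i],
         targets = tg,
         prn = prn_edge_scan(tg, ppi_edges),
         expected_sign_2w = sign_at("2w"),
         expected_sign_4w = sign_at("4w"))
  })
  ground_truth <- list(seed = config$seed,
                       n_mirnas = config$n_mirnas,
                       n_genes = config$n_genes,
                       planted = gt_planted)

  structure(list(se = se, gene_de = gene_de, targets = targets,
                 ppi_edges = ppi_edges, gene_sets = gene_sets,
                 ground_truth = ground_truth, config = config),
            class = "rcifh_simulation")
}

#' Write a simulated study to disk
#'
#' Writes the on-disk formats the pipeline stages read:
#' `mirna_expression.tsv`, `samples.tsv`, `gene_de_<lineage>.tsv`,
#' `targets.tsv`, `ppi_edges.tsv`, `gene_sets.gmt` and
#' `ground_truth.json`. Output is deterministic: the same simulation writes
#' byte-identical files.
#'
#' @param sim result of [simulate_study()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_simulation <- function(sim, out_dir) {
  stopifnot(inherits(sim, "rcifh_simulation"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  p <- function(name) file.path(out_dir, name)

  m <- SummarizedExperiment::assay(sim$se, "log2")
  expr <- data.frame(mirna_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv(expr, p("mirna_expression.tsv"))
  paths["expression"] <- p("mirna_expression.tsv")

  cd <- as.data.frame(SummarizedExperiment::colData(sim$se))
  write_tsv(cd[, c("sample_id", "cohort", "timepoint", "replicate")],
            p("samples.tsv"))
  paths["samples"] <- p("samples.tsv")

  for (lin in names(sim$gene_de)) {
    f <- p(sprintf("gene_de_%s.tsv", lin))
    write_tsv(sim$gene_de[[lin]], f)
    paths[paste0("gene_de_", lin)] <- f
  }
  write_tsv(sim$targets, p("targets.tsv"))
  paths["targets"] <- p("targets.tsv")
  write_tsv(sim$ppi_edges, p("ppi_edges.tsv"))
  paths["ppi"] <- p("ppi_edges.tsv")

  gmt <- vapply(names(sim$gene_sets), function(nm)
    paste(c(nm, "synthetic", sim$gene_sets[[nm]]), collapse = "\t"), "")
  writeLines(unname(gmt), p("gene_sets.gmt"))
  paths["gene_sets"] <- p("gene_sets.gmt")

  jsonlite::write_json(sim$ground_truth, p("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["ground_truth"] <- p("ground_truth.json")
  invisible(paths)
}
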