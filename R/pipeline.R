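#' Run the full scoring pipeline
#'
#' Chains every stage — synthetic-study generation (or loading of user
#' inputs), miRNA differential expression in both cohorts, target-interaction
#' filtering, PPI network power, contribution scoring, and pathway
#' over-representation — with plain-file handoff between stages, a JSON run
#' manifest of file digests and record counts, and a JSON-lines stage log.
#' Stage inputs are re-read from the files the previous stage wrote, so a
#' run also exercises every parser.
#'
#' The configuration is a named list (or path to a YAML file) with blocks:
#' \describe{
#'   \item{`seed`}{integer; fixes all randomness.}
#'   \item{`timepoints`}{subset of `c("2w", "4w")` to score.}
#'   \item{`simulation`}{arguments for [simulation_config()]; entries of
#'     `planted_mirnas` are given as plain lists. Mutually exclusive with
#'     `inputs`.}
#'   \item{`inputs`}{paths `expression`, `samples`, `targets`, `ppi`,
#'     `gene_de` (named list or vector of paths), `gene_sets` (GMT).}
#'   \item{`de`}{`alpha`, `min_abs_log2fc`, `var_equal`, `fc_method` for
#'     [test_differential()].}
#'   \item{`targets`}{`combine`, `gene_alpha`, `direction_cohort` (cohort
#'     whose contrast orients the opposite-direction rule; default
#'     `"aged"`).}
#'   \item{`scoring`}{`universe_alpha` and `universe_min_abs_log2fc`
#'     (membership rule for the scored universe: DE at `p < universe_alpha`
#'     with `|log2fc|` strictly above the floor, in either cohort),
#'     `top_k`, `top_min_abs_log2fc`, `signed` for [select_top()].}
#'   \item{`enrichment`}{`alpha` for [enrich()].}
#' }
#'
#' @param config named list or path to a YAML file.
#' @param out_dir output directory; all stage files, `manifest.json` and
#'   `log.jsonl` are written there.
#' @param seed optional override of `config$seed`.
#' @return Invisibly, a list of class `rcifh_run` with the manifest, output
#'   paths, and in-memory stage results (`de`, `filtered`, `prn`, `rcifh`,
#'   `top`, `top_targets`, `enrichment`, keyed by timepoint).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config))
    stop_rcifh("config must be a named list or a YAML file path",
               class = "rcifh_config_error")
  if (!is.null(seed)) config$seed <- seed
  config$seed <- config$seed %||% 1L
  timepoints <- config$timepoints %||% c("2w", "4w")
  bad <- setdiff(timepoints, c("2w", "4w"))
  if (length(bad))
    stop_rcifh("invalid configuration field `timepoints`: %s",
               paste(bad, collapse = ", "), class = "rcifh_config_error")
  if (!is.null(config$simulation) && !is.null(config$inputs))
    stop_rcifh("config blocks `simulation` and `inputs` are mutually exclusive",
               class = "rcifh_config_error")
  de_cfg <- config$de %||% list()
  tg_cfg <- config$targets %||% list()
  sc_cfg <- config$scoring %||% list()
  en_cfg <- config$enrichment %||% list()
  direction_cohort <- match.arg(tg_cfg$direction_cohort %||% "aged", COHORTS)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.jsonl")
  unlink(log_path)
  stages <- list()
  log_stage <- function(name, files, counts = list()) {
    entry <- list(stage = name,
                  outputs = as.list(basename(unname(files))),
                  counts = counts)
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
        sep = "", file = log_path, append = TRUE)
    stages[[name]] <<- list(
      outputs = lapply(unname(files), function(f)
        list(path = basename(f), md5 = unname(tools::md5sum(f)))),
      counts = counts)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_rcifh("pipeline stage `%s` failed: %s", name, conditionMessage(e),
                 class = "rcifh_stage_error")
    })
  }

  ## stage 1: obtain inputs -------------------------------------------------
  if (!is.null(config$inputs)) {
    paths <- run_stage("load_inputs", {
      inp <- config$inputs
      gd <- inp$gene_de
      if (is.null(names(gd)))
        names(gd) <- sprintf("lineage%d", seq_along(gd))
      c(expression = inp$expression, samples = inp$samples,
        targets = inp$targets, ppi = inp$ppi,
        stats::setNames(unlist(gd), paste0("gene_de_", names(gd))),
        gene_sets = inp$gene_sets)
    })
    log_stage("load_inputs", character(0),
              list(n_input_files = length(paths)))
  } else {
    paths <- run_stage("simulate", {
      sim_cfg <- config$simulation %||% list()
      sim_cfg$seed <- config$seed
      if (!is.null(sim_cfg$planted_mirnas))
        sim_cfg$planted_mirnas <- lapply(sim_cfg$planted_mirnas, function(pe)
          if (inherits(pe, "planted_effect")) pe else do.call(planted_effect, pe))
      sim <- simulate_study(do.call(simulation_config, sim_cfg))
      write_simulation(sim, out_dir)
    })
    log_stage("simulate",
              paths[setdiff(names(paths), "ground_truth")],
              list(n_mirnas = length(readLines(paths[["expression"]])) - 1L))
  }

  se <- read_expression(paths[["expression"]], paths[["samples"]])
  gene_de_paths <- paths[grep("^gene_de_", names(paths))]
  gene_alpha <- tg_cfg$gene_alpha %||% 0.05
  gene_de <- lapply(gene_de_paths, read_gene_de_table, alpha = gene_alpha)
  names(gene_de) <- sub("^gene_de_", "", names(gene_de_paths))
  interactions <- read_target_table(paths[["targets"]])
  ppi_edges <- read_ppi_edges(paths[["ppi"]])

  ## stage 2: differential expression ---------------------------------------
  de <- list(); de_files <- character(); de_counts <- list()
  run_stage("diffexpr", {
    for (tp in timepoints) for (cohort in COHORTS) {
      tab <- test_differential(
        se, cohort, tp,
        alpha = de_cfg$alpha %||% 0.05,
        min_abs_log2fc = de_cfg$min_abs_log2fc %||% 1,
        var_equal = de_cfg$var_equal %||% TRUE,
        fc_method = de_cfg$fc_method %||% "linear")
      key <- paste0(cohort, "_", tp)
      de[[key]] <- tab
      f <- file.path(out_dir, sprintf("de_%s.tsv", key))
      write_tsv(tab, f)
      de_files[key] <- f
      de_counts[[paste0("n_significant_", key)]] <- sum(tab$significant)
    }
  })
  log_stage("diffexpr", de_files, de_counts)

  ## stage 3: target filtering ----------------------------------------------
  graph <- build_ppi_graph(ppi_edges)
  filtered <- list(); prn <- list()
  tg_files <- character(); tg_counts <- list()
  run_stage("targets", {
    for (tp in timepoints) {
      mirna_de <- de[[paste0(direction_cohort, "_", tp)]]
      ft <- filter_target_interactions(
        interactions, mirna_de, gene_de,
        combine = tg_cfg$combine %||% "union")
      filtered[[tp]] <- ft
      f <- file.path(out_dir, sprintf("filtered_targets_%s.tsv", tp))
      write_tsv(ft[, c("mirna_id", "gene_id", "validated", "n_methods",
                       "kept_evidence", "kept_direction", "kept", "reasons")],
                f)
      tg_files[tp] <- f
      tg_counts[[paste0("n_kept_", tp)]] <- sum(ft$kept)
    }
  })
  log_stage("targets", tg_files, tg_counts)

  ## stage 4: network power -------------------------------------------------
  prn_files <- character(); prn_counts <- list()
  run_stage("prn", {
    for (tp in timepoints) {
      universe <- scored_universe(
        de, tp,
        alpha = sc_cfg$universe_alpha %||% 0.05,
        min_abs_log2fc = sc_cfg$universe_min_abs_log2fc %||% 0)
      lists <- interactions_for_mirna_set(universe, filtered[[tp]])
      prn[[tp]] <- compute_prn(lists, graph)
      f <- file.path(out_dir, sprintf("prn_%s.tsv", tp))
      write_tsv(prn[[tp]], f)
      prn_files[tp] <- f
      prn_counts[[paste0("n_scored_", tp)]] <- nrow(prn[[tp]])
    }
  })
  log_stage("prn", prn_files, prn_counts)

  ## stage 5: contribution scores -------------------------------------------
  rcifh <- list(); top <- list(); top_targets <- list()
  sc_files <- character(); sc_counts <- list()
  run_stage("rcifh", {
    for (tp in timepoints) {
      rec <- compute_rcifh(se, prn[[tp]], tp)
      rcifh[[tp]] <- rec
      f <- file.path(out_dir, sprintf("rcifh_%s.tsv", tp))
      write_tsv(rec, f)
      sc_files[tp] <- f
      sel <- select_top(rec,
                        k = sc_cfg$top_k %||% 100,
                        min_abs_log2fc = sc_cfg$top_min_abs_log2fc %||% 0,
                        signed = sc_cfg$signed %||% FALSE)
      top[[tp]] <- sel
      lists <- interactions_for_mirna_set(sel$mirna_id, filtered[[tp]])
      tt <- gather_top_targets(sel, lists)
      top_targets[[tp]] <- tt
      f2 <- file.path(out_dir, sprintf("top_targets_%s.tsv", tp))
      write_tsv(tt, f2)
      sc_files[paste0(tp, "_targets")] <- f2
      sc_counts[[paste0("n_top_", tp)]] <- nrow(sel)
      sc_counts[[paste0("n_top_targets_", tp)]] <- nrow(tt)
    }
  })
  log_stage("rcifh", sc_files, sc_counts)

  ## stage 6: enrichment ----------------------------------------------------
  enr <- list(); en_files <- character(); en_counts <- list()
  run_stage("enrichment", {
    gene_sets <- if (!is.null(paths["gene_sets"]) &&
                     !is.na(paths["gene_sets"]))
      read_gmt(paths[["gene_sets"]]) else list()
    universe <- unique(unlist(lapply(gene_de, `[[`, "gene_id")))
    for (tp in timepoints) {
      query <- top_targets[[tp]]$gene_id
      res <- if (length(gene_sets) && length(query))
        suppressMessages(enrich(query, gene_sets, universe,
                                alpha = en_cfg$alpha %||% 0.05))
      else
        enrich_empty()
      enr[[tp]] <- res
      f <- file.path(out_dir, sprintf("enrichment_%s.tsv", tp))
      write_tsv(res, f)
      en_files[tp] <- f
      en_counts[[paste0("n_significant_sets_", tp)]] <- sum(res$significant)
    }
  })
  log_stage("enrichment", en_files, en_counts)

  ## manifest ----------------------------------------------------------------
  manifest <- list(
    tool = "rcifh",
    version = as.character(packageVersion("rcifh")),
    seed = config$seed,
    timepoints = timepoints,
    config = config[setdiff(names(config), "seed")],
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(structure(list(manifest = manifest, paths = paths,
                           out_dir = out_dir, de = de, filtered = filtered,
                           prn = prn, rcifh = rcifh, top = top,
                           top_targets = top_targets, enrichment = enr),
                      class = "rcifh_run"))
}

# miRNAs DE in either cohort at a timepoint: p below alpha and |log2fc|
# strictly above the floor (the scored universe)
scored_universe <- function(de, timepoint, alpha = 0.05, min_abs_log2fc = 0) {
  hits <- lapply(COHORTS, function(cohort) {
    tab <- de[[paste0(cohort, "_", timepoint)]]
    tab$feature_id[tab$p_value < alpha & abs(tab$log2fc) > min_abs_log2fc]
  })
  sort(unique(unlist(hits)))
}

enrich_empty <- function() {
  data.frame(set = character(), k = integer(), K = integer(), n = integer(),
             N = integer(), p_value = numeric(), q_value = numeric(),
             significant = logical(), stringsAsFactors = FALSE)
}
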