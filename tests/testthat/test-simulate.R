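test_that("invalid configuration fields are rejected by name", {
  expect_error(simulation_config(n_mirnas = 0), "n_mirnas",
               class = "rcifh_config_error")
  expect_error(simulation_config(replicates_per_group = 1),
               "replicates_per_group", class = "rcifh_config_error")
  expect_error(simulation_config(replicate_sd = 0), "replicate_sd",
               class = "rcifh_config_error")
  expect_error(simulation_config(frac_validated_evidence = 1.2),
               "frac_validated_evidence", class = "rcifh_config_error")
  expect_error(simulation_config(targets_per_mirna = c(9, 3)),
               "targets_per_mirna", class = "rcifh_config_error")
  expect_error(simulation_config(ppi_model = list(type = "smallworld")),
               "ppi_model", class = "rcifh_config_error")
  expect_error(
    simulation_config(n_mirnas = 1, planted_mirnas = list(
      planted_effect("a"), planted_effect("b"))),
    "planted_mirnas", class = "rcifh_config_error")
})

test_that("near-zero noise and no planted effects give log2FC ~ 0 everywhere", {
  cfg <- simulation_config(n_mirnas = 40, n_genes = 60,
                           replicate_sd = 1e-9, seed = 11)
  sim <- simulate_study(cfg)
  for (cohort in c("adult", "aged")) for (tp in c("2w", "4w")) {
    fc <- compute_log2fc(sim$se, cohort, tp)
    expect_lt(max(abs(fc)), 1e-6)
  }
})

test_that("planted effects are recovered exactly when noise vanishes", {
  cfg <- simulation_config(
    n_mirnas = 30, n_genes = 80, replicate_sd = 1e-12, seed = 5,
    planted_mirnas = list(
      planted_effect("miR-a", adult_log2fc_2wk = 1.5, aged_log2fc_2wk = -0.5,
                     adult_log2fc_4wk = 0.25),
      planted_effect("miR-b", aged_log2fc_2wk = 2)))
  sim <- simulate_study(cfg)
  fc_adult_2w <- compute_log2fc(sim$se, "adult", "2w")
  fc_aged_2w <- compute_log2fc(sim$se, "aged", "2w")
  fc_adult_4w <- compute_log2fc(sim$se, "adult", "4w")
  expect_equal(fc_adult_2w[["miR-a"]], 1.5, tolerance = 1e-6)
  expect_equal(fc_aged_2w[["miR-a"]], -0.5, tolerance = 1e-6)
  expect_equal(fc_adult_4w[["miR-a"]], 0.25, tolerance = 1e-6)
  expect_equal(fc_aged_2w[["miR-b"]], 2, tolerance = 1e-6)
  expect_equal(fc_adult_2w[["miR-b"]], 0, tolerance = 1e-6)
})

test_that("identical config and seed write byte-identical files", {
  cfg <- simulation_config(n_mirnas = 25, n_genes = 50, seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_study(cfg), d1)
  write_simulation(simulate_study(cfg), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
})

test_that("different seeds change the data", {
  cfg1 <- simulation_config(n_mirnas = 25, n_genes = 50, seed = 1)
  cfg2 <- simulation_config(n_mirnas = 25, n_genes = 50, seed = 2)
  s1 <- simulate_study(cfg1); s2 <- simulate_study(cfg2)
  expect_false(isTRUE(all.equal(SummarizedExperiment::assay(s1$se),
                                SummarizedExperiment::assay(s2$se))))
})

test_that("ground-truth PRN matches the ppi module on the emitted files", {
  cfg <- simulation_config(
    n_mirnas = 40, n_genes = 120, seed = 9,
    planted_mirnas = list(
      planted_effect("miR-hub", aged_log2fc_2wk = 2,
                     target_degree_bias = "high"),
      planted_effect("miR-low", aged_log2fc_2wk = 2,
                     target_degree_bias = "low")))
  sim <- simulate_study(cfg)
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d)
  graph <- build_ppi_graph(read_ppi_edges(paths[["ppi"]]))
  for (rec in sim$ground_truth$planted) {
    prn <- compute_prn(stats::setNames(list(rec$targets), rec$mirna_id), graph)
    expect_equal(prn$prn, rec$prn, label = rec$mirna_id)
  }
})

test_that("planted annotations survive the full filter cascade", {
  cfg <- simulation_config(
    n_mirnas = 50, n_genes = 150, seed = 3,
    planted_mirnas = list(
      planted_effect("miR-imp", aged_log2fc_2wk = 2,
                     target_degree_bias = "high")))
  sim <- simulate_study(cfg)
  mirna_de <- test_differential(sim$se, "aged", "2w")
  ft <- filter_target_interactions(sim$targets, mirna_de, sim$gene_de)
  planted <- sim$ground_truth$planted[[1]]
  kept <- interactions_for_mirna_set("miR-imp", ft)[["miR-imp"]]
  expect_identical(kept, planted$targets)
})

test_that("hub bias places targets on higher-degree nodes than low bias", {
  cfg <- simulation_config(
    n_mirnas = 10, n_genes = 300, seed = 21,
    planted_mirnas = list(
      planted_effect("miR-hub", aged_log2fc_2wk = 2,
                     target_degree_bias = "high"),
      planted_effect("miR-low", aged_log2fc_2wk = 2,
                     target_degree_bias = "low")))
  sim <- simulate_study(cfg)
  gt <- sim$ground_truth$planted
  hub <- gt[[which(vapply(gt, `[[`, "", "mirna_id") == "miR-hub")]]
  low <- gt[[which(vapply(gt, `[[`, "", "mirna_id") == "miR-low")]]
  expect_gt(hub$prn / length(hub$targets), low$prn / length(low$targets))
})

test_that("expected score sign reflects the cohort effect difference", {
  cfg <- simulation_config(
    n_mirnas = 5, n_genes = 60, seed = 2,
    planted_mirnas = list(
      planted_effect("miR-aged-up", aged_log2fc_2wk = 2),
      planted_effect("miR-adult-up", adult_log2fc_2wk = 2),
      planted_effect("miR-balanced", adult_log2fc_2wk = 1,
                     aged_log2fc_2wk = 1)))
  gt <- simulate_study(cfg)$ground_truth$planted
  signs <- vapply(gt, `[[`, 0, "expected_sign_2w")
  names(signs) <- vapply(gt, `[[`, "", "mirna_id")
  expect_equal(unname(signs[c("miR-aged-up", "miR-adult-up", "miR-balanced")]),
               c(-1, 1, 0))
})
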