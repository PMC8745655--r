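test_that("sim_config validates the stated world", {
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(planted_effects = data.frame(
    feature = "mir0001", group = "A2780CR1", fold = 0.5)), "fold")
  expect_error(sim_config(planted_effects = data.frame(
    feature = "mir0001", group = "NOPE", fold = 8)), "unknown")
  # effects may not target the reference group
  expect_error(sim_config(planted_effects = data.frame(
    feature = "mir0001", group = "A2780", fold = 8)), "reference")
})

test_that("zero-noise limit plants the exact log2 shift", {
  cfg <- sim_config(n_features = 10, noise_sd = 1e-12, seed = 2,
                    planted_effects = data.frame(
                      feature = "mir0003", group = "A2780CR1", fold = 8))
  sim <- simulate_expression(cfg)
  g <- groups(sim$matrix)
  diff <- mean(sim$matrix["mir0003", g == "A2780CR1"]) -
    mean(sim$matrix["mir0003", g == "A2780"])
  expect_equal(diff, 3.0, tolerance = 1e-9)
  # unplanted features sit at baseline in every group
  diff0 <- mean(sim$matrix["mir0001", g == "A2780CR2"]) -
    mean(sim$matrix["mir0001", g == "A2780"])
  expect_equal(diff0, 0, tolerance = 1e-9)
})

test_that("identical configuration gives bit-identical output", {
  cfg <- sim_config(n_features = 50, seed = 7,
                    planted_effects = plant_signature_effects(
                      5, 10, sim_config(n_features = 50)))
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$truth, b$truth)
  ra <- simulate_target_resources(a$truth, cfg)
  rb <- simulate_target_resources(b$truth, cfg)
  expect_identical(ra$db, rb$db)
  expect_identical(ra$gene_de, rb$gene_de)
})

test_that("null simulations select nothing at the panel cut-offs", {
  for (seed in 1:20) {
    sim <- simulate_expression(sim_config(n_features = 200, seed = seed,
                                          noise_sd = 0.5))
    calls <- contrasts_to_calls(run_all_contrasts(sim$matrix))
    sel <- apply_two_tier_selection(calls)
    expect_equal(sum(sel$selected), 0)
  }
})

test_that("planted signature effects are recovered with high sensitivity", {
  sens <- vapply(1:3, function(seed) {
    cfg <- sim_config(n_features = 200, seed = seed,
                      planted_effects = plant_signature_effects(
                        20, 10, sim_config(n_features = 200)))
    sim <- simulate_expression(cfg)
    calls <- contrasts_to_calls(run_all_contrasts(sim$matrix))
    sel <- apply_two_tier_selection(calls)
    evaluate_recovery(sel, NULL, sim$truth)$sensitivity
  }, numeric(1))
  expect_gte(mean(sens), 0.9)
})

test_that("target resources honor their construction contract", {
  cfg <- sim_config(n_features = 60, seed = 13,
                    planted_effects = plant_signature_effects(
                      6, 10, sim_config(n_features = 60)))
  sim <- simulate_expression(cfg)
  res <- simulate_target_resources(sim$truth, cfg, decoy_rate = 0.5)
  pe <- sim$truth$de_features
  # every planted edge is in the database under >= 1 source
  for (i in seq_len(nrow(res$truth$target_edges_true))) {
    e <- res$truth$target_edges_true[i, ]
    hit <- res$db[res$db$mirna == e$mirna & res$db$gene == e$gene, ]
    expect_equal(nrow(hit), 1)
    expect_gte(nchar(hit$sources), 1)
  }
  # a miRNA planted down has a positive target fold in its planted line
  down <- pe[pe$fold < 0, ][1, ]
  gene <- res$truth$target_edges_true$gene[
    res$truth$target_edges_true$mirna == down$feature]
  gf <- res$gene_de[res$gene_de$gene == gene &
                      res$gene_de$cell_line == down$group, ]
  expect_gt(gf$fold, 0)
  # every planted gene carries a GO label
  expect_true(all(res$truth$target_edges_true$gene %in%
                    names(res$truth$go_labels)))
  expect_error(simulate_target_resources(
    structure(list(de_features = data.frame()), class = "ground_truth"),
    cfg), "no planted")
})

test_that("decoy rate 0 gives exact pipeline closure on planted pairs", {
  cfg <- sim_config(n_features = 100, seed = 31,
                    planted_effects = plant_signature_effects(
                      10, 10, sim_config(n_features = 100)))
  sim <- simulate_expression(cfg)
  res <- simulate_target_resources(sim$truth, cfg, decoy_rate = 0)
  mir_de <- contrasts_to_calls(run_all_contrasts(sim$matrix))
  pairs <- select_inverse_pairs(mir_de, res$gene_de, res$db)
  pairs <- filter_by_go(pairs, res$go)
  rec <- evaluate_recovery(character(), pairs, res$truth)
  expect_equal(rec$pair_sensitivity, 1.0)
  expect_equal(rec$pair_fdp, 0.0)
})

test_that("evaluate_recovery arithmetic", {
  truth <- structure(list(
    de_features = data.frame(feature = sprintf("m%02d", 1:20),
                             group = "A2780CR1", fold = 10),
    target_edges_true = data.frame(mirna = "m01", gene = "G1"),
    go_labels = list(G1 = "stem cell")), class = "ground_truth")
  # perfect recovery
  r <- evaluate_recovery(sprintf("m%02d", 1:20), NULL, truth)
  expect_equal(r$sensitivity, 1.0)
  expect_equal(r$fdp, 0.0)
  # empty selection
  r <- evaluate_recovery(character(), NULL, truth)
  expect_equal(r$sensitivity, 0.0)
  expect_equal(r$fdp, 0.0)
  # 18 recovered + 2 spurious out of 20
  r <- evaluate_recovery(c(sprintf("m%02d", 1:18), "x1", "x2"), NULL, truth)
  expect_equal(r$sensitivity, 0.9)
  expect_equal(r$fdp, 0.1)
})
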