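toy_pairs <- function() {
  data.frame(mirna = c("miR-1", "miR-2"), gene = c("TIMP3", "ABCB1"),
             cell_line = "A2780CR1",
             mir_fold = c(-29.12, 8), mir_p_adj = c(3.6e-9, 1e-4),
             gene_fold = c(8, -6.5), gene_p_adj = c(1e-4, 1e-3),
             sources = c("TargetScan,miRwalk", "DIANA"),
             validated = c(TRUE, FALSE))
}

test_that("aggregate_targets has union semantics with provenance", {
  db <- aggregate_targets(list(
    TargetScan = data.frame(mirna = "miR-1", gene = "TIMP3"),
    miRwalk = data.frame(mirna = "miR-1", gene = "TIMP3")))
  expect_equal(nrow(db), 1)
  expect_equal(db$sources, "TargetScan,miRwalk")
  expect_true(db$validated)

  disjoint <- aggregate_targets(list(
    DIANA = data.frame(mirna = "miR-1", gene = "G1"),
    PicTar = data.frame(mirna = "miR-2", gene = "G2")))
  expect_equal(nrow(disjoint), 2)
  expect_false(any(disjoint$validated))

  expect_error(aggregate_targets(list(Bogus = data.frame(
    mirna = "m", gene = "g"))), "unrecognized")
  expect_message(aggregate_targets(list(DIANA = data.frame(
    mirna = c("m", NA), gene = c("g", "h")))), "malformed")
})

test_that("aggregate_targets equals a brute-force set union", {
  set.seed(8)
  tabs <- lapply(1:3, function(i)
    unique(data.frame(mirna = sample(sprintf("miR-%d", 1:5), 8, TRUE),
                      gene = sample(LETTERS[1:6], 8, TRUE))))
  names(tabs) <- c("DIANA", "TargetScan", "miRTAR")
  db <- aggregate_targets(tabs)
  # oracle: plain union of keys; provenance from membership checks
  keys <- unique(do.call(rbind, tabs))
  keys <- keys[order(keys$mirna, keys$gene), ]
  expect_equal(db[c("mirna", "gene")], keys, ignore_attr = TRUE)
  for (i in seq_len(nrow(db))) {
    in_src <- names(tabs)[vapply(tabs, function(t)
      any(t$mirna == db$mirna[i] & t$gene == db$gene[i]), logical(1))]
    expect_equal(db$sources[i], paste(sort(in_src), collapse = ","))
    expect_equal(db$validated[i], "miRTAR" %in% in_src)
  }
})

test_that("select_inverse_pairs applies sign, cut-off and significance rules", {
  db <- aggregate_targets(list(TargetScan = data.frame(
    mirna = c("miR-a", "miR-b", "miR-c"), gene = c("G1", "G2", "G3"))))
  mir_de <- data.frame(mirna = c("miR-a", "miR-b", "miR-c"),
                       cell_line = "L1",
                       fold = c(-29.12, 6, 6), p_adj = c(3.6e-9, 0.001, 0.001))
  gene_de <- data.frame(gene = c("G1", "G2", "G3"), cell_line = "L1",
                        fold = c(8, 7, -4.9), p_adj = c(1e-4, 0.001, 0.001))
  pairs <- select_inverse_pairs(mir_de, gene_de, db)
  # inverse significant pair retained; same-sign and sub-threshold dropped
  expect_equal(pairs$mirna, "miR-a")
  expect_equal(pairs$gene_fold, 8)
  expect_true(all(sign(pairs$mir_fold) * sign(pairs$gene_fold) == -1))

  # a passing miRNA with no edge is reported, not an error
  mir_extra <- rbind(mir_de,
                     data.frame(mirna = "miR-z", cell_line = "L1",
                                fold = 20, p_adj = 1e-5))
  expect_message(select_inverse_pairs(mir_extra, gene_de, db), "no edge")
})

test_that("select_inverse_pairs equals the brute-force edge scan", {
  cfg <- sim_config(n_features = 40, seed = 21,
                    planted_effects = plant_signature_effects(
                      8, 10, sim_config(n_features = 40)))
  sim <- simulate_expression(cfg)
  res <- simulate_target_resources(sim$truth, cfg, decoy_rate = 0.5)
  mir_de <- contrasts_to_calls(run_all_contrasts(sim$matrix))
  thr <- thresholds()
  got <- select_inverse_pairs(mir_de, res$gene_de, res$db, thr)
  want <- inverse_pairs_oracle(mir_de, res$gene_de, res$db, thr)
  expect_equal(pair_key(got), pair_key(want))
})

test_that("filter_by_go keeps keyword-annotated genes only", {
  pairs <- toy_pairs()
  ann <- data.frame(gene = c("TIMP3", "TIMP3", "ABCB1"),
                    term = c("Extracellular Matrix", "nucleus", "nucleus"))
  out <- filter_by_go(pairs, ann)
  expect_equal(out$gene, "TIMP3")
  expect_equal(out$matched_go_terms, "extracellular matrix")

  # unannotated genes are counted and dropped
  expect_message(
    out2 <- filter_by_go(pairs, ann[ann$gene == "TIMP3", ]), "no GO")
  expect_equal(out2$gene, "TIMP3")

  # superset keywords keep everything annotated with any pair term;
  # disjoint keywords drop everything
  ann_all <- data.frame(gene = c("TIMP3", "ABCB1"),
                        term = c("stem cell", "response to drug"))
  expect_equal(nrow(filter_by_go(pairs, ann_all)), 2)
  expect_equal(nrow(filter_by_go(pairs, ann_all, keywords = "ribosome")), 0)
  expect_error(filter_by_go(pairs, ann_all, keywords = character()),
               "non-empty")
})

test_that("filter_by_go equals a brute-force keyword scan", {
  set.seed(5)
  pairs <- do.call(rbind, replicate(5, toy_pairs(), simplify = FALSE))
  pairs$gene <- sample(c("G1", "G2", "G3", "G4"), nrow(pairs), TRUE)
  ann <- data.frame(gene = c("G1", "G2", "G3", "G4"),
                    term = c("stem cell", "nucleus", "extracellular space",
                             "cytoplasm"))
  kw <- default_go_keywords()
  out <- filter_by_go(pairs, ann, kw)
  keep <- vapply(pairs$gene, function(g) {
    any(tolower(ann$term[ann$gene == g]) %in% tolower(kw))
  }, logical(1))
  expect_equal(nrow(out), sum(keep))
  expect_equal(sort(unique(out$gene)),
               sort(unique(pairs$gene[keep])))
})

test_that("network export: SIF, TSV round trip, GraphML parse-back", {
  pairs <- toy_pairs()
  pairs$matched_go_terms <- c("extracellular matrix", "response to drug")

  sif <- tempfile(fileext = ".sif")
  export_network(pairs, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, 2)
  expect_true(all(grepl(" targets ", lines)))

  tsv <- tempfile(fileext = ".tsv")
  export_network(pairs, tsv, "tsv")
  back <- read_pairs(tsv)
  expect_equal(back, pairs, ignore_attr = TRUE)
  # empty list allowed for tsv only
  empty <- pairs[0, ]
  expect_silent(export_network(empty, tsv, "tsv"))
  expect_error(export_network(empty, sif, "sif"), "empty")

  gml <- tempfile(fileext = ".graphml")
  export_network(pairs, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  n_expected <- length(unique(pairs$mirna)) + length(unique(pairs$gene))
  expect_equal(igraph::vcount(g), n_expected)
  expect_equal(igraph::ecount(g), nrow(pairs))
  expect_setequal(unique(igraph::V(g)$type), c("miRNA", "gene"))
})
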