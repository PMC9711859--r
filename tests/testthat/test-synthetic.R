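test_that("generate_network respects structural contracts", {
  net <- generate_network(10, 100, mean_out_degree = 3,
                          negative_edge_fraction = 0.3, seed = 42)
  tfs <- net$nodes$gene[net$nodes$is_tf]
  expect_true(all(net$edges$source %in% tfs))
  expect_false(any(net$edges$source == net$edges$target))
  expect_false(anyDuplicated(paste(net$edges$source, net$edges$target)) > 0)
  expect_true(all(net$edges$sign %in% c(-1L, 1L)))
})

test_that("generate_network without targets only wires TF->TF", {
  net <- generate_network(2, 0, mean_out_degree = 1,
                          negative_edge_fraction = 0, seed = 1)
  expect_setequal(net$nodes$gene, c("TF01", "TF02"))
  expect_true(all(net$edges$target %in% c("TF01", "TF02")))
})

test_that("zero negative fraction gives all-activating edges", {
  net <- generate_network(5, 50, mean_out_degree = 3,
                          negative_edge_fraction = 0, seed = 7)
  expect_true(all(net$edges$sign == 1L))
})

test_that("negative-edge fraction stays within exact binomial 99% bounds", {
  net <- generate_network(10, 100, mean_out_degree = 3,
                          negative_edge_fraction = 0.3, seed = 42)
  n <- nrow(net$edges)
  k <- sum(net$edges$sign == -1L)
  expect_gte(k, qbinom(0.005, n, 0.3))
  expect_lte(k, qbinom(0.995, n, 0.3))
})

test_that("invalid generator parameters are rejected", {
  expect_error(generate_network(1, 10), class = "aegrn_invalid_parameter")
  expect_error(generate_network(5, -1), class = "aegrn_invalid_parameter")
  expect_error(generate_network(5, 10, negative_edge_fraction = 1.2),
               class = "aegrn_invalid_parameter")
})

test_that("identical seeds give byte-identical serialized outputs", {
  a <- simulate_study(n_tfs = 6, n_targets = 30, seed = 5)
  b <- simulate_study(n_tfs = 6, n_targets = 30, seed = 5)
  expect_identical(serialize(a$network, NULL), serialize(b$network, NULL))
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$promoters, b$promoters)
  c_ <- simulate_study(n_tfs = 6, n_targets = 30, seed = 6)
  expect_false(identical(a$expr$values, c_$expr$values))
})

test_that("signed influence propagates one hop per timepoint", {
  net <- toy_network("A +B", "B +C", "B -D", tfs = c("A", "B"))
  truth <- structure(list(noise_sd = 0, timepoints = c(2, 4, 10), seed = 1,
                          conditions = NULL), class = "SyntheticTruth")
  conds <- list(
    ctrl = list(genotype = "WT", treatment = "EtOH",
                masters_on = character(), silenced_edges = character()),
    trt = list(genotype = "WT", treatment = "ATRA",
               masters_on = "A", silenced_edges = character()))
  expr <- simulate_temporal_expression(net, truth, conds,
                                       timepoints = c(2, 4, 10),
                                       effect_log2 = 4, seed = 1)
  de <- de_status_table(expr, "WT:EtOH", threshold_log2 = 2)
  st <- node_states(de, "WT:ATRA", c(2, 4, 10))
  expect_equal(unname(st$status["A", ]), c("UP", "UP", "UP"))
  expect_equal(unname(st$status["B", ]), c("NEUTRAL", "UP", "UP"))
  expect_equal(unname(st$status["C", ]), c("NEUTRAL", "NEUTRAL", "UP"))
  expect_equal(unname(st$status["D", ]), c("NEUTRAL", "NEUTRAL", "DOWN"))
})

test_that("conditions referencing unknown identifiers are rejected", {
  net <- toy_network("A +B", tfs = "A")
  truth <- structure(list(noise_sd = 0, timepoints = c(2, 4), seed = 1),
                     class = "SyntheticTruth")
  ctrl <- list(genotype = "WT", treatment = "EtOH",
               masters_on = character(), silenced_edges = character())
  bad_m <- list(ctrl = ctrl, x = list(genotype = "WT", treatment = "T",
                                      masters_on = "NOPE",
                                      silenced_edges = character()))
  expect_error(simulate_temporal_expression(net, truth, bad_m,
                                            timepoints = c(2, 4)),
               class = "aegrn_unknown_identifier")
  bad_e <- list(ctrl = ctrl, x = list(genotype = "WT", treatment = "T",
                                      masters_on = "A",
                                      silenced_edges = "Z->Q"))
  expect_error(simulate_temporal_expression(net, truth, bad_e,
                                            timepoints = c(2, 4)),
               class = "aegrn_unknown_identifier")
})

test_that("noisy DE calling recalls nearly all planted responsive genes", {
  # noise_sd 0.2 vs margin (effect 4, threshold 2): over seeds, recall
  # should be essentially complete (Gaussian tail at >2 sd of the
  # replicate-averaged noise).
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    st <- simulate_study(n_tfs = 10, n_targets = 60, conditions = "gold",
                         markers = FALSE, promoters = FALSE, seed = s)
    de <- de_status_table(st$expr, "WT:EtOH", threshold_log2 = 2)
    gold_states <- node_states(de, "WT:ATRA", st$truth$timepoints)
    truth_status <- st$truth$truth_states$gold$status
    responsive <- rownames(truth_status)[
      apply(truth_status != "NEUTRAL", 1, any)]
    called <- rownames(gold_states$status)[
      apply(gold_states$status != "NEUTRAL", 1, any)]
    hits <- hits + length(intersect(responsive, called))
    total <- total + length(responsive)
  }
  expect_gte(hits / total, 0.99)
})

test_that("marker catalog coverage is honored exactly under a fixed seed", {
  st <- simulate_study(n_tfs = 10, n_targets = 100, seed = 3,
                       marker_coverage = 0.5, promoters = FALSE)
  all_neutral <- paste(rep("NEUTRAL", 3), collapse = "/")
  prog <- names(st$truth$path_membership)[
    st$truth$path_membership != all_neutral]
  labeled <- unique(unlist(st$catalog$class_sets))
  expect_equal(sum(toupper(prog) %in% labeled), round(0.5 * length(prog)))
  # full coverage labels every program gene; zero coverage labels none
  full <- generate_marker_catalog(st$network, st$truth, coverage = 1)
  expect_true(all(toupper(prog) %in% unique(unlist(full$class_sets))))
  none <- generate_marker_catalog(st$network, st$truth, coverage = 0)
  expect_length(intersect(toupper(prog), unique(unlist(none$class_sets))), 0)
  expect_error(generate_marker_catalog(st$network, st$truth, coverage = 2),
               class = "aegrn_invalid_parameter")
})

test_that("subtype labels are confined to neuron-class genes", {
  st <- simulate_study(n_tfs = 10, n_targets = 100, seed = 4,
                       promoters = FALSE)
  ann <- annotate_genes(st$network$nodes$gene, st$catalog)
  expect_true(all(ann$subtype[ann$class != "neuron"] == "UNASSIGNED"))
})

test_that("noise-free promoter table encodes the planted signature", {
  st <- simulate_study(n_tfs = 10, n_targets = 60, seed = 2,
                       promoter_noise_sd = 0, signal_log2 = 2)
  prom <- st$promoters
  sil <- prom$gene %in% st$truth$silenced_genes
  expect_true(all(prom$h3k27me3[sil] == 2))
  expect_true(all(prom$h3k27me3[!sil] == 0))
  expect_true(all(prom$h3k4me3 %in% c(0, 2)))
  expect_true(all(prom$h3k4me3 == prom$faire))
  expect_true(all(prom$h3k4me3 == prom$rnapii))
  # active and silenced signatures never overlap
  expect_true(all(prom$h3k4me3[sil] == 0))
})

test_that("planted masters are upstream of most of the responsive program", {
  st <- simulate_study(seed = 9, markers = FALSE, promoters = FALSE,
                       conditions = "gold")
  g <- as_igraph(st$network)
  truth_status <- st$truth$truth_states$gold$status
  responsive <- rownames(truth_status)[
    apply(truth_status != "NEUTRAL", 1, any)]
  for (m in st$truth$planted_masters) {
    reach <- names(igraph::subcomponent(g, m, mode = "out"))
    expect_gte(length(intersect(reach, responsive)) / length(responsive),
               0.5)
  }
})
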