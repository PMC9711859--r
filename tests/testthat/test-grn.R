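test_that("master GRN keeps only edges fully inside the responsive set", {
  net <- toy_network("A +B", "A -C", "B +C", "B +D", "C +E",
                     tfs = c("A", "B", "C"))
  all_g <- net$nodes$gene
  expect_equal(nrow(build_master_grn(net, all_g)$edges), 5)
  expect_equal(nrow(build_master_grn(net, character())$edges), 0)
  sub <- build_master_grn(net, c("A", "B", "C"))
  expect_setequal(sub$edges$edge_id, c("A->B", "A->C", "B->C"))
  # isolated nodes are dropped
  expect_false("D" %in% sub$nodes$gene)
})

test_that("network constructor rejects malformed inputs", {
  expect_error(regulatory_network(
    data.frame(source = "A", target = "A", sign = 1)),
    class = "aegrn_invalid_parameter")
  expect_error(regulatory_network(
    data.frame(source = c("A", "A"), target = c("B", "B"),
               sign = c(1, -1))),
    class = "aegrn_invalid_parameter")
  expect_error(regulatory_network(
    data.frame(source = "A", target = "B", sign = 2)),
    class = "aegrn_invalid_parameter")
  expect_error(regulatory_network(
    data.frame(source = "B", target = "C", sign = 1), tfs = "A"),
    class = "aegrn_invalid_parameter")
})

test_that("target-rule stratification partitions edges; either-rule dominates it", {
  net <- toy_network("A +B", "A +C", "B +C", "B -D", "C +D", "C +A",
                     tfs = c("A", "B", "C"))
  ann <- data.frame(gene = c("A", "B", "C", "D"),
                    class = c("neuron", "neuron", "astrocyte",
                              "UNASSIGNED"),
                    subtype = "UNASSIGNED")
  st_a <- stratify_network(net, ann, rule = "target")
  expect_equal(sum(st_a$edge_counts), nrow(net$edges))
  expect_equal(unname(st_a$edge_counts["neuron"]), 2L)   # targets B, A
  expect_equal(unname(st_a$edge_counts["astrocyte"]), 2L)
  st_b <- stratify_network(net, ann, rule = "either")
  expect_true(all(st_b$edge_counts >= st_a$edge_counts))
  expect_error(stratify_network(net, ann[-1, ]),
               class = "aegrn_annotation_gap")
})

test_that("single-class networks concentrate all edges in that class", {
  net <- toy_network("A +B", "B +C", tfs = c("A", "B"))
  ann <- data.frame(gene = c("A", "B", "C"), class = "neuron",
                    subtype = "UNASSIGNED")
  st <- stratify_network(net, ann)
  expect_equal(unname(st$edge_counts["neuron"]), 2L)
})

test_that("active-edge rule matches the exhaustive hand enumeration", {
  got <- is_active_edge(ACTIVE_EDGE_TRUTH$source, ACTIVE_EDGE_TRUTH$target,
                        ACTIVE_EDGE_TRUTH$sign)
  expect_equal(got, ACTIVE_EDGE_TRUTH$active)
  # up-only mode drops the repressed-side coherences
  up_only <- is_active_edge(ACTIVE_EDGE_TRUTH$source,
                            ACTIVE_EDGE_TRUTH$target,
                            ACTIVE_EDGE_TRUTH$sign, up_only = TRUE)
  expect_equal(up_only, ACTIVE_EDGE_TRUTH$active &
                 ACTIVE_EDGE_TRUTH$source == "UP")
})

test_that("active-edge evaluation reproduces the worked 3-edge example", {
  net <- toy_network("A +B", "A -C", "B +C", tfs = c("A", "B"))
  mat <- status_matrix(c("A", "B", "C"), c(2, 4, 10))
  mat["A", ] <- "UP"; mat["B", ] <- "UP"; mat["C", ] <- "DOWN"
  aes <- evaluate_active_edges(net, toy_states(mat), 10)
  expect_setequal(aes$edge_ids, c("A->B", "A->C"))
  expect_equal(active_edge_fraction(aes, net), 2 / 3)
})

test_that("all-NEUTRAL states give no active edges; uniform UP gives all", {
  net <- toy_network("A +B", "B +C", tfs = c("A", "B"))
  flat <- status_matrix(c("A", "B", "C"), c(2, 4))
  expect_length(evaluate_active_edges(net, toy_states(flat), 4)$edge_ids, 0)
  up <- status_matrix(c("A", "B", "C"), c(2, 4), default = "UP")
  aes <- evaluate_active_edges(net, toy_states(up), 4)
  expect_equal(active_edge_fraction(aes, net), 1)
})

test_that("cumulative mode unions the per-timepoint active sets", {
  net <- toy_network("A +B", "B +C", tfs = c("A", "B"))
  mat <- status_matrix(c("A", "B", "C"), c(2, 4))
  mat["A", "2"] <- "UP"; mat["B", ] <- "UP"; mat["C", "4"] <- "UP"
  at2 <- evaluate_active_edges(net, toy_states(mat), 2)$edge_ids
  at4 <- evaluate_active_edges(net, toy_states(mat), 4)$edge_ids
  any_tp <- evaluate_active_edges(net, toy_states(mat), "any")$edge_ids
  expect_setequal(any_tp, union(at2, at4))
})

test_that("group fractions use the group's own edge denominator", {
  net <- toy_network("A +B", "A +C", "B +D", "C +D", tfs = c("A", "B", "C"))
  ann <- data.frame(gene = c("A", "B", "C", "D"),
                    class = c("neuron", "neuron", "neuron", "astrocyte"),
                    subtype = "UNASSIGNED")
  mat <- status_matrix(c("A", "B", "C", "D"), c(2, 4))
  mat["A", ] <- "UP"; mat["B", ] <- "UP"
  aes <- evaluate_active_edges(net, toy_states(mat), 4)
  # neuron-target edges: A->B, A->C; active among them: A->B
  expect_equal(active_edge_fraction(aes, net, "neuron", ann), 0.5)
  expect_equal(active_edge_fraction(aes, net, "astrocyte", ann), 0)
  expect_warning(
    f <- active_edge_fraction(aes, net, "OPC",
                              rbind(ann, data.frame(gene = "Z",
                                                    class = "OPC",
                                                    subtype = "UNASSIGNED"))),
    "no edges")
  expect_true(is.na(f))
})

test_that("missing node states are reported", {
  net <- toy_network("A +B", tfs = "A")
  mat <- status_matrix("A", c(2, 4))
  expect_error(evaluate_active_edges(net, toy_states(mat), 2),
               class = "aegrn_incomplete_series")
})

test_that("rescue condition exceeds blocked on the planted inhibited subnetwork", {
  st <- simulate_study(conditions = c("blocked", "rescue"),
                       markers = FALSE, promoters = FALSE, seed = 17)
  tr <- st$truth
  de <- de_status_table(st$expr, "WT:EtOH", threshold_log2 = 2)
  inh_net <- subset_network(
    tr$network,
    unique(unlist(tr$network$edges[
      tr$network$edges$edge_id %in% tr$inhibited_edge_set,
      c("source", "target")])))
  frac <- function(cond) {
    aes <- evaluate_active_edges(
      inh_net, node_states(de, cond, tr$timepoints), 10)
    active_edge_fraction(aes, inh_net)
  }
  expect_gt(frac("RaraKO:BMS641+BMS961"), frac("WT:BMS641+BMS961"))
})
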