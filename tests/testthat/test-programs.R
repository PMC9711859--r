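aes_of <- function(ids, condition = "c", timepoint = 10) {
  structure(list(condition = condition, timepoint = timepoint,
                 edge_ids = ids), class = "ActiveEdgeSet")
}

test_that("intersection of active-edge sets", {
  expect_setequal(intersect_active_sets(list(aes_of(c("a", "b", "c")),
                                             aes_of(c("b", "c", "d")),
                                             aes_of("c"))), "c")
  expect_setequal(intersect_active_sets(list(aes_of(c("x", "y")))),
                  c("x", "y"))
  expect_length(intersect_active_sets(list(aes_of(c("a", "b")),
                                           aes_of(character()))), 0)
  expect_error(intersect_active_sets(list()),
               class = "aegrn_invalid_parameter")
})

test_that("program set algebra splits alpha-specific edges three ways", {
  part <- derive_programs(list(aes_of(c("e1", "e2", "e3"))),
                          aes_of("e1"), aes_of(c("e1", "e2")))
  expect_setequal(part$common, "e1")
  expect_setequal(part$inhibited, "e2")
  expect_setequal(part$residual, "e3")
  # identical blocked and rescue means nothing is inhibited
  all3 <- aes_of(c("e1", "e2", "e3"))
  part2 <- derive_programs(list(all3), all3, all3)
  expect_length(part2$inhibited, 0)
  expect_length(part2$residual, 0)
})

test_that("partition identity holds on random inputs", {
  for (s in 1:20) {
    withr::with_seed(s, {
      pool <- sprintf("e%03d", 1:60)
      alpha <- lapply(1:3, function(i) aes_of(sample(pool, 45)))
      blocked <- aes_of(sample(pool, 25))
      rescue <- aes_of(sample(pool, 35))
    })
    part <- derive_programs(alpha, blocked, rescue)
    expect_length(intersect(part$common, part$inhibited), 0)
    expect_setequal(c(part$common, part$inhibited, part$residual),
                    part$alpha_specific)
    expect_equal(length(part$common) + length(part$inhibited) +
                   length(part$residual), length(part$alpha_specific))
    # order of the alpha sets never matters
    part_rev <- derive_programs(rev(alpha), blocked, rescue)
    expect_setequal(part$alpha_specific, part_rev$alpha_specific)
    expect_setequal(part$inhibited, part_rev$inhibited)
  }
})

test_that("lax variant ignores the rescue requirement", {
  part <- derive_programs(list(aes_of(c("e1", "e2", "e3"))),
                          aes_of("e1"), aes_of("e2"),
                          require_rescue = FALSE)
  expect_setequal(part$inhibited, c("e2", "e3"))
  expect_length(part$residual, 0)
})

test_that("edge ids outside the network universe are rejected", {
  net <- toy_network("A +B", tfs = "A")
  expect_error(derive_programs(list(aes_of("Z->Q")), aes_of(character()),
                               aes_of(character()), network = net),
               class = "aegrn_incompatible_universe")
})

test_that("program gene and TF sets are derived from edge endpoints", {
  net <- toy_network("A +B", "C -D", "A +D", tfs = c("A", "C"))
  part <- derive_programs(list(aes_of(c("A->B", "C->D", "A->D"))),
                          aes_of("A->B"), aes_of("C->D"))
  mem <- program_gene_tf_sets(part, net)
  expect_setequal(mem$genes$alpha_specific, c("A", "B", "C", "D"))
  expect_setequal(mem$tfs$alpha_specific, c("A", "C"))
  expect_setequal(mem$genes$common, c("A", "B"))
  expect_setequal(mem$genes$inhibited, c("C", "D"))
  ov <- mem$overlap
  row <- ov[ov$program_a == "common" & ov$program_b == "inhibited", ]
  expect_equal(row$gene_overlap, 0L)
  # disjoint edge sets sharing a node overlap in that node
  part2 <- derive_programs(list(aes_of(c("A->B", "A->D"))),
                           aes_of("A->B"), aes_of("A->D"))
  mem2 <- program_gene_tf_sets(part2, net)
  row2 <- mem2$overlap[mem2$overlap$program_a == "common" &
                         mem2$overlap$program_b == "inhibited", ]
  expect_equal(row2$gene_overlap, 1L)   # shared TF node A
})

test_that("induced subnetworks keep edges with both endpoints retained", {
  net <- toy_network("A +B", "B +C", "C -D", "A +E",
                     tfs = c("A", "B", "C"))
  full <- subset_network(net, net$nodes$gene)
  expect_equal(nrow(full$edges), 4)
  empty <- subset_network(net, character())
  expect_equal(nrow(empty$edges), 0)
  sub <- subset_network(net, c("A", "B", "C"))
  expect_setequal(sub$edges$edge_id, c("A->B", "B->C"))
  expect_warning(subset_network(net, c("A", "NOPE")), "not in network")
  expect_error(subset_network(net, "NOPE", strict = TRUE),
               class = "aegrn_unknown_gene")
  # state filter drops genes failing the predicate
  filt <- subset_network(net, c("A", "B", "C"),
                         state_filter = function(g) g != "B")
  expect_length(filt$edges$edge_id, 0)
})

test_that("planted inhibited program is recovered by the set algebra", {
  st <- simulate_study(n_tfs = 15, n_targets = 120,
                       conditions = c("alpha_wt", "alpha_bko", "alpha_gko",
                                      "blocked", "rescue"),
                       markers = FALSE, promoters = FALSE, seed = 29)
  tr <- st$truth
  de <- de_status_table(st$expr, "WT:EtOH", threshold_log2 = 2)
  lbl <- function(k) paste(tr$conditions[[k]]$genotype,
                           tr$conditions[[k]]$treatment, sep = ":")
  act <- lapply(c("alpha_wt", "alpha_bko", "alpha_gko", "blocked",
                  "rescue"), function(k)
    evaluate_active_edges(tr$network,
                          node_states(de, lbl(k), tr$timepoints), 10))
  part <- derive_programs(act[1:3], act[[4]], act[[5]], network = tr$network)
  hits <- intersect(part$inhibited, tr$inhibited_edge_set)
  expect_gte(length(hits) / length(part$inhibited), 0.9)
  expect_gte(length(hits) / length(tr$inhibited_edge_set), 0.9)
})
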