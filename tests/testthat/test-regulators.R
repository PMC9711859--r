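test_that("cascades traverse coherent chains and stop at incoherence", {
  net <- toy_network("A +B", "B +C", tfs = c("A", "B"))
  mat <- status_matrix(c("A", "B", "C"), c(2, 4, 10))
  mat["A", ] <- "UP"
  mat["B", c("4", "10")] <- "UP"
  mat["C", "10"] <- "UP"
  st <- toy_states(mat)
  expect_equal(propagate_cascade(net, st, "A"), c("B", "C"))
  expect_equal(master_regulatory_index(net, st, "A"), 1.0)
  # incoherent edge blocks traversal
  mat2 <- mat
  mat2["B", ] <- c("NEUTRAL", "DOWN", "DOWN")
  expect_length(propagate_cascade(net, toy_states(mat2), "A"), 0)
  # downstream TF only reaches its own cone
  expect_equal(propagate_cascade(net, st, "B"), "C")
})

test_that("temporal causality forbids upstream-late cascades", {
  net <- toy_network("A +B", tfs = c("A", "B"))
  mat <- status_matrix(c("A", "B"), c(2, 4))
  mat["A", "4"] <- "UP"          # A responds late
  mat["B", ] <- "UP"             # B responds early
  st <- toy_states(mat)
  expect_length(propagate_cascade(net, st, "A"), 0)
  expect_equal(propagate_cascade(net, st, "A", temporal = FALSE), "B")
})

test_that("cascade seeds must be responsive TF nodes", {
  net <- toy_network("A +B", tfs = "A")
  mat <- status_matrix(c("A", "B"), c(2, 4))
  expect_error(propagate_cascade(net, toy_states(mat), "B"),
               class = "aegrn_invalid_start")
  expect_error(propagate_cascade(net, toy_states(mat), "A"),
               class = "aegrn_invalid_start")
})

test_that("MRI equals reached over responsive-minus-one", {
  # star TF coherently regulating 7 of 10 responsive nodes
  spokes <- sprintf("N%d", 1:9)
  net <- toy_network(paste("HUB", paste0("+", spokes)),
                     tfs = "HUB")
  mat <- status_matrix(c("HUB", spokes), c(2, 4))
  mat["HUB", ] <- "UP"
  mat[spokes[1:7], "4"] <- "UP"
  mat[spokes[8:9], "4"] <- "DOWN"    # incoherent under + edges
  st <- toy_states(mat)
  expect_equal(master_regulatory_index(net, st, "HUB"), 7 / 9)
})

test_that("MRI is zero when every edge is incoherent", {
  net <- toy_network("A +B", "A +C", tfs = "A")
  mat <- status_matrix(c("A", "B", "C"), c(2, 4))
  mat["A", ] <- "UP"; mat["B", "4"] <- "DOWN"; mat["C", "4"] <- "DOWN"
  expect_equal(master_regulatory_index(net, toy_states(mat), "A"), 0)
})

test_that("cascade equals brute-force walk enumeration on seeded networks", {
  checked <- 0L
  for (s in 1:100) {
    net <- generate_network(n_tfs = 2 + s %% 4, n_targets = 3 + s %% 6,
                            mean_out_degree = 2.5,
                            negative_edge_fraction = 0.3, seed = s)
    genes <- net$nodes$gene
    mat <- random_status_matrix(genes, c(2, 4, 10), seed = 1000 + s)
    st <- toy_states(mat)
    tfs <- intersect(genes[net$nodes$is_tf],
                     names(st$first_response)[!is.na(st$first_response)])
    for (tf in tfs) {
      expect_identical(propagate_cascade(net, st, tf),
                       oracle_cascade(net, st, tf))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 100L)
})

test_that("double-edge swaps preserve degrees and sign multiset", {
  net <- generate_network(8, 40, mean_out_degree = 4,
                          negative_edge_fraction = 0.3, seed = 3)
  r0 <- randomize_network(net, n_swaps = 0, seed = 1)
  expect_identical(r0$edges, net$edges)
  rnd <- randomize_network(net, seed = 7)
  expect_false(identical(rnd$edges$target, net$edges$target))
  deg0 <- aegrn:::network_degrees(net)
  deg1 <- aegrn:::network_degrees(rnd)
  expect_identical(deg0, deg1)
  expect_identical(sort(rnd$edges$sign), sort(net$edges$sign))
  expect_false(any(rnd$edges$source == rnd$edges$target))
  expect_false(anyDuplicated(paste(rnd$edges$source, rnd$edges$target)) > 0)
  # determinism
  expect_identical(randomize_network(net, seed = 7)$edges, rnd$edges)
  tiny <- toy_network("A +B", tfs = "A")
  expect_warning(randomize_network(tiny, seed = 1), "too small")
})

test_that("empirical p-values use the add-one tie-inclusive rule", {
  expect_equal(empirical_pvalue(0.9, rep(0.1, 99)), 0.01)
  expect_equal(empirical_pvalue(0.1, rep(0.9, 9)), 1)
  expect_equal(empirical_pvalue(0.5, c(rep(0.5, 4), rep(0.1, 5))), 0.5)
  expect_error(empirical_pvalue(0.5, numeric()),
               class = "aegrn_invalid_parameter")
})

test_that("ranking orders TFs by MRI with deterministic tie-breaks", {
  net <- toy_network("A +B", "B +C", "C +D", tfs = c("A", "B", "C"))
  mat <- status_matrix(c("A", "B", "C", "D"), c(2, 4, 10))
  mat["A", ] <- "UP"; mat["B", c("4", "10")] <- "UP"
  mat["C", "10"] <- "UP"; mat["D", "10"] <- "UP"
  rk <- rank_master_regulators(net, toy_states(mat), n_null = 19, seed = 5)
  expect_equal(rk$tf[1], "A")
  expect_equal(rk$rank, 1:3)
  expect_true(all(rk$p_value >= 1 / 20 & rk$p_value <= 1))
  # cutoff 1 selects nothing without a perfect-plus MRI
  rk2 <- rank_master_regulators(net, toy_states(mat), mri_cutoff = 1,
                                n_null = 0)
  expect_false(any(rk2$selected))
})

test_that("planted masters lead the MRI ranking on synthetic studies", {
  ok <- 0L
  for (s in 1:10) {
    st <- simulate_study(conditions = "gold", markers = FALSE,
                         promoters = FALSE, seed = 300 + s)
    de <- de_status_table(st$expr, "WT:EtOH", threshold_log2 = 2)
    resp <- unique(de$gene[de$condition == "WT:ATRA" &
                             de$status != "NEUTRAL"])
    grn <- build_master_grn(st$truth$network, resp)
    rk <- rank_master_regulators(grn,
                                 node_states(de, "WT:ATRA",
                                             st$truth$timepoints),
                                 n_null = 0)
    if (all(match(st$truth$planted_masters, rk$tf) <= 5)) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})
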