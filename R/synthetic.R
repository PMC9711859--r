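#' Generate a random signed TF-to-target network with hub TFs
#'
#' Out-degrees are drawn from a heavy-tailed (log-normal rate, Poisson
#' count) distribution so that a few TFs act as hubs, mimicking the
#' topology of curated TF-target annotation collections. Edge targets are
#' sampled uniformly from all other nodes (TF-to-TF edges allowed); each
#' edge is repressive (-1) with probability `negative_edge_fraction`,
#' activating (+1) otherwise.
#'
#' @param n_tfs number of TF nodes (>= 2).
#' @param n_targets number of non-TF target genes (>= 0).
#' @param mean_out_degree mean TF out-degree.
#' @param negative_edge_fraction probability an edge is repressive.
#' @param seed integer RNG seed; identical seed gives identical output.
#' @param degree_sdlog log-scale SD of the out-degree rates (heavy-tail
#'   strength); default 1.
#' @return a `RegulatoryNetwork`.
#' @examples
#' generate_network(5, 50, mean_out_degree = 3, negative_edge_fraction = 0.2,
#'                  seed = 1)
#' @export
generate_network <- function(n_tfs, n_targets, mean_out_degree = 4,
                             negative_edge_fraction = 0.1, seed = 1L,
                             degree_sdlog = 1) {
  n_tfs <- assert_count(n_tfs, "n_tfs", min = 2L)
  n_targets <- assert_count(n_targets, "n_targets", min = 0L)
  assert_positive(mean_out_degree, "mean_out_degree")
  assert_fraction(negative_edge_fraction, "negative_edge_fraction")
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  targets <- if (n_targets > 0) sprintf("G%03d", seq_len(n_targets))
    else character()
  nodes <- c(tfs, targets)
  withr::with_seed(seed, {
    w <- stats::rlnorm(n_tfs, meanlog = 0, sdlog = degree_sdlog)
    lambda <- mean_out_degree * n_tfs * w / sum(w)
    deg <- pmin(stats::rpois(n_tfs, lambda), length(nodes) - 1L)
    edges <- do.call(rbind, lapply(seq_len(n_tfs), function(i) {
      if (deg[i] == 0L) return(NULL)
      data.frame(source = tfs[i],
                 target = sample(setdiff(nodes, tfs[i]), deg[i]),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(edges))
      edges <- data.frame(source = character(), target = character(),
                          stringsAsFactors = FALSE)
    edges$sign <- ifelse(stats::runif(nrow(edges)) < negative_edge_fraction,
                         -1L, 1L)
  })
  regulatory_network(edges, tfs = tfs, nodes = nodes)
}

# Deterministic signed propagation of master activation through the
# network: one hop per round; a node's state is decided the first round a
# determined, non-NEUTRAL parent reaches it, as the sign of the summed
# signed influence over all its already-determined parents (net zero =>
# NEUTRAL, which does not propagate further). Returns per-gene value
# (+1/0/-1), determination round (0 = master) and the trichotomous status
# matrix over timepoints: a gene first responds at timepoint index
# `min(round + 1, T)` (responses deeper than the series saturate at the
# last timepoint) and keeps its state afterwards.
propagate_truth <- function(network, masters_on, silenced_edges = character(),
                            timepoints) {
  genes <- network$nodes$gene
  n_tp <- length(timepoints)
  ed <- network$edges[!network$edges$edge_id %in% silenced_edges, ]
  value <- structure(integer(length(genes)), names = genes)
  round_det <- structure(rep(NA_integer_, length(genes)), names = genes)
  value[masters_on] <- 1L
  round_det[masters_on] <- 0L
  d <- 1L
  repeat {
    src_det <- !is.na(round_det[ed$source]) & value[ed$source] != 0L
    cand <- ed[src_det & is.na(round_det[ed$target]), ]
    if (nrow(cand) == 0L) break
    infl <- tapply(cand$sign * value[cand$source], cand$target, sum)
    value[names(infl)] <- sign(infl)
    round_det[names(infl)] <- d
    d <- d + 1L
  }
  status <- matrix("NEUTRAL", length(genes), n_tp,
                   dimnames = list(genes, as.character(timepoints)))
  responsive <- !is.na(round_det) & value != 0L
  first_idx <- pmin(round_det + 1L, n_tp)
  for (g in which(responsive)) {
    status[g, seq(first_idx[g], n_tp)] <-
      if (value[g] > 0) "UP" else "DOWN"
  }
  list(value = value, round = round_det, status = status,
       first_idx = ifelse(responsive, first_idx, NA_integer_))
}

# Truth-level active edges of a condition: sign-coherent edges among
# responsive nodes at the final-timepoint state snapshot.
truth_active_edges <- function(network, prop) {
  st <- prop$status[, ncol(prop$status)]
  ed <- network$edges
  ed$edge_id[is_active_edge(st[ed$source], st[ed$target], ed$sign)]
}

#' Plant ground truth on a network and define the study conditions
#'
#' Chooses the planted master regulators (boosting their direct out-reach
#' so they genuinely sit upstream of the response), designates the last
#' master's outgoing edges as the branch silenced in the "blocked"
#' condition, and precomputes the zero-noise truth (per-condition states,
#' active-edge sets, the inhibited edge set and path memberships).
#'
#' The default condition panel mirrors a receptor-agonist study design:
#' a vehicle control; a pan-agonist gold standard; three alpha-agonist
#' conditions (wild type and two non-alpha receptor knockouts, all masters
#' on); a "blocked" condition (wild type under combined beta+gamma
#' agonists, where the silenced branch stays off); and a "rescue"
#' condition (alpha-null line, same agonists, branch restored).
#'
#' @param network a [generate_network()] result; master boosting adds
#'   edges, so the returned truth carries the augmented network.
#' @param n_masters number of planted master TFs; default 3.
#' @param master_reach fraction of nodes each master directly regulates;
#'   default 0.5.
#' @param negative_edge_fraction sign probability for the boosted edges.
#' @param timepoints ordered timepoints in days; default `c(2, 4, 10)`.
#' @param noise_sd SD of log2 expression noise recorded in the truth.
#' @param seed integer RNG seed.
#' @return a `SyntheticTruth`: list with `network` (augmented), `planted_masters`,
#'   `conditions` (named list of specs: `genotype`, `treatment`,
#'   `masters_on`, `silenced_edges`), `planted_program_edges` (per active
#'   condition), `inhibited_edge_set`, `silenced_genes`, `truth_states`
#'   (per condition, from [propagate_truth()]), `path_membership` (gold
#'   condition signatures), `noise_sd`, `timepoints`, `seed`.
#' @export
synthetic_truth <- function(network, n_masters = 3, master_reach = 0.5,
                            negative_edge_fraction = 0.25,
                            timepoints = c(2, 4, 10), noise_sd = 0.2,
                            seed = 1L) {
  n_masters <- assert_count(n_masters, "n_masters", min = 1L)
  assert_fraction(master_reach, "master_reach")
  stopifnot(inherits(network, "RegulatoryNetwork"))
  deg <- network_degrees(network)
  tf_deg <- deg[match(network$nodes$gene[network$nodes$is_tf], deg$gene), ]
  masters <- tf_deg$gene[order(-tf_deg$out_degree, tf_deg$gene)][seq_len(n_masters)]
  # Boost each master's direct targets to `master_reach` of the node set.
  withr::with_seed(sub_seed(seed, 11L), {
    ed <- network$edges[, c("source", "target", "sign")]
    n_reach <- ceiling(master_reach * nrow(network$nodes))
    for (m in masters) {
      have <- ed$target[ed$source == m]
      pool <- setdiff(network$nodes$gene, c(m, have))
      need <- min(max(0L, n_reach - length(have)), length(pool))
      if (need > 0L) {
        new_t <- sample(pool, need)
        ed <- rbind(ed, data.frame(
          source = m, target = new_t,
          sign = ifelse(stats::runif(need) < negative_edge_fraction, -1L, 1L),
          stringsAsFactors = FALSE))
      }
    }
  })
  net <- regulatory_network(ed, tfs = network$nodes$gene[network$nodes$is_tf],
                            nodes = network$nodes$gene)
  silenced <- net$edges$edge_id[net$edges$source == masters[n_masters]]
  conditions <- list(
    control = list(genotype = "WT", treatment = "EtOH",
                   masters_on = character(), silenced_edges = character()),
    gold = list(genotype = "WT", treatment = "ATRA",
                masters_on = masters, silenced_edges = character()),
    alpha_wt = list(genotype = "WT", treatment = "BMS753",
                    masters_on = masters, silenced_edges = character()),
    alpha_bko = list(genotype = "RarbKO", treatment = "BMS753",
                     masters_on = masters, silenced_edges = character()),
    alpha_gko = list(genotype = "RargKO", treatment = "BMS753",
                     masters_on = masters, silenced_edges = character()),
    blocked = list(genotype = "WT", treatment = "BMS641+BMS961",
                   masters_on = masters, silenced_edges = silenced),
    rescue = list(genotype = "RaraKO", treatment = "BMS641+BMS961",
                  masters_on = masters, silenced_edges = character())
  )
  truth_states <- lapply(conditions, function(cs)
    propagate_truth(net, cs$masters_on, cs$silenced_edges, timepoints))
  active <- lapply(truth_states, function(p) truth_active_edges(net, p))
  active$control <- character()
  inhibited <- setdiff(active$rescue, active$blocked)
  silenced_genes <- names(which(
    !is.na(truth_states$rescue$first_idx) &
      is.na(truth_states$blocked$first_idx)))
  sig <- apply(truth_states$gold$status, 1, paste, collapse = "/")
  truth <- list(network = net, planted_masters = masters,
                conditions = conditions,
                planted_program_edges = active[setdiff(names(conditions), "control")],
                inhibited_edge_set = inhibited,
                silenced_genes = silenced_genes,
                truth_states = truth_states,
                path_membership = sig,
                noise_sd = noise_sd, timepoints = timepoints, seed = seed)
  class(truth) <- "SyntheticTruth"
  truth
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf(paste0("SyntheticTruth: masters %s | %d conditions | ",
                     "inhibited edges %d | noise_sd %.2f\n"),
              paste(x$planted_masters, collapse = ", "),
              length(x$conditions), length(x$inhibited_edge_set),
              x$noise_sd))
  invisible(x)
}

#' Simulate temporal expression under the planted truth
#'
#' Expression is generated directly on the log2 scale around a positive
#' baseline: a responding gene is offset by `+effect_log2` (net
#' activation) or `-effect_log2` (net repression) from its first-response
#' timepoint onwards, one network hop per timepoint; Gaussian noise of SD
#' `truth$noise_sd` is added per sample on the log2 scale. Control
#' samples are baseline plus noise only.
#'
#' @param network the truth's `RegulatoryNetwork` (kept as an explicit
#'   argument so alternative wirings can be simulated).
#' @param truth a [synthetic_truth()] object.
#' @param conditions named list of condition specs (default
#'   `truth$conditions`); each has `genotype`, `treatment`, `masters_on`,
#'   `silenced_edges`.
#' @param timepoints ordered timepoints; default `truth$timepoints`.
#' @param baseline positive baseline expression; default 100.
#' @param effect_log2 log2 effect size of a planted response; default 4.
#' @param n_replicates replicates per condition-timepoint; default 3.
#' @param seed integer RNG seed; default `truth$seed`.
#' @return an [expression_matrix()].
#' @export
simulate_temporal_expression <- function(network, truth,
                                         conditions = NULL,
                                         timepoints = NULL,
                                         baseline = 100, effect_log2 = 4,
                                         n_replicates = 3, seed = NULL) {
  stopifnot(inherits(network, "RegulatoryNetwork"),
            inherits(truth, "SyntheticTruth"))
  conditions <- conditions %||% truth$conditions
  timepoints <- timepoints %||% truth$timepoints
  seed <- seed %||% truth$seed
  assert_positive(baseline, "baseline")
  assert_positive(effect_log2, "effect_log2")
  if (!any(vapply(conditions, function(cs) length(cs$masters_on) == 0L,
                  logical(1))))
    abort_aegrn("at least one control condition (no masters on) is required",
                "aegrn_invalid_parameter")
  for (cs in conditions) {
    bad_m <- setdiff(cs$masters_on, network$nodes$gene[network$nodes$is_tf])
    if (length(bad_m))
      abort_aegrn(sprintf("unknown master '%s' in condition spec", bad_m[1]),
                  "aegrn_unknown_identifier")
    bad_e <- setdiff(cs$silenced_edges, network$edges$edge_id)
    if (length(bad_e))
      abort_aegrn(sprintf("unknown silenced edge '%s' in condition spec",
                          bad_e[1]), "aegrn_unknown_identifier")
  }
  genes <- network$nodes$gene
  n_tp <- length(timepoints)
  cols <- list(); meta <- list()
  withr::with_seed(sub_seed(seed, 23L), {
    for (ci in seq_along(conditions)) {
      cs <- conditions[[ci]]
      prop <- propagate_truth(network, cs$masters_on, cs$silenced_edges,
                              timepoints)
      offset <- matrix(0, length(genes), n_tp, dimnames = dimnames(prop$status))
      offset[prop$status == "UP"] <- effect_log2
      offset[prop$status == "DOWN"] <- -effect_log2
      for (ti in seq_len(n_tp)) for (r in seq_len(n_replicates)) {
        sample_id <- sprintf("%s_%s_d%s_r%d", cs$genotype, cs$treatment,
                             timepoints[ti], r)
        noise <- if (truth$noise_sd > 0)
          stats::rnorm(length(genes), 0, truth$noise_sd) else 0
        cols[[sample_id]] <- 2^(log2(baseline) + offset[, ti] + noise)
        meta[[sample_id]] <- data.frame(
          sample = sample_id, genotype = cs$genotype,
          treatment = cs$treatment, timepoint = timepoints[ti],
          replicate = r, stringsAsFactors = FALSE)
      }
    }
  })
  values <- do.call(cbind, cols)
  rownames(values) <- genes
  expression_matrix(values, do.call(rbind, meta))
}

#' Generate a hierarchical marker catalog overlapping the planted program
#'
#' A stated fraction (`coverage`) of the planted responsive program genes
#' receive a top-level class label (neuron, astrocyte or OPC, drawn with
#' the given class weights); additional labels are drawn from non-program
#' genes as background. A fraction of the neuron-class genes also receive
#' a neuron-subtype label, and a small fraction of labeled genes are
#' added to a second class set to emulate the overlap of real marker
#' sources (resolved downstream by priority).
#'
#' @param network the truth's network.
#' @param truth a [synthetic_truth()].
#' @param coverage fraction of program genes labeled, in `[0, 1]`.
#' @param class_weights sampling weights for classes
#'   (neuron/astrocyte/OPC); default `c(0.5, 0.25, 0.25)`.
#' @param subtype_fraction fraction of neuron-class genes given a subtype
#'   label; default 0.7.
#' @param background_fraction fraction of non-program genes labeled;
#'   default 0.15.
#' @param overlap_fraction fraction of labeled genes duplicated into a
#'   second class set; default 0.05.
#' @param seed integer RNG seed; default derived from `truth$seed`.
#' @return a [marker_catalog()].
#' @export
generate_marker_catalog <- function(network, truth, coverage = 0.8,
                                    class_weights = c(0.5, 0.25, 0.25),
                                    subtype_fraction = 0.7,
                                    background_fraction = 0.15,
                                    overlap_fraction = 0.05,
                                    seed = NULL) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  assert_fraction(coverage, "coverage")
  seed <- seed %||% sub_seed(truth$seed, 31L)
  classes <- c("neuron", "astrocyte", "OPC")
  subtypes <- c("dopaminergic", "glutamatergic", "GABAergic")
  all_neutral <- paste(rep("NEUTRAL", length(truth$timepoints)),
                       collapse = "/")
  program_genes <- names(truth$path_membership)[
    truth$path_membership != all_neutral]
  other_genes <- setdiff(network$nodes$gene, program_genes)
  sets <- stats::setNames(vector("list", length(classes)), classes)
  sub_sets <- stats::setNames(vector("list", length(subtypes)), subtypes)
  withr::with_seed(seed, {
    labeled <- if (length(program_genes))
      sample(program_genes, round(coverage * length(program_genes)))
      else character()
    bg <- if (length(other_genes))
      sample(other_genes, round(background_fraction * length(other_genes)))
      else character()
    pool <- c(labeled, bg)
    cls <- sample(classes, length(pool), replace = TRUE,
                  prob = class_weights)
    for (cl in classes) sets[[cl]] <- pool[cls == cl]
    neuron_genes <- sets$neuron
    n_sub <- round(subtype_fraction * length(neuron_genes))
    if (n_sub > 0) {
      sub_pool <- sample(neuron_genes, n_sub)
      sub_cls <- sample(subtypes, n_sub, replace = TRUE)
      for (st in subtypes) sub_sets[[st]] <- sub_pool[sub_cls == st]
    }
    n_ov <- round(overlap_fraction * length(pool))
    if (n_ov > 0) {
      ov <- sample(pool, n_ov)
      for (g in ov) {
        own <- cls[match(g, pool)]
        second <- sample(setdiff(classes, own), 1)
        sets[[second]] <- c(sets[[second]], g)
      }
    }
  })
  sets <- lapply(sets, function(s) sort(unique(s)))
  sub_sets <- Filter(length, lapply(sub_sets, function(s) sort(unique(s))))
  marker_catalog(Filter(length, sets), sub_sets,
                 neuron_class = "neuron")
}

#' Generate promoter enrichment values correlated with planted activity
#'
#' Genes silenced in the blocked condition (responsive under rescue but
#' not under blocked) receive high H3K27me3 (Polycomb-style repression);
#' genes up-regulated within the first `early_timepoints` of the
#' reference state series receive high H3K4me3, FAIRE and RNAPII (active
#' promoters); everything else is unmarked. Each enrichment is
#' `signal_log2 * indicator + Gaussian noise`.
#'
#' @param states a [node_states()] series (or truth-level states) for the
#'   reference condition providing per-gene temporal statuses.
#' @param truth a [synthetic_truth()] providing `silenced_genes`.
#' @param signal_log2 planted enrichment level; default 2.
#' @param noise_sd Gaussian noise SD; default 0.2.
#' @param early_timepoints number of leading timepoints defining "early
#'   activity"; default 2.
#' @param seed integer RNG seed; default derived from `truth$seed`.
#' @return data frame with columns `gene`, `h3k4me3`, `h3k27me3`,
#'   `faire`, `rnapii`.
#' @export
generate_promoter_table <- function(states, truth, signal_log2 = 2,
                                    noise_sd = 0.2, early_timepoints = 2,
                                    seed = NULL) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  assert_positive(signal_log2, "signal_log2")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    abort_aegrn("`noise_sd` must be non-negative", "aegrn_invalid_parameter")
  seed <- seed %||% sub_seed(truth$seed, 47L)
  status <- if (inherits(states, "NodeStateSeries")) states$status else
    states
  genes <- rownames(status)
  early_cols <- seq_len(min(early_timepoints, ncol(status)))
  silenced <- genes %in% truth$silenced_genes
  early_active <- !silenced &
    apply(status[, early_cols, drop = FALSE] == "UP", 1, any)
  n <- length(genes)
  withr::with_seed(seed, {
    noise <- function() if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else
      numeric(n)
    out <- data.frame(
      gene = genes,
      h3k4me3 = signal_log2 * early_active + noise(),
      h3k27me3 = signal_log2 * silenced + noise(),
      faire = signal_log2 * early_active + noise(),
      rnapii = signal_log2 * early_active + noise(),
      stringsAsFactors = FALSE)
  })
  rownames(out) <- NULL
  out
}

#' Simulate a full synthetic study
#'
#' One-call generator of the whole benchmark: network with planted
#' masters, condition panel, temporal expression, marker catalog and
#' promoter enrichments, all derived from one seed.
#'
#' @param n_tfs,n_targets,mean_out_degree,negative_edge_fraction network
#'   parameters, see [generate_network()].
#' @param n_masters,master_reach truth parameters, see
#'   [synthetic_truth()].
#' @param timepoints ordered timepoints in days.
#' @param baseline,effect_log2,n_replicates,noise_sd expression
#'   parameters, see [simulate_temporal_expression()].
#' @param marker_coverage marker coverage of program genes.
#' @param signal_log2,promoter_noise_sd promoter-table parameters.
#' @param conditions optional character vector naming which of the truth's
#'   conditions to simulate expression for (always including the
#'   control); default all.
#' @param markers,promoters set `FALSE` to skip generating the marker
#'   catalog or promoter table.
#' @param seed master integer seed.
#' @return list with `network`, `truth`, `expr`, `catalog`, `promoters`.
#' @export
simulate_study <- function(n_tfs = 30, n_targets = 300, mean_out_degree = 8,
                           negative_edge_fraction = 0.25, n_masters = 3,
                           master_reach = 0.5, timepoints = c(2, 4, 10),
                           baseline = 100, effect_log2 = 4,
                           n_replicates = 3, noise_sd = 0.2,
                           marker_coverage = 0.8, signal_log2 = 2,
                           promoter_noise_sd = 0.2, conditions = NULL,
                           markers = TRUE, promoters = TRUE, seed = 1L) {
  base_net <- generate_network(n_tfs, n_targets, mean_out_degree,
                               negative_edge_fraction,
                               seed = sub_seed(seed, 1L))
  truth <- synthetic_truth(base_net, n_masters = n_masters,
                           master_reach = master_reach,
                           negative_edge_fraction = negative_edge_fraction,
                           timepoints = timepoints, noise_sd = noise_sd,
                           seed = seed)
  conds <- truth$conditions
  if (!is.null(conditions))
    conds <- conds[unique(c("control", conditions))]
  expr <- simulate_temporal_expression(truth$network, truth,
                                       conditions = conds,
                                       baseline = baseline,
                                       effect_log2 = effect_log2,
                                       n_replicates = n_replicates,
                                       seed = seed)
  catalog <- if (markers)
    generate_marker_catalog(truth$network, truth, coverage = marker_coverage)
    else NULL
  prom <- if (promoters)
    generate_promoter_table(truth$truth_states$blocked$status, truth,
                            signal_log2 = signal_log2,
                            noise_sd = promoter_noise_sd)
    else NULL
  list(network = truth$network, truth = truth, expr = expr,
       catalog = catalog, promoters = prom)
}
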