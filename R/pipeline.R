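#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end synthetic-study pipeline with
#' the defaults used throughout: DE log2 threshold 2 (4-fold) for
#' endpoint analyses and 1 (2-fold) for path stratification, promoter
#' classification threshold at half the planted signal, MRI cutoff 0.7.
#'
#' @param n_tfs,n_targets,mean_out_degree,negative_edge_fraction,n_masters,master_reach,timepoints,baseline,effect_log2,n_replicates,noise_sd,marker_coverage,signal_log2,promoter_noise_sd
#'   synthetic-study parameters, see [simulate_study()].
#' @param de_tau_log2 DE threshold for network/marker analyses.
#' @param path_tau_log2 DE threshold for co-expression paths.
#' @param epi_tau promoter classification threshold; default
#'   `signal_log2 / 2`.
#' @param mri_cutoff master-regulator selection cutoff.
#' @param n_null randomized networks for the MRI null.
#' @param edge_rule `"target"` or `"either"` stratification rule.
#' @param require_rescue inhibited-program variant, see
#'   [derive_programs()].
#' @param pseudocount pseudocount for fold changes.
#' @param seed master seed for every stochastic stage.
#' @return a validated `PipelineConfig` list.
#' @export
pipeline_config <- function(n_tfs = 30, n_targets = 300,
                            mean_out_degree = 8,
                            negative_edge_fraction = 0.25, n_masters = 3,
                            master_reach = 0.5, timepoints = c(2, 4, 10),
                            baseline = 100, effect_log2 = 4,
                            n_replicates = 3, noise_sd = 0.2,
                            marker_coverage = 0.8, signal_log2 = 2,
                            promoter_noise_sd = 0.2, de_tau_log2 = 2,
                            path_tau_log2 = 1, epi_tau = NULL,
                            mri_cutoff = 0.7, n_null = 100,
                            edge_rule = c("target", "either"),
                            require_rescue = TRUE, pseudocount = 1,
                            seed = 1L) {
  cfg <- list(n_tfs = assert_count(n_tfs, "n_tfs", 2L),
              n_targets = assert_count(n_targets, "n_targets"),
              mean_out_degree = assert_positive(mean_out_degree,
                                                "mean_out_degree"),
              negative_edge_fraction = assert_fraction(
                negative_edge_fraction, "negative_edge_fraction"),
              n_masters = assert_count(n_masters, "n_masters", 1L),
              master_reach = assert_fraction(master_reach, "master_reach"),
              timepoints = timepoints, baseline = baseline,
              effect_log2 = assert_positive(effect_log2, "effect_log2"),
              n_replicates = assert_count(n_replicates, "n_replicates", 1L),
              noise_sd = noise_sd,
              marker_coverage = assert_fraction(marker_coverage,
                                                "marker_coverage"),
              signal_log2 = assert_positive(signal_log2, "signal_log2"),
              promoter_noise_sd = promoter_noise_sd,
              de_tau_log2 = assert_positive(de_tau_log2, "de_tau_log2"),
              path_tau_log2 = assert_positive(path_tau_log2,
                                              "path_tau_log2"),
              epi_tau = epi_tau %||% (signal_log2 / 2),
              mri_cutoff = assert_fraction(mri_cutoff, "mri_cutoff"),
              n_null = assert_count(n_null, "n_null"),
              edge_rule = match.arg(edge_rule),
              require_rescue = isTRUE(require_rescue),
              pseudocount = pseudocount,
              seed = assert_count(seed, "seed"))
  if (length(cfg$timepoints) < 1L || is.unsorted(cfg$timepoints,
                                                 strictly = TRUE))
    abort_aegrn("timepoints must be strictly increasing",
                "aegrn_invalid_parameter")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    abort_aegrn(sprintf("config file not found: %s", path),
                "aegrn_missing_file")
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full synthetic-study pipeline
#'
#' Executes every stage end to end: simulate the study, call differential
#' expression, stratify co-expression paths, annotate markers, build the
#' master GRN, evaluate per-condition active edges, derive the program
#' partition, classify promoter states, and rank master regulators. All
#' counts and fractions are collected into a report; when `outdir` is
#' given, every intermediate artifact plus `report.json` is written there
#' (reruns with the same config are byte-identical).
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the study objects, stage results and
#'   the `report` list.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("[simulate] seed %d: %d TFs, %d targets", config$seed, config$n_tfs,
      config$n_targets)
  study <- simulate_study(
    n_tfs = config$n_tfs, n_targets = config$n_targets,
    mean_out_degree = config$mean_out_degree,
    negative_edge_fraction = config$negative_edge_fraction,
    n_masters = config$n_masters, master_reach = config$master_reach,
    timepoints = config$timepoints, baseline = config$baseline,
    effect_log2 = config$effect_log2, n_replicates = config$n_replicates,
    noise_sd = config$noise_sd, marker_coverage = config$marker_coverage,
    signal_log2 = config$signal_log2,
    promoter_noise_sd = config$promoter_noise_sd, seed = config$seed)
  truth <- study$truth
  cond_label <- function(key) paste(truth$conditions[[key]]$genotype,
                                    truth$conditions[[key]]$treatment,
                                    sep = ":")
  control <- cond_label("control")
  gold <- cond_label("gold")

  say("[de] thresholds log2 %s (network) / %s (paths)", config$de_tau_log2,
      config$path_tau_log2)
  de_net <- de_status_table(study$expr, control,
                            threshold_log2 = config$de_tau_log2,
                            pseudocount = config$pseudocount)
  de_path <- de_status_table(study$expr, control,
                             threshold_log2 = config$path_tau_log2,
                             pseudocount = config$pseudocount)

  say("[paths] stratifying %s", gold)
  paths <- assign_paths(de_path, gold, config$timepoints)

  ann <- annotate_genes(truth$network$nodes$gene, study$catalog)

  responsive <- unique(de_net$gene[de_net$condition == gold &
                                     de_net$status != "NEUTRAL"])
  grn <- build_master_grn(truth$network, responsive)
  say("[grn] master GRN: %d nodes, %d edges", nrow(grn$nodes),
      nrow(grn$edges))
  strat <- stratify_network(grn, ann, rule = config$edge_rule)

  final_tp <- config$timepoints[length(config$timepoints)]
  cond_keys <- setdiff(names(truth$conditions), "control")
  states <- lapply(cond_keys, function(k)
    node_states(de_net, cond_label(k), config$timepoints))
  names(states) <- cond_keys
  active <- lapply(states, function(s)
    evaluate_active_edges(grn, s, final_tp))
  fractions <- vapply(active, active_edge_fraction, numeric(1),
                      network = grn)

  say("[programs] set algebra over %d conditions", length(active))
  partition <- derive_programs(
    active[c("alpha_wt", "alpha_bko", "alpha_gko")],
    active$blocked, active$rescue, network = grn,
    require_rescue = config$require_rescue)
  membership <- program_gene_tf_sets(partition, grn)

  promoter <- promoter_state_table(study$promoters, tau = config$epi_tau)
  epi_counts <- promoter_state_counts(
    promoter, lapply(membership$genes[c("common", "inhibited")],
                     intersect, y = promoter$gene))

  say("[mri] ranking TFs (%d null networks)", config$n_null)
  ranking <- rank_master_regulators(grn, states$gold,
                                    mri_cutoff = config$mri_cutoff,
                                    n_null = config$n_null,
                                    seed = sub_seed(config$seed, 91L))

  # recovery of the planted truth
  truth_inh <- intersect(truth$inhibited_edge_set, grn$edges$edge_id)
  tp_hits <- intersect(partition$inhibited, truth_inh)
  recovery <- list(
    masters_top_ranks = ranking$rank[match(truth$planted_masters,
                                           ranking$tf)],
    masters_in_top5 = all(match(truth$planted_masters, ranking$tf) <= 5),
    inhibited_precision = if (length(partition$inhibited))
      length(tp_hits) / length(partition$inhibited) else NA_real_,
    inhibited_recall = if (length(truth_inh))
      length(tp_hits) / length(truth_inh) else NA_real_)

  report <- list(
    config = unclass(config),
    network = as.list(network_size(truth$network)),
    master_grn = as.list(network_size(grn)),
    degs_gold_final = count_degs(de_net, gold, "ANY", final_tp),
    path_sizes = stats::setNames(
      as.list(paths$sizes$n[paths$sizes$n > 0]),
      paste0("path_", ifelse(is.na(paths$sizes$path_id[paths$sizes$n > 0]),
                             "none",
                             paths$sizes$path_id[paths$sizes$n > 0]))),
    node_counts = as.list(strat$node_counts),
    edge_counts = as.list(strat$edge_counts),
    active_edge_fraction = as.list(fractions),
    programs = list(alpha_specific = length(partition$alpha_specific),
                    common = length(partition$common),
                    inhibited = length(partition$inhibited),
                    residual = length(partition$residual)),
    promoter_state_counts = apply(epi_counts, 1, as.list),
    n_selected_tfs = sum(ranking$selected),
    top_tfs = utils::head(ranking$tf, 10),
    recovery = recovery,
    runtime_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      2))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_expression_tsv(study$expr, p("expression.tsv"), p("samples.tsv"))
    write_edge_tsv(truth$network, p("edges.tsv"))
    write_marker_gmt(study$catalog, p("markers.gmt"))
    write_promoter_tsv(study$promoters, p("promoters.tsv"))
    write_truth_json(truth, p("truth.json"))
    write_de_tsv(de_net, p("de_status.tsv"))
    write_tsv(paths$assignment, p("paths.tsv"))
    write_tsv(ann, p("annotation.tsv"))
    write_edge_tsv(grn, p("master_grn.tsv"))
    for (k in names(active))
      write_active_edges_tsv(active[[k]], grn,
                             p(sprintf("active_edges_%s.tsv", k)))
    prog_tab <- do.call(rbind, lapply(
      c("common", "inhibited", "residual"), function(pr)
        if (length(partition[[pr]]))
          data.frame(edge_id = partition[[pr]], program = pr,
                     stringsAsFactors = FALSE)))
    write_tsv(prog_tab, p("programs.tsv"))
    write_tsv(promoter, p("promoter_states.tsv"))
    write_tsv(as.data.frame(ranking), p("mri_ranking.tsv"))
    report_no_time <- report
    report_no_time$runtime_s <- NULL
    writeLines(jsonlite::toJSON(report_no_time, auto_unbox = TRUE,
                                pretty = TRUE, digits = 10),
               p("report.json"))
  }

  say("[done] %.1f s", report$runtime_s)
  invisible(list(study = study, de_net = de_net, de_path = de_path,
                 paths = paths, annotation = ann, grn = grn,
                 stratification = strat, states = states, active = active,
                 fractions = fractions, partition = partition,
                 membership = membership, promoter = promoter,
                 epi_counts = epi_counts, ranking = ranking,
                 report = report))
}
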