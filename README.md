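# aegrn — active-edge gene regulatory network analysis

`aegrn` is an R package for dissecting how nuclear-receptor agonists
rewire transcription during stem-cell specialization, built around the
analysis style used for retinoid-driven neuronal differentiation of
pluripotent cells. It takes normalized temporal expression (vehicle
control plus agonist treatments), a curated signed TF→target edge
collection, hierarchical cell-type marker sets and promoter chromatin
enrichments, and provides:

* **Trichotomous DE calling** — per gene, condition and timepoint,
  `status = UP` iff `log2 FC > τ`, `DOWN` iff `< −τ`, else `NEUTRAL`
  (strict inequalities; defaults τ = 2 for endpoint analyses, τ = 1 for
  temporal paths).
* **Co-expression paths** — deterministic stratification of each gene's
  status signature over timepoints (Path 1 = `(UP,UP,UP)`,
  Path 2 = `(NEUTRAL,UP,UP)`, Path 4 = `(NEUTRAL,NEUTRAL,UP)`, full
  `3^T` space enumerated).
* **Active edges** — an edge `u →(s) v` is *active* iff both endpoints
  are responsive and coherent with the sign:
  `s · σ(u) · σ(v) = +1`, with `σ(UP)=+1, σ(DOWN)=−1, σ(NEUTRAL)=0`.
* **Program set algebra** — receptor-specific, common and *inhibited*
  programs from condition-wise active-edge sets
  (`inhibited = (∩ alpha ∩ rescue) \ blocked`).
* **Promoter states** — ACTIVE_FAIRE / REPRESSED_K27 / BIVALENT /
  UNMARKED from H3K4me3, H3K27me3 and FAIRE enrichments.
* **Master regulator ranking** — per-TF master regulatory index
  `MRI = |cascade(tf)| / (n_responsive − 1)` via coherent, temporally
  ordered cascades, with empirical p-values against a
  degree- and sign-preserving double-edge-swap null.
* **A seeded synthetic-study generator** with planted masters, programs
  and promoter states, so the entire pipeline is testable end to end
  without any external download.

## Worked example

```r
library(aegrn)
res <- run_pipeline(pipeline_config(seed = 1), outdir = "aegrn_out")
#> [simulate] seed 1: 30 TFs, 300 targets
#> [de] thresholds log2 2 (network) / 1 (paths)
#> [paths] stratifying WT:ATRA
#> [grn] master GRN: 266 nodes, 531 edges
#> [programs] set algebra over 6 conditions
#> [mri] ranking TFs (100 null networks)

res$report$programs
#> $alpha_specific [1] 473   $common [1] 397   $inhibited [1] 76   $residual [1] 0

res$report$recovery
#> $masters_top_ranks [1] 3 2 1
#> $masters_in_top5   [1] TRUE
#> $inhibited_precision [1] 1
#> $inhibited_recall    [1] 1

head(res$ranking, 3)
#>     tf       mri null_mean   null_sd    p_value rank selected
#> 1 TF26 0.8867925 0.5918113 0.1204375 0.00990099    1     TRUE
#> 2 TF11 0.6000000 0.6892830 0.1611360 0.74257426    2    FALSE
#> 3 TF18 0.6000000 0.5354717 0.1173531 0.40594059    3    FALSE
```

The report says: of the 531 edges of the reconstructed master GRN, 473
are active in all three RARα-agonist conditions; 397 of those are also
active under combined RARβ+γ agonists in wild-type cells ("common"),
while 76 only reactivate in the RARα-null line — the program inhibited
by the unliganded receptor. Those 76 edges coincide exactly with the
planted inhibited set, and the three planted master TFs occupy the top
three MRI ranks. `aegrn_out/` holds every intermediate (expression and
metadata TSV, edge list, GMT markers, promoter table, DE status, path
and program tables, MRI ranking) plus `report.json`, which is
byte-identical across reruns with the same seed.

Individual stages are available as plain functions
(`de_status_table()`, `assign_paths()`, `annotate_genes()`,
`build_master_grn()`, `evaluate_active_edges()`, `derive_programs()`,
`classify_promoter_state()`, `rank_master_regulators()`, …) and accept
data read from standard formats (`read_expression_tsv()`, `read_sif()`,
`read_gmt()`, `read_bed()`).

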