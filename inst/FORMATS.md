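# File formats

All tables are tab-separated with a header line; booleans are written 0/1.
These are the formats `write_simulation()` emits and every pipeline stage
reads.

## mirna_expression.tsv
First column `mirna_id`; one further column per sample holding log2-scale
intensities. Column names match `sample_id` in `samples.tsv`.

## samples.tsv
Columns: `sample_id`, `cohort` (`adult` | `aged`), `timepoint`
(`0w` | `2w` | `4w`), `replicate` (integer index within the group).

## gene_de_<lineage>.tsv
Gene differential-expression table for one lineage (e.g. angiogenesis).
Columns: `gene_id`, `log2fc`, `p_value`. Significance (p < 0.05, no
fold-change floor) and direction are derived on read.

## targets.tsv
miRNA-target interactions with evidence provenance. Columns: `mirna_id`,
`gene_id`, `validated` (0/1 wet-experiment support), `prediction_methods`
(comma-joined predictor names, may be empty). Method names are
canonicalised case-insensitively on read.

## ppi_edges.tsv
Protein-protein interaction edge list. Columns: `gene_a`, `gene_b`,
`evidence_type`. Only rows whose `evidence_type` is in the configured
experimental set (default `experimental`) enter the graph; self-loops and
duplicate/reversed pairs are collapsed. Gene identifiers must already be
harmonised with the target and gene tables.

## gene_sets.gmt
Standard GMT: one set per line — set name, description, then tab-separated
member gene ids. The simulated collection is synthetic (random sets plus
one module made of the planted miRNAs' targets).

## ground_truth.json
Simulation ground truth: the seed, feature counts, and one record per
planted miRNA with its target list, its network power (computed by an
independent edge-list scan), the lineage whose gene table carries its
targets, and the expected sign of the contribution score at each
timepoint.

## Pipeline stage outputs
`de_<cohort>_<tp>.tsv` (per-feature contrast results),
`filtered_targets_<tp>.tsv` (interaction table with `kept_*` flags and
machine-readable `reasons`), `prn_<tp>.tsv` (`mirna_id`, `n_targets`,
`prn`), `rcifh_<tp>.tsv` (group means, cohort fold changes, `prn`,
`rcifh`, `rank`), `top_targets_<tp>.tsv` (pooled target genes with
`activated`/`inhibited`/`mixed` status), `enrichment_<tp>.tsv`,
`manifest.json` (config snapshot, seed, per-stage output digests and
record counts), `log.jsonl` (one JSON object per stage).
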