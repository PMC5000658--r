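---
title: "Scoring miRNA contributions to impaired fracture healing: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring miRNA contributions to impaired fracture healing: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcifh)
```

## The method

The package ranks differentially expressed miRNAs by how much each one
contributes to the impairment of bone fracture healing in an aged cohort
relative to an adult one. The premise is that a miRNA's biological impact
is not captured by its own fold change alone: a modestly regulated miRNA
whose targets sit at the centre of the protein-interaction network can
matter more than a strongly regulated miRNA with peripheral targets.

Two quantities are combined per miRNA *i*:

1. **Network power.** `PRN_i = Σ_t PN_t`, the sum over the miRNA's
   filtered target genes of each target's degree `PN_t` in an undirected
   protein-protein interaction (PPI) graph restricted to edges with
   wet-experiment evidence. Degree counts distinct neighbours
   (multi-edges and self-loops are collapsed on construction).
2. **Cohort fold-change difference.** With `ENH/ENN` the adult cohort's
   linear-scale mean expression at the post-fracture timepoint versus
   week 0 and `EAH/EAN` the aged cohort's,

   `RCIFH_i = (log2(ENH_i/ENN_i) − log2(EAH_i/EAN_i)) × PRN_i`

The sign convention follows from miRNAs being repressors: a negative score
means the miRNA is relatively more up-regulated in the aged cohort, hence
presses harder on its target network exactly where healing fails — it
*impairs* healing. A positive score marks a healing-promoting miRNA. The
magnitude, driven by `PRN`, measures how much network the miRNA can move.

### The filter cascade

Raw miRNA→target assertions are noisy, so two orthogonal filters precede
scoring:

* **Evidence rule** — keep an interaction if it has at least one
  wet-experiment validation *or* support from at least two distinct
  prediction methods (method names are canonicalised case-insensitively,
  so `"M1, m1"` counts as one method).
* **Opposite-direction rule** — a repressor and its target should move in
  opposite directions: an up-regulated miRNA is only credited with targets
  that are significantly down-regulated (p < 0.05, no fold-change floor)
  in a supplied gene differential-expression table, and symmetrically for
  down-regulated miRNAs. Genes absent from every table count as unchanged
  and the interaction is dropped.

The two rules are independent, so their composition is order-invariant
(tested). Every dropped interaction carries a machine-readable reason
(`insufficient_evidence`, `gene_not_opposite`, `mirna_unchanged`),
semicolon-joined when several apply.

With several lineage-specific gene tables (angiogenesis, chondrogenesis,
osteogenesis), the default is **union** semantics — the direction rule may
hold in any one table — because an interaction acting through any lineage
of fracture repair is biologically actionable; `combine = "intersection"`
is available for stricter use.

### Which cohort orients the direction rule

The direction rule needs a single miRNA direction, but the two cohorts can
disagree. The package defaults to the **aged** cohort's contrast, since the
question being asked is aged-specific impairment; `direction_cohort =
"adult"` switches it. A consequence worth knowing: a miRNA whose effect
exists only in the adult cohort has an essentially random direction in the
aged contrast, so roughly half of such miRNAs lose their targets at the
direction filter and score near zero. This is a property of the method,
not of the implementation — orienting the rule by the scored cohort is what
makes the negative tail (aged-driven impairing miRNAs) reliable.

## Differential expression

miRNA contrasts are within-cohort, 2-week vs 0-week and 4-week vs 0-week,
on log2 intensities. The screen flags a miRNA when `p < 0.05` **and**
`|log2FC| ≥ 1` (both configurable); gene tables use `p < 0.05` alone. No
multiple-testing correction is applied by default, matching the screening
character of the analysis; Benjamini–Hochberg q-values are available via
`adjust = "BH"` (they never drive the flag).

The test is a pooled-variance two-sample t-statistic, the form underlying
ordinary microarray linear-model t-tests, computed vectorised across
features. Under the package's simulated null (equal group variances,
Gaussian replicate noise) its size is exactly nominal, which is what the
calibration test asserts; a Welch/Satterthwaite variant (`var_equal =
FALSE`) is provided for heteroscedastic data, at the cost of being
conservative at n = 3 per group. Both variants are cross-checked against
`stats::t.test()` on fixtures. Empirical-Bayes variance moderation is
deliberately out of scope: with the tiny group sizes of this design its
behaviour is dominated by the prior, and reproducibility of the plain test
was judged more valuable.

Fold change defaults to the log2 ratio of **linear-scale** group means
(intensities are stored as log2, so means are taken on `2^x`). This makes
the DE fold change algebraically identical to the `ENH/ENN` ratios in the
contribution score. The alternative — difference of mean log2 values,
which is what linear-model contrasts on log2 data estimate — is exposed as
`fc_method = "log"`. The two differ under replicate noise (Jensen's
inequality); internal consistency with the score decided the default.

Degenerate inputs: groups with fewer than 2 replicates error; groups of
exactly 2 are accepted with a warning (array drop-outs make this common in
real designs); a feature with zero variance in both groups gets `p = 1`
when the means are equal and `p = 0` otherwise, by documented convention.

## Scoring and selection

`compute_rcifh()` evaluates the closed form exactly (tested to 1e-12
against the identity) and returns records sorted by `|RCIFH|` descending,
ties broken lexicographically by miRNA id — determinism under ties is part
of the contract. The scored universe defaults to miRNAs DE at `p < 0.05`
with `|log2FC| > 0` in either cohort; the stricter `|log2FC| ≥ 1` table
view is a display choice, not a scoring one. "Top k" selection ranks by
absolute value by default, because both strongly impairing (negative) and
strongly promoting (positive) miRNAs carry pathway information; `signed =
TRUE` restores signed ordering. Network power is recomputed per timepoint,
since the direction filter — and therefore each miRNA's surviving target
list — is timepoint-specific.

Pooled targets of the selected miRNAs are annotated `inhibited` when every
selecting miRNA has a negative score (the miRNA is relatively up in aged,
so the target is relatively repressed there), `activated` for positive
scores, and `mixed` when reached by both signs.

## Enrichment

Over-representation uses the one-sided upper hypergeometric tail
(`P(X ≥ k)`), the convention behind pathway-tool p-values; sidedness is a
design choice the package fixes rather than exposes. The background
universe defaults to all genes appearing in any supplied gene DE table and
is overridable — the reference universe of commercial pathway tools is
proprietary and unrecoverable, so results are only comparable within a
chosen universe. p-values come from `stats::phyper` and are verified in
the tests against exhaustive enumeration of every draw for universes up to
N = 12 (agreement to 1e-10), and against `fisher.test`'s one-sided
alternative. Raw `p < 0.05` drives the significance flag; BH q-values are
reported alongside.

## The synthetic-study generator

`simulate_study()` emulates the study design the pipeline was built for:
two cohorts (adult, aged) × three timepoints (0, 2, 4 weeks post-fracture)
× replicated arrays, on log2-scale intensities.

* **Expression model**: per-miRNA baseline ~ N(8, 1) log2 units, additive
  planted cohort×timepoint effects, i.i.d. Gaussian replicate noise
  (default sd 0.3 log2 units — the scale of replicate scatter on
  normalised arrays). Additivity on the log2 scale means that with
  vanishing noise the empirical fold change of a planted miRNA equals its
  configured effect exactly (tested).
* **Defaults**: 200 miRNAs, 1000 genes, 3 replicates per group — a
  desk-scale version of a realistic design (arrays measure ~1000 miRNAs;
  animal studies run 3 replicates per group).
* **Target map**: 5–15 targets per miRNA; background interactions get
  wet-experiment support with probability 0.3 and each of 4 prediction
  methods with probability 0.3. Planted miRNAs' interactions are annotated
  as validated, and their targets are written into one lineage's gene DE
  table with significant, opposite-direction fold changes, so the filter
  cascade provably retains exactly the planted target sets (tested).
* **PPI graph**: preferential-attachment (scale-free, m = 2) by default,
  matching the heavy-tailed degree distribution of real interactomes;
  Erdős–Rényi available. The emitted edge list also contains ~10% decoy
  edges labelled `predicted`, which the graph builder must discard.
  `target_degree_bias` places a planted miRNA's targets on top-decile
  ("high") or bottom-quartile ("low") degree nodes, giving controlled
  network power.
* **Ground truth**: per planted miRNA, the target set, its network power
  computed by an *independent edge-list scan* (never via the graph
  module), and the expected score sign per timepoint
  (`sign(adult effect − aged effect)`). Everything is a deterministic
  function of (config, seed); identical runs write byte-identical files.
* **Gene sets**: a synthetic GMT collection (random sets plus one module
  of the planted targets) so the enrichment stage has something real to
  find. It stands in for proprietary pathway content and is labelled
  synthetic throughout.

What the generator does **not** emulate: probe-level array artifacts,
normalisation, batch effects, correlated noise, or quality-control sample
drops. Passing tests therefore demonstrate the correctness and calibration
of the analysis given clean normalised intensities, not robustness to
upstream array pathology.

## Numerical and design choices

* Group means for the score use linear-scale intensities (`2^log2`), which
  are strictly positive, so the log ratios are always defined; the scorer
  still validates positivity and errors naming the miRNA and group.
* Targets absent from the PPI graph contribute degree 0 but stay in the
  target count — the score sums degrees and never renormalises.
* Tie-breaks are lexicographic by miRNA id everywhere a ranking is
  emitted.
* The pipeline writes plain TSV/JSON between stages and re-reads its own
  outputs, so a run doubles as a parser round-trip; the manifest holds md5
  digests and record counts per stage, and the stage log contains no
  wall-clock timestamps precisely so reruns are byte-identical.
* Problem sizes used by the shipped verification runs — 200 random graphs
  of up to 50 nodes against a brute-force degree scan, 10,000 random
  tuples for the score identity, 50 × 1000-feature null screens for test
  calibration, 20 seeded replicates of the 200-miRNA recovery experiment —
  were chosen to give tight Monte-Carlo bands while staying comfortable on
  a laptop core.

## Known limitations

* Identifier harmonisation between expression, target and PPI tables is
  the caller's responsibility; no ortholog or alias mapping is attempted.
* The evidence filter treats all prediction methods as exchangeable; no
  method weighting.
* Degree is the only centrality; the score is linear in it by definition.
* With `direction_cohort = "aged"`, adult-only effects are scored
  unreliably (see above); run both orientations if both tails matter.
* The generator plants at most one direction override per gene per
  lineage; a gene targeted by planted miRNAs of opposite directions keeps
  the last override.
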