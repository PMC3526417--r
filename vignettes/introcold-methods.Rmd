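---
title: "Methods: comparative cold-stress transcriptome analysis with planted-truth validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative cold-stress transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

A cold-tolerant introgression line (IL) carries a handful of donor
chromosome segments in an otherwise recurrent-parent background. Profiling
both genotypes across a cold time course and asking *which genes respond,
when, in which genotype, and whether the differences sit on the introgressed
segments* requires a chain of analyses: differential expression with a
permutation test, a temporal set algebra over the calls, pattern
clustering, promoter-motif regulon construction, functional enrichment and
genomic co-localization. `introcold` implements that chain as composable
tibble-in/tibble-out functions, and ships a generator that plants known
truth into synthetic data so every stage can be validated end to end.

# The experimental design being modelled

Two genotypes (`recurrent`, `introgression`); a cold time course at 2, 6,
12, 24 and 48 h; three biological replicates per cell. Control collections
are modelled as a single pooled control per genotype (`condition =
"control"`, `time_h = 0`) rather than as separate control timepoints,
matching the analysed design in which control samples from two collection
times are pooled. That yields 2 × (1 + 5) × 3 = 36 arrays.

# Differential expression

## The statistic

For each gene, on log2-scale values,
\[ d = \frac{\bar{x}_A - \bar{x}_B}{s_i + s_0}, \]
where \(s_i\) is the pooled two-sample standard error and \(s_0\) a fudge
factor stabilising low-variance genes. With \(s_0 = 0\), \(d\) is exactly
the equal-variance two-sample t statistic (a tested identity). By default
\(s_0\) is the median (50th percentile, type-7 quantile) of the per-gene
\(s_i\); a fixed value can be supplied. `d` is computed on log2-normalized
values; the fold change is computed on linear means, because the 5-fold
calling criterion reads as a linear ratio.

## The permutation null and a deliberate design choice

Group labels are permuted; when the number of distinct label assignments
\(\binom{n}{n_A}\) is at most `n_permutations` (default 1000), all of them
are enumerated — a 3v3 contrast gives exactly 20 assignments, so the test
is exhaustive and fully reproducible. Otherwise assignments are sampled
under the seed in `sam_params()`.

How the permuted statistics are referenced is the one genuinely open design
point. A *per-gene* p-value (the fraction of that gene's own permuted
\(|d^*|\) at or above its observed \(|d|\), identity included) has
granularity 1/20 in a 3v3 design — and because the complement assignment
reproduces \(|d|\) exactly for equal group sizes, such a p can never fall
below 2/20 = 0.10. A strict p < 0.05 gate would then never fire. The
package therefore defaults to the *pooled* null that standard SAM uses:
each gene's \(|d|\) is referenced against the permuted statistics of **all**
genes, giving granularity 1/(genes × assignments), well-calibrated type-I
behaviour (verified on null simulations: the fraction of genes with
p < 0.05 sits near 0.05), and enough resolution for the 0.05 gate. The
per-gene rule is kept as `null_mode = "per_gene"` for diagnostics and is
tested against brute-force enumeration. Ties count as exceedances and the
identity assignment is always included, so p > 0 always.

The q-value is the SAM-style median false-call ratio: at each gene's
\(|d|\) cutoff, the median over permutations of the number of permuted
statistics clearing the cutoff, divided by the number of genes called
there, clipped to [0, 1] and monotonized (running minimum from the largest
\(|d|\) downwards).

## Calling

A gene is significant only when p < `p_threshold` (default 0.05, strict)
**and** its linear fold change is > `fc_threshold` (default 5) or
< 1/`fc_threshold`. Both gates are deliberate: a huge fold change with a
flat p, or a tiny p with a 2-fold change, is not called.

# Preprocessing choices

*Normalization* is per-array median scaling: every array is rescaled so its
median equals the global median of per-array medians. This is a deliberate,
documented simplification of invariant-set array normalization; it is
idempotent and preserves all downstream contracts. One consequence worth
knowing: when a large fraction of genes is genuinely induced on an array,
median scaling deflates fold changes slightly; at the default study scale
(~20% of genes planted) the effect is negligible.

*Presence calling* uses a fixed linear intensity threshold (default 100,
inclusive, in at least one sample). A percentile-based rule was considered
and rejected as less reproducible across simulated designs; the threshold
is exposed everywhere.

*Log2 views* add a linear pseudocount (default 1.0) before the transform;
a zero pseudocount with non-positive values is an error, not a warning.

# Temporal set algebra

Timepoints map onto phases: I = {2, 6 h}, II = {12 h}, III = {24, 48 h}.
Per direction, common/specific status is decided **globally** — common =
significant in both genotypes at one or more timepoints, genotype-specific
= significant in exactly one genotype and never in the other (any
timepoint) — and the per-phase tables intersect those global sets with
phase-level significance. Defining per-phase commonality locally instead
would drop genes significant in different phases in the two genotypes from
every set; the global definition matches the redundancy-removed totals this
kind of study reports and makes "the three sets tile the phase-significant
genes" an invariant (tested against a brute-force oracle on random masks).
An optional `same_timepoint` flag tightens per-phase commonality to
same-timepoint co-significance.

Genes induced in one genotype and repressed in the other are placed in both
directions' specific ledgers and flagged as conflicts rather than silently
dropped. Biphasic genes (down-then-up patterns) legitimately appear in both
directions of the *common* sets; that is information, not an error.

Constitutive DEGs are genes significant in the IL-vs-recurrent contrast at
control and never significant in any within-genotype cold contrast.

# Clustering

Average-linkage (UPGMA) agglomeration under the centered correlation
distance \(1 - r\) on gene-median-centred log2 profiles (the heat-map
convention). The implementation is in-package rather than a wrapper because
the tie-break is pinned: ties in the minimum inter-cluster distance are
broken by the lexicographically smallest index pair, which makes trees
deterministic and partitions invariant to input order. Merge heights are
verified exactly (tolerance 1e-12) against a naive O(n³) oracle that
recomputes every cluster distance from scratch, and cross-checked against
`stats::hclust(method = "average")` on tie-free data. `cut_k()` removes the
k−1 highest merges. Constant profiles are an error (their correlation is
undefined), not a silent NA.

# The DRE/CRT regulon

Promoter windows span −1000..−10 relative to the start codon (991 nt);
where a source states "1-kb upstream" loosely, the −10..−1000 window is the
one implemented, and the discrepancy is noted here rather than hidden. On
the minus strand the window is the reverse complement of the 991 bases
starting 10 bp after the gene end; windows truncated at a chromosome edge
warn and proceed.

Scanning reports every occurrence of `GCCGAC`/`ACCGAC`, plus (default)
their reverse complements as minus-strand hits — DRE elements act
orientation-independently in the literature, and a `both_strands = FALSE`
mode covers the strict plus-only reading. Overlapping hits are all
reported.

A commonly induced gene with ≥1 hit is in the DREB1 regulon. Driver
co-expression uses Pearson r over the concatenated genotype-wise
time-courses of replicate-mean log2 values (control, 2, 6, 12, 24, 48 h;
recurrent then IL; 12 points), with the strict cutoff r > 0.9. *Exclusively
DREB1C-regulated* is operationalised as: in the regulon, co-expressed with
the DREB1C driver, and co-expressed with **neither** other driver — the
strictest reading consistent with "exclusive"; the correlations to all
drivers are returned so other cutoffs can be applied downstream. Flat
profiles have undefined correlation and are flagged and excluded rather
than coerced. Driver genes themselves are not listed as regulon members.

# GO enrichment

The exact upper hypergeometric tail \(P(X \ge k)\) with study size n,
population size N, term size K. The annotation is a flat term→gene map
(GO-slim style); ontology-graph (true-path) propagation is out of scope and
must be pre-applied to the GMT if wanted. Unannotated genes count in N.
Raw p and Benjamini–Hochberg adjusted p are both emitted; the reported
`fraction` is k/n.

# Co-localization

Intervals are 0-based half-open internally (BED native; a 1-based inclusive
import mode converts marker-style tables). Overlap requires a shared
chromosome and `max(starts) < min(ends)`, so abutting intervals do not
overlap. "Near a segment" is a configurable symmetric flank, default 0 bp —
marker-resolution segment boundaries make any nonzero default arbitrary.
Containment is flagged separately from overlap.

# The synthetic-data generator

The generator is the study-design oracle, not a tuning knob. Its expression
model is log2-additive: gene baseline + genotype offset + condition×time
effect + Gaussian noise, exponentiated to linear intensities.

Defaults, chosen once for realism at microarray scale: baseline log2
intensity ~ N(10, 1) (linear intensities centred near 1000, comfortably
above the detection threshold of 100 so presence calling does not censor
planted repressed genes); replicate noise SD 0.25 on the log2 scale (the
source design does not report within-genotype variance; 0.25 is a typical
between-replicate spread for this platform class and is exposed in the
config); planted effect 3.0 log2 units (8-fold, clearing the 5-fold gate
with margin). Truth classes mirror the six canonical heat-map pattern
groups — commonly induced/repressed, constitutive up/down in the IL,
down-then-up in both genotypes, up-then-down in the IL only — plus
genotype-specific induced/repressed classes and a null remainder. Default
class sizes total ~20% of 2000 genes, scaled from the proportions such
studies report.

Three driver genes (DREB1A/B/C analogues) and a configurable number of
DREB1C-follower genes live inside the commonly induced class: drivers A and
B (and plain common-induced genes) share a flat induction pattern, while
the C driver and its followers are induced from the first timepoint in the
IL but only late in the recurrent parent, so that follower–C correlation is
near 1 while follower–A correlation is ≈ 0.5, well below the 0.9 cutoff.
Followers and drivers always receive a planted DRE word; other commonly
induced genes receive one at `motif_plant_rate` (default 0.3). Promoter
backgrounds are uniform over A/C/G/T, so accidental DRE hits occur at the
binomial rate (~0.96 expected hits per 991-nt window over four words and
both strands) — the truth table records only planted offsets, and scanner
tests compare against planted-plus-oracle-detected hits. A consequence:
the *fraction* of regulon genes is higher in synthetic data than in real
promoters, whose base composition and motif ecology differ; tests therefore
assert recovery of planted structure, not the fraction itself.

The toy genome is 12 chromosomes × 2 Mb with 17 pairwise disjoint
introgressed segments (at most two per chromosome, placed in disjoint
halves), 31 QTL intervals planted to overlap at most 15 distinct segments,
and genes placed inside or outside segments according to the truth table.
The GO map draws 0–5 flat terms per gene at a 5% base rate, with one term
planted at 10× that rate inside the IL-specific induced class.

What the generator does **not** emulate: probe-level structure and spatial
array artifacts, intensity-dependent (nonlinear) array effects,
heteroskedastic noise, correlated gene modules beyond the planted patterns,
and realistic promoter composition. Passing tests demonstrate the
correctness of the algorithms under the stated model, not performance on
any particular real dataset.

# Problem sizes and determinism

Test and validation runs use 600–2000 genes, 36 arrays, 20-assignment
exhaustive permutation nulls, 50–150-profile clustering oracles and
1000×1000-interval brute-force comparisons — sizes at which the brute-force
oracles are exact and the whole suite runs in well under a minute of
compute. Every stochastic step is seeded: the generator derives all its
draws from `sim_config(seed)` (promoters and annotation use fixed offsets
of that seed), sampled-mode permutation uses `sam_params(seed)`, and
`run_cold_pipeline()` writes a manifest with the seed, full parameter set
and md5 of every output; re-running a config reproduces the manifest
byte-for-byte. Timing logs are kept out of the manifest for exactly that
reason.

# Known limitations

- The normalization is median scaling, not invariant-set or quantile
  normalization; gross differential fractions (>30% of genes) visibly
  shrink fold changes.
- The per-gene permutation p cannot resolve below 0.10 in a 3v3 design (see
  above); it is a diagnostic, not the calling route.
- GO enrichment ignores the ontology graph.
- The Cluster-3.0 CDT/GTR export dialect and heat-map image export are not
  implemented; `autoplot()`/`plot_profiles()` cover visual inspection.
- QTL mapping itself, probe summarization, and segment inference from
  genotyping data are out of scope; intervals are taken as given.
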