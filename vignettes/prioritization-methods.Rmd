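---
title: "Prioritizing candidate genes by conservation and brain expression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing candidate genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

RNA-seq studies in rodent models of complex behavior — drug
self-administration and abstinence being the motivating case — routinely
produce candidate-gene lists with hundreds of entries, many of them false
positives when only a nominal p-value threshold is applied. Before
investing in functional validation or translational follow-up, a
researcher wants to know which candidates are worth the effort: genes
whose biology is conserved between rodent and human, and whose human
expression is concentrated in the brain regions relevant to the phenotype.

`brainprior` scores each candidate's human ortholog on two families of
metrics and bins every metric into **High / Medium / Low** priority:

* **Evolutionary conservation** — protein sequence similarity per species
  pair, the dN/dS ratio per species pair, and conservation of the
  developmental expression trajectory in the forebrain.
* **Human brain expression** — a brain specificity score, brain-region
  enrichment from a two-way ANOVA with Tukey post hocs, mean CNS
  expression, and sex effects.

The metrics are deliberately kept as separate categorical columns rather
than collapsed into one composite score: a gene that is superbly conserved
but ubiquitously expressed poses different follow-up questions than a
brain-specific gene with a diverged sequence.

## Conservation metrics

**Sequence similarity** (percent of the matched protein sequence, rodent
perspective) is a fixed-threshold step function: `>= 90` High,
`[80, 90)` Medium, `< 80` Low. The identity percentage that ortholog
databases report differs by perspective (rodent-vs-human or the reverse);
this package consumes the rodent-perspective value, and the reader's
column contract (`pct_similarity`) makes the choice explicit.

**dN/dS** is categorized *relative to the candidate set of one dataset*:
values strictly below the candidate median are High, values outside the
quartile fences (`Q1 - 1.5 IQR`, `Q3 + 1.5 IQR`) are Low, everything else
is Medium. Two consequences deserve emphasis:

* Categories are **not comparable across datasets** — the median moves
  with the candidate set. This mirrors how a per-study shortlist is
  actually triaged, but any cross-dataset comparison must use the
  categorical distributions, not the raw labels.
* The fence rule sends *both* tails to Low, although a low-tail dN/dS
  outlier is biologically the most conserved gene in the set. The rule is
  implemented as stated; `categorize_dnds()` counts low-tail outliers in
  its result (`low_tail_outliers`) so reports can annotate them.

Quartiles use linear interpolation between order statistics
(`quantile(type = 7)`, the R default); with a dataset-relative rule the
convention only matters near ties. A ratio equal to the median is *not*
"below the median" and lands in Medium. A missing ratio is High when it is
missing because dS is undefined at 100% sequence similarity (no synonymous
divergence to measure — the strongest possible conservation signal) and
uncategorized for every other reason, including `dS = 0` below 100%
similarity.

**Developmental conservation** classes come from cross-species
developmental expression data for the forebrain: `HMR` (trajectory shared
by human, mouse, and rat) is High, `HM`/`HR` Medium, `H` Low, and genes
with data for neither rodent are uncategorized. When only one rodent was
testable the single-species classes apply (Medium if shared with that
species, Low if not); the candidate-vs-background contingency test,
however, uses only genes with complete data for both species pairs, so the
background composition is not distorted by data availability.

Candidate-vs-background comparisons use two-sided Mann-Whitney U tests
with Bonferroni correction for the numeric metrics and a Monte-Carlo
Fisher's exact test for the class table. Background sets must exclude the
candidates — the functions verify disjointness when IDs are supplied —
and one-to-one orthologs only, while per-gene categorization uses the best
available pair for every candidate (preferring the one-to-one pair when a
gene maps to several).

## Brain-expression metrics

All expression computations start from a tissue-level TPM panel with
per-sample tissue, sex, and age. The default tissue configuration mirrors
a 12-tissue CNS panel: 10 reward-related tissues (amygdala, anterior
cingulate cortex, caudate, frontal cortex, hippocampus, hypothalamus,
nucleus accumbens, pituitary, putamen, substantia nigra) and two primarily
motor-related ones (cerebellum, spinal cord). Duplicate brain collections
and cultured cell lines are dropped at read time. All names are
configurable to match whatever labels a panel uses.

**Specificity** is `log2(sum of CNS per-tissue mean TPM / sum of non-CNS
per-tissue mean TPM)`; a score of 3 means 8-fold higher expression in the
brain than in the rest of the body. Per-tissue means use *all*
individuals — the age filter applies only to the sex/tissue ANOVA, where
hormonal status is a confounder. Genes with zero expression on either
side have no finite ratio and are excluded from this metric.

**Region enrichment** fits a two-way type III ANOVA (Sex, Tissue,
Sex:Tissue) on CNS samples from donors at or above the age cutoff
(default 55 years, a typical postmenopausal age, controlling for sex
hormones; studies of adolescent-onset phenotypes may prefer a young-adult
band instead). Type III sums of squares — each effect tested against the
model containing all others — are the appropriate choice because donor
counts per sex × tissue cell are unbalanced in real panels. Empty cells
are an error rather than a silently reduced model: the intended designs
have every cell occupied, and an empty cell after age filtering is a data
problem the caller should see. Tukey HSD across tissues is consulted
**only when the global Tissue effect passes alpha** (post hocs follow a
significant omnibus test; genes without a Tissue effect are "not enriched
in any specific region"). The Tukey step runs one-way across tissues,
pooling the sexes — the same contrast a reader of per-tissue expression
profiles applies — with Tukey-Kramer handling of unequal group sizes.
The all-pairs results are summarized as a compact letter display (CLD)
via insert-and-absorb; letters are ordered by descending tissue mean so
the highest-expression cluster always carries `"a"`, and a gene's
*enriched tissues* are those whose letters include `"a"`. The CLD
invariant — two tissues share a letter exactly when their comparison is
non-significant — is asserted on every call.

**The combined specificity/enrichment category** implements the rule
table: High needs specificity `> 0` *and* enrichment confined to reward
regions; Medium covers positive specificity without reward-only
enrichment (including no enrichment, non-reward enrichment, or mixed
reward + non-reward enrichment) and non-positive specificity with reward
enrichment; Low is non-positive specificity with enrichment only in
cerebellum/spinal cord. Two cells of the rule table are not covered by
the stated rules and were resolved as follows: specificity `<= 0` with no
enrichment is Low (neither brain-specific nor reward-linked), and exactly
zero specificity is handled by the `<= 0` clauses since High explicitly
requires a strictly positive score. The function is total over
{specificity sign} × {enrichment pattern} and unit tests enumerate every
combination.

**Mean CNS expression** is the unweighted grand mean of per-CNS-tissue
means (not the pooled sample mean — tissues with more donors must not
dominate), categorized at `>= 20` TPM High, `[10, 20)` Medium, `< 10`
Low.

**Sex effects** report the Sex main effect, its direction (by comparing
male and female grand means over CNS tissues), and the Sex:Tissue
interaction, all at the same alpha as enrichment.

## Ages, brackets, and panel input

Public expression panels often publish donor age as decade brackets
("50-59"). An exact age cutoff cannot be applied to a bracket, so the
reader rejects bracketed ages by default; passing
`age_bracket_lower_bound = TRUE` coerces each bracket to its lower bound,
which makes a `>= 55` cutoff conservative (a "50-59" donor is excluded
even though they might be 56). Sex labels are normalized through a small
alias map (`M`, `F`, any case, optional plural). Expression matrices are
accepted as plain TSV (either orientation, declared by a flag) or GCT
1.2, whose declared gene/sample counts are validated against the body.

## Comparing priority distributions across datasets

For each metric, the per-dataset High/Medium/Low counts (excluding
uncategorized genes metric-by-metric) form a k × 3 table tested with a
Monte-Carlo Fisher's exact test; pairwise 2 × 3 follow-ups run only when
the omnibus p clears alpha. Pairwise p-values are reported unadjusted by
default (an adjustment flag exists) — the follow-ups are descriptive,
gated behind the omnibus test. Tables are canonically oriented (datasets
sorted by name) before testing so results do not depend on argument
order for a fixed seed.

Monte-Carlo p-values use the add-one estimator
`(1 + #extreme) / (1 + n_sim)` with extremeness defined by table
probability at or below the observed table's. The estimator never
returns 0 and is reproducible for a given seed; all seeded package
functions restore the caller's RNG state.

## Power simulation

The power module plans two-group RNA-seq designs by explicit Monte-Carlo
simulation rather than an analytic approximation. Per replicate: counts
for `n_genes` genes × 2n samples are drawn from a negative binomial
(Poisson when dispersion is 0) with control mean `mu`; a fraction
`prop_de` of genes get mean `mu * fc` or `mu / fc` in the treatment
group, split evenly between directions (an `all_up` switch exists for
sensitivity analysis); samples are normalized with **median-of-ratios
size factors**; each gene is tested with a pooled-variance two-sample
t-test on `log2(normalized count + 0.5)`; Benjamini-Hochberg is applied
at `fdr_q`; and power is the fraction of truly DE genes rejected,
averaged over replicates. The sample-size search walks n = 2, 3, … with
the *same* per-replicate seeds at every n, so the curve is paired and
monotonicity checks are not washed out by simulation noise.

Two numerical choices matter and were made for statistical correctness:

* **Normalization.** Scaling by total library size looks natural but is
  wrong under this generator: `fc` up and `1/fc` down are asymmetric in
  linear space, so the treatment group's library is systematically
  larger, and total-count scaling transfers that composition bias onto
  every null gene — the realized FDR then lands well above the BH
  target. Median-of-ratios size factors (the median across genes of each
  sample's ratio to a per-gene reference) are robust to a 20% DE
  fraction and restore FDR control. This is the same reason real
  pipelines use TMM or median-of-ratios instead of raw library size.
* **The per-gene test.** Group sizes are equal by design and null genes
  have equal variances in both groups, so the pooled-variance t-test is
  exact under the null and keeps the full `2n - 2` degrees of freedom. A
  Welch test computes the same statistic here but its estimated df can
  collapse toward 2 for low-count genes, flooring the attainable
  p-values and understating power at the small n this module exists to
  explore. The pooled test is also the closer analogue of the
  moderated-t machinery used in standard differential-expression
  pipelines, while remaining deliberately simpler: no precision weights,
  no variance moderation. Because of that simplicity the simulator
  should be read as a slightly conservative planner — it will not
  overstate what a voom-style analysis can do.

The default scenario (10,000 genes, mean control count 100, target power
0.8 at FDR < 0.1, 25 replicates) reflects a typical filtered bulk
dataset; dispersion defaults to 0.015, a low-variability value estimated
from a well-behaved dataset, and should be replaced with the user's own
tagwise estimate — a vector of per-gene dispersions is accepted. The
mean control count is not recoverable from most published tables, so
scenarios must state it explicitly; 100 is a reasonable filtered-gene
average. The search caps at n = 30 per group by default, past which bulk
designs are rarely budgeted.

## The synthetic-data module

Every pipeline stage is testable without downloads because the generators
emit schema-valid files with *planted* truth:

* **Ortholog tables** draw similarities from class-separated ranges
  (High `>= 92`, Medium `[81, 88]`, Low `<= 75` — margins beyond the
  90/80 thresholds so recovery failures indicate code defects, not
  boundary noise), give a fraction of High genes exactly 100% similarity
  with missing dN/dS, plant dN/dS outliers on `[1, 3]` far above the
  bulk's (`[0.05, 0.25]`) upper fence, and mix in one2many rows.
* **Expression panels** use log-normal TPM noise (`sdlog` 0.3) around
  per-tissue means — TPM are continuous, so a count distribution would
  be the wrong noise model; the negative binomial is reserved for the
  power module's counts. Twelve CNS and 24 generic non-CNS tissues give
  a uniformly expressed gene an expected specificity of `log2(12/24) =
  -1`, matching the fact that most genes in a whole-body panel are not
  brain-specific. Planted effects are multiplicative: CNS fold 16
  (expected specificity 3), single-reward-tissue or
  cerebellum+spinal-cord enrichment fold 4 (≈ 4.6 residual SD on the
  log scale — detectable, while keeping a non-specific enriched gene's
  expected specificity safely below 0), whole-brain male/female fold
  2.5, and a caudate-only male fold 6 for interactions. Ages default to
  55-75 so the default cutoff keeps the panel balanced.
* **DEG lists** reproduce a requested overlap structure exactly
  (shared genes and direction concordance are constructed, then
  *measured* by the comparison routine).

What the generators do **not** emulate: correlated genes, batch
structure, realistic tissue-composition covariance, heavy-tailed TPM
noise, or GTEx's unbalanced donor design. Passing recovery tests
therefore demonstrates that the pipeline's logic is correct under its own
assumptions, not that those assumptions hold in any particular real
panel; real-data use goes through the same readers and functions but
deserves its own sanity checks (the reader's validation errors are
designed to surface the common problems: bracketed ages, unknown
tissues, mismatched samples).

## Problem sizes used by the test-suite and acceptance runs

Statistical property tests run on deliberately small inputs where
enumeration oracles are exact (group sizes ≤ 5 for rank tests, single-digit
cell counts for contingency enumeration, ≤ 4 groups for exhaustive CLD
checks). Simulation-based checks use 1,000-gene ortholog tables over 10
seeds, panels of up to 12 genes × 288 samples, and power scenarios of
2,000-10,000 genes × 25 replicates — sizes chosen so each suite settles
in seconds while Monte-Carlo error stays far below the tested margins.

## Known limitations

* dN/dS values are consumed, not estimated; ortholog calls drift across
  annotation releases, and profiles built from different releases should
  not be mixed.
* The dataset-relative dN/dS rule makes that one column incomparable
  across datasets (see above).
* The enrichment ANOVA treats donors as independent samples; real panels
  have donor-level correlation across tissues that this model ignores,
  as does the convention it follows.
* The power simulator's scalar-dispersion default understates the
  between-gene variance heterogeneity of real data; supply tagwise
  dispersions for planning real experiments.
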