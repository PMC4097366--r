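---
title: "Methods: yeast-augmented network analysis of disease-gene modifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: yeast-augmented network analysis of disease-gene modifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yana)
```

# The problem

When a human disease gene is expressed in fission yeast, deletion strains
whose growth is changed by that expression — synthetic lethal (SL) or
synthetic suppressor (SS) interactions — point at the genetic network the
disease gene operates in. This package implements the full downstream
analysis of such a synthetic genetic array (SGA) screen: hit calling from
colony-size grids, consensus ortholog mapping, protein-interaction
subnetwork construction in both species, network augmentation, and
cross-species overlap to nominate therapeutic-target candidates. Because
public screen data in this format are rarely machine-readable, every input
also has a seeded generator, so the whole pipeline is testable end to end
without downloads.

# The hit-calling statistic

The screen pins each deletion strain in quadruplicate (a 2x2 block of a
1536-format plate) under an inducing and a non-inducing condition. Scoring
proceeds in four steps.

**Plate-median normalization.** Colony areas are multiplicative: media
batches, pinning pressure and incubation shift whole plates by a common
factor. Each plate is divided by the median of its nonzero colony sizes, so
the median normalized colony is exactly 1 and plate effects cancel exactly.
Zeros encode missing or dead colonies and are excluded from statistics
rather than imputed; a pinning failure is indistinguishable from lethality
except through the condition contrast itself.

**Optional replicate exclusion.** A single aberrant colony in a
quadruplicate is removed when the coefficient of variation exceeds 0.35 and
removing the one value farthest from the median brings it back below the
threshold. At most one value is ever removed, never from fewer than three.
Scoring is offered with and without this rule as two first-class modes
(`replicate_exclusion` in `score_screen()` and the pipeline config),
because both conventions are in active use and they can disagree at the
margin.

**Log growth ratio.** Per gene,
`lgr = ln(mean non-inducing size / mean inducing size)`; positive values
mean induction slows that strain. Log-normal colony noise makes `lgr`
normal under the null, which the generators exploit (see below). A gene
dead in the non-inducing condition is dead regardless of induction and is
dropped; a gene dead *only* under induction is the strongest possible SL
candidate and is assigned the largest finite `lgr` on the screen plus one
population SD, flagged rather than infinite. A condition with a single
surviving replicate is insufficient support and the gene is dropped.

**Population z-score.** `z = (lgr - mean(lgr)) / sd(lgr)` over all
scoreable genes, with a two-tailed normal p-value. Centering on the
population matters: expressing the wild-type query gene slows *every*
strain, and a per-gene contrast against the non-inducing condition alone
would call the whole genome SL. Standardizing against the population
absorbs this genome-wide induction cost, leaving z to measure differential
response. Whether screens of this kind derive p-values from a z-test,
t-test, or a scoring service's internal model is usually unstated in
publications; we use the normal tail and say so in the audit output rather
than inferring someone else's choice.

Hits are genes with raw `p <= alpha` (default 0.05), split by sign into SL
(`z > 0`) and SS (`z < 0`), ranked by ascending p with ties broken by
`|z|` then gene ID. No multiple-testing correction is applied by default —
ranked raw-p lists at 0.05 are the convention this type of screen reports —
but a Benjamini–Hochberg mode is available (`adjust = "BH"`).

# Ortholog mapping

Yeast-to-human mapping is table-driven over several curated sources,
consumed as static TSVs. Two consensus policies are exposed: `union` (any
source suffices) and `majority` (a symbol must appear in more than half of
the sources that mention the gene). The default is union: curated resources
aggregated in this field rarely conflict for the conserved core genome, and
union maximizes network recall; majority is the conservative alternative
when sources disagree. One-to-many mappings are kept throughout. Coverage
is reported as a count and a percentage rounded to one decimal, the
precision such figures are conventionally printed at.

# Network construction and augmentation

Interaction data enter as STRING-style weighted edge lists (integer scores
0–1000, divided by 1000 on load), restricted to the experiments channel.
The confidence threshold is inclusive at 0.900, matching the "highest
confidence" preset of that scoring scheme; symmetric duplicates collapse to
the maximum score.

* **Primary network**: the subgraph induced on the hit set. Hits with no
  qualifying edge to another hit are retained as degree-0 *orphans*, not
  discarded — they are exactly what augmentation is for.
* **Clusters**: connected components of at least 2 members, sorted by size
  then smallest member.
* **Degree filter**: keeps hits with at least `k = 2` interactions with
  other hits. Degrees are measured once against the unfiltered hit-induced
  subgraph and survivors are re-induced in a single pass — deliberately
  *not* an iterative k-core, because the selection criterion is "interacts
  with at least two screen hits", judged against the full hit set.
* **Extension**: adds all first-degree neighbors of hits and every
  qualifying edge among the extended node set, including neighbor–neighbor
  edges. The open design choice here was whether to admit neighbor–neighbor
  edges at all; we include them because the extended map is meant to show
  the local interaction neighborhood faithfully, and excluding such edges
  fabricates star topologies. A neighbor may well be an essential gene
  absent from the deletion library, which is the scientific rationale for
  extending at all.
* **Orphan rescue**: a non-hit node of the extended network adjacent to at
  least two orphans joins them into a cluster and is promoted as a new
  candidate. "Orphan" is operationalized as zero degree in the thresholded
  primary network. The implementation is cross-checked in the test suite
  against a brute-force enumerator on hundreds of random graphs and an
  exhaustive sweep of all 1024 edge subsets of a 5-node template.
* **Cross-species overlap**: every node of the extended yeast network is
  humanized through the ortholog tables and intersected with the human
  primary network's nodes; each shared symbol is reported with its yeast
  provenance (hit / rescued / neighbor). Species ID spaces never mix inside
  one graph; the ortholog map is the only crossing point.

Networks export deterministically to SIF and GraphML (node attributes
`species`, `role`; edge attribute `confidence`), byte-identical across
repeated exports.

# Phenotype summaries

The downstream validation assay scores motor axons per embryo (20 scored:
myotomes 6–15, both sides) and bins embryos into severe / moderate / mild /
no-defect categories. Published work of this kind does not print its bin
edges, so the bins are configuration with documented defaults
(`none = 0`, `mild = 1–3`, `moderate = 4–7`, `severe = 8–20`) that must
partition 0..20; tests use the generator's own bins, never guessed ones.
Percentages are computed per independent experiment (summing to 100
exactly) and summarized as mean ± SEM *across experiments*, matching the
"n per experiment" reporting convention — SEM across embryos would
understate between-experiment variability. Group comparisons use a
chi-square test of homogeneity on pooled counts with a Fisher-exact
fallback when any expected count is below 5; the test's identity is always
part of the output, and no attempt is made to reproduce any particular
published p-value whose test is unidentified.

# What the generators emulate

`simulate_screen()` builds colony sizes as
`200 x plate_effect x gradient(row, col) x condition_factor x gene_effect
x exp(N(0, sigma^2))`:

* log-normal noise, `sigma = 0.1` — colony areas are positive and
  heteroskedastic, and the log-normal choice makes `lgr` exactly normal
  under the null so calibration tests have clean expectations;
* per-plate multiplicative effects, `sigma = 0.15`, drawn independently per
  (plate, condition) since the two conditions are different physical
  plates;
* a linear row+column gradient of amplitude 0.1 (±10% corner to corner),
  emulating edge and pinning gradients;
* a genome-wide induction cost of 0.8 on inducing plates, kept as a
  separate factor from per-gene effects precisely so that hit calling must
  demonstrably absorb it via population centering;
* planted SL genes at multiplier 0.5 and SS genes at 1.5 on inducing
  plates, with disjoint planted sets and a ground-truth table returned for
  recovery tests.

What it does **not** emulate: pinning-failure dropouts, agar-edge nonlinear
trends, colony-shape artifacts, mating/germination efficiency of the SGA
cross, or correlated neighbor effects. Passing recovery tests therefore
demonstrates the statistic's behavior under its own model assumptions, not
robustness to every artifact of real plates; the plate-median normalization
and CV exclusion are the designed defenses for the latter and are tested on
their own contracts.

`simulate_ppi()` draws a preferential-attachment graph (attachment 2, the
standard scale-free-ish null for PPI degree distributions), scores
background edges above threshold with a configurable probability, and
plants modules as cliques scoring ≥ 900. `simulate_orthologs()` maps each
gene with probability 0.838 — a realistic conserved-core coverage for
fission yeast against human — with 10% one-to-many expansions, four
sources, 20% per-source dropout, and a guarantee that every true pair
survives in at least one source. `simulate_embryos()` inverts the severity
bins exactly. Every generator saves and restores the caller's RNG state and
is bit-reproducible from its seed.

# Numerical choices and degenerate inputs

* All confidence comparisons are inclusive (`>=`).
* Tie-breaks are total and documented (hit ranking: p, then `|z|`, then
  gene ID; cluster ordering: size, then smallest member; exports:
  lexicographic), so all outputs are deterministic.
* An all-zero plate, a zero population SD, fewer than 20 scoreable genes,
  non-partitioning severity bins, and out-of-range scores or coordinates
  are hard errors naming the offending input, not warnings.
* `alpha = 0` is rejected (`p <= 0` is unsatisfiable by a two-tailed normal
  p except at exact zero); a vanishingly small alpha yields empty hit
  tables and the pipeline completes with empty-but-valid downstream
  outputs.
* The imaging day is a selector (`day` argument), not a guess: screens of
  this design document plates over several consecutive days and which day
  enters scoring is a user decision.

# Problem sizes in the test suite

The packaged tests run the calibration and recovery suites at 2000 genes
(4 replicates, 2 conditions, 6 plates per screen) across 5 fixed seeds,
the rescue-oracle comparison on 200 random graphs of up to 12 nodes plus
the exhaustive 1024-configuration template sweep, and module recovery on a
200-node generated network — sizes chosen so the entire suite completes in
well under a minute on one core while leaving the binomial error bounds
tight enough to be meaningful (3 SDs at n = 2000 is ±1.5 percentage points
around the nominal 5% type-I rate).

# Known limitations

* Published cluster counts from historical interaction-database snapshots
  are not reproducible from synthetic networks, and no attempt is made;
  what is preserved and tested is the logic that produced them, at toy and
  simulated scale.
* The scoring scheme is a documented reimplementation of the standard
  log-growth-ratio statistic, not a bit-compatible clone of any particular
  screen-scoring service.
* Spatial correction beyond plate-median normalization (row/column lowess)
  is out of scope; the generator's gradient cancels in the condition
  contrast by design, and real gradients that differ between condition
  plates would require such a correction.
* Ortholog mapping is strictly table-driven; no sequence-based inference
  or paralog disambiguation.
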