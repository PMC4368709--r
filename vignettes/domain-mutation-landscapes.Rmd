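---
title: "Methods: domain-level mutation landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain-level mutation landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainscape)
```

This vignette is the package's own account of the statistical model it
implements: the test designs, the tunable parameters, what the synthetic
cohort generator does and does not emulate, the numerical conventions, and
the design decisions that were genuinely open.

## The model

The unit of analysis is the **domain instance**: a specific amino-acid
subsequence of one protein matching a domain model (one Pfam-style hit on
one protein). A **domain type** is the model itself, which may have
instances in many genes. All coordinates are 1-based residue indices with
inclusive ranges, matching `p.X123Y` protein-change notation.

Inputs are (a) a table of somatic missense mutations (gene, protein,
sample, cancer type, protein change, predicted impact category), (b) a
table of domain-instance coordinates with E-values from a precomputed
domain scan, (c) a sample registry saying which samples were sequenced per
cancer type, and optionally gene labels, functional-site annotations, gene
sets and interaction-mediating domain pairs. Running the domain scan
itself, predicting impact, or lifting genomic coordinates are out of scope:
those arrive as columns.

Two filters precede everything: domain instances are kept only when
`e_value < 0.001` (the conventional domain-match confidence cutoff,
configurable), and mutations predicted to have *no* or *unknown* functional
effect are removed, keeping the `high`/`medium`/`low` impact categories.
Both filters are idempotent, and rows a reader cannot parse are skipped and
tallied in a machine-readable skip report rather than aborting a run —
COSMIC-derived tables are heterogeneous enough that a hard failure on one
malformed row is the wrong default.

### The SMD test

For each instance $i$ and cancer $c$ with at least one mapped mutation, the
2×2 table

$$\begin{array}{l|cc} & \text{in } i & \text{not in } i\\\hline
c & a & b\\ \text{other cancers} & c & d \end{array}$$

is tested with a two-sided Fisher's exact test. The "not in $i$" column
counts **all other damaging mutations of the analysed protein set**, not
just the same gene. This dataset-wide, cross-cancer contrast is the core of
the design: an instance is called only when its mutational enrichment in
cancer $c$ exceeds what the same instance shows in all other cancers
pooled, which implicitly controls for regional differences in background
mutation rate (a region that is mutable in every cancer will inflate $c$ as
much as $a$). Calls require `p < smd_alpha` (default $10^{-7}$),
Benjamini–Hochberg adjusted `p < smd_fdr` (default 0.05) and odds ratio
$> 1$: the analysis reports enrichment only, never depletion, so the
direction constraint is explicit.

A mutation overlapping $k$ instances is mapped to all $k$, and each
instance's test is assembled independently, so results for one instance do
not depend on the presence of overlapping instances. Mutations matching no
instance still count in $b$ and $d$.

### The hotspot test

Within every instance of a gene carrying at least one SMD, each residue
with at least one mutation in a focal cancer is tested with the analogous
table one level down: (this residue vs the instance's other residues) ×
(focal cancer vs all other cancers), restricted to mutations mapped to that
instance. Thresholds default to `p < 0.01` and BH `FDR < 0.05`, again with
an enrichment-direction requirement.

Whether the per-residue test should condition on the instance or on the
whole gene was an open design point; we condition on the instance, because
the SMD stage has already localised the signal there and the instance is
the unit whose length normalisation we trust. Note the consequence: the
test only has power when the instance carries appreciable mutation mass
*in other cancers* (the comparison column). A residue can hold every single
focal-cancer mutation of its instance and still not reach $p < 0.01$ if
other cancers contribute only two or three mutations to the instance.

### BH families

One adjustment family covers all executed SMD tests; a separate family
covers all executed hotspot tests. Per-analysis global families are the
most conservative reproducible reading of "FDR < 0.05 per analysis", and
keep calls invariant to how results are later grouped or filtered.

### Downstream interpretation

* **Hotspot ratio** — per (gene, cancer) with ≥ 1 SMD: hotspot positions
  divided by distinct mutated positions within the gene's SMDs, a number in
  $[0, 1]$. Distinct mutated positions are counted per instance over the
  residues the hotspot scan actually tested (those mutated in the focal
  cancer).
* **Oncogene vs tumor-suppressor comparison** — two-sided Mann–Whitney U on
  the ratio, exact when the pooled sample is ≤ 20 without ties, otherwise
  the normal approximation with tie and continuity corrections. The
  comparison unit is the (gene, cancer) profile; the alternative (per gene,
  pooling cancers) was rejected because a gene can genuinely behave
  differently in different cancers, which is precisely the signal of
  interest.
* **Classification** — a decision threshold on the ratio minimising the
  misclassification count over labeled profiles, ties broken toward the
  midpoint of the optimal threshold interval (intervals bounded to
  $[0, 1]$, adjacent tied-optimal intervals merged before taking the
  midpoint). Profiles with fewer than 3 distinct mutated residues are left
  `undetermined` — with one or two residues the ratio is almost
  uninformative about a distribution pattern.
* **Functional-site overlap** — hotspots of labeled genes cross-classified
  by class × at-functional-site, matched exactly on (gene, residue); no
  positional tolerance window, since both hotspots and site annotations are
  residue-precise. Percentages are reported unrounded alongside
  nearest-integer rounding. The estimate is the unconditional sample odds
  ratio $ad/bc$ — a reproducible closed form — not the conditional MLE that
  some software prints; zero cells yield `Inf`/`NaN` rather than a
  continuity-corrected value, preferring transparency over smoothing.
* **Cross-cancer sharing, pooling, co-occurrence, exclusivity** — instances
  significant in ≥ 2 cancers; hotspot positions pooled across instances of
  a domain type via model positions (from the instance's explicit
  protein→model map when present, else the linear offset
  `position − start + 1`); SMD pairs tested for co-occurrence across the
  focal cancer's samples; and a per-sample exclusivity check that no single
  tumor sample is mutated at the same pooled hotspot position in two
  instances of the same type.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `smd_alpha` | $10^{-7}$ | per-test p cutoff for SMD calls |
| `smd_fdr` | 0.05 | BH ceiling, SMD family |
| `hotspot_alpha` | 0.01 | per-residue p cutoff |
| `hotspot_fdr` | 0.05 | BH ceiling, hotspot family |
| `evalue_cutoff` | 0.001 | domain-match E-value ceiling |
| `damaging_categories` | high, medium, low | impact categories retained |

The stringent SMD alpha reflects that genome-scale cohorts contain a high
proportion of passenger mutations; a conservative threshold trades
sensitivity for a clean candidate list.

Densities are mutations per megabase of domain-encoding DNA per sample,
`count × 10^6 / (3 × length_aa × n_samples)`; the factor 3 converts
amino-acid length to coding nucleotides. Per-sample normalisation makes
cancers with very different cohort sizes comparable; it is a documented
package convention, since published density figures in this area are not
always reconstructible from any single normalisation.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the statistical structure the
detection stack assumes, plus ground-truth tables for recovery testing.
The generative model, per cancer $c$, sample $s$, gene $g$, residue $r$:

* a damaging missense mutation occurs with probability $\mu$ (default
  $4 \times 10^{-5}$ per residue per sample), independently across
  (sample, residue), with at most one mutation per (sample, residue) —
  recurrence is counted across patients, not within one patient;
* planted SMD cells multiply the per-residue rate by a fold $f > 1$
  (default 20) inside one instance for one cancer — the detection statistic
  is a rate contrast, so the effect is planted multiplicatively on the
  rate;
* `cross_cancer_fold` (default 1) multiplies a planted instance's rate in
  the *other* cancers. Values > 1 emulate the empirical pattern of real
  driver domains — the DNA-binding domain of a tumor suppressor is mutated
  in many cancer types while being disproportionately enriched in some.
  This matters for validating the hotspot stage: its contingency design
  compares against other cancers, so without cross-cancer mutation mass in
  the instance the comparison column is nearly empty and no residue can
  reach significance, however concentrated the focal cancer's mutations
  are;
* oncogene-like planted instances redirect each of their mutations, with
  probability $\rho$ (default 0.8), onto one of $h$ designated hotspot
  positions (default 2, uniform among them), otherwise place it uniformly
  over the instance; tumor-suppressor-like instances place all mutations
  uniformly — concentrated versus dispersed within-domain patterns;
* a fraction of records (default 0.2) is downgraded to impact
  `none`/`unknown` to exercise the damaging filter; reference/alternate
  residues are uniform over the standard alphabet with ref ≠ alt;
* functional sites are planted on oncogene-like hotspot positions with
  probability 0.8 and padded with random positions, so site-overlap
  statistics have signal to find.

Defaults describe a cohort of 4 cancer types × 250 samples and 50 genes ×
3 domains of 150 aa with 20-aa linkers — large enough that the SMD test
operates in its intended regime (hundreds of mutations per cancer),
small enough that a full generate-and-scan cycle takes about a second.

The random stream is partitioned by (cancer, gene): each block seeds its
own generator from a deterministic function of (seed, cancer index, gene
index), so enlarging the cohort leaves existing blocks' draws untouched and
regression tests stay stable. Output is byte-identical for identical
configurations.

Deliberate simplifications: every generated instance gets a **unique
domain accession**, so pooled domain-type analyses on generated cohorts are
trivially instance-confined — cross-gene pooling and its exclusivity
property are exercised with hand-built multi-gene fixtures instead; and
there is no trinucleotide signature structure, no isoform diversity, no
copy-number or indel events, and no inter-sample rate heterogeneity.
Passing recovery tests therefore demonstrate that the statistics detect the
effects they target under a clean null, not that the pipeline is robust to
every artefact of real tumor sequencing data.

## Numerical conventions

* Fisher's exact test enumerates the hypergeometric support in log space
  (`lchoose`); the two-sided p sums probabilities
  $\le P(a) \cdot (1 + 10^{-7})$ — the relative tolerance absorbs
  floating-point ties, matching the convention of standard statistical
  environments.
* `bh_adjust()` is a validated front-end over `stats::p.adjust(method =
  "BH")`; `mann_whitney_u()` over `stats::wilcox.test()` with the exact /
  approximate switch described above.
* Heat-map export clips p-values below at $10^{-300}$ before $-\log_{10}$.
* Gene-level outputs aggregate isoforms by union of instances; mapping and
  statistics are keyed by `protein_id` throughout, since domain coordinates
  are isoform-specific.
* Writers emit TSV with headers, deterministic row order and full double
  precision; every writer/reader pair round-trips exactly.

## Validation layout

The test suite validates each operation against independent oracles:
Fisher p-values against full enumeration with factorial-based
probabilities, BH against the raw step-up rule, Mann–Whitney against
assignment enumeration, and the scans against hand-built cohorts with
known contingency tables. Recovery experiments run at the default
generator scale: planted-SMD recovery over 5 seeds, null calibration over
20 seeds with no planted effects, hotspot-pattern recovery (concentrated
vs dispersed) with 20 planted genes at fold 60 and `cross_cancer_fold` 10,
and exclusivity over 10 seeds. These sizes keep the whole suite around a
minute while leaving the binomial noise small relative to the planted
effects.

## Known limitations

* The hotspot test inherits the power constraint discussed above: genes
  mutated in only one cancer type yield few or no hotspot calls regardless
  of concentration.
* The sample odds ratio differs from conditional-MLE estimates printed by
  some tools; no confidence intervals or mid-p variants are provided.
* The classifier is a single threshold on one statistic; it is meant as an
  operationalisation of "pattern similarity", not a tuned model.
* Gene symbols are matched verbatim; synonym resolution is the caller's
  responsibility.
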