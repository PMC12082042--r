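---
title: "Methods: BCR repertoire measures and exposure association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BCR repertoire measures and exposure association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrtools)
```

## Scope and data model

`bcrtools` analyzes targeted IGH repertoire sequencing from blood RNA in
epidemiological cohorts. The unit of input is an AIRR-standard
rearrangement row: one sequenced heavy-chain transcript with V/J/C calls,
the junction (CDR3) nucleotide sequence, and a precomputed count of bases
differing from the IMGT germline reference. Upstream alignment is out of
scope: the germline-mismatch count is consumed, never recomputed. The
participant metadata carry the exposure grouping (never / former /
cigarette / vaping / dual use), demographics, spirometry grouping, and
optional socioeconomic, CT, and genetic-similarity covariates.

## Clonal inference and the counting unit

Reads descending from one expanded B-cell clone must be counted once, or
expression and usage measures would simply measure clone size. Sequences
are partitioned by V **gene**, J **gene**, and junction length, then
single-linkage clustered within partitions under normalized Hamming
distance on the junction; components linked at distance ≤ 0.15 become
clones. The choices here:

- **Hierarchical distance clustering** was chosen as the clonal-inference
  method because it is deterministic, has a single interpretable
  parameter, and is directly checkable against a brute-force
  transitive-closure oracle (the test suite does exactly that). 0.15 is a
  conventional heavy-chain junction threshold; it is exposed as
  `distance_threshold` everywhere and clone counts are provably
  non-increasing in it.
- **Gene-level partition keys** (not allele-level): allele miscalls within
  a clone are common, and allele-level keys would fragment true clones.
- **Clone–isotype units.** A class-switched lineage observed as both IgM
  and IgA2 is biologically present in both compartments, so collapse
  yields one countable record per (participant, clone, isotype). Within a
  unit, the V allele is the member majority (lexicographic tie-break), the
  representative junction is the highest-abundance member's, and
  `abundance` sums member read support. Whether to merge isotypes within a
  clone instead was genuinely open; per-isotype counting was adopted
  because the isotype measures are defined per class and a merged unit
  would force an arbitrary class assignment.

## Per-participant measures

With `N` clone–isotype units for a participant and `n_c` of them in
subclass `c`:

| measure | definition | default knobs |
|---|---|---|
| isotype usage | `n_c / N` | — |
| isotype expression | `log2(n_c + 1)` | `pseudo_count = 1` |
| class switching | `#{switched & mutated} / N` | `mutation_gate = 1` |
| V-allele usage | `#{mutated units with allele a} / N` | — |
| CDR3 length | mean junction nt per subclass | `cdr3_stat = "mean"` |
| Hill profile | `(Σ p_i^q)^(1/(1−q))` | `q_grid = seq(0, 4, 0.1)` |

Decisions where the definitions left room:

- **Mutation gate.** "Mutated" means at least one base differing from
  germline (`mutation_count ≥ 1`). A stricter reading (≥ 2) circulates in
  some descriptions of switching; the gate is an integer argument to
  `collapse_clones()`, so the stricter variant is one flag away. The
  default follows the ≥ 1 definition because class-switch recombination
  accompanied by any somatic hypermutation already evidences germinal
  center activity.
- **Expression pseudo-count.** `log2(n_c)` is undefined at zero; the `+ 1`
  keeps empty subclasses at 0 on the log2 scale and is configurable.
- **V-allele denominator.** The numerator counts *mutated* units only; the
  denominator is **all** unique units, so per-allele usages do not sum
  to 1. The alternative (mutated-only denominator) was rejected because
  the stated definition divides by the total repertoire size.
- **CDR3 aggregator.** The per-participant summary statistic is the
  arithmetic mean; `median` is available since repertoire length
  distributions can be skewed. Subclasses with zero units are missing, not
  zero — a zero would masquerade as a 0-nt junction in the models.
- **Hill abundances** merge a clone's isotype records and sum read support
  (`duplicate_count`): diversity quantifies clonal expansion, which is
  read from read counts, and isotype splitting would inflate richness.
  Using unique-sequence counts per clone instead would compress the
  profile toward richness; read counts were adopted as the measure of
  expansion. `q = 1` uses the exponential-Shannon closed form (the
  `q → 1` limit; the suite verifies continuity to 1e-4 at `q = 1 ± 1e-6`),
  and log-Hill values are natural-log.

## Prevalence filter

Rarely expressed classes yield near-constant measures that waste multiple-
testing budget. A class is analyzable when **strictly more than 1%** of a
participant's unique sequences fall in it for **at least ⌈0.25 ·
n_participants⌉** participants; the filter runs separately for isotypes
and V alleles, and IgE is exempt (clinically important despite low
abundance). The boundary is deliberately strict-greater: a class sitting
exactly at 1% everywhere is dropped.

## Association framework

Each retained measure is modelled untransformed by ordinary least squares
(usage as fractions, expression on log2 scale, lengths in nt), with
exposure group referenced to **former smokers** — in a cohort where almost
everyone has smoked, former use is the natural baseline — and GOLD group
referenced to normal spirometry. The primary adjustment set is age, sex
(0 = female, 1 = male), race (0 = AA, 1 = NHW), exposure group, GOLD
group, pack-years, and inhaled-corticosteroid use; participants on oral
corticosteroids are excluded before modelling, and rows with missing
covariates are dropped (complete-case) with a logged count — no
imputation. Additional families: socioeconomic sensitivity (income +
area-deprivation index), genetic-PC sensitivity, race×exposure
interaction (cross-product terms are the terms of interest), and reduced
univariable COPD (GOLD + ICS only) and CT wall-area (wall area + scanner +
ICS) models.

Benjamini–Hochberg adjustment is applied **within an analysis family
across all (measure × term-of-interest) pairs** — terms of interest being
the exposure contrasts, demographics, and GOLD contrasts, not the
nuisance covariates. Family-wise pooling was chosen over per-measure or
global pooling because a family's tests answer one question and are
reported together; the boundary is a documented convention of this
package. Tiers: significant q < 0.05, suggestive q < 0.1. Coefficients,
standard errors, and t-based p-values come from the QR least-squares
solution with `n − k` residual degrees of freedom; the tests cross-check
them against an independent normal-equations evaluation to 1e-8.

## Synthetic cohort generator

The generator exists so the pipeline is testable end to end without
controlled-access human data. Defaults encode a 234-participant cohort
(44 former / 41 never / 41 vaping / 51 cigarette / 57 dual) with
covariate distributions matching a realistic smoking/vaping case-mix
(e.g. dual-users mean age 61.3 ± 6.5 y, 52.9 ± 25.3 pack-years, about half
male; never smokers fixed at 0 pack-years). Per participant it draws a
Poisson number of clones (mean 300 — a desk-scale repertoire size chosen
so full-cohort runs complete in seconds while leaving hundreds of units
per participant for stable fractions), then per clone: isotype from the
group mixture, V allele from a 12-allele panel, CDR3 length as a normal
rounded to a multiple of 3 and floored at 9 nt, a uniform-random junction,
a mutation flag (rate by switched status, realized as `1 + Poisson(2)`
mismatches), and a clone abundance from a discrete power law `P(k) ∝
k^−(1+1/shape)` — heavier-tailed for larger `shape`, giving one-parameter
control of clonal expansion and hence Hill diversity. Expanded clones may
surface as several near-identical member rows so the clustering stage has
real work to do.

Group-effect defaults follow the qualitative exposure pattern: dual-use
shifts the mixture toward IgA1/IgA2/IgG1/IgG2 and away from IgM, raises
switch-mutation rates, enriches IGHV5-51\*01 / IGHV1-18\*01 / IGHV3-7\*01,
and raises the clone-size shape; cigarette and vaping sit between dual
and former; never resembles former. These are direction conventions, not
calibrated magnitudes. What the generator does **not** emulate: SHM
lineage structure within clones, biologically realistic junction motifs,
germline-faithful V sequences, sequencing error, and isotype switching
within a single simulated clone. Passing tests therefore demonstrate the
pipeline's arithmetic and inferential behaviour, not biological fidelity
of any particular effect size.

## Numerical and degenerate-input conventions

- Junction distance links use `mismatches ≤ threshold × length`; ties at
  the boundary are links. Clone labels are the lexicographically smallest
  member `sequence_id`, making partitions order-invariant.
- Multi-allele calls resolve to the first listed allele; the majority and
  representative tie-breaks are lexicographic — all deterministic.
- Empty repertoires are errors at the measure level; cohort summarization
  skips and reports empty participants rather than failing.
- An exactly singular design matrix is an error (never silently dropped
  columns); factor levels absent from the data are dropped from the dummy
  expansion with the reference level's presence enforced.
- The type-I and recovery properties of the association stage are
  exercised at 40–200 participants with 28 measures and 50–200 replicates;
  the end-to-end determinism check runs the full 234-participant default
  twice. These sizes are the package's test conventions and can be scaled
  up by the user.

## Known limitations

- OLS on fractions can in principle predict outside [0, 1]; the measures
  analyzed here sit well inside the interval, matching the framework this
  pipeline mirrors, but logistic or beta regression would be a natural
  extension.
- Single-linkage clustering can chain distinct clones through
  intermediates in very dense partitions; at realistic junction diversity
  this is rare, and the threshold is tunable.
- The prevalence filter is applied to whatever cohort is supplied;
  filtering and modelling on the same cohort means retained-measure
  selection is not accounted for in the q-values.
- No rarefaction or richness correction: participants with very different
  sequencing depths are compared on raw clone counts.
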