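---
title: "Candidate-gene prioritization in inbred rat strains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene prioritization in inbred rat strains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catifunnel)
```

# The problem

The Ihara Cataract Rat (ICR) develops cortical lens opacity between 4 and 8
weeks of age; crosses with wild-type animals produce unaffected offspring,
so the causal mutation is recessive. Two linkage loci are known from the
closely related IER model: *Cati1* on chromosome 8 (cataract formation) and
*Cati2* on chromosome 15 (cataract timing), each delimited by SSLP markers.
catifunnel implements the three evidence arms used to prioritize candidate
genes in this setting — an expression screen around the opacity onset, an
RT-qPCR validation layer, and a whole-genome variant-prioritization funnel —
together with generators of synthetic inputs carrying planted ground truth.

# The expression screen

The screen operates on normalized, linear-scale signal matrices (genes ×
samples) for a case strain (3 replicates per timepoint) and a control
strain (1 replicate per timepoint) at 4, 8 and 10 weeks.

**Stages.** (1) Genes with signal below the detection floor in *all*
samples are removed — the rule is "strictly below everywhere", so a single
sample at the floor keeps the gene. (2) Group means are taken per (strain,
timepoint); single-replicate groups pass through unchanged, which is the
only reading compatible with an n = 1 control design — fold changes are
ratios *of group means*, never means of per-replicate ratios. (3) A gene is
*increased* in a contrast when mean(test)/mean(reference) > 1.5 and
*decreased* when mean(reference)/mean(test) > 2.25. Both inequalities are
strict ("more than"), so a ratio of exactly 2.25 is not called. The
asymmetry of the two defaults reflects the original screen design and both
are configuration values, not constants. (4) The 4→8 and 4→10 week sets are
unioned per direction. (5) Control-strain sets are subtracted from the case
sets (Venn exclusion): changes shared with the control strain are
attributed to normal lens maturation.

**Numerical choices.** Genes with a zero group mean in a denominator are
excluded from that side of the contrast and reported in the `flagged` field
rather than producing infinities. The detection floor (default 5 signal
units) is applied per strain dataset, before group means, on the linear
scale; if a file stores log2 signals the reader de-logs on an explicit flag
(`delog = TRUE`) — there is no auto-detection, because a wrong guess would
silently square or root every fold change. Fold-change calls are invariant
under rescaling all signals by a positive constant; the detection floor is
deliberately *not* scale-invariant since it is an absolute detection limit.

# RT-qPCR validation

Relative expression is quantified as $2^{-(Ct_\mathrm{target} -
Ct_\mathrm{reference})}$, i.e. the efficiency-2 ΔCt model against a
reference gene (*Gapdh* in the motivating design). Per-figure rescaling to
a baseline group is presentation only and is kept out of the statistics.

The two-sample test between the 4-week group and an 8- or 10-week group is
*gated*: a two-tailed variance-ratio *F*-test at α = 0.05 decides between
Student's *t*-test with pooled variance (homoscedasticity not rejected) and
Welch's *t*-test with Satterthwaite degrees of freedom. The gate itself is
a design choice — the motivating protocol states only that the test was
chosen by "homoscedasticity approval" — and the classical *F*-pre-test is
the standard formalization paired with a Student/Welch switch. Degenerate
inputs are defined explicitly: two all-constant samples have equal
variances by construction (gate returns `TRUE`), and the t-test on two
constant samples returns p = 1 at equal means and p = 0 otherwise.

A gene is `case_only_increased` when significantly increased (*P* < 0.05,
two-tailed) in the case strain in at least one contrast and not
significantly increased in the control strain in any contrast;
`both_increased` genes are interpreted as maturation markers. A significant
*decrease* in the control strain does not disqualify a case-only call: the
rule keys on increases only. No multiple-testing correction is applied,
matching the per-gene *P* < 0.05 convention of the validation design this
reproduces; users screening many genes should treat the labels as
descriptive, not as FWER-controlled discoveries.

Under null simulation (equal means and variances, n = 4 vs 3 — the group
sizes of the motivating design) the gated test holds its nominal type-I
error: the acceptance script recomputes this rate at 10,000 simulations.

# The variant funnel

Every stage is a pointwise, monotone filter over (chrom, pos, ref, alt)
atoms; multi-allelic sites are decomposed at read time, and per-stage
input/output counts are recorded.

* **Homozygosity.** Only `hom_alt` genotypes survive; missing genotypes
  are removed because absence of evidence is not evidence of homozygosity.
* **Impact class.** Sequence-ontology consequence terms map to the
  conventional HIGH/MODERATE/LOW/MODIFIER vocabulary (the SnpEff-style
  table shipped as `so_impact_table()`, user-overridable); several terms on
  one record combine by maximum severity. Unknown terms classify as
  `UNCLASSIFIED` rather than being dropped. MODERATE (missense, in-frame
  single-codon indels) and HIGH (stop gain/loss, frameshift, splice-site
  disruption) variants are tracked as separate funnel tracks.
* **Dual-assembly concordance.** A variant is kept only if the call set
  against the second assembly contains a match. Because the assemblies
  disagree on coordinates, the default key is coordinate-free: (gene
  symbol, ref, alt, most severe SO term). A pure-coordinate mode exists for
  same-assembly comparisons. The choice is a design decision: gene-anchored
  matching is the only coordinate-free key available without a liftover
  chain, at the cost of excluding records with no gene symbol (done loudly,
  with a warning).
* **Strain-panel exclusion.** A case variant carried by *any* panel strain
  at *any* zygosity is excluded by default: under a recessive model a
  homozygous non-affected carrier is decisive, and a heterozygous carrier
  still makes the allele an old segregating polymorphism rather than a
  strain-specific mutation. `hom_only = TRUE` gives the strictly recessive
  alternative.
* **Locus restriction.** Intervals are 1-based with both endpoints
  inclusive, matching the "from marker A to marker B" phrasing of linkage
  intervals.

**Marker-offset estimation.** When a marker has a published position on one
assembly only, its position on the other is estimated as the anchor's
target position minus the signed source-assembly distance to the anchor.
This assumes local colinearity (no inversion or net indel between marker
and anchor) and is deliberately the naive estimate rather than a chain-file
liftover; the assumption is recorded in the estimator's output. On the
shipped marker table this reproduces the *Cati2* start, 32,677,550, from
the 20,135,471-base inter-marker distance. The table's Rnor_6.0 rows are
synthetic placeholders — only that distance is real, as documented in the
file itself.

# Synthetic data: what it does and does not emulate

The generators are pure functions of (spec, seed): the caller's RNG state
is saved and restored, same seed gives bit-identical output.

**Expression.** Baselines are log-normal (meanlog log 100, sdlog 1 —
a right-skewed signal distribution typical of linear-scale array
summaries); replicate noise is multiplicative log-normal with default sd
0.05 on the natural-log scale (≈ 0.07 log2 units, the low end of replicate
scatter for pooled-tissue arrays). Planted classes multiply the 8- and
10-week means: case-only up (fold 2), shared maturation up (fold 2, both
strains), case-only down (fold 3), null. The defaults place planted
effects several noise standard deviations beyond the 1.5/2.25 thresholds
even for the n = 1 control groups, so exact recovery (precision = recall
= 1) is a construction guarantee of the default spec, and the planted
baselines are truncated above twice the detection floor so the low-signal
filter cannot delete a planted gene. What this does *not* emulate:
probe-level effects, correlated genes, batch structure, or genes near the
threshold — a passing recovery test validates the set logic, not the
screen's behaviour on marginal real-data fold changes.

**Variants.** Background variants (random position outside the target
locus, mixed genotypes/impacts/panel sharing/assembly presence) plus five
decoy classes planted inside the locus, each violating exactly one stage
(heterozygous; panel-shared; absent from assembly B; off-locus; LOW
impact), plus one causal variant constructed to pass everything. The two
assemblies differ by a uniform per-chromosome shift — intentionally the
same colinearity model the marker estimator assumes, so estimator exactness
is testable. Not emulated: linkage disequilibrium, mutation-rate
heterogeneity, annotation errors, or coordinate rearrangements between
assemblies (which would break both the gene key and the offset estimator in
characteristic ways).

**qPCR.** Target cycles are reference cycle + baseline ΔCt − log2(planted
fold) + Gaussian noise (default sd 0.2 cycles). Not emulated:
amplification-efficiency deviations from 2 and plate effects.

# Defaults, units, problem sizes

| Parameter | Default | Units / meaning |
|---|---|---|
| `up_threshold` | 1.5 | linear fold, test/reference, strict |
| `down_threshold` | 2.25 | linear fold, reference/test, strict |
| `signal_floor` | 5 | linear signal units; keep if any sample ≥ floor |
| `alpha_test` | 0.05 | two-tailed t-test significance |
| `alpha_homoscedasticity` | 0.05 | two-tailed F-test gate |
| expression sim | 2000 genes, 20+20+20 planted | default study size |
| variant sim | 500 background, 5 decoys/mode, 10 panel strains | default funnel size |

The test suite exercises the property checks at sizes chosen to make the
checks sharp but quick on a single CPU: 1000 random variant sets for funnel
monotonicity, 200 random set pairs for inclusion–exclusion, 10,000 null
simulations for the type-I error of the gated test (Monte-Carlo standard
error ≈ 0.002 at α = 0.05), and the default generator specs for
planted-truth recovery.

# Other design decisions

* Stage logging (input count, output count, parameters) goes to standard
  error via R conditions but is gated behind
  `options(catifunnel.verbose = TRUE)`, which the CLI wrapper enables;
  programmatic use stays quiet by default.
* Reports serialize as JSON (counts, parameters) plus TSVs (surviving
  items); counts are computed from the same sets that are serialized, and
  all output is canonically sorted so reruns are byte-identical.
* Configuration comes from YAML with unknown keys rejected; the CLI refuses
  to run analyses without an explicit `--config` or `--defaults`.
* Annotation dialect: the SnpEff-style `ANN` INFO field is the accepted
  dialect because its four-level impact vocabulary maps one-to-one onto the
  moderate/severe classes the funnel needs; the impact is always recomputed
  from the SO terms so it remains a pure function of the annotation.

# Known limitations

* The expression screen has no error model: with one control replicate a
  fold-change threshold is the only defensible statistic, but it cannot
  separate biological change from control-sample noise — that is what the
  qPCR layer is for.
* Gene-anchored concordance cannot distinguish two identical-allele
  variants in the same gene with the same worst consequence; on desk-scale
  inputs this is harmless, at genome scale it slightly over-matches.
* The offset estimator is only as good as local colinearity; across real
  assembly rearrangements it is wrong by construction and should be read as
  the historical method, not a liftover replacement.
* The shipped panel stub carries a single membership fact and stands in for
  real panel call sets, which are far larger; panel exclusion at genome
  scale should be fed real VCFs via the panel manifest.
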