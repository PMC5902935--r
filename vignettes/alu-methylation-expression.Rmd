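---
title: "Methods: Alu insertion enrichment, COBRA methylation and AluS expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Alu insertion enrichment, COBRA methylation and AluS expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alupipe)
```

# The question and the design

Alu elements are ~300 bp primate SINE retrotransposons present in more than
a million copies in the human genome. They are CpG-rich, so their
methylation contributes a large share of all methylated cytosines, and an
Alu copy inserted into a gene (intron, exon, exonized segment or promoter)
can alter that gene's regulation. `alupipe` implements an integrated
analysis of this idea in the context of autism spectrum disorder (ASD)
blood samples and lymphoblastoid cell lines (LCLs):

1. call differentially expressed genes (DEGs) in case/control blood
   transcriptome matrices;
2. test whether DEG lists are enriched for Alu-inserted genes, per
   insertion type and regulation direction, and intersect the per-study
   significant lists into a reproducible gene set;
3. quantify global AluS methylation (level and two-CpG patterns) from
   COBRA gel band intensities;
4. quantify AluS expression from qPCR Ct tables by `2^-ddCt`;
5. compare both between phenotypic subgroups and correlate methylation
   patterns with expression.

Every stage has a matching synthetic-data generator with planted ground
truth, so the whole workflow is testable end to end without external
downloads. The `analysis/` scripts run the stages in order on one
simulated cohort.

# DEG calling

Matrices are gene × sample intensity tables with explicit missing values.
A presence filter retains genes observed in at least 70% of samples (the
boundary is inclusive; the fraction is computed over all samples jointly,
not per group, because the filter models transcript detectability rather
than group structure). Per gene, a two-tailed two-sample t-test compares
cases with controls on the non-missing values; missing entries are omitted
pairwise, never imputed. The pooled-variance Student test is the default —
the classical microarray-viewer behaviour this stage reproduces — with
Welch behind `var_equal = FALSE`. Bonferroni adjustment uses the number of
genes actually tested (genes with fewer than two values in a group are
excluded and flagged, and do not inflate the correction factor). A gene is
a DEG when the adjusted p-value is below `alpha` (default 0.05), with
direction from the sign of the case-minus-control mean.

Input is assumed gene-level. For probe-level matrices,
`collapse_probes()` optionally keeps the most significant probe per gene;
it is off the main path because probe handling is a platform decision the
analysis does not want to hide.

# Enrichment and the reproducible gene set

For each study, the tested (post-filter) genes form the universe — not the
whole annotation — because enrichment must condition on testability. The
DEGs of a stratum (insertion type × direction; 5 × 3 = 15 strata by
default) are classified into the 2×2 crosstab

|            | Alu-inserted | not inserted |
|------------|:---:|:---:|
| DEG        | a | b |
| non-DEG    | c | d |

and tested with a two-sided Fisher exact test. Genes absent from the
annotation count as "without Alu": membership is positive evidence only.
Benjamini–Hochberg adjustment spans the 15 strata of one study, mirroring
a per-study correction; `0.05` on the adjusted value declares
significance.

The reproducibility step intersects per-study gene lists: by default the
downregulated DEGs carrying any Alu insertion, taken only from studies
whose down × all-insertion stratum was significant (significance gating),
kept when supported by at least two studies. All three choices
(direction, insertion type, `min_support`) are arguments.

The exact test, BH and Bonferroni adjustments, and the Pearson
coefficient are implemented in the package (log-space factorials; the
minimum-likelihood two-sided convention, i.e. the summed probability of
all tables with the observed margins no more likely than the observed
one, within relative tolerance 1e-7). Mid-p and tail-doubling variants
exist in the literature; the minimum-likelihood rule is the convention of
mainstream implementations and the test suite pins the implementation to
an independent enumeration oracle for every table with total up to 40,
and to the reference adjustment implementations on random inputs.

# COBRA quantification

Bisulfite conversion deaminates unmethylated cytosines; a methylated CpG
in either of the two interrogated positions of the 133-bp AluS amplicon
retains a TaqI site (TCGA) and is cut. The four molecule states therefore
produce distinct fragment sets:

| state | fragments (bp) |
|-------|----------------|
| uCuC  | 133 |
| mCuC  | 90 + 43 |
| uCmC  | 75 + 58 |
| mCmC  | 58 + 43 + 32 |

Band intensity percentages are divided by fragment length — `%133/133 =
A`, `%58/58 = B`, `%75/75 = C`, `%90/90 = D`, `%43/43 = E`, `%32/32 = F` —
because an intercalating stain reports mass, and mass/length is molarity.
The estimator is then evaluated verbatim:

$$\%mC = 100\,\frac{E + B}{2A + E + B + C + D}, \qquad
\%mCmC = 100\,\frac{F}{A + C + D + F},$$

with `%uCmC`, `%mCuC`, `%uCuC` given by C, D and A over the same
denominator. The four pattern percentages are closed (sum to 100). The
formulas are kept as printed even where redundant encodings exist (mCmC
is represented by both the 43- and 32-bp bands but estimated from F
alone): fidelity to the published estimator matters more than algebraic
economy, and under the forward model the printed `%mC` formula is exactly
the methylated-locus fraction

$$\%mC = 100\left(\tfrac{p_{mu} + p_{um}}{2} + p_{mm}\right),$$

as the round-trip tests verify to 1e-9. Note that on real gels the `%mC`
and pattern estimators use different band subsets and need not be
mutually consistent; the identity `%mC = (%mCuC + %uCmC)/2 + %mCmC` is
asserted only on noise-free forward-simulated profiles.

The forward simulator models complete TaqI digestion by default. A
`digestion_efficiency < 1` exists in the simulator only, to probe
estimator bias (an uncut methylated site leaves the molecule looking
unmethylated at that site, biasing all methylation quantities downward).
Gel quantification noise is multiplicative lognormal per band
(mean-preserving, constant CV), matching densitometry error on positive
intensities.

# qPCR quantification

Per sample, `dCt = mean(Ct target) - mean(Ct reference)` over replicates,
and `ddCt = dCt - mean(dCt of controls)`. The group fold change is
`2^(-mean ddCt of cases)` — the geometric mean of per-sample relative
expression — because the reported FC/log2(FC) pairs this package
reproduces (1.75/0.81, 3.68/1.88) are internally consistent with that
definition; the arithmetic-mean alternative sits behind
`fc_method = "arithmetic"`. Group differences are tested on dCt values,
which are approximately normal, never on exponentiated fold changes.
Amplification-efficiency correction (Pfaffl) is out of scope.

# Group comparisons and correlation

Methylation comparisons are unpaired two-tailed t-tests per metric, with
BH adjustment across the five metrics of one comparison — matching the
per-comparison row structure of the cohort this emulates. Matched
case–control pairs are handled by matching, not pairing: the emulated
study reports group means, not pair differences, so unpaired tests are
used. Correlation is Pearson (the emulated analyses report a plain
coefficient *r*); Spearman is available since gel-derived percentages may
be non-normal.

# What the generators emulate — and what they do not

* **Expression** (`generate_expression_study`): i.i.d. normal intensities
  (gene means N(8, 1), unit residual SD), a planted DEG fraction (default
  5%, effect 3 SD, half down), completely-at-random missingness (default
  10%), and a 60% Alu-inserted universe whose downregulated DEGs are
  drawn with an odds multiplier (default 1 = null; the planted scenarios
  use 3). The generator omits gene–gene correlation, batch structure and
  platform effects; passing tests therefore show calibration and power
  under independence, not robustness to correlated noise. Between-sample
  sizes (20 vs 20 by default) are kept modest so the simulation suites run
  in seconds; the enrichment operating-characteristic runs use 2000-gene
  null universes and 5000-gene planted universes, 200 and 60 replicates
  respectively.
* **Annotation** (`generate_annotation`): independent per-type membership
  with frequencies 0.12/0.06/0.95/0.04 (exonic/exonized/intronic/
  promoter) among inserted genes, matching the intronic-dominated type
  distribution of TranspoGene-style hg18 gene lists.
* **COBRA** (`generate_cobra_cohort`): group state-mixtures taken from
  the reported LCL cohort values (e.g. control uCmC ≈ 18.8%, mild-subgroup
  ≈ 20.1%), per-sample Dirichlet jitter with concentration 2000 — chosen
  once so the per-sample uCmC SD is ≈ 0.9 points, the reported
  between-sample spread — and gel CV 0.03. A symmetric Dirichlet cannot
  match all four reported pattern SDs simultaneously; the uCmC target was
  chosen because the mild-subgroup analysis rides on that metric.
* **qPCR** (`generate_ct_cohort`): reference Ct ~ N(18, 0.3), replicate
  SD 0.15 (triplicates), and a between-sample biological SD of dCt of
  0.25 cycles — a typical LCL qPCR variability; neither the emulated
  study nor its tables state this quantity, so it was fixed once at that
  value. Per-sample log2 offsets allow coupling a sample's expression to
  another per-sample quantity (the integration analysis couples
  subgroup-M expression to uCmC with target correlation ≈ 0.51).

# Numerical and degenerate-input choices

* Fisher: any zero margin returns p = 1 (no association testable);
  boundary round-off within 1e-12 of 1 is snapped to 1.
* BH ties are broken by stable input order and results returned in input
  order.
* Zero-variance t-tests: equal-mean constant groups give p = 1, unequal
  constant groups p = 0 (the reference implementation refuses such input).
* Blank or partially blank gel lanes (zero estimator denominators) yield
  an undefined summary (`NA`) with a warning; comparisons drop such
  samples per metric.
* Pearson correlation of a zero-variance vector is undefined and returns
  `NA` with a warning rather than a number.
* Presence-filter boundary: exactly 70% observed is retained (the filter
  removes strictly more-than-30% missingness).

# Known limitations

* The exact test is conservative in sparse strata (promoter and exonized
  overlaps of a few genes); per-stratum type-I error sits at ~5% only
  where counts make the null distribution near-continuous. The test suite
  asserts ≈5% on the dense strata and a never-anti-conservative bound
  everywhere.
* Detection of the mild-subgroup uCmC elevation (+1.3 points, SD ≈ 0.9,
  n = 10 vs 10) on the BH-adjusted metric p-value has true power of
  roughly 0.75 even under ideal conditions — adjusted-power targets above
  0.8 are not reachable for this effect size at this sample size, as the
  package's own simulations document; the raw-p detection rate is ≈ 0.86.
* COBRA measures global AluS methylation; it carries no positional
  information, and the workflow makes no claim about specific genomic
  loci.
* Symbol-keyed gene identity with no alias resolution: probe annotations
  that disagree on symbols will silently miss.
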