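---
title: "Methods: somatic mutation, clonality and relapse analysis in ALL cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic mutation, clonality and relapse analysis in ALL cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticALL)
```

somaticALL implements the downstream analysis of deep targeted sequencing of
pediatric acute lymphoblastic leukemia (ALL): it starts from somatic mutation
call tables (VCF or TSV) with per-sample allele fractions and read counts and
ends at cohort-level statements about clonality, mutational processes, driver
genes, relapse risk and clonal evolution. This vignette explains the models
and rules each stage uses, the parameters that matter, what the bundled
synthetic-cohort generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## Allele fractions and clonality

A somatic mutation present in every leukemic cell of a diagnostic sample with
blast fraction $b$ is expected at allele fraction (AF) $\approx b/2$ for a
heterozygous autosomal site, and $\approx b$ for hemizygous sites
(chromosome X in males, mitochondrial DNA). Mutations restricted to a subclone
appear at lower AF. Cohort-wide AF distributions are therefore bimodal: a
clonal peak slightly below 0.5 and a subclonal peak at low AF.

`estimate_af_boundary()` finds the boundary between the peaks as the minimum
of a Gaussian kernel density (bandwidth by Silverman's rule, `bw.nrd0`)
between the two largest modes on a fixed grid, searched inside (0.05, 0.5) —
the range where diploid heterozygous signal can live. Two numerical guards
matter: modes whose density is below 1% of the window maximum are discarded
(kernel densities wiggle at floating-point scale in empty tails and would
otherwise fabricate modes), and a unimodal density returns an explicit
no-boundary state rather than a number. Whether AFs should be
purity-adjusted before estimation is left to the caller: both raw and
ploidy-scaled AFs are accepted, and `classify_clonality()` always divides by
the ploidy factor (2 for chrX-male/chrM, else 1) before comparing with the
boundary, so hemizygous mutations are retained rather than excluded
(exclusion is available via a flag).

Burden comparisons use the Wilcoxon rank-sum test (exact when both groups
have at most 12 patients and no ties, tie-corrected normal approximation
otherwise), clonal-fraction comparisons the Pearson chi-square without
continuity correction (configurable), and burden-age association Spearman's
rank correlation. These are intentionally the plain textbook tests; the
package's contribution is the surrounding pipeline, not novel inference.

## Mutational signatures on a targeted panel

SNVs are tabulated into the canonical 96 pyrimidine-centered trinucleotide
contexts (six substitution classes $\times$ 16 flank pairs, lexicographic
flank order; purine-reference SNVs are reverse-complemented). Recurrent SNVs
— identical chrom/pos/ref/alt in more than one patient — are removed before
tabulation so a single event cannot be counted repeatedly.

Because a targeted panel over- or under-represents trinucleotide motifs
relative to the genome, per-context counts are rescaled by
$f_\text{genome}(m)/f_\text{panel}(m)$ of the context's central motif $m$
before decomposition (`normalize_motifs()`, frequencies from
`kmer_frequencies()` on FASTA, optionally restricted by BED). The correction
deliberately does not conserve total counts, and swapping the two frequency
arguments inverts it exactly. Whether corrected counts should additionally be
row-normalized before factorization is exposed to the caller (pass the matrix
as-is or normalized); the default pipeline uses raw corrected counts.

`nmf_decompose()` factorizes the groups × 96 matrix into $k$ signatures with
multiplicative Frobenius updates: 50 random restarts, at most 10,000
iterations, stopping when the relative error decrease falls below $10^{-6}$,
keeping the best restart; the procedure is deterministic given its seed, and
the error trace is non-increasing by construction. Signature rows are
normalized to sum to one with exposures rescaled to compensate. $k$ is
user-set (3 in the study setting of five to six group rows); no attempt is
made to estimate it.

A caution documented here because it shapes the validation design: NMF is
only identifiable when exposures are "scattered". If one process's exposure
vector dominates another elementwise across all groups, an exactly-fitting
alternative factorization exists that mixes them. The recovery checks in the
test suite therefore plant exposures in which each signature dominates at
least one group — which is also what the grouped study design provides.
The shipped reference catalogue
(`inst/extdata/signature_catalog_synthetic.tsv`) is synthetic: an
aging-like CpG C>T process, an APOBEC-like C>G/C>T-at-TpC process and a flat
background over the remaining classes, with nearly disjoint supports.
Published catalogues are not redistributed; matching against any catalogue in
the same 96-context order works via `match_signatures()` (cosine best-match,
ties by catalogue order, plus a complete-linkage Euclidean clustering of the
row-scaled stacked matrix for dendrogram-style inspection).

## Driver genes

Three per-subgroup statistics capture the classical detection axes, as
deliberately simple analogues of the heavyweight tools used in practice
(which depend on external covariate tracks and annotation scores):

* **Burden** (`burden_test()`): upper-tail Poisson test of a gene's
  non-silent count against rate × coding length × patients. The background
  rate used by the pipeline is estimated leave-one-out from the subgroup's
  non-silent counts — the tested gene's own mutations are excluded — which
  keeps the null calibrated for passengers without letting a true driver
  inflate its own expectation. (A silent/noncoding-based estimate,
  `background_rate()`, is also provided; it needs an explicit class-ratio
  correction because non-silent opportunity exceeds neutral opportunity.)
* **Functional impact bias** (`impact_bias_test()`): one-sided mid-rank
  rank-sum test of the gene's per-mutation impact scores (any 0–1 score
  column) against the cohort background; genes with fewer than two scored
  mutations are not tested. When the pooled scores are completely tied the
  tie-corrected variance is zero and the p-value is 1 — the
  exact-permutation answer in that degenerate case.
* **Positional clustering** (`clustering_test()`): maximum fraction of the
  gene's mutations inside any sliding window (default 50 bp) along the CDS,
  with a Monte-Carlo permutation p against uniform positions and add-one
  smoothing, so $p \ge 1/(n_\text{perm}+1)$.

P-values are converted to q-values by Benjamini–Hochberg within each
(subgroup, statistic) family. The consensus rule is the study's: a gene is a
putative driver if at least one subgroup predicts it (any statistic with
$q \le 0.1$ by default; a strict all-statistics mode exists because the
source convention is ambiguous) *and* it carries at least three non-silent
mutations. The five screening subgroups are T-ALL, all BCP-ALL, and the
BCP-ALL subtypes high-hyperdiploid, t(12;21) and normal karyotype.
`driver_summary()` reproduces the count-table arithmetic of the usual
subtype summary (Ras-gene carriers, mean driver mutations, driver-free
patients), with percentages rounded half-up to integers.

## Competing-risks relapse association

Relapse competes with death in first remission, secondary malignancy and
resistant disease; naive Kaplan–Meier complements overstate incidence.
`cumulative_incidence()` computes the Aalen–Johansen estimator through a
multistate product-limit fit (`survival::survfit`); with no competing events
it reduces exactly to one minus product-limit survival, which the tests
verify on random instances. At tied times events precede censorings.

`gray_test()` compares subdistribution hazards across groups (Gray 1988,
$\rho = 0$ weighting — the standard default, as no weighting parameter is
specified by the method's users here), with the statistic computed by the
`cmprsk` implementation and a chi-square reference on $k-1$ degrees of
freedom. For small samples a permutation mode re-computes the statistic
under relabelings — exhaustively for two groups when the assignment count is
modest ($\le$ 20,000), Monte-Carlo otherwise. At $n = 8$ the asymptotic and
exhaustive references agree closely on representative datasets, but any
borderline p near the threshold can land on either side — which is exactly
why the permutation mode exists.

`relapse_screen()` applies the study's filters in order: restrict to a
patient subgroup, drop infants (< 1 year), keep non-silent diagnostic
mutations, test every gene (or KEGG-style pathway via `pathway_collapse()`)
mutated in at least five patients, and Bonferroni-correct by the number of
units actually tested in that subgroup. The subgroups derivable from the
metadata model are: complete, T-ALL, BCP-ALL, HeH, t(12;21) and normal
karyotype (a risk-group stratification would require a risk-group field the
metadata model does not carry).

## Clonal evolution between diagnosis and relapse

For patients with samples at two or more timepoints, `classify_status()`
assigns each mutation exactly one status from its per-timepoint called
flags: `shared`, `diagnosis_only`, or `relapse_gained`; mutations first
called at a second relapse are classified against the first relapse, chained
with the same rules. `rescue_low_af()` then uses raw read support at the
earlier timepoint (the stand-in for re-genotyping output): a relapse-gained
mutation with at least 2 supporting reads at AF < 2% was already present in
a minor subclone (`rescued`); symmetrically a diagnosis-only mutation with
such support at relapse is `residual`. The 2-read default is a choice — the
rule in the field is stated as an AF threshold only — and is configurable.
`flag_rising()` marks shared mutations whose relapse AF is at least twice
the diagnostic AF (boundary inclusive); rescued mutations are rising by
construction and are kept as their own class instead of dividing by
near-zero AFs.

`group_clones()` is an explicit algorithmic proxy for the manual clone
clustering practised in the field: group by detectability pattern across
timepoints, then single-linkage clustering of AF trajectories (Chebyshev
distance over the detectable timepoints) cut at a configurable tolerance
(default 0.05 AF). It is deterministic and invariant to input order. Clone
fate is eradicated / persisting / expanding. The tolerance interacts with
the generator's clone spacing (below): clones whose AFs differ by less than
the tolerance at every timepoint are indistinguishable in principle.

`relapse_associated_genes()` implements the two-criterion rule: (1) at
least two non-silent relapse-gained mutations in the gene, or (2) at least
one relapse-gained mutation plus additional non-silent diagnostic mutations
in relapsed patients — voided if any same-immunophenotype patient who
remained in first remission carries a non-silent diagnostic mutation in the
gene. Records without AF (e.g. pooled-cohort calls) participate in the
criteria but are excluded from AF-based flags.

## The synthetic cohort generator

`simulate_cohort()` and `simulate_relapse_pairs()` generate cohorts with the
statistical structure the analysis assumes, plus complete ground truth, so
every stage can be validated end to end. The defaults are the study
conditions the package targets:

* subtype composition of a 172-patient diagnostic cohort (24 T-ALL, 47 HeH,
  36 t(12;21), …), ~83% with a matched germline sample;
* negative-binomial burdens with means 6.4 (T-ALL) and 3.5 (BCP-ALL) and
  dispersion 1.5 — the dispersion is chosen so that a 0–31 per-patient range
  around a mean near 4 is plausible, and it is the reason a rank-sum test at
  $n = 100$ per arm has ~91% power at $\alpha = 0.01$ (not ~99%, as a
  Poisson model would give);
* one hypermutated HeH outlier (120 mutations, almost all subclonal);
* blast fractions uniform on (0.80, 0.95); founder mutations at blast/2
  (blast for chrX-male), subclonal AF levels on a grid below
  0.3 × blast spaced by ≥ 0.12 so that clones remain resolvable by the
  default 0.05 grouping tolerance; clonal fractions 0.65 (T) / 0.45 (BCP);
* trinucleotide contexts drawn from per-group signature mixtures — every
  group gets the CpG C>T process, the t(12;21) group additionally the
  APOBEC-like process — with mutation sites sampled from genomic positions
  whose reference context matches, on a synthetic genome tiled by a
  225-gene panel (25 recognisable leukemia genes plus 200 passengers);
* per-subtype spiked driver genes with recurrent hotspot positions, and
  continuous impact scores (Beta(4, 1.5) for drivers, uniform for
  passengers);
* a read-count layer: depth negative-binomial around 638× (floor 150),
  alt reads binomial — or the rounded expectation in noise-free mode, which
  is what the exactness checks use;
* competing-risks outcomes from cause-specific exponential hazards
  (relapse 0.03/yr, competing 0.015/yr, administrative censoring at 10 yr),
  with the relapse hazard multiplied by 3 for patients carrying a
  non-silent Notch-pathway mutation;
* relapse pairs for half of the relapsed patients: whole subclones
  eradicated until a Poisson(3.6) lost-mutation target is met, Poisson(5)
  gained mutations arriving in one or two new clones, 21% of gained clones
  seeded at AF < 2% at the earlier timepoint, 9% of eradicated clones
  leaving residual reads, one low-AF subclone rising at 2.5× (safely past
  the 2× rule under read-count rounding), and a second relapse for 15% of
  pairs, chained against the first.

Everything is reproducible from a single integer seed, and every emitted
mutation carries exactly one truth record (clone, true AF, driver flag,
status/rescue/rising labels for pairs).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: copy-number change and loss of heterozygosity
(AFs above the hemizygous expectation are out of model), fusion genes
(subtype labels are metadata only), context-dependent coverage bias,
sequencing error and contamination in the read layer, germline leakage in
patients without matched remission samples, and real panel motif
composition (the synthetic genome is i.i.d. uniform, so its panels are much
flatter than exome captures). Clone-structure recovery is demonstrated
under noise-free reads; with binomial read noise the same labels are
approximate near thresholds, which is the realistic situation.

## Orchestration and problem sizes

`run_pipeline()` chains the stages (simulate, clonality, signatures,
drivers, survival, evolution, report) with plain TSV artifacts, a config
hash in every output header, and a JSON manifest; `inst/exec/somaticall` is
a thin command-line front-end with exit codes 0/2/3 (success / validation
error / missing upstream artifact). The validation suite runs the default
172-patient cohort for cohort-level checks, 1,000 patients per phenotype for
burden-mean calibration, 2,000 replicates of two groups of 150 for the
Gray-test size check, 50,000 counts for signature recovery, and a
100-patient two-subtype cohort with 200 passenger genes for driver
recovery; these sizes give Monte-Carlo error comfortably inside each check's
margin while keeping a full run in the minutes range.

## Known limitations

Simplified driver statistics are not substitutes for covariate-aware tools
on real cohorts; the Poisson burden model ignores regional mutation-rate
covariates (expression, replication timing) that drive false positives in
real exomes. The AF boundary is a cohort-level construct — per-patient
purity deconvolution is out of scope. The clone grouping is a proxy for
manual curation and inherits its ambiguity when clones are close in AF.
Gene-level screens use Bonferroni within subgroup as specified by the
procedure it mirrors, which is conservative when units overlap (pathways
share genes).
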