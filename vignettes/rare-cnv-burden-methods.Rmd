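---
title: "Methods: rare CNV burden, exact locus association, inbreeding, and variant prioritisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare CNV burden, exact locus association, inbreeding, and variant prioritisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvburden)
```

This vignette is the package's account of its statistical machinery: the
models and procedures, the parameters that matter, the numerical and
design choices that were genuinely open, and what the synthetic-data
generator does and does not establish about real data.

## The study design

The package targets a common design in the genetics of complex disease,
here oriented to spermatogenic failure: several case-control cohorts,
each genotyped on a different SNP-array platform, with CNVs called per
sample by multiple algorithms of partial concordance. Because platforms
differ in probe content, CNV frequencies and locus tests are computed
per platform, and cohort is carried as a stratification or
random-effect term in every cross-cohort summary. Downstream of the CNV
layer the same samples contribute homozygosity-by-descent (HBD) segment
calls, and individual patients contribute annotated exome variants.

## Interval algebra and consensus

Coordinates are 0-based half-open internally (BED convention); 1-based
inclusive tables are accepted via a reader flag and shifted on ingest.
The similarity between two calls is the *reciprocal overlap*
`min(ovl/len(a), ovl/len(b))` — symmetric, in [0, 1], and zero across
chromosomes.

Consensus (`consensus_merge()`) retains calls supported by at least 2
distinct algorithms (configurable). Grouping is greedy in start order
within sample, platform, chromosome and class: a seed call absorbs later
calls from unused algorithms whose reciprocal overlap with *every*
current member meets the threshold. The all-pairs rule means each group
is a clique of mutually-matching calls; by Helly's theorem in one
dimension the members then share a common intersection, which is taken
as the consensus span (conservative); the union span is kept as
metadata. The grouping is deterministic given the sort order.

Region clustering (`cluster_cnvrs()`) is single-linkage and seeded:
sorted by start, the first unassigned call seeds a region and any call
with reciprocal overlap at least the threshold (default 0.5) against
the *growing envelope* is absorbed, iterating to a fixpoint. The
envelope rule (rather than overlap against the seed call alone) is the
default because it is the common CNVR-construction practice; both are
deterministic. Gains and losses never merge. Frequency is carriers over
all samples in the supplied sheet — cases and controls together — so the
caller passes the platform batch as the denominator.

Rarity (`filter_rare()`) uses a *strict* frequency inequality
(frequency < 5% by default), matching the "less than 5%" convention, and
an inclusive size floor in bp.

NAHR classification (`classify_nahr()`) flags calls at least 100 kb long
whose two breakpoints each fall within one member of the same homologous
segmental-duplication pair, in either orientation, with a breakpoint
slack of 20 kb by default — roughly the breakpoint uncertainty implied by
SNP-array probe spacing. Both the floor and the slack are arguments.

## Exact 2×2 association

Locus evidence is a carrier table: case/control × carrier/non-carrier.
Inference conditions on the margins, under which the case-carrier count
follows a (noncentral) hypergeometric distribution.

- `fisher_exact()` computes the exact p by summation over the support:
  two-sided by the point-probability rule (all tables with probability
  at most the observed, with the conventional `1 + 1e-7` relative
  guard), one-sided over the case-enrichment tail.
- `odds_ratio()` offers the sample odds ratio *ad/bc* and the
  conditional MLE, found by solving `E_psi[X] = a` for the noncentral
  parameter on the log scale by root bracketing in `log psi` within
  [−40, 40] (tolerance 1e-10); the estimate is exactly 0 or infinite
  when the observed count sits at the support boundary.
- Confidence intervals: Woolf `exp(log OR ± z * sqrt(1/a+1/b+1/c+1/d))`,
  or exact conditional bounds obtained by inverting the two one-sided
  exact tests at `alpha/2` per side. The exact interval is the companion
  of the conditional MLE and is what this package reports next to an
  infinite odds ratio (a finite exact lower bound, upper bound infinite).
- Zero-cell policy: the default reports the infinite/zero odds ratio
  as such with exact conditional bounds; `"haldane"` adds 0.5 to every
  cell for the sample estimate and Woolf interval; `"strict"` errors.

These routines are hand-implemented on hypergeometric point
probabilities and are cross-checked in the test suite both against a
brute-force fixed-margins enumeration oracle (exhaustively over all
tables with total at most 30) and against `stats::fisher.test()` as an
independent reference implementation.

## Burden statistics

`summarize_burden()` reduces rare consensus calls to one row per sample
(event count, aneuploid bp) within a compartment (autosomes, X, Y, or
genome) and optional class, zero-filling samples without events; totals
are invariant to input order and file splits.

`ranksum_burden()` is the two-sided Mann-Whitney U test, exact when both
groups have at most 50 tie-free observations and the tie-corrected
normal approximation otherwise (delegated to `stats::wilcox.test()`);
all-identical input returns p = 1 rather than an error.

`logistic_burden()` fits `status ~ burden + covariates` by IRLS
(`stats::glm`). Constant covariates are dropped with a warning and
collinear ones removed by QR rank detection. Separation is flagged — not
silently returned — when the fit warns of fitted probabilities at 0/1 or
the coefficient/standard error diverge (|beta| > 15 or SE > 100); a
Jeffreys-prior penalised Newton fit (Firth-style, hat-adjusted score) is
available via `engine = "firth"`. Inference on the burden coefficient is
Wald.

`combine_cohorts()` approximates a cohort-random-effect logistic model in
two testable ways: inverse-variance meta-analysis of per-cohort fits
(fixed effect, or DerSimonian-Laird random effects via `metafor::rma`),
and a pooled logistic fit with cohort indicator covariates. Both agree
with the mixed model asymptotically; the random-effects meta is the
default summary because it also surfaces between-cohort heterogeneity
(tau²).

`permutation_locus_test()` uses the case-carrier count per locus as the
statistic, the add-one estimator `(1 + #{perm >= obs}) / (n_perm + 1)`
(never zero), and the max-T rule for genomewide correction, which
controls family-wise error under the complete null. Labels are shuffled
*within cohort* by default: each cohort sits on one platform, so
unstratified shuffles would mix platform-specific call rates into the
null. `geneset_burden()` reuses the same machinery with platform as the
stratum and a per-sample indicator of carrying a rare deletion
intersecting the set; platforms with zero probe coverage of the set are
excluded, since their samples cannot be carriers by construction.

## Inbreeding from HBD segments

HBD callers misread large hemizygous deletions as homozygosity, so
`filter_deletion_artifacts()` removes segments whose reciprocal overlap
with a same-sample deletion call reaches the threshold, reporting the
removed segments with sizes; kept plus removed is exactly the input.

The inbreeding coefficient is the segment-based estimator: F = total
autosomal HBD length / total autosomal manifest length, after clipping
segments to the manifest and merging overlaps, making F invariant to
how segments are split. The autosomal-manifest denominator (rather than
the assayed SNP span) and a minimum-segment floor of 0 bp are the
defaults; both are explicit arguments because HBD callers differ in how
much short background homozygosity they report. Sex chromosomes are
excluded (the male X is hemizygous). Threshold classification uses
strict inequalities over the ladder 0.5%, 1.6%, 6.25% — the last being
the first-cousin expectation 1/16 — so counts are monotone
non-increasing up the ladder. `detect_upd()` flags sample-chromosome
pairs with merged HBD coverage at least 0.9 of the chromosome; isodisomy
of a whole chromosome produces coverage near 1, and the margin tolerates
telomeric call gaps. `inbreeding_association()` reuses the logistic
machinery on F (continuous) or an `F > threshold` indicator
(categorical).

## Two-dimensional variant prioritisation

Five annotator scores are mapped affinely onto [0, 1] with 1 = most
damaging; SIFT is flipped. The default ranges (phyloP [−14, 6], GERP
[−12.3, 6.17], PolyPhen2, SIFT and LRT [0, 1]) are the annotators'
conventional ranges and live in a configuration tibble, not in code —
empirical quantile normalization can be substituted by passing different
bounds per dataset. Out-of-range raw values are clamped with a message;
missing values normalize to 0 (benign) by default, or drop the variant.

The Individual Score is `p_ind = ploidy × sum(normalized)`, in [0, 10]
(ploidy 1 for heterozygous, 2 for homozygous). The Population Score is
`p_pop = p_ind − p_max(gene)`, where `p_max` is the gene-wise maximum
Individual Score across a reference panel; genes absent from the panel
take `p_max = 0`, so variation in genes with no known population
variation keeps its full score — intentionally favouring gene-novel
candidates. Panel genotypes supply ploidy where available, otherwise
heterozygosity is assumed (a panel entry contributes its single-copy
score). The MAF filter is strict (< 10%) and must hold in *both*
reference panels. Ranking is a total order: descending `p_pop`, then
descending `p_ind`, then lexicographic variant id.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with
serialised ground truth.

**CNV cohorts.** Per sample, rare events are Poisson per
compartment-class category (defaults: 2 autosomal losses and gains per
genome, 0.25 X events, 0.15 Y events per class — enough rare events to
power burden fits at cohort scale), with log-normal sizes (median 30 kb,
sigma 1.2 on the log scale, populating both the <100 kb and >100 kb
strata). Case status follows a logistic model on the category counts,
with generative per-event odds ratios defaulting to 1.10 (autosomal
loss), 1.29 (X, both classes) and 1.88 (Y gain). Cohort quotas (defaults
83/62, 179/974 and 61/100 cases/controls — 323 cases and 1136 controls
over three platforms) are filled retrospectively: candidates are
generated, labelled by the model, and sampled until each margin is met.
Case-control sampling shifts only the intercept of a logistic model, so
the burden coefficient remains identifiable. Each true event is then
emitted once per calling algorithm with per-algorithm sensitivity
(defaults 0.95/0.90/0.85) and Gaussian breakpoint jitter (sd 2 kb),
giving realistic partial concordance; setting sensitivities to 1 and
jitter to 0 makes the channel lossless, which the tests exploit to prove
exact consensus recovery. Common polymorphic regions (default 20, at
frequencies 5–40%) are added independently of status to exercise the
frequency filter.

**HBD.** For a sample whose parents share an ancestor g generations
back, segment lengths are exponential with mean 100/(2g) cM (16.7 cM at
g = 3, first cousins), mapped at a uniform 1 cM/Mb. Starts follow a
stationary Poisson process on each autosome (extended left of the origin
so edge effects do not thin coverage), with intensity chosen so the
expected covered fraction equals the target F; overlaps merge on
analysis. A short-segment background (coverage 0.001, mean 500 kb)
emulates population-level homozygosity. Whole-chromosome segments can be
injected to emulate uniparental isodisomy.

**Exomes.** Annotator scores are drawn benign-skewed (Beta(0.8, 4) on
the normalized scale, mapped back to raw ranges), genotypes mostly
heterozygous (5% homozygous), reference MAFs uniform on [0, 0.3] so the
10% filter bites. One homozygous variant with maximally damaging scores
and sub-filter MAFs is planted in a gene excluded from the panel; with
continuous scores elsewhere, it is almost surely the unique maximum of
`(p_pop, p_ind)`.

**What passing on synthetic data does and does not show.** The
generator matches the *structure* of array studies — cohort/platform
confounding, multi-algorithm concordance, rare-versus-common frequency
mixture, L-shaped HBD length distributions — but not linkage
disequilibrium, probe-density variation along the genome, batch-specific
noise, or correlated annotator errors. Recovery of the generative burden
coefficient on synthetic cohorts validates the estimation machinery, not
the published effect sizes, which would require the original raw arrays.

## Genome, problem sizes, and determinism

The default manifest is a toy genome (22 autosomes × 10 Mb, X 8 Mb, Y
3 Mb): large enough for compartment contrasts and realistic event sizes,
small enough that the full test suite runs in seconds-to-minutes. Real
manifests are accepted everywhere. The acceptance checks use 100
study-scale cohort replicates for burden recovery, 500 permutation-null
simulations of 20 loci (FWER), 200 coverage replicates at 500 cases and
500 controls, 500 simulated first-cousin genomes, 50 UPD injections, and
100 seeded exomes — sizes chosen to give binomial noise well inside the
asserted margins. Every stochastic function takes a `seed` argument and
reproduces bit-identical output for a fixed seed; operations are seeded
independently rather than sharing a global stream.

## Known limitations

- Consensus grouping and region clustering are greedy/sorted-order
  procedures; pathological overlapping-call configurations could be
  grouped differently by an exhaustive clique search, though the two
  agree on realistically jittered callsets (tested).
- The cohort-random-effect logistic model is approximated (meta-analysis
  or stratified fit), not fitted by joint maximum likelihood.
- The exact conditional CI is known to be conservative for strongly
  discrete tables; Woolf intervals undercover with small cells. Both are
  reported as what they are.
- F is measured against the full autosomal manifest; if HBD calls come
  from a sparse assay, the caller should pass the assayed span as the
  manifest to avoid systematic underestimation.
- The variant score treats the five annotators as exchangeable after
  normalization; no per-annotator weighting is attempted.
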