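---
title: "Genetic management of a minimal clonal collection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic management of a minimal clonal collection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonemate)
```

## The problem

When a plant species is down to a handful of individuals, genetic management
stops being an abstraction: every surviving genotype matters, clonal
(vegetative) propagation can hide how few genotypes actually remain, and in a
dioecious species a biased sex ratio can make most theoretically possible
crosses impossible. The questions a collection manager needs answered are
concrete. How many distinct multilocus genotypes (genets) do the sampled
ramets represent? Are recent seedlings true conspecific offspring, or hybrids
with a congener held in the same garden? How much heterozygosity is left, in
the wild versus in cultivation? And which pairs of plants should be crossed
to lose as little diversity as possible in the next generation?

`clonemate` implements that workflow for biallelic SNP panels (DArT-style
reduced-representation genotyping, plain dosage matrices, or VCF), end to
end: QC filtering, clone calling, diversity summaries, pairwise
$F_{ST}$ with subsampling, principal coordinates ordination,
opposing-homozygote parentage exclusion, and Mendelian cross simulation.
Every stage is also exercised by a synthetic-data generator whose truth
(genets, pedigree, sexes, divergences) is known, so the pipeline can be
validated without access to field data.

## Genotype representation

Calls are alternate-allele dosages: 0 (homozygous reference), 1
(heterozygous), 2 (homozygous alternate), with missing data a distinct
state, never conflated with 0. All statistics in the package are symmetric
under swapping allele labels at any locus, so the reference/alternate
orientation of the input file is taken as given and never re-polarised.
DArT one-row reports use a different convention (0 = homozygous reference,
1 = homozygous alternate, 2 = heterozygous, `-` = missing); `read_dart_report()`
remaps it. Multi-allelic VCF records are rejected with an error rather than
silently split: the downstream statistics are defined for biallelic SNPs,
and splitting would distort allele frequencies.

## The QC cascade

`run_cascade()` applies, in a fixed order: individual call rate (default
keep $\ge 0.25$), locus reproducibility (technical-replicate agreement,
keep $\ge 0.99$), mean read depth (keep within $[5, 500]$), locus call rate
(keep $\ge 0.97$ in the first pass, $\ge 0.95$ in the second), removal of
monomorphic loci, and removal of secondaries (extra SNPs on an already
represented sequenced fragment, kept to one marker per fragment for
pseudo-independence). Conventions that matter and are easy to get wrong
silently:

* every threshold is inclusive on the *keep* side — "below 0.99" removes
  strictly $< 0.99$, "outside 5–500" removes strictly outside the closed
  interval;
* locus call rates are always recomputed from the current sample set, never
  read from file metadata, which is what makes the two-pass "recall on the
  target species" workflow meaningful — after restricting to conspecific
  samples, call rates and polymorphism change;
* a locus with no calls at all counts as monomorphic (it carries no
  information);
* the secondaries tie-break is deterministic: highest call rate, then
  highest reproducibility, then first in file order;
* a step that would remove everything is a hard error, and each step's
  removals are recorded in the returned report.

The two-pass structure mirrors field practice: a first pass over all
samples (including congeners) supports the hybridisation check; after
hybridisation is excluded, a second pass over conspecific samples only, with
a slightly relaxed call-rate threshold, maximises within-species resolution.

## Clone calling

Ramets of one genet differ only by genotyping error, so clone-mates are
separated from distinct genets by their pairwise dissimilarity: the fraction
of shared-called loci with unequal codes. `call_clones()` clusters the
dissimilarity matrix with *complete* linkage and cuts at a threshold
(default 0.05). Complete linkage guarantees that every pair inside a genet
is within the threshold; single linkage could chain two true genets through
one intermediate, erroneous sample. The default threshold is calibrated
against the error model: at a per-call error rate $\varepsilon$, two
clone-mates differ at about $2\varepsilon$ of loci (0.01 at the default
$\varepsilon = 0.005$), an order of magnitude below the threshold, while
distinct genets in a low-diversity SNP panel typically differ at 20–40% of
loci. Pairs sharing fewer than `min_shared` called loci (default 50) are
*incomparable*; clone calling refuses to run rather than guess a merge
decision for them. Each genet gets a consensus genotype (per-locus majority
among members; ties and empty loci become missing), used downstream for
genet-level diversity and crosses.

This distance-based approach deliberately replaces likelihood pedigree
reconstruction for the clone-detection step: clone-mates are separated from
everything else by a wide margin, so a threshold rule is transparent,
deterministic and auditable — properties worth more than statistical
machinery in a management context. Parent–offspring structure is handled
separately (below).

## Diversity statistics

Observed heterozygosity ($H_O$) per locus is the heterozygote fraction among
non-missing calls; group $H_O$ is the mean over loci with data (identical to
the per-individual mean when data are complete). Expected heterozygosity is
the Hardy–Weinberg $H_E = 2p(1-p)$; the unbiased variant multiplies each
locus by $2n/(2n-1)$, with $n$ the individuals called there — at the group
sizes this package targets (often $n \le 7$), the correction is far from
cosmetic. The inbreeding coefficient is reported under *both* common
aggregations, because published tables rarely say which their tool used and
the two differ noticeably on small groups:

* ratio of means (default): $F_{IS} = 1 - \bar{H_O} / \bar{H_E}$;
* mean of ratios: the average of $1 - h_o/h_e$ over loci with $h_e > 0$.

When the reference $H_E$ is zero everywhere, $F_{IS}$ is undefined and
reported as `NA`, never as 0. Diversity in the orchestrated workflow is
computed on one representative per genet (clones would otherwise
pseudo-replicate their founder), with a flag to use all samples instead.

## Population structure

`fst_wc()` implements the Weir & Cockerham (1984) $\theta$ estimator for
two populations: per-locus variance components $a$ (among populations) and
$b, c$ (within) from sample sizes, allele frequencies and observed
heterozygote counts, combined as $\sum_\ell a_\ell / \sum_\ell (a_\ell +
b_\ell + c_\ell)$. Choices worth stating: loci missing in one group are
excluded per locus, not listwise; negative estimates are reported unclipped
(clipping at zero biases subsampled means upward near zero
differentiation); and when the denominator vanishes across all loci — both
groups monomorphic and identical — the estimate is undefined (`NA`), not 0.
The implementation is cross-checked in the tests against a hand-evaluated
two-locus worked example and an independent loop-written oracle.

Because $\theta$ is sensitive to unequal sample sizes at this scale,
`fst_subsampled()` repeatedly draws equal subsamples (default $n = 3$,
matching the smallest meaningful group; 1000 iterations) without
replacement, and reports the mean over iterations with a defined estimate;
undefined draws (e.g. monomorphic subsamples) are counted, not silently
dropped. Groups at or below the subsample size are used whole. Each group
pair derives its seed from the master seed and the sorted pair labels, so
adding a group never changes the other pairs' results.

`pcoa_genotypes()` is classical metric scaling (double-centred Gram matrix
eigendecomposition) on Euclidean distances between dosage vectors, with
per-locus mean imputation of missing calls — neutral with respect to
cluster placement, and the only manufactured values anywhere in the
package (they never feed any other statistic). Axis percentages are
eigenvalues over the sum of positive eigenvalues; requesting more axes than
there are positive eigenvalues truncates with a warning.

## Parentage exclusion by opposing homozygotes

A true parent and offspring share at least one allele at every locus, so
one individual homozygous for the reference allele and the other homozygous
for the alternate is Mendelian-impossible absent genotyping error.
`violation_rate()` is the fraction of such loci among those called in both
individuals — a symmetric statistic (no direction is assumed; the rule
itself is symmetric). Only this opposing-homozygote class is counted;
other incompatibility classes (e.g. two identical homozygotes producing a
heterozygote) involve a third genotype and are not pairwise-decidable.
`assign_parental_group()` ranks candidate groups by the mean rate against a
seedling cohort, with the margin to the next group reported. The decision
is descriptive — rate ordering with margins, no significance test — which
matches how the statistic is used in management: a conspecific parental
group sits near the error floor (about $2\varepsilon$ at error rate
$\varepsilon$), while a congener sits an order of magnitude higher. The
statistic cannot distinguish the two parental groups of a hybrid cohort
from each other, only both from unrelated groups; the tests document this
boundary explicitly.

## Cross simulation and pair ranking

`simulate_offspring()` draws, per offspring per locus, one allele from each
parent (homozygotes transmit their allele; heterozygotes transmit either
with probability 1/2). Loci are unlinked — no genetic map exists for
species at this rarity, and unlinked SNPs are the standard assumption for
reduced-representation panels. A locus missing in either parent is missing
in the offspring: a management tool must never invent genotype information.
`cross_mean_ho()` averages the observed heterozygosity of $n$ simulated
offspring (default 10, the approximate seed yield per cross in the target
setting); the expected value has closed forms per parent-genotype category
(opposite homozygotes $\to 1$; identical homozygotes $\to 0$; heterozygote
$\times$ anything $\to 1/2$), which the tests verify distributionally.

`all_crosses()` enumerates every unordered genet pair except self-pairs
(dioecy makes selfing impossible) and pairs where both sexes are known and
equal; unknown-sex genets pair with everyone. Parents are canonically
ordered and each pair's seed is derived from the master seed plus the
sorted genet ids, so results are symmetric in argument order and stable
when the collection grows. `rank_pairs()` sorts by mean offspring $H_O$
(ties broken by pair id); `cross_group_summary()` aggregates to management
groups for when pair-level decisions are impractical.

## The synthetic-data generator

`generate_study_like_dataset()` emulates the structure of a minimal clonal
collection: 20 wild samples in four clonal patches (2/7/3/8 samples)
realising 7 genets; 12 ex-situ adult samples realising 5 genets — one
female, four male, two shared with the wild patches; 7 F1 seedlings
mothered by the single female genet with fathers among the ex-situ males;
and four congener groups (3+2+2+2 samples) on a divergence ladder. That
composition yields 17 conspecific genets — 1 known female, 4 known males,
12 of unknown sex — and hence $\binom{17}{2} - \binom{4}{2} = 130$
permissible crosses.

Allele frequencies are hierarchical Balding–Nichols draws. From an
ancestral pool (uniform on $[0.1, 0.5]$, symmetrised about $0.5$), the
target species' branch drifts with $F = 0.35$ at "variable" loci and
$F = 0.95$ at a species-diagnostic fraction (30%) of loci — the
diagnostic class is what keeps within-species diversity low while leaving
room for strong between-species differentiation, mimicking the locus
composition of a reduced-representation panel spanning several species.
Within the target species, a wild/male pool and an "extinct source" female
pool drift a further $F = 0.15$ apart; this is what separates the single
female genet from the males along the first ordination axis and makes the
seedlings (female $\times$ male F1s) intermediate. Congeners drift from
the ancestral pool at $F = 0.5, 0.7, 0.85, 0.95$. The realised
between-species $\theta$ ladder is ordered by these divergences but
compressed relative to them (roughly 0.55–0.75 at the defaults): because
congener frequencies descend from the same ancestral pool, opposite
fixation is rarer than between real species, where ascertainment actively
selects species-differentiating markers. The generator is therefore
*conservative* for between-species contrasts — a pipeline that separates
these congeners will separate real ones more easily.

Noise is a symmetric nearest-state miscall at rate 0.005 per call and 1%
missing data, matching the low-percent missingness typical of filtered
DArT panels. QC metadata is drawn so that a known, stored set of loci
fails each metadata-driven step (30 low-reproducibility, 30 out-of-depth,
20 forced low-call-rate loci, ~8% secondaries); the generator tallies its
expected removals with plain vector arithmetic, independently of the
filtering module, and the tests require the two routes to agree exactly.
Of 1800 generated loci the default cascade retains about 1300 in the
first pass and 850–900 after restriction to the target species.

What the generator does **not** emulate: linkage, ascertainment bias,
allele dropout/null alleles (error is symmetric), locus-specific error
rates, and the magnitudes of published diversity tables (its within-species
heterozygosity is somewhat higher than heavily bottlenecked real
populations). Passing tests therefore demonstrate the pipeline's
correctness and its qualitative orderings — clone recovery, parentage
exclusion, divergence ordering, heterozygote-excess patterns — not
agreement with any particular field dataset's numbers.

## Determinism and numerical conventions

Every stochastic function takes a seed and restores the caller's RNG
state. Sub-seeds are derived from the master seed plus a stage or pair
label through a small string hash (kept below $2^{31}$), so independent
stages are decoupled: re-running any stage alone, or growing the
collection, reproduces all untouched results bit-exactly. Undefined
statistics are always `NA` with a recorded count, never 0 and never
silently dropped. All thresholds sit on the keep side of their boundary.
Ties (consensus genotypes, secondaries, pair ranking, clustering order)
break by documented deterministic rules.

## Worked example

```{r example, eval = FALSE}
d <- generate_study_like_dataset(seed = 1)
run <- run_full_analysis(d$genotypes, d$meta, default_run_config(seed = 1))
run$diversity
run$ranked_pairs[1:5, ]
```

The test suite exercises the same pipeline at the generator's default
problem size (48 samples, 1800 loci) for the end-to-end recovery checks,
and at reduced sizes (hundreds of loci, tens of iterations) for unit-level
properties; the acceptance script `scripts/acceptance.R` re-runs the full
default-size analysis, including 1000 subsampling iterations per group
pair, and writes every headline quantity it computes.

## Known limitations

* Clone calling assumes clone-mate dissimilarity and inter-genet
  dissimilarity are separated by a margin around the threshold; a somatic
  mutation load or error rate approaching half the threshold would need a
  recalibrated threshold (`call_clones()` reports the threshold used in
  all outputs for exactly this reason).
* The opposing-homozygote test excludes hybridisation; it cannot assign
  individual parentage within a group, and full-sib versus half-sib
  structure among seedlings is out of scope.
* $F_{IS}$ on groups collapsed to a handful of genets says little about
  mating systems; it is reported because managers compare it across
  groups, not because it estimates an inbreeding rate here.
* PCoA mean imputation slightly shrinks ordination distances for samples
  with much missing data; at the $\le 2\%$ missingness the QC cascade
  leaves, the effect is negligible.
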