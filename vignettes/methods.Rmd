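---
title: "Models and methods behind recurrevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind recurrevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recurrevol)
```

recurrevol analyzes paired primary and early-recurrent hepatocellular
carcinoma (HCC) genomes. Its central question is whether a recurrent tumor
is *ancestral* — clonally descended from the primary tumor via
intra-hepatic dissemination — or *de novo*, an independent second primary.
Around that call it reconstructs each patient's subclonal architecture,
times driver alterations, quantifies spatial and temporal heterogeneity,
and decomposes mutational signatures by evolutionary stage. This vignette
explains the models, the tunable parameters, the numerical choices, and
what the synthetic cohort can and cannot tell you about real data.

## Mutation-set harmonization

All downstream statistics operate on per-sample somatic mutation sets that
have been harmonized across a patient's samples in three steps:

1. **High-confidence filter.** A (variant, tumor sample) call is retained
   iff tumor and matched-normal depth are both at least 10x, the tumor VAF
   is at least 5%, the normal VAF is strictly below 1%, and at least three
   reads support the variant in the tumor.
2. **CNV drop.** A mutation called in one sample but absent from another
   is discarded from *all* samples when the locus falls in a copy-number
   loss region (total copy number at most 1) of a non-carrying sample: the
   absence is then explained by the loss, and presence/absence at that
   site is uninterpretable for clonality.
3. **Force calling.** For every mutation in the patient's aggregate call
   set, samples without a call recover one if the site is covered at 10x
   or more with at least two supporting reads. This rescues truly shared
   mutations whose VAF fell below the caller's threshold in one sample.

Force calling only adds and CNV drop only removes, so the mean shared
fraction between the primary and recurrent sets never decreases after
force calling — a structural guarantee the test suite asserts on every
simulated case. The order (filter, then drop, then force) matters: forced
calls never resurrect CNV-dropped sites. Whether the normal-depth
requirement applies again at force-calling time is not specified upstream;
we require tumor depth only, since the normal evidence was already
screened at the first step.

## Clonal relatedness

Two tumors are compared through their shared **nonsynonymous** SNVs and
indels (variant identity is exact chromosome/position/allele identity
after indel normalization). For a shared mutation with population
frequency $p$ — its occurrence count in a background cohort catalog
divided by the total number of mutations in that cohort — the chance of
independent co-occurrence in two tumors is the binomial probability of two
successes in two trials, $P = p^2$. Over $M$ shared mutations the
clonality index is

$$\mathrm{CI} = -\log_{10} \prod_{m=1}^{M} p_m^2
             = -2 \sum_{m=1}^{M} \log_{10} p_m ,$$

evaluated in log space. Shared mutations absent from the catalog receive a
pseudo-count of one occurrence ($p = 1/N$): the conservative floor, since
an unobserved mutation is at most as common as a singleton, and rarer
shared mutations are *stronger* evidence of relatedness. CI is additive
over disjoint sets and zero for an empty set. Promoter and other
noncoding hotspot variants are excluded from CI; the index is defined on
nonsynonymous events only.

### Cutoff calibration

The classification threshold is calibrated by resampling a reference
cohort of unrelated tumors. Positive controls imitate clonally related
pairs: for each reference tumor and each fraction in {0.40, 0.60, 0.80},
two independent subsamples of its mutation set are drawn (duplicate
versus duplicate) and scored; with 200 tumors this yields 600 related
pairs per repeat. Negative controls are 600 random unrelated tumor pairs.
The per-repeat optimal cutoff maximizes accuracy, and the calibration
result is the median over 100 repeats. Tumor sets are sorted into a
canonical content order before resampling so the result does not depend
on input order.

One design point deserves emphasis. With genome-scale mutation sets the
positive controls are overwhelming (hundreds of shared rare mutations,
CI in the thousands) while negatives share at most a few hotspot sites,
so *every* threshold in a wide gap maximizes accuracy. We place the
cutoff at the low end of that gap — one CI unit above the strongest
negative control, far less than the contribution of a single shared
mutation (about 6-11 CI units). This keeps the classifier sensitive to
weakly related pairs, whose CI can sit one to two orders of magnitude
below the positive controls, while retaining full specificity against
the empirical null. It also mirrors where the published threshold for
this assay sits relative to its control distributions: close to the
unrelated-pair scale, far below typical related pairs. A cutoff placed
mid-gap would misclassify genuinely related pairs that share only a
handful of nonsynonymous mutations.

A recurrence is called ancestral iff CI is at or above the cutoff (a tie
goes to ancestral — the convention is arbitrary but fixed). The shared
fraction grouping, the Jaccard coefficient, shared structural-variant and
viral-integration breakpoints (matched by type, chromosome pair, and
10 bp position tolerance) are reported alongside as concordance checks.

### Location, WGD, gene CNV classes

Recurrence location is summarized by the hepatic segment interval (HSI):
the smallest absolute difference between any Couinaud segment occupied by
the primary and any occupied by the recurrence, capped at 4; HSI of 0 or
1 is a local recurrence, 2-4 distant. This linearizes the Couinaud
numbering; true three-dimensional adjacency of liver segments is not
modeled. Whole-genome doubling is called when ploidy exceeds 2.9
(strictly). Gene-level copy-number classes compare a gene's total copy
number with the gene-level median ploidy: 0 is a deletion, more than
twice the median an amplification, above the median a gain, below it a
loss; precedence deletion > amplification > gain > loss.

## Cancer cell fractions and clustering

For a mutation with variant allele fraction $f$, tumor purity $\rho$,
local tumor copy number $C_t$ and normal copy number $C_n$ (2 on
autosomes),

$$f = \frac{\rho \,\mathrm{CCF}}{C_n (1 - \rho) + \rho\, C_t}
\quad\Longrightarrow\quad
\mathrm{CCF} = f\,\frac{C_n (1 - \rho) + \rho\, C_t}{\rho},$$

clipped to $[0, 1]$. Mutation multiplicity is fixed at one copy per
mutated cell — the CCF relation above carries no multiplicity term — and
$C_n = 2$ throughout (sex-chromosome hemizygosity is not modeled). Both
are documented limitations. Unsegmented loci fall back to the rounded
sample ploidy.

Mutations are grouped by shared CCFs across all of a patient's tumor
samples with a finite binomial mixture: cluster $k$ has one CCF per
sample, and the alt count of mutation $m$ in sample $s$ is binomial with
success probability $\kappa_{ms}\,\phi_{ks}$, where $\kappa$ folds purity
and local copy number into the expected-VAF relation above. The model is
fitted by EM; the M-step uses the closed-form weighted moment estimator
$\hat\phi_{ks} = \sum_m r_{mk} a_{ms} / \sum_m r_{mk} d_{ms}\kappa_{ms}$,
exact when $\kappa$ is constant within a sample. The number of clusters
is chosen by BIC over $K = 1..8$; each $K$ is fitted from a k-means
initialization on per-mutation CCF estimates plus 10 seeded random
restarts (short runs, best one polished). The procedure is deterministic
under a seed, and with noiseless input and distinct CCF vectors it
recovers the exact partition. For whole-genome burdens the mixture is
fitted on a capped subsample (default 3,000 mutations) and remaining
mutations are assigned by maximum posterior — the standard practice for
this model class.

One estimation caveat: a cluster private to a single sample enters the
analysis only through mutations that were *called* there, and
conditioning on calling (VAF at least 5%, three reads) biases low-CCF
branch centers upward. The synthetic generator therefore prefers branch
CCFs comfortably above the calling floor where purity allows; in real
low-purity samples the same bias applies and should be kept in mind when
reading branch CCFs near the detection limit.

Clusters holding fewer than 5/1,000 of the patient's mutations
(strictly) or containing only silent mutations are removed before any
architecture or category interpretation.

## Categories and subclonal architecture

A cluster is *present* in a sample when its CCF center is at least 0.05
(the presence threshold is not defined upstream; it is configurable).
Cluster centers, not per-mutation CCFs, are compared against the clonal
threshold of 0.8 (strict). Under the paired ancestral scheme, clusters
present in both tumors are trunk — the trunk clone requires CCF above 0.8
in every tumor sample, and at most one cluster can be the clone (ties
resolved toward the largest minimum CCF) — while one-sided clusters are
primary or recurrence branches. De novo cases are classified per tumor
into clone/subclone, and multi-region cases into trunk, branch (several
regions), and leaf (one region) subclones.

The architecture is a rooted tree over the retained clusters obeying two
constraints within a tolerance $\varepsilon$: a parent's CCF dominates
each child's in every sample, and the children of any node never sum
above the node, per sample. These encode the pigeonhole rules — two
clusters whose CCFs sum above 1 in some sample cannot be disjoint
lineages, and clusters with reversed CCF ordering across samples cannot
be nested. Construction inserts clusters in decreasing total-CCF order
(ties: larger size, then id) and tries feasible parents by decreasing
minimum margin, backtracking when a later cluster becomes unplaceable;
the search is deterministic and, by exhaustive enumeration on up to six
clusters, always returns a member of the valid-tree set. The default
$\varepsilon$ is 0.05 CCF, sized to sampling noise at ~54x depth; the
pipeline relaxes it stepwise (up to 3x) if noise leaves no valid tree at
the nominal value. Branch lengths scale cluster mutation counts by the
primary tumor's total burden, making tree size comparable across
patients; trees serialize to Newick with cluster ids as labels.

Driver alterations are nonsynonymous SNVs/indels and promoter mutations
in a configurable driver-gene list (timed by the category of their
cluster), and gene-level amplifications/deletions of those genes (timed
by the sample set exhibiting them: all samples - trunk clone; both tumors
but not all samples - trunk subclone; one tumor - branch). Structural
variant breakpoints can be supplied pre-annotated with genes; without
gene annotation they contribute to breakpoint sharing but not to driver
timing.

Spatial heterogeneity is the mean of $1 - \mathrm{Jaccard}$ over region
pairs within a tumor (primary and recurrent pooled); temporal
heterogeneity the mean over cross-tumor region pairs. The upstream
definition of an "ITH percentage" is not given; both per-pair values and
means are exported so either denominator convention can be recovered.
Polyclonal seeding is called when at least two non-clonal trunk clusters
are present subclonally (CCF in [0.05, 0.8)) in two or more recurrent
regions; clusters present in every recurrent region but absent from all
primary regions are flagged as monophyletic-dissemination candidates.

## Mutational spectra and signatures

Single-nucleotide substitutions are tabulated in the six
pyrimidine-reference classes and, with trinucleotide context, in the 96
standard categories (purine-reference records are reverse-complemented).
Exposures are refitted by non-negative least squares against a reference
signature matrix, with iterative thresholding: any signature whose
normalized weight falls below 6% is zeroed and the remaining columns are
refitted until stable; final weights are renormalized to sum to one. The
6% cutoff mirrors the documented default of the standard refitting tool;
exposures are computed on normalized spectra per category. Hypermutation
is flagged above 9 mutations/Mb (strict) with a fixed 2,800 Mb callable
autosomal genome.

The reference matrix shipped with the package,
`synthetic_signature_matrix()`, is **synthetic**: 30 deterministic
probability columns with a few designed anchors at familiar column
positions (CpG-deamination-like column 1, tobacco-like C>A column 4, a
near-flat clock-like column 5, the T>A-dominant aristolochic-acid-like
column 22 used by the hypermutator simulation, and an aflatoxin-like
column 24). It stands in for an external signature catalog so the
refitting machinery is fully testable offline; any user-supplied matrix
with matching 96-category row labels can be passed wherever a signature
matrix is accepted, and results on real data should use a real catalog.

## The synthetic cohort

`simulate_cohort()` generates patients with known ground truth under the
study conditions the package targets: 40 patients per cohort with a
22/40 ancestral fraction; 2-5 retained mutation clusters per tumor;
3,000-85,000 genome-wide mutations per tumor (log-uniform; means near
16,000); Poisson depth with mean 54x in tumors and 36x in the normal;
binomial allele counts around the expected VAF; per-sample purity uniform
on 0.3-0.9 (per-patient purities are not published; this range is the
package's choice); shared-fraction targets of 0.25-0.80 for ancestral and
0.006-0.05 for de novo pairs; a 12.5% per-patient hypermutator
probability with burdens of 26,000-83,437 and a T>A-dominant spectrum;
whole-genome doubling rates of 8/40 in primaries and 12/22 vs 2/18 in
ancestral vs de novo recurrences; and local-recurrence probabilities of
20/22 given ancestral and 8/18 given de novo, so the published
pattern-location association is built in.

The background catalog couples a shared hotspot layer — hotspot $k$
enters each tumor independently with probability proportional to
$k^{-1.5}$ (top hotspot 0.35) — with tumor-private keys, giving the
long-tailed rank-frequency curve of recurrent sites while keeping
unrelated-pair sharing at the low level observed between independent
tumors. De novo pairs share mutations through two channels: chance
hotspot co-occurrence (clonal in both tumors), and a low-CCF silent-only
background cluster, callable in one tumor and recoverable only by force
calling in the other — reproducing the observation that de novo shared
mutations are nearly all subclonal, never drivers, and that the shared
fraction rises after force calling. Each case additionally plants: CNV
artifacts (clonal mutations private to one tumor inside a copy-number
loss window of the other, placed in a reserved chr22 interval so they
never collide with ordinary mutations) to exercise CNV drop; a deepest
trunk subclone that is sub-threshold in the primary sample in half of
paired cases, the natural force-calling substrate; a silent-only decoy
cluster to exercise the silent filter; and driver mutations on designated
nodes (trunk-clone TP53/AXIN1, trunk-subclone CTNNB1/TERT-promoter,
branch ARID1A, plus recurrent-only oncogene amplifications). Trunk
subclones jointly receive most of the trunk burden (the clone gets
12-22%), reproducing the reported excess of trunk-subclonal over
trunk-clonal mutations. Cluster CCFs are drawn by budget-tracked
stick-breaking that respects the pigeonhole constraints, keeps clusters
separated (at least 0.1 in max-norm, relaxed to 0.08 when low purity
forces a leaner structure), and guarantees each non-decoy cluster is
callable in at least one sample.

In noiseless mode (fixed large depth, rounded expected counts) the
generator's analytic truth — per-sample final sets, shared fractions,
categories — is reproduced *exactly* by the pipeline, which the test
suite asserts; at 54x the truth values are the noiseless-limit targets.

What the generator does not emulate: sequencing error and artifact
processes (the de novo background cluster is a phenomenological stand-in
for whatever produces low-VAF shared calls in real pairs), germline
variation, subclonal copy number, multiplicity above one,
sex-chromosome copy states, and real signature profiles. Passing tests
therefore demonstrate that the statistical machinery recovers the truth
of a faithful generative model at realistic depth and purity — not that
caller-specific artifacts in real data are handled.

## Problem sizes used by tests and the acceptance script

Unit and acceptance runs scale the per-tumor burden down (typically
600-8,000 mutations per tumor, with hypermutator burdens scaled
alongside) and cap the clustering subsample at 1,200 mutations so a full
run completes in minutes; depth, purity, shared-fraction targets and the
200 x 1,000 Zipf catalog stay at study conditions. Pattern-recovery runs
use cohorts of 40 patients; distribution-level checks use 20 seeds.
These sizes are stated here once as the package's chosen test scale.

## Interfaces

The package is function-first: `simulate_cohort()` / `simulate_case()`
produce inputs, `harmonize_case()`, `clonality_index()`,
`calibrate_ci_cutoff()`, `cluster_mutations()`,
`build_subclonal_architecture()`, `category_exposures()` expose each
stage, and `run_case()` / `run_cohort()` orchestrate them; results come
back as tibbles (with `tidy()`/`glance()` methods) plus plot helpers. On
disk, cases are MAF-like and SEG-like TSVs tied together by a YAML/JSON
manifest, and case reports are JSON summaries, TSV tables and Newick
trees. A shell entry point is deliberately not shipped: the intended user
drives analyses from R, and `scripts/acceptance.R` shows the end-to-end
invocation pattern.
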