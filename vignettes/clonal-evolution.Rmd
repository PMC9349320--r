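---
title: "Models and methods behind mmclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mmclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmclone)
```

# The problem

Multiple myeloma infiltrates the bone marrow diffusely (sampled by
random iliac-crest aspirates) and as focal lesions (sampled by
CT-guided biopsy). When a patient is sequenced at several anatomical
sites and several treatment lines, the variant allele fractions of
somatic SNVs carry enough information to reconstruct the subclonal
architecture at each site and time, and to ask how relapse arises:
from one surviving cell, from several coexisting subclones, or from
site-unique expansions. `mmclone` implements this reconstruction as a
tested pipeline with a synthetic-cohort generator providing ground
truth.

# Cancer clonal fractions

For one mutation in one sample, with variant allele fraction
$f_s$, tumor purity $p \in (0, 1]$ and locus total copy number
$n_\mathrm{locus}$, the mutation copy number is

$$ n_\mathrm{mut} \;=\; f_s \cdot \frac{1}{p}\,
   \bigl[\, p\, n_\mathrm{locus} + 2\,(1 - p) \,\bigr], $$

i.e. the allele fraction rescaled by the average number of
chromosome copies per cell at the locus (tumor contributes
$p\,n_\mathrm{locus}$, the diploid admixed normal $2(1-p)$). The
multiplicity $n_\mathrm{chr}$ is the copy count
$C \in \{1, \dots, n_\mathrm{locus}\}$ that maximizes the binomial
likelihood of the observed variant reads at the allele fraction a
fully clonal mutation on $C$ copies would show,
$f(C) = C p / (p\,n_\mathrm{locus} + 2(1-p))$, with ties broken
toward the smaller $C$. The cancer clonal fraction is
$\mathrm{CCF} = n_\mathrm{mut} / n_\mathrm{chr}$, capped at 1 with a
`capped` flag preserved for diagnostics.

Two numerical choices matter here:

* **Saturated sites.** At $C = n_\mathrm{locus}$ and high purity the
  expected allele fraction reaches 1 exactly, which would give
  probability zero to any non-variant read and make the fully
  mutated state unselectable. Likelihood evaluations therefore clamp
  expected allele fractions at $1 - 0.02$, a small allowance for
  sequencing error at the base-quality-20 level and residual
  reference bias. `expected_vaf()` itself returns the pure formula.
* **Unevaluable entries.** A mutation without a covering copy-number
  segment, or inside a homozygous-deletion call
  ($n_\mathrm{locus} = 0$), gets an explicitly unevaluable entry —
  never a silent default — and is excluded from clustering. The
  capped CCF is a reporting convention: recovery checks average the
  uncapped ratio $n_\mathrm{mut}/n_\mathrm{chr}$, which is unbiased,
  whereas the mean of the capped value is necessarily below 1 for a
  clonal mutation at finite depth.

# Inclusion filters

The analysis-ready mutation set of a patient keeps SNVs that
(1) have coverage strictly exceeding 20x in every sample of the
patient, (2) pass base/mapping quality everywhere, (3) lie outside
the immunoglobulin loci, and (4) reach a CCF of at least 0.20 in at
least one sample. The CCF floor uses provisional CCFs computed on
the full candidate set in a single two-pass sweep (no iteration).
When several rules fail, the first in the order coverage, quality,
Ig locus, CCF floor is reported, and the per-category counts always
reconcile with the input size. A mutation with no evaluable CCF in
any sample fails the floor: the required evidence cannot be shown.
Detection in a paired sample requires at least two variant reads.
The packaged Ig intervals (IGH on 14, IGK on 2, IGL on 22, GRCh37)
are defaults a user can override with any interval file; they are
not derived from any specific cohort. Copy-number segments are gated
at 5 Mb for global analyses and at 1 Mb for deletions overlapping
supplied driver intervals.

# Paired-sample heterogeneity

For a pair of samples, each mutation detected in at least one of
them falls in exactly one class: *unshared* if detected in only one
(minor/major by whether its CCF in the detecting sample is below or
at least 0.60), *shared-differential* if detected in both with at
least a threefold CCF difference (subclonal/clonal by the larger CCF
against 0.60), *shared* otherwise. The threefold rule is
$\max/\min \ge 3$ with $\min > 0$; an exact threefold ratio counts
as shared-differential, and a $10^{-9}$ relative slack keeps that
boundary safe from floating-point rounding. The clonal/subclonal
split of a shared-differential mutation uses the larger CCF — the
choice is open in principle, and the larger CCF reflects the sample
where the subclone is actually expanded. Proportions are exact count
ratios. Group comparisons use the two-sided
Mann–Whitney–Wilcoxon test: exhaustive enumeration of group
assignments for a combined size up to 12 (two-sided by the
deviation of the U statistic from its null mean, ties mid-counted),
a tie-corrected normal approximation with continuity correction
beyond.

# Subclones and clone trees

Mutations are clustered across a patient's samples with a binomial
mixture model. Cluster $k$ has a per-sample CCF vector
$\phi_{ks}$; mutation $i$ contributes
$\prod_s \mathrm{Binom}(a_{is} \mid d_{is}, \phi_{ks} c_{is})$,
where $c_{is}$ is the clonal allele-fraction factor implied by the
sample's purity and the mutation's copy number and multiplicity.
The fit is by EM (compiled), with the per-(cluster, sample) M-step a
weighted binomial MLE solved by a moment start plus Newton
refinement. The number of clusters is chosen by BIC over
$k = 1, \dots, k_\mathrm{max}$ (default 8; the scan stops early
after two consecutive BIC deteriorations). Initialization is
deterministic Ward-linkage hierarchical clustering of the naive CCF
matrix, with a seeded k-means restart — elongated, well-separated
clusters are exactly the shape on which random k-means starts
occasionally collapse, and the Ward tree does not. Only mutations
with depth of at least 50 in every sample enter the EM; the rest
are assigned afterwards by maximum likelihood. Clusters with fewer
than two mutations and no attached copy-number aberration are
invalid and merged into the nearest valid cluster.

The clone tree is built over the cluster centroids under two rules
with a shared tolerance (default 0.10 CCF): a parent must be at
least each child minus tolerance in every sample (pigeonhole), and
the children of a node may not sum above it plus tolerance in any
sample. All rooted trees are scored exhaustively for up to five
non-root nodes (greedy insertion beyond), minimizing the total rule
violation; ties prefer fewer branching points, mirroring parsimony
(a chain is preferred to a fork when both are consistent). The root
is the cluster that dominates all others everywhere; if none does, a
mutation-free most-recent-common-ancestor node is synthesized. When
no tree is violation-free the best tree is returned together with an
explicit violation report — the discrepancy is surfaced, never
guessed away.

Terminal clone proportions are centroid minus the sum of child
centroids, floored at zero. A clonal sweep between consecutive
timepoints of one site class is a dominance turnover: some clone
rises from below the minor threshold (0.20) to dominance (0.60)
while a previously dominant clone falls below 0.20. The 0.60 and
0.20 defaults deliberately reuse the clonal cutoff and the CCF
floor; both are configurable, as the sweep thresholds are not
printed quantities. Parallel evolution flags a gene (or a configured
gene family such as KDM/KMT) mutated on two branches neither of
which is ancestral to the other, with no ancestral event in that
gene.

# Treatment-signature analysis

Branch-defining (cluster-private) mutations are binned into the 96
pyrimidine-normalized trinucleotide substitution classes and fitted
against a signature catalog by maximizing the multinomial
log-likelihood of the counts under a mixture of catalog profiles.
The optimizer is EM with closed-form updates, accelerated by squared
extrapolation (SQUAREM) with a monotone fallback; convergence is an
improvement below $10^{-10}$ in log-likelihood. The simplex
projection after extrapolation floors coordinates at $10^{-10}$
because an exact zero is a fixed point of the multiplicative EM map
and could freeze the iteration at a non-optimal boundary.

The presence of a target (melphalan-like) signature is tested by a
likelihood ratio between fits with and without the target, with the
null distribution obtained by parametric bootstrap from the
constrained fit and the $(r+1)/(B+1)$ continuity correction
(default $B = 1000$, seeded). Observed and bootstrap fits use the
same uniform initialization; warm-starting only the bootstrap fits
at the constrained optimum was measurably anti-conservative
(bootstrap statistics converge from a different side than the
observed one) and is not done. A subclone is flagged as a
single-cell-expansion candidate when it has at least 25 defining
mutations, the presence test rejects at 0.05, and the fitted target
exposure is positive; below 25 mutations the verdict is "not
evaluable", never negative. The packaged catalog is synthetic —
seven smooth background profiles labelled after the signatures
commonly refitted in myeloma plus a sparse eight-context treatment
profile — and is **not** the COSMIC catalog nor the real SBS-MM1;
any COSMIC-format catalog can be supplied at runtime.

# Evolutionary patterns

Relapse branches are the subtrees hanging off the root whose cells
reach the detection proportion (0.20, again the CCF floor) in at
least one follow-up sample; a patient whose follow-ups contain only
the trunk counts as one branch. One branch means single-cell
expansion. With two or more, the patient is *coexisting subclones*
if two branches are co-detected in at least one sample, and
*alternating spatial dominance* if they never are. A patient with
both co-located and site-unique branches is labelled coexisting
(co-location dominates) with the site-unique evidence recorded — the
mixtures exist and the label alone should not hide them. The
signature flag corroborates but is not required for the single-cell
label. The per-patient report collects the pattern, sweep count,
flagged branches, parallel-evolution genes and subclone counts per
timepoint and in total.

Clinical association uses Fisher's exact test with the
point-probability two-sided convention (all tables with fixed
margins whose probability does not exceed the observed one, within
$10^{-12}$ relative slack), which is the common statistical
practice; conventions differ, so it is stated here. The GEP70 score
is the mean log2 expression of the 51-gene up set minus the mean of
the 19-gene down set, high risk at 0.66 or above; the gene lists
are configuration, a placeholder list ships for tests, and a set
with more than 20% of its genes missing is refused with a
missing-gene report rather than imputed silently.

# The synthetic cohort

The generator scripts clone trajectories per scenario rather than
simulating growth dynamics, so truth labels are unambiguous:

* *single-cell expansion*: a minor baseline branch (CCF 0.10) sweeps
  to dominance after treatment while the baseline-dominant branch
  (0.65) is extinguished; a descendant subclone (0.55) appears at
  the last timepoint. One planted sweep.
* *coexisting*: two branches co-detected at follow-up (0.60/0.30,
  then 0.25/0.70), dominance switching without a sweep under the
  configured thresholds.
* *alternating*: one branch dominates the iliac crest (0.90), the
  other a focal lesion (0.85), never co-detected. One planted sweep
  at the iliac crest.
* *null*: trunk only.

Per patient: 100 trunk mutations; per-branch mutation counts uniform
in 25–400; purity uniform in 0.5–0.95 per sample; depth
negative-binomial with mean 121 (dispersion size 10) — the study
conditions the package is built around. Reads are binomial at the
allele fraction implied by inverting the CCF equation from the
scripted clone fractions, purity, multiplicity and local copy
number. The genome layout is simple: a trunk gain on chromosome 1
(total copy 3, trunk mutations there carry multiplicity 1 or 2), a
deletion on chromosome 13 (total copy 1), diploid elsewhere; two
immunoglobulin-locus decoy variants exercise the exclusion filter.
Trinucleotide contexts are drawn from branch-specific signature
mixtures; post-treatment branches receive the treatment signature at
exposure 0.3.

What the simulator does **not** emulate: subclonal copy number,
over-dispersed (beta-binomial) read counts, stochastic clonal
growth, sampling geometry within the marrow, germline variation, or
purity estimation error. Passing recovery tests therefore shows that
the estimators invert the stated generative model at realistic depth
and purity — not that they are robust to every artefact of real
sequencing data.

# Problem sizes and verification

The test suite verifies, among others: multiplicity assignment
against brute-force likelihood enumeration on randomized grids; CCF
recovery within ±0.05 on a grid of clonal fraction × purity × copy
number at depth 121 with 200 replicates per cell; exposure fits
against a grid-search oracle on the 1-simplex (step 0.001);
presence-test type-I error at nominal 0.05 over 1000 null
simulations with $B = 200$; cluster-count, topology, pattern and
sweep recovery on 50 simulated patients per scenario (one shared
cached run); Fisher and Mann–Whitney against enumeration oracles;
and bit-exact behaviour of every published threshold at its
boundary. Newick output round-trips through `ape::read.tree`.

# Known limitations

* The tree search is exhaustive only up to five non-root subclones;
  larger fits fall back to greedy insertion, which can miss the
  global violation minimum in pathological configurations (a
  violation report still makes any inconsistency visible).
* The binomial read model ignores over-dispersion; on real data a
  beta-binomial would be the natural extension.
* Manual tree refinement as practiced on real cohorts (driver
  knowledge, translocations) is out of scope: translocation status
  is consumed as annotation only.
* Purity and copy number are consumed as inputs; errors in them
  propagate directly into CCFs.
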