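---
title: "Reconstructing and improving 3D genome models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and improving 3D genome models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genome3d)
```

# The model

Chromosomes are represented as beads on a string: each chromosome is cut into
fixed-size bins (default 10 kbp), and each bin is a point in 3D space inside
a spherical nucleus centered at the origin. A Hi-C experiment counts
proximity-ligation events between pairs of bins; contact frequency decreases
with spatial distance, so a contact map can be converted into a map of
*target distances* $\delta_{ij}$ in nanometers. A consensus structure is then
the solution of the constrained non-linear least-squares problem

$$\min_{p} \sum_{(i,j)} \big(\lVert p_i - p_j\rVert - \delta_{ij}\big)^2$$

subject to five constraint classes: all beads inside the nucleus sphere;
bounded stretch between adjacent beads; a minimal separation between
non-adjacent beads; optionally a nucleolar exclusion sphere; and optionally
beads pinned at known coordinates. Because population Hi-C averages over many
conformations and the optimization is non-convex, reconstruction is treated
as a stochastic procedure: several random restarts are run and populations of
models are compared, never a single structure.

## Contact frequencies to distances

`fit_distance_profile()` builds a monotone profile of mean contact frequency
versus genomic separation from **all** intra-chromosomal bin pairs —
unobserved pairs count as frequency zero. This zero-inclusive averaging
matters: if only observed entries were averaged, the lowest profile knot
would sit at the mean of the observed far-separation counts, roughly half of
all entries would fall below it, and the inversion would clamp them all to
the maximal distance. Counting zeros pushes far-separation bin means down to
realistic small values so that observed entries invert inside the profile.

Frequencies are forced monotone non-increasing in separation by
pooled-adjacent-violators (the flat tail produced by spatial confinement
collapses into a single knot), and the profile is inverted by linear
interpolation on the frequency axis. Frequencies above the largest knot clamp
to the smallest separation; below the smallest knot, to the largest.
Separation in bp becomes nm through a constant chromatin packing ratio of
130 bp/nm. The linear packing assumption is only approximately valid at
large separations, where real (and simulated) polymers saturate at the
confinement scale; consequences for integration are discussed below.

## The optimizer

Eq. 1 plus the constraint classes is solved with a quadratic-penalty scheme
over L-BFGS-B with analytic gradients implemented in C++. Penalty weights
escalate (up to four rounds, factor 10) until the maximum constraint
violation falls below the feasibility tolerance (default 5 nm). Fixed beads
use box constraints with `lower = upper`. Among `n_starts` random
initializations (default 4), the best model is the one minimizing
(thresholded violation, objective) lexicographically — a feasible model
always beats an infeasible one. Convergence is governed by L-BFGS-B's
relative-improvement criterion with an iteration cap of 2,000, near the
original implementation's typical ~1,800 iterations.

Initialization lays each chromosome out as a confined random walk with steps
bounded by the adjacency constraint, reflected into the nucleus sphere; it is
deterministic per seed, and so is the entire reconstruction.

# Predicted interactions

Two sources of predicted distances can be merged into a base map.

**Orthologous projection.** Given a distance map for a related organism B,
each organism-B gene pair receives the distance of the nearest measured bin
pair around the genes' midpoints. Distances transfer to organism A by
averaging over all ortholog pairs: for families $O_i$, $O_j$,
$D^{B\to A}_{ij} = \frac{1}{|O_i||O_j|}\sum_{k\in O_i}\sum_{l\in O_j} D^B_{kl}$
(restricted to measurable ortholog pairs). Projected distances are rescaled
so their median matches the organism-A Hi-C distances (nuclear dimensions
differ between organisms), and by default the bottom 5% — the shortest,
best-supported distances — are retained as integration candidates. A
(0.50, 0) band is the preset for integrating into a complete map, where
coverage matters more.

**Codon usage.** Each gene's 64-codon frequency vector $p$ (stop codons
included, normalized to sum 1) yields a functional distance between genes:
with $m = (p+q)/2$,
$d(p,q) = d_{KL}(p,m) + d_{KL}(q,m)$, the symmetrized divergence underlying
the Endres–Schindelin metric. The metric proper carries a square root
(`sqrt = TRUE`); both variants are rank-equivalent, as is the choice of
logarithm base (natural log by default), so quantile-band selection is
unaffected. Codon-usage distances are median-scaled against the Hi-C
distances (a pure scaling, no intercept) and the top and bottom 10% are
retained — the extremes carry the co-localization and dispersion signal.

**Poor-get-richer merging.** Candidates overlapping the base map are
excluded. Each bead's degree is its number of distinct interaction partners,
floored at 0.5 for isolated beads. Candidates are then drawn sequentially
without replacement with probability proportional to $1/(d_i d_j)$, and both
endpoint degrees are updated after every draw. This preferentially reinforces
poorly covered regions and demonstrably reduces the variance of the
post-merge degree distribution relative to uniform sampling.

# The benchmark battery

* **NSD (normalized set distance)** — mean pairwise 3D distance within a
  locus set divided by the mean over 100 random equal-size sets drawn from
  the appropriate universe (annotated genes for gene sets, the uniform bin
  grid for interval sets); < 1 indicates co-localization. Partitioned sets
  report the mean of their subsets' NSDs. The normalizer is calibrated: the
  mean NSD of random sets lies in [0.95, 1.05].
* **Telomere radius** — mean distance of first/last beads of each chromosome
  from the nucleus center.
* **Chromosome-arm ratios** — cis-vs-trans, short-vs-long (250 kbp
  threshold), self-vs-else; arms are the bead runs flanking the centromere
  bead (which belongs to neither arm).
* **Model similarity** — Spearman correlation between the full bead-pair
  distance vectors of two models, averaged over model pairs (distances are
  rigid-motion and mirror invariant). `per_model_similarity()` returns each
  model's mean correlation with the rest of its category, usable as a paired
  per-model value.
* **Binned covariate correlations** — gene pairs sorted by a covariate
  (co-expression, PPI graph distance with 255 for disconnected pairs,
  protein-abundance distance $2|p-q|/(p+q)$, codon-usage distance), cut into
  2,000 equal-count bins, Spearman over bin means. Equal-count binning was
  chosen because it reduces exactly to plain Spearman when bins equal pairs.
* **Telomere clustering** — average-linkage tree on the telomere distance
  matrix averaged across a model population.

# Hypothesis testing

Paired model categories (a sampled map and its integrated extension) are
compared by one-tailed Wilcoxon signed-rank tests; independent categories by
rank-sum. Both agree with exhaustive enumeration for $n \le 8$.

The category-level permutation test shuffles models between two categories
10,000 times and recomputes a total benchmark statistic. The default
statistic is the sum over tests of the directed difference of category
medians standardized by the pooled SD. A directional win count (ties 0.5) is
available via `statistic = "wins"`, but it saturates at the battery size:
any permuted partition holding a majority of one category's models tilts
every test simultaneously, flooring the attainable p-value around 0.05–0.3
regardless of effect size. The standardized sum resolves small p-values and
is therefore the default. The p-value uses add-one smoothing,
$(1 + \#\{\text{perm} \ge \text{obs}\})/(n_{\text{perm}}+1)$.

`minimal_sparseness()` reports, per test, the smallest sampling fraction
such that it and all larger fractions are two-tailed-indistinguishable from
the complete data at the chosen level (default 0.01).

# The synthetic world

The generators produce a ground truth with the organization the method is
meant to detect, so every pipeline stage is testable without downloads.

* `make_genome()` — by default 3 chromosomes; the `"small"` preset uses
  70/50/30 beads at 10 kbp (150 beads, ~1.5 Mb). Each chromosome grows as a
  confined random walk from its centromere, which is tethered in a small cap
  near the envelope (Rabl-like clustering). Arms drift toward a
  per-chromosome territory axis (azimuths spread around the cap) and
  outward, so telomeres end peripheral and cis-vs-trans < 1. A relaxation
  pass guarantees zero violation of the default constraint set.
* `simulate_contacts()` — Poisson counts with rate $\propto d^{-\alpha}$
  (default $\alpha = 1$), expected total 4×10^5 reads for the small preset,
  emitted as fragment-level records at random positions within bins.
* `make_genes()` / `make_planted_set()` — ~2 genes per bead; the planted
  compact set is the 15 beads nearest a random anchor in 3D (true NSD well
  below 0.8).
* `make_cds()` — genes are k-means clustered by 3D position (default 20
  clusters); cluster codon-frequency centers are distance-weighted mixtures
  of 4 Dirichlet archetypes anchored at random nuclear positions (mixing
  scale 300 nm), so codon-usage distance tracks spatial separation
  continuously rather than only within/between clusters; CDS of 600 codons
  (a typical ORF length) are sampled codon-by-codon with a 0.1 noise
  admixture. With iid cluster centers, inter-cluster codon distances carry
  no geometry and the emulated premise — codon usage strongly correlated
  with 3D distance — fails; the anchored mixture is the minimal construction
  that delivers it.
* `make_organism_b()` — organism B is the truth plus isotropic Gaussian
  coordinate jitter (default 50 nm), with an ortholog table covering 90% of
  genes (10% of families 1:2); its distance map is the exact bead-pair
  distances of the jittered structure, standing in for an experimentally
  calibrated map.

**What a green test does and does not establish.** The world is a single
polymer-like structure with planted, noiseless organization; real Hi-C
carries population heterogeneity, restriction-site and mappability biases,
and genome rearrangements between organisms, none of which are emulated.
Green acceptance tests establish that the machinery recovers planted signals
under the stated noise models at desk scale — not that the biological
magnitudes of any particular dataset are reproduced.

## A scale caveat that shaped the acceptance battery

At this size the distance profile spans at most 69 distinct separations, and
spatial distance saturates at the confinement scale well inside that range.
The bp→nm conversion therefore overestimates far distances, and the mass of
far/trans entries clamps at the largest profile knot, which can place the
*median* of the assay-derived distance map on the saturation plateau. The
integration pipeline normalizes predicted distances by matching medians —
with a plateau median, correct candidate distances would be inflated several
fold and turned into harmful constraints. The acceptance battery therefore
exercises sparseness and randomization logic (criteria 2–3) on the
assay-derived map, where only orderings matter, and the integration logic
(criterion 4) on the exact truth-derived map, where the median normalization
is meaningful. At realistic genome sizes the profile reaches far lower
frequencies and the plateau holds a much smaller mass, so this is a
desk-scale artifact, not a property of the method.

# Numerical choices

* Distance maps store each unordered pair once (i < j), exclude the
  diagonal, and require positive distances.
* Iterative correction equalizes per-bin coverage on the support to a
  coefficient of variation below 10^-8 by default and rescales to the input
  total; zero-coverage bins are untouched.
* Damping rounds half away from zero ("nearest integer" with an explicit tie
  rule); rank conversion of damped maps breaks count ties by a seeded
  shuffle.
* $0 \log 0 = 0$ in all divergence computations; a tiny negative rounding of
  the codon-usage distance is clipped to 0.
* Genes map to the bin containing their midpoint; strand is ignored.
* All randomized operations take explicit seeds and restore the caller's RNG
  state; derived sub-seeds stay below 2^31.

# Known limitations

* The minimal-separation constraint is enforced as a soft short-range
  penalty, not a hard constraint; reported feasibility uses the 5 nm
  tolerance.
* `gene_pair_distances()` searches a bounded window (default ±10 bins) for
  the nearest measured bin pair; genes in measurement deserts are skipped.
* The permutation-test statistic is a design choice (see above); p-values
  are not claimed to reproduce any published values exactly.
* No FDR filtering of contacts, no ortholog inference, no population
  deconvolution, no diploid phasing.
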