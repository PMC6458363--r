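---
title: "Models and methods behind rhizonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rhizonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rhizonet)
```

rhizonet analyses paired 16S (prokaryote) and ITS (fungal) sample-by-OTU
count tables from plant roots and rhizosphere soil, in designs where
host individuals are classified into health states (`green`, `yellow`,
`no_leaf`) along planting lines. This vignette explains the statistical
machinery, the defaults and why they are what they are, what the
simulator does and does not emulate, and the known limitations. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Preprocessing

Three table-level filters, applied in a fixed order:

1. **Cell filter** (`filter_rare_cells()`, default 0.1%): a cell is
   zeroed when its count is *strictly less than* `threshold` times its
   sample's total, with totals taken before any zeroing (single pass,
   never iterated — iterating would make the filter depend on its own
   output). Ties at the threshold are kept. This removes index-hopping
   and PCR carry-over noise that otherwise inflates rare-OTU prevalence.
2. **Rarefaction** (`rarefy()`, default depth 1000): a uniform draw
   without replacement (multivariate hypergeometric) of exactly `depth`
   reads per sample; shallower samples are discarded and listed in the
   attached report. Each sample uses an RNG stream hashed from
   `(seed, sample_id)`, so subsetting a table never changes another
   sample's draw — reruns are reproducible under subsetting, which a
   single global stream cannot guarantee.
3. **Prevalence filter** (`filter_prevalence()`, default 30 samples,
   inclusive): applied only on the network branch, because partial
   correlations estimated from OTUs present in a handful of samples are
   dominated by zeros.

## The preference screen

For OTU $i$ and state $j$, with $N_{\mathrm{obs}}(i,j)$ the mean read
count over state-$j$ samples,

$$\mathrm{preference}(i,j) =
  \frac{N_{\mathrm{obs}}(i,j) - \overline{N_{\mathrm{rand}}}(i,j)}
       {\mathrm{sd}\,N_{\mathrm{rand}}(i,j)},$$

where the null moments are the mean and (population) standard deviation
of the per-state mean across label shufflings of all samples. The
population denominator is deliberate: it makes Monte-Carlo values
converge exactly to enumeration over all label assignments, which is
what the small-sample oracle tests check. Defaults: 100 000
permutations; shuffling is joint across all samples (a
`stratify_by_set` switch restricts it within sampling sets as a
sensitivity analysis — the unrestricted shuffle is the primary
procedure, and on spatially structured data the two can disagree).

Implementation details that matter:

* The permutation loop is a two-pass C++ kernel: pass one records every
  permuted label vector and accumulates the null moments; pass two
  replays them to count permutations at least as extreme as the
  observation, giving the two-sided empirical p with the add-one
  estimator $(1 + \#\,\mathrm{exceed})/(n_{\mathrm{perm}} + 1)$ — never
  zero, slightly conservative.
* Samples are processed in `sample_id` order internally, so results are
  exactly invariant to row order.
* `null_sd = 0` (an OTU constant across samples) is flagged
  `degenerate`, given preference 0 and p 1: such an OTU carries no
  label information and must never pass a screen.
* q-values are Benjamini–Hochberg over all (OTU, state) pairs of one
  marker × compartment dataset.
* The shortlist rule is `preference >= 3`, *inclusive*. The screening
  convention this implements is usually stated as "greater than three",
  but ties at exactly 3.0 have measure zero and the inclusive form
  matches how shortlists are tabulated in practice.

### What the calibration shows — and does not

`screen_calibration()` simulates the full design (150 OTUs, 97/19/15
samples, 10% of OTUs planted 8-fold enriched, Dirichlet-multinomial
depth 1000, 20 000 permutations per replicate, 50 replicates) and pools
all `preference >= 3` calls against the planted truth. Sensitivity for
planted effects at ≥ 1% baseline abundance is essentially 1, and stays
above 0.9 well below that.

The empirical FDR of the bare `z >= 3` rule, however, lands near 0.09
under these conditions, not below 0.05. The arithmetic is unforgiving:
15 planted effects cap the true-call count, so FDR ≤ 0.05 requires a
per-pair null exceedance below ~0.002, while the permutation z of a
mean of 15–19 right-skewed counts has a one-sided tail at 3 of
0.003–0.007 (the kernel itself is correctly calibrated: on near-Gaussian
null counts the measured tail matches the normal 0.00135, and even in
the pure-multinomial limit the pooled FDR stays slightly above 0.05).
The practical recommendation follows directly: treat `preference >= 3`
as a ranking device and gate decisions on the empirical q-value, which
the package computes for every pair — the BH-adjusted q, not a normal
approximation to z, is what controls FDR for small, skewed state groups.

## Community statistics

**Bray–Curtis**: $d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$,
with 0 for a pair of empty samples.

**PERMANOVA** uses the Gower-centered inner-product formulation: with
$A = -\tfrac12 d^2$ elementwise and $G = JAJ$, the SS explained by a
nested model with hat matrix $H$ is $\mathrm{tr}(HG)$. Sums of squares
are sequential (type I) in the order given — `sampling_set` is entered
before `plant_state` or `dry_mass` so the line effect is absorbed first
— and the permutation test permutes raw sample rows (no strata),
recomputing the full sequential table each time. Factors get
`levels − 1` df, covariates 1 df; samples missing a term value (e.g.
unrecorded dry mass) are dropped with a message. For $n \le 8$ an
`exact = TRUE` switch enumerates all $n!$ orderings. The test suite
checks SS conservation to 1e-8, exact-enumeration agreement, nominal
type-I error, and term-for-term equality with vegan's `adonis2`.

**NMDS** minimizes Kruskal stress-1 by alternating isotonic regression
(primary approach to ties: tied dissimilarities are pre-sorted by
current distance, so they may untie) with Guttman majorization updates;
a step that fails to reduce stress is rejected, making the stress path
non-increasing by construction. Twenty starts by default: one metric
(classical scaling) start plus random Gaussian configurations;
convergence at stress improvement < 1e-7. Solutions are identified only
up to rotation/reflection/scale, so `procrustes_error()` is the
comparison tool.

**Mantel correlogram**: spatial distance is `|position difference| ×
0.30 m` within a sampling set, `NA` across sets — the two lines are
separate transects and no cross-line geometry is assumed. Distances are
binned by Sturges' rule; per class, the statistic is the (sign-flipped)
correlation between community dissimilarity and class membership, so
positive $r$ means samples in that distance class are more similar than
average. Significance is by joint row/column permutation of the
community matrix, with progressive Holm correction (class $k$ corrected
over classes $1..k$). Classes with fewer than two pairs are dropped
with a warning.

**Curves**: rarefaction uses the exact hypergeometric expectation
$E[S(d)] = \sum_i \left(1 - \binom{N-n_i}{d}/\binom{N}{d}\right)$ — no
resampling noise — and accumulation curves average cumulative richness
over random sample orderings.

## Co-abundance networks

Counts are CLR-transformed with pseudocount 1 (the standard treatment
of zeros at rarefied depths; CLR removes the total-sum constraint so
covariance reflects co-abundance, not closure). Two estimators of the
conditional-dependence graph:

* **mb** (default): per-node lasso over a shared lambda path (20
  log-spaced values from the maximum absolute off-diagonal CLR
  covariance down to 1% of it), OR-rule symmetrization; the edge weight
  and sign come from the larger-magnitude of the two directed
  coefficients.
* **glasso**: an in-package graphical lasso (block coordinate descent in
  covariance space, diagonal penalized); edge sign is the sign of the
  negated precision entry, i.e. the partial correlation. The tests
  verify it against an independent ADMM solver to 1e-4 on small
  problems.

Lambda is chosen by **StARS**: the path is refit on 50 random
subsamples of size `floor(min(0.8, 10√n/n) · n)`, per-lambda
instability is the mean over node pairs of $2\theta(1-\theta)$ with
$\theta$ the selection frequency, the instability curve is monotonized
from the sparse end, and the smallest lambda whose monotonized
instability stays ≤ 0.05 wins. The final graph is refit on the full
data at that lambda, and each edge carries its subsample selection
frequency. If no lambda meets the budget the empty network is returned
with a flag rather than an arbitrary graph. CLR rows are sorted by
sample id before subsampling, so the selected network does not depend
on input row order.

Neither variant claims directed or causal structure: a stable edge
means two taxa co-vary conditionally on the rest of the panel, which
shared habitat preference alone can produce.

## The simulator

`generate_community()` draws, in order: a ranked log-normal baseline
composition (`sdlog` 1.5 — heavy-tailed, top OTU around 5–10% of a
150-OTU community, matching the shape of rarefied field tables); an
AR(1) spatial field along positions within each sampling set (rho 0.4,
loading scale 0.3) that shifts whole-community composition, giving the
PERMANOVA line term and the Mantel correlogram something real to
detect; a Gaussian copula over the OTUs named in a planted precision
support (scale 0.6), which is what the network stage must recover;
planted fold-enrichments multiplying chosen OTUs in chosen states; and
finally Dirichlet-multinomial counts (total concentration 500 — mild
field-realistic overdispersion beyond multinomial) at fixed or
log-normal depths. States are assigned uniformly at random to
positions, so with no planted effects the labels are exchangeable by
construction and permutation p-values are exactly valid — the null
configuration used for calibration.

`plant_preferential()` places planted OTUs in triples of *consecutive*
abundance ranks split across the three states, rotating the assignment
per triple. Consecutive ranks carry near-identical mass, so each state
receives almost exactly the same planted mass. This balance is a design
requirement, not cosmetics: compositions are renormalized per sample,
so unbalanced planted mass would dilute the unplanted majority
differently by state and manufacture spurious "preferences" for null
OTUs. Triples span the 10th–90th percentile ranks, keeping the
community dominants unplanted (state-responsive taxa are rarely the
dominants) while covering two orders of magnitude of baseline
abundance.

What the simulator does *not* emulate: taxonomy-structured effects
(placeholder ranks only), raw reads and their error modes, aggregated
spatial clustering of host states (states are placed at random;
real infestations clump), sequencing-depth/biomass covariation, and
cross-compartment coupling between the root and soil tables. Passing
tests therefore demonstrate correctness of the statistics under a
faithful but idealized field design, not robustness to every artifact
of real amplicon data.

## Numerical choices and degenerate inputs

* Empirical p-values use the add-one estimator everywhere (screen,
  PERMANOVA, Mantel), so no permutation p is ever 0.
* The null s.d. of the screen uses the population denominator
  (matches enumeration); comparisons at thresholds use a 1e-12 slack so
  float noise cannot flip a tie.
* Pairs of all-zero samples get Bray–Curtis 0; constant OTUs are
  degenerate in the screen; constant model terms and saturated designs
  are hard errors in PERMANOVA.
* Problem sizes in the tests (e.g. 50 calibration replicates at 20 000
  permutations, 500 type-I replicates, chain graphs at $p=20, n=300$
  over 5 seeds) were chosen as the smallest designs at which the
  Monte-Carlo error of each check is comfortably below the tolerance it
  asserts.
* All randomized routines take an explicit integer seed, restore the
  caller's RNG state on exit, and are bit-reproducible given
  `(seed, n_perm)`.

## Known limitations

* The screen's z-threshold shortlist is a ranking device; FDR control
  for small, skewed state groups comes from the empirical q (see the
  calibration section).
* The Mantel correlogram's spatial model assumes a fixed within-set
  spacing and ignores cross-set geometry.
* The graphical lasso is written for panels of at most a few hundred
  OTUs; mb scales better and is the default.
* `merge_tables()` joins markers by exact sample-id string match by
  design; id normalization is the caller's responsibility.
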