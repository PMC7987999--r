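---
title: "Models and methods behind ychron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ychron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ychron` re-implements, as composable R functions, the computational
pipeline used in high-coverage Y-chromosome haplogroup studies: bespoke
region-based variant QC, haplotree construction and nomenclature,
node-calibrated Bayesian dating with skyline demography, continuous-space
Brownian phylogeography, ancient-sample affiliation, and Y-STR population
statistics. This vignette explains each model, its assumptions, the
tunable parameters, and the design decisions taken where the methodology
is genuinely open. Every empirical claim made here is recomputed by the
test suite or by `scripts/acceptance.R`; the `analysis/` scripts run the
same machinery end-to-end on a simulated cohort.

## The synthetic cohort and what it does (not) emulate

All validation rests on a simulator with complete ground truth.

**Genealogy.** `simulate_genealogy()` draws a Kingman coalescent under a
piecewise-constant effective population size `Ne(t)`. While `k` lineages
survive, the next coalescence arrives at rate `choose(k,2) / (2*Ne(t)*g)`
per year, with `g = 31` years per male generation: the standard
coalescent time scale on which a pair of lineages coalesces after `2*Ne`
generations in expectation. Waiting times across epoch boundaries are
drawn exactly by inverting the piecewise cumulative hazard, never by
discretised time stepping.

**Mutations.** `drop_mutations()` places `Poisson(mu * L * t_b)`
mutations on each branch `b` (default `mu = 7e-10` per bp per year over
an `L = 9.4e6` bp callable region, the scale of modern Y-chromosome
panels), each at a distinct uniform position: an infinite-sites model, so
the clean matrix is homoplasy-free by construction and the true
site-to-branch map is recorded.

**Geography.** `simulate_brownian_locations()` runs an isotropic
Brownian random walk in a kilometre plane (per-axis variance
`sigma^2 * t` along a branch of `t` years) centred on the root location.
The plane is an azimuthal equidistant projection; within a ~3,000 km
window its pairwise distances stay within 1.5 percent of great-circle
values (property-tested), so the Gaussian algebra in the plane is an
accurate stand-in for diffusion on the sphere at regional scale.

**STRs.** `simulate_str_haplotypes()` mutates each locus as a stepwise
(+1/-1) process at `str_rate` per generation with a reflecting floor at
one repeat. Published per-locus Y-STR rates are of order `1e-3`–`1e-2`
per generation; the default 0.002 sits in that range. The floor is a
modelling choice: repeat counts cannot reach zero, and a step below the
floor bounces back.

**Degradation and artifacts.** `degrade_sample()` models an ancient,
low-coverage genome as independent site drop-out (`missing_rate`) plus
symmetric allele flips (`error_rate`); strand-specific deamination
damage is deliberately out of scope. `inject_qc_artifacts()` plants the
four artifact classes the QC removes — same-carrier singleton clusters,
duplicated discordant sample columns, three-origin recurrent sites, and
high-missingness blocks — at positions chosen so that no two injections
overlap and ground truth stays unambiguous. Because uniformly placed
mutations occasionally create *natural* same-carrier singleton pairs
within the cluster window (indistinguishable from the artifact class by
definition), fixture construction conditions the position draw on the
no-cluster event via `respace_singleton_runs()`; this is a property of
the test fixtures, not of the QC itself.

What the simulator does *not* emulate: read-level errors and mapping
bias, platform-specific genotyping error structure, recombination (the
male-specific region does not recombine), selection, and aDNA damage
asymmetry. Passing tests therefore demonstrate correctness of the
algorithms under the stated generative model, not robustness to every
real-data pathology.

## Variant QC

`run_qc()` applies, in a fixed order, the four region-exclusion rules
used to clean merged Y-chromosome call sets, after restricting to a
callable mask (BED, 0-based half-open; VCF positions 1-based; the
converters are centralised and property-tested):

1. **Replicate discordance.** For sample groups known to be the same or
   paternally related individuals, any site with discordant non-missing
   calls condemns its whole containing mask interval; one column per
   group survives — the one with fewest no-calls, ties broken by sample
   ID.
2. **Singleton clusters.** A run of two or more singletons carried by
   the *same* sample with successive gaps of at most 50 bp marks a
   terminal-branch artifact; the run's span, extended 50 bp each side,
   is excised. The same-carrier restriction is configurable.
3. **Recurrence.** Within each sequencing-platform subset, each site's
   minimum number of origins on a preliminary perfect-phylogeny tree is
   scored by Fitch/Hartigan small parsimony (exact at polytomies,
   missing calls as wildcards). Three or more origins condemn the
   containing mask interval; exactly two origins are kept but flagged.
4. **Missingness.** Sites with strictly more than 10 percent no-calls
   are dropped, and the gap between two consecutive such sites is also
   excised when it contains no retained variant and is at most 1,000 bp
   long.

The excised extent is the one genuinely open design choice: the cluster
rule uses the run span plus or minus the window, the discordance and
recurrence rules use the containing callable interval, and the
missingness bridge uses a 1,000 bp proximity bound. All are exposed as
arguments. A site removable by several rules is attributed to the first
rule in pipeline order, which makes the filter report's accounting exact
(`surviving = input - sum(excluded)`), and the pipeline is idempotent.
Because interval-granularity excision removes whole mask intervals,
clean sites sharing an interval with an artifact are removed with it;
exactness is therefore asserted at region granularity (every excised
region overlaps a labelled artifact, every labelled artifact is gone).

## Haplotree construction and naming

On binary, nearly homoplasy-free Y-SNP data the rooted topology is
determined by carrier-set compatibility, so `build_parsimony_tree()`
constructs the tree directly instead of delegating to a likelihood
program: distinct carrier sets are ranked by support (number of
identical sites, then smaller size first) and accepted greedily while
they remain pairwise nested or disjoint. The support-first order makes
the construction "majority-compatible": a rare homoplasic carrier set
cannot displace clades supported by more sites, and smaller-first
tie-breaking prevents a single multi-clade union from blocking the
nested structure beneath it. Rejected sites are exactly the recurrent
ones. Branches carrying zero mutations are undeterminable in principle
and appear as polytomies; topology recovery is therefore tested against
the truth genealogy with unsupported branches collapsed.

`map_sites_to_branches()` assigns each site to the branch whose
descendant tip set equals its carrier set (missing calls as wildcards,
ties towards the smaller set); carrier sets matching no branch receive a
minimal Fitch/Hartigan multi-branch placement and are counted recurrent,
giving the recurrence fraction reported alongside the tree.

`annotate_branch_names()` applies the hierarchical haplogroup
convention: at every split, children rank by descendant count (ties by
marker name), suffixes alternate letters and numbers with depth, the
major child takes `a`/`1`, single-child chains collapse into their
parent's name, and each branch is additionally labelled by a defining
marker — preferring markers flagged as genotyped, else the
lexicographically smallest, else a synthetic `M<position>`. Names parse
back into their suffix path (`parse_branch_name()`), so the naming walk
is invertible.

## Calibrated dating and skyline demography

`run_dating_mcmc()` samples node ages, the clock rate and skyline sizes
on the fixed topology. The data likelihood treats the SNP count on
branch `b` as `Poisson(n_b | r_b * L * t_b)`; under the strict clock
`r_b = mu`, under the relaxed lognormal clock `r_b = mu * m_b` with
multipliers of prior mean 1 and their spread `s` under an
exponential(mean 0.3) prior, summarised by the coefficient of rate
variation. `mu` carries a log-uniform prior on `[1e-11, 1e-8]`.

Two tree priors are provided, and the choice matters:

* **Skyline coalescent** (default for demography): the classic grouped
  piecewise-constant model — coalescent events are split into
  `skyline_groups = 5` contiguous groups (group boundaries at events),
  each with its own `Ne` under a log-uniform prior, with interval rate
  `choose(k,2)/(2*Ne_j*g)` matching the simulator's convention.
  `skyline_from_trace()` evaluates each posterior state's step function
  on a fixed grid and returns pointwise medians and HPD envelopes.
* **Ratio-flat** (`tree_prior = "flat"`, used for node-age estimation):
  uniform over the node-height *ratio* parameterization, i.e. a density
  proportional to `root^-(k-1)` over ages. Conditional on the root the
  internal configuration is uniform, so with no data the calibrated
  node's posterior reproduces its normal prior exactly — the standard
  sampler-validity check — and in calibrated recovery experiments the
  root median is unbiased. A naive flat-in-ages prior fails that check
  (the configuration volume grows like `root^(k-1)` and inflates the
  root), and the skyline prior with log-uniform `Ne` tilts the
  likelihood-flat rate-time ridge towards younger roots by around ten
  percent at these data sizes; both effects are measurable with the
  package's own tools. Node ages are therefore estimated under the
  ratio-flat prior, while the skyline prior is used where `Ne(t)` itself
  is the target.

Proposals are bounded uniform slides on internal node ages, scale moves
on the root, `mu`, each `Ne`, the multipliers and `s`, and a repeated
joint up/down scale of all ages against `mu` — the move that traverses
the rate-time ridge, without which the root age and clock rate mix
poorly. Desk-scale defaults (2 chains, 2,000–3,000 sweeps, thinning 2–3)
give effective sample sizes in the hundreds-to-thousands for root age
and rate on 50–100-tip trees; convergence is judged by `ess()` above
200, the same criterion used at cluster scale. `combine_chains()` drops
the first 10 percent of each chain. `hpd_interval()` returns the
shortest (leftmost on ties) contiguous interval; `ess()` uses the
initial-positive-sequence truncation with the estimate clipped to
`[0, n]` and a flag on constant series.

## Continuous phylogeography

`prune_recent_same_population()` removes one tip of every
same-population cherry younger than 1,000 years (the one with more
missing data; ties drop the second ID), iterated to stability — the
standard thinning applied before continuous-space runs.

`infer_locations()` samples ancestral locations under homogeneous
Brownian diffusion on the dated tree. Both axes share one diffusion
variance; given the tips, phylogenetic contrasts yield its
scaled-inverse-chi-squared conditional under a Jeffreys prior (2(n-1)
degrees of freedom pooling both axes), and internal nodes are then drawn
from their exact conditional Gaussian by upward filtering / downward
sampling. This is a Gibbs sampler whose draws are exact, so no diffusion
chain has to be monitored. Coincident tip coordinates are jittered by up
to 1 km (the model is degenerate at duplicated points). Zero-length
branches are floored at `1e-8` years for numerical stability.

`hpd_region_2d()` builds a Gaussian-kernel density on a grid (default
200 per axis with 35 percent margins), takes the smallest set of cells
reaching the probability level (default 0.80), contours it into
polygons, and reports the area by cell summation. `diffusion_rate()`
divides total great-circle displacement by total branch time per
posterior draw, in km/year — a tree-length-weighted rate, summarised by
median and 95 percent HPD.

## Ancient-sample placement

`informative_site_panel()` exports the single-origin branch-defining
sites; recurrent sites are excluded from the panel.
`observe_alleles()` reduces a per-position allele/depth table to
derived/ancestral/missing states (deepest call per position, depth
threshold defaulting to 1 as appropriate for aDNA, non-panel alleles
counted and treated as missing). `place_sample()` scores each branch by
its observed panel sites: supported when derived calls outnumber
ancestral, contradicted in the reverse case, pass-through when
unobserved — pass-through is essential at 80–99 percent missingness.
The sample affiliates to the deepest supported branch whose root path
contains no contradicted branch; a derived call at a sister-defining
site degrades the assignment one node up (`degraded_to_parent`), and
with no supported branch anywhere the sample is `unassigned`. A strict
mode (any ancestral call blocks) is available. The majority rule in
place of manual per-SNP curation, and the one-node degradation
on sister conflicts, are the documented choices; both guarantee the
monotone-degradation property (more missingness never deepens an
assignment), which is property-tested on nested missingness masks.

## Population statistics

`str_gene_diversity()` is Nei's unbiased gene diversity
`D = n/(n-1) * (1 - sum p_i^2)` over exact 8-locus haplotype identity —
algebraically identical to the fraction of unequal sample pairs, which
is the oracle the tests compare against to `1e-12`.
`branch_frequency_table()` produces per-population counts and
percentages at a chosen, non-overlapping tree level.
`interpolate_surface()` provides ordinary kriging with a linear
variogram and no nugget (the slope cancels in the weights; exact
interpolation at data points) and inverse-distance weighting (power 2,
bounded by the data range) as a dependency-light alternative; duplicate
coordinates are averaged with a warning. Map cosmetics are out of scope;
surfaces are numeric grids exportable as ESRI ASCII.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: single-tip trees simulate to
a tree with no internal nodes; `mu = 0`, `sigma = 0` and
`str_rate = 0` produce exact degenerate outputs; constant MCMC series
report `ess = 0` with a flag; empty masks and empty observation tables
are valid. Ties are deterministic everywhere (leftmost HPD window,
alphabetical sample/marker ordering, first-rule attribution in QC). All
stochastic operations take a single integer seed and are bit-reproducible.

The validation experiments run at desk scale by design:
20 replicates of 50-tip TMRCA recovery, 10 constant-`Ne` and 5 expansion
skyline runs at 100 tips, 50 Brownian coverage replicates at 25 tips and
200 degraded placements — sizes chosen so the full suite completes on a
laptop-class single core while keeping Monte Carlo error far below the
tolerances being asserted. Chain lengths are the desk defaults above;
all scale linearly if more precision is wanted.

## Known limitations

* The haplotree is built by compatibility, not likelihood; with
  appreciable homoplasy or genotyping error beyond the QC's reach a
  likelihood tree would differ.
* Dating fixes the topology; co-sampling topology with ages is not
  implemented (on clean binary Y data the topology is effectively
  determined, but poorly supported branches would deserve the joint
  treatment).
* The skyline prior's younger-root tilt under weak data means node ages
  and demography are estimated under different tree priors (see above);
  with strong sequence data the difference shrinks.
* Diffusion is homogeneous Brownian; relaxed random walks and
  landscape-aware models are out of scope, as is map rendering.
* Placement treats sites independently; no genotype likelihoods or
  damage-aware weighting beyond the depth threshold.
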