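---
title: "Methods: coalescent estimation of neutral substitution rates from GBS loci"
author: "isthmusclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coalescent estimation of neutral substitution rates from GBS loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Transisthmian sister species — taxa split by the rise of the Isthmus of
Panama — provide one of the few calibration points precise enough to turn
mutation-scaled coalescent quantities into absolute rates. Snapping shrimp
(*Alpheus*) contribute several such pairs. Given genotyping-by-sequencing
(GBS) loci from multiple pairs, a multi-species coalescent model yields,
for every species pair, a divergence time $\tau$ and population sizes
$\Theta$ measured in expected substitutions per site. Dividing the
calibrated pair's $\tau$ by the age of the seaway closure (3 Ma, or the
older 10 Ma proposal) gives the genome-wide neutral substitution rate
$\mu$ in substitutions/site/year, which then converts every other
parameter to absolute units:

$$\mu = \tau_{cal}/T_{cal}, \qquad T = \tau/\mu, \qquad
  N_e = \Theta/(4\mu g),$$

with $g$ the generation time in years (annual here).

The package implements the whole workflow as testable components: a
coalescent simulator for GBS data (`simulate_dataset()`), locus filters
(`apply_paralog_filters()`, `apply_ms_filter()`), locus-sharing bias
diagnostics (`build_lpa()`, `jaccard_distances()`, `nmds()`,
`fit_shared_locus_models()`), an isolation-with-migration MCMC sampler
(`run_mcmc()`), and the calibration layer (`calibrate_mu()` and
relatives). `run_study()` chains them from one YAML configuration.

# The demographic model

A fixed rooted binary species tree carries one constant $\Theta = 4N_e\mu$
per branch (leaf and ancestral populations, $2n-1$ parameters for $n$
species), one divergence time $\tau$ per internal node (backward from the
present, in substitutions per site), and optional directional migration
bands. A band (source $\to$ target, rate $M = m/\mu$) moves
forward-in-time migrants from source to target; backward in time, lineages
resident in the target jump to the source at rate $M$ while both
populations coexist. This forward-time reading of band direction is stated
explicitly because conventions differ between implementations of this
model class; `migrants_per_generation()` applies the matching definition
$M_{A\to B}\Theta_B$.

Within a population holding $k$ lineages, coalescences occur at total rate
$k(k-1)/\Theta$; at each $\tau$ the daughter populations' lineages merge
into the ancestor. The per-locus genealogy density is

$$\prod_b \left(\frac{2}{\Theta_b}\right)^{C_b}
  e^{-\sum_i k_i(k_i-1)\Delta t_i/\Theta_b}
  \prod_{bands} M^{E} e^{-ML},$$

with $C_b$ coalescences in population $b$, $E$ migration events on a band
and $L$ the lineage-time exposed to it. `genealogy_log_density()` exposes
this quantity; unit tests verify it against hand-evaluated closed forms
and check, by quadrature, that it is a normalized density for two and
three lineages.

# Likelihood on unphased genotypes

Sequence evolution is Jukes–Cantor (JC69) with uniform root frequencies;
rate variation is *between* loci (a mean-one multiplier $r_\ell$), not
within them — matching the model class of the coalescent samplers this
package mirrors. GBS genotypes are unphased: a heterozygous site is one
IUPAC ambiguity code, and the two alleles of diploid $i$ are tips $2i-1,
2i$ of the locus genealogy. At each site the likelihood sums analytically
over both assignments of the two bases to the two tips; because sites are
independent and assignments are per site, this per-site summation equals
the explicit sum over all $2^h$ whole-locus phasings, which the test suite
asserts exactly. `N` bases and absent samples are marginalized. Felsenstein
pruning is pattern-compressed and implemented in C++ alongside the
sampler.

# The MCMC sampler

`run_mcmc()` runs a Metropolis-within-Gibbs sweep:

1. **Lineage regraft by conditional-prior resimulation.** A non-root node
   is detached and its lineage re-simulated backward from the structured
   coalescent conditional on the remaining genealogy (migrating at the
   current band rates, coalescing with any coexisting lineage in its
   population at rate $2/\Theta$). Because the proposal density is exactly
   the conditional prior, the Hastings ratio reduces to the data
   likelihood ratio. This single move family also performs migration-event
   birth and death: events are born and die on resimulated paths, which
   makes a separate event-level birth/death move redundant.
2. **Coalescent node-age slides** within the window allowed by the node's
   population, its neighbors and adjacent migration events.
3. **$\Theta$ multiplier updates** against pooled coalescent sufficient
   statistics (no likelihood recomputation needed, since node ages are in
   mutation units).
4. **$\tau$ rubber-band updates**: a proposed $\tau'$ linearly rescales
   event times inside the affected populations ($[a,b] \to [a,b']$ maps
   $t \mapsto a + (t-a)(b'-a)/(b-a)$), with the per-event Jacobian in the
   acceptance ratio and full genealogy revalidation (a rescaled migration
   event that leaves its band's active window rejects the move).
5. **$M$ updates**: a log-scale multiplier walk, mixed 50/50 with an
   independence draw from the prior. The independence draw crosses between
   the "no flow" and "flow" regimes of the diffuse migration prior, whose
   spike at zero a pure random walk traverses slowly.
6. **Locus-rate pair updates** (when `variable_rates`): an additive
   transfer between two loci keeps the realized mean at exactly 1,
   mirroring the identifiability constraint of the variable-rates model.
7. **A joint scaling move** multiplying all times and sizes by a common
   factor (and dividing migration rates by it), which decorrelates the
   global scale.

Proposal step sizes adapt toward 25–45% acceptance during the finetune
window (default: the first 10,000 burn-in iterations) and are frozen
afterwards, preserving detailed balance for the recorded samples. The
whole run is deterministic under `mcmc_settings(seed=)`.

**Initialization.** Parameters are drawn from their priors (divergence
times nudged upward to respect the tree ordering) and genealogies are
simulated from the structured coalescent under those values, so the
initial state is consistent by construction and the likelihood finite.
Migration rates start at their prior mean rather than at a prior draw: the
diffuse migration prior concentrates near zero, and a chain started
without migration events cannot gain its first one (regraft paths propose
events at the current rate), whereas a chain started with events readily
discards them when the data reject gene flow.

**Priors.** Independent Gammas: $\Theta, \tau \sim$ Gamma(1, 100)
(mean 0.01, weakly informative at GBS divergence scales) and $M \sim$
Gamma(0.002, $10^{-5}$), the diffuse spike-at-zero prior conventional for
this model class. The migration prior matters scientifically: the
significance rule below asks whether the 95% credible interval of $M$
excludes $10^{-5}$, which is only informative if the prior itself allows
mass on both sides. All hyperparameters are configurable globally or per
parameter (`prior_spec(overrides=)`).

**Convergence gate.** Effective sample sizes (initial-positive-sequence
estimator, `effective_sample_size()`) are computed per reported parameter;
`run_mcmc()` warns below 100. Credible intervals are equal-tailed
2.5–97.5% percentiles throughout — simpler to reproduce than HPD intervals
and monotone-transform-equivariant, which is what the calibration layer
relies on when it transforms interval endpoints.

# The synthetic GBS generator

`simulate_dataset()` is first-class, tested code that defines the study
conditions for every property test:

* six species in the fixed transisthmian topology (three sister pairs and
  their ancestors), defaults $\Theta \approx 0.018$–$0.027$ and pair
  divergence times $5.95\times10^{-3}$–$12.5\times10^{-3}$, at the
  magnitudes the vicariance calibration implies;
* 4 diploid individuals per species by default (the study design spans
  2–5), thousands of loci of 90 bp (reads of ~100 bp lose their cut sites
  to trimming; the exact post-trim length is a package choice);
* unphased IUPAC genotypes produced by collapsing each diploid's two
  simulated haplotypes;
* per-locus rate multipliers $r_\ell$ from a mean-one Gamma, renormalized
  so the realized mean is exactly 1 (the inference-side constraint);
* restriction-site allelic dropout: an auxiliary 6-bp recognition segment
  (EcoT22I) evolves on the same genealogy with the same $r_\ell$; an
  allele is lost iff the segment was hit anywhere on its root-to-tip path.
  Sharing the locus rate couples conserved loci to conserved cut sites —
  the mechanism by which strict filtering enriches for slowly evolving
  loci. The segment is auxiliary, not part of the reported alignment,
  because real GBS loci are trimmed of the cut site. A diploid's locus is
  missing only when both alleles drop; a single surviving allele yields an
  apparently homozygous sequence, as in real data;
* depth-driven missingness: each surviving (sample, locus) is kept with a
  per-sample capture probability; simulated total read counts are
  log-normal (≈7.4M reads, 45% CV — a realistic multiplexed GBS lane) with
  ranks tied to capture probability.

Sites are simulated by exact JC69 transition sampling at branch ends
(distributionally identical to event-level simulation, much faster); the
recognition segment uses Poisson substitution counts. Per-site JC69
sampling and the structured-coalescent simulator are written in R,
deliberately independent of the C++ likelihood/sampler code, so parameter
recovery cross-validates two implementations of the same model.

The generator does **not** emulate: read-level errors and quality,
indels, PCR duplicates, paralog collapse, clustering artifacts, linkage
between loci, or selection. Passing tests therefore demonstrate method
correctness under the model's assumptions, not robustness to assembly
artifacts in real data; the paralog heterozygosity filters are exercised
on constructed cases instead.

# Filters and diagnostics

The m/s dataset grammar (`"Am4s2"` = all samples, ≥4 individuals, ≥2
species per locus) is parsed by `parse_dataset_name()`. Presence means a
sequence with at least one called base; all-N sequences count as absent.
The paralog heuristics discard sequences with more than 8 heterozygous
sites, then loci with any site heterozygous in more than 2 samples; the
first rule is applied per consensus sequence (the upstream assembler's
semantics — the alternative per-locus reading would be stricter).
Multi-allelic SNPs stay in the SNP table but are excluded from Ts/Tv,
matching common VCF tooling.

Locus-sharing diagnostics follow standard practice: shared-locus counts
$LPA \cdot LPA^\top$, Jaccard distances, Kruskal NMDS (via
`vegan::monoMDS`, best of seeded random restarts; tie handling is vegan's
primary treatment), and nested OLS models of pairwise shared loci on
$\log_{10}\sqrt{R_iR_j}$ (base 10 chosen; the base only shifts the
intercept/slope, not $r^2$) with and without patristic distance. Counts,
not proportions, are the response; with a fixed locus total the two give
identical $r^2$. Poorly sequenced samples are excluded by an explicit
`exclude` argument rather than automatic outlier detection.

# Calibration layer

`summarize_replicates()` pools replicate chains for means and CIs;
`migration_significant()` applies the $10^{-5}$ exclusion rule **per
replicate** (a band is significant only if every replicate's interval
excludes the threshold — the literal, two-sided reading, so an interval
entirely below the threshold also counts as exclusion).
`calibrated_estimates()` anchors $\mu$ on the EC pair by default — its
individuals are the best sequenced — and transforms CI endpoints through
the same deterministic maps as the point estimates. The identity
$T(\tau_{cal}, \mu(\tau_{cal})) = T_{cal}$ holds exactly and is asserted
in the tests.

# Numerical choices and problem sizes

* Coalescent boundary comparisons use absolute tolerances of $10^{-12}$
  in the validators; event ties at population boundaries have measure
  zero under the continuous-time model and are funneled upward.
* Pattern compression makes the likelihood cost proportional to the
  number of distinct genotype columns, which for 90–100 bp loci at these
  diversities is typically under ten.
* Property tests run at sizes chosen to hold Monte-Carlo error near or
  below the assertion tolerances on a single CPU: simulator analytics at
  1,200–4,000 replicates (3 MC SE bands), prior recovery at 30,000
  iterations, parameter recovery at 300 loci × 100 bp × 2 diploids per
  species across 3 seeds, migration detection at 200 loci across 5 seeds,
  and the filter-bias comparison on a 600-locus dropout-coupled
  simulation with 200-locus inference subsets. Full-scale runs (tens of
  thousands of loci) are supported through the same interfaces via random
  subsetting (`random_subsets()`), the strategy used when a dataset is
  too large to analyze whole.

# Known limitations

* JC69 only; no GTR or within-locus rate heterogeneity. Ts/Tv in real
  arthropod data (~1.4) exceeds the JC expectation (0.5), so simulated
  spectra are flatter than real ones; the Ts/Tv and spectrum estimators
  themselves are substitution-model-agnostic counts.
* The species topology is conditioned on, never inferred.
* The migration significance rule inherits its prior sensitivity: with an
  informative prior bounded away from the threshold it would flag
  everything, and with an extreme spike-at-zero prior a no-flow posterior
  collapses entirely below the threshold, which the literal two-sided rule
  also counts as exclusion. The default Gamma(0.01, 1e-4) keeps a no-flow
  posterior straddling the threshold.
* Migration **direction** is only weakly identified at small sample
  designs. Gene-flow *magnitude* between a sister pair is detected
  reliably, but with few diploids per species a recent cross-species
  coalescence is explained almost equally well through either directional
  band: when one-way flow is simulated, the reverse band typically absorbs
  part of the signal, and the joint posterior over the two band rates is
  strongly multimodal (a chain started at the true one-way configuration
  stays there; cold-started chains usually find a shared-flow mode). Tests
  document both the detection success and the exclusivity failure.
  Direction claims from this model class should be treated with
  corresponding caution.
* Desk-scale chains (thousands of iterations) suffice for the test-scale
  data sizes; real datasets need the default-scale settings (100k burn-in,
  200k iterations) and replicate-chain agreement checks.
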