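---
title: "Models and methods behind somaclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind somaclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaclock)
```

## The scientific question

Long-lived trees accumulate heritable, stochastic gains and losses of
cytosine methylation — spontaneous epimutations — as their meristems
divide. The *mitotic-rate hypothesis* holds that the per-year rate of
these events is governed by the number of stem-cell divisions per unit
time, so that faster-growing trees should accumulate epimutations
faster per calendar year even at identical chronological age.

`somaclock` implements the analysis chain needed to test this
hypothesis from whole-genome bisulfite sequencing (WGBS) of samples
collected within a single tree: methylation state calling, pairwise
methylation divergence, intra-organismal pedigree dating from branch
ages and ring widths, and neutral gain/loss rate estimation — plus a
simulator in which epimutation accrual is explicitly coupled to the
cell-division rate, so every stage can be exercised and validated
without any external data.

## The neutral two-state model

Each cytosine (or 100-bp region) is either methylated (m) or
unmethylated (u) along a haploid lineage, and flips state once per year
with gain probability $\alpha$ (u→m) and loss probability $\beta$
(m→u). Writing $\gamma = 1 - \alpha - \beta$ for the per-year retention
factor and $\pi = \alpha/(\alpha+\beta)$ for the steady state, the
probability that a tip descending from an ancestor $\tau$ years back is
methylated is

$$a(\tau) = \pi + (1-\pi)\gamma^\tau \quad\text{(ancestor m)},\qquad
  b(\tau) = \pi(1-\gamma^\tau) \quad\text{(ancestor u)}.$$

Two samples whose lineages split at their most recent common branch
point, $\tau_i$ and $\tau_j$ years before each tip, then differ at a
site with probability

$$D(\tau_i,\tau_j) = c
  + p_0\,[a_i(1-a_j) + a_j(1-a_i)]
  + (1-p_0)\,[b_i(1-b_j) + b_j(1-b_i)],$$

where $p_0$ is the methylated proportion at the branch point and $c$
absorbs residual divergence that cannot be dated past the tree's
earliest branch point. At $p_0 = \pi$ this reduces to the familiar
$c + 2\pi(1-\pi)(1-\gamma^{\tau_i+\tau_j})$, a function of the
divergence time $\Delta t = \tau_i + \tau_j$ alone
(`model_divergence()`).

### Rate fitting and what is — and is not — identified

`fit_neutral_model()` minimises
$\sum_\text{pairs} (D_\text{obs} - D_\text{model})^2$ over
$(\alpha, \beta, c)$, with rates log-parameterised for conditioning,
bounds $\alpha,\beta \in [10^{-12}, 10^{-2}]$, $c \in [0, 0.4]$, and a
multi-start grid spanning three decades around a moment-based slope
guess crossed with $c \in \{0, \min D\}$. The minimiser is `nls`'s
`port` (nl2sol) algorithm followed by a short Levenberg–Marquardt
polish; on exact (noiseless) inputs the generating parameters are
recovered to machine precision.

$p_0$ is deliberately **fixed**, not fitted: with only genome-wide mean
divergences per pair, $(\alpha, \beta, c, p_0)$ is weakly identified,
so the caller supplies the mean observed methylated fraction.

An important honest caveat: at realistic per-year rates (a few
$10^{-6}$) and divergence times below a few hundred years,
$\gamma^{\Delta t} \approx 1 - (\alpha+\beta)\Delta t$, so divergence is
nearly linear in $\Delta t$ and only one rate *combination* is strongly
identified. The least-squares surface is a ridge, and $\alpha$ and
$\beta$ separate only through second-order curvature. Three design
choices follow:

* standard errors come from the Jacobian-based asymptotic covariance on
  the **natural** scale with column equilibration — along the ridge they
  become honestly large rather than artificially small;
* among multi-start solutions with numerically indistinguishable
  residual sums of squares, the most interior (closest to equal-rates)
  solution is preferred over bound-hitting ridge endpoints;
* `bootstrap_se()` offers a resampling alternative when the Jacobian is
  rank-deficient (flagged in the fit object).

Simulation checks confirm that each true rate falls inside its
2-standard-error interval in well over 90% of replicates at the scale
of the published estimates, which is the correct frequentist behaviour
even though the per-parameter intervals are wide.

The steady state $\pi = \alpha/(\alpha+\beta)$ is invariant under
proportional scaling of both rates (`steady_state()`): two trees can
share methylation *levels* while differing markedly in methylation
*dynamics* — the package verifies this property in silico.

## State calling

`call_states()` assigns u / i / m states with posterior confidence from
binomial count data. Emissions are binomial with success probabilities
$(p_u, p_i, p_m)$ estimated by EM under the ordering constraint
$p_u < p_i < p_m$: initialisation $(0.01, 0.5, 0.95)$, floors/ceilings
$p_u \in [0.001, 0.15]$, $p_m \in [0.6, 0.999]$, and $p_i$ fixed midway
between the other two — the floors keep the three components
identifiable on sparse data, and the fixed midpoint prevents the
intermediate component from collapsing when true epiheterozygotes are
rare. EM runs at most 200 iterations to a log-likelihood tolerance of
$10^{-6}$ from a fixed initialisation (no random restarts), so calls
are deterministic; non-convergence is flagged, never silent.
`"independent"` mode treats units as a mixture; `"chain"` mode fits a
first-order hidden chain along genome order with forward–backward
posteriors. Posterior argmax ties break toward `i` (conservative; such
units fail the 0.99 confidence filter anyway).

The intermediate state captures somatic epiheterozygotes — sites
methylated on one allele only, visible in bulk WGBS as ~50%
methylation.

SMPs (single methylation polymorphisms) and DMRs (100-bp differentially
methylated regions) are state *switches* between two samples at sites
or windows where both samples pass `posterior_max >= 0.99`; filtered
units are excluded from the eligible denominator. Window counting
treats a per-site `i` call as half a methylated cytosine, rounded
half-up per window; this choice is recorded in the function
documentation because the procedure it reimplements does not specify
it.

## Divergence statistics

`pairwise_divergence()` implements
$D = \tfrac1n \sum_i |M(A,i) - M(B,i)|$ with the three-level encoding
u = 0, i = 0.5, m = 1 by default; a DMP-indicator encoding (any state
switch counts 1) is available since both are used in practice. Site
universes are pairwise-complete — the intersection of sites passing the
posterior filter in *both* members of a pair — maximising $n$ per pair.

Group comparisons use the unpaired one-sided Wilcoxon rank-sum test and
Cohen's $d_C = (\bar D_1 - \bar D_2)/s$ with the pooled standard
deviation; effect bands are small (0.2–0.5), medium (>0.5), large
(>0.8). The replicate-normalised fold change between treatments is
$(\bar D_\text{heavy} - \bar D_\text{RR}) /
 (\bar D_\text{moderate} - \bar D_\text{RR})$,
undefined (and flagged) when the denominator is not positive; it is
invariant to affine rescaling of all three means.

`cluster_samples()` performs average-linkage (UPGMA) clustering of the
divergence matrix. Because the true pedigree is ultrametric in time and
expected divergence is monotone in divergence time, UPGMA is consistent
here; recovery is checked against the generating topology by
Robinson–Foulds distance in the test-suite.

## Pedigree dating and growth

`divergence_times()` traces each leaf pair back to its most recent
common branch point; $\Delta t = \tau_i + \tau_j$. Pairs coalescing at
the tree root are flagged `root_censored` — divergence cannot be dated
past the earliest branch point — and excluded from rate fitting by
default (an option re-includes them for sensitivity analysis).

Ring widths convert to basal area increments,
$bai_t = \pi (r_t^2 - r_{t-1}^2)$, with the stem growth rate defined as
the mean annual increment over all four cardinal-direction series;
per-series-then-average is the default order since averaging radii
first changes the quadratic terms. `growth_cellcount_correlation()`
relates cumulative growth to cumulative cell counts (Pearson), the
cross-check that growth acceleration reflects increased cell
proliferation.

## gbM classification

`classify_gbm()` reimplements the exon-background binomial procedure:
a gene is gene-body methylated when its exonic methylated-CG position
count is significantly above the cohort's exonic CG background
(one-sided binomial, BH-FDR at 0.05 across genes) while exonic CHG and
CHH are **not significantly elevated** above their backgrounds
(one-sided, unadjusted p > 0.05). Two deliberate choices:

* the non-CG tests are one-sided *greater*: with a nonzero cohort
  background, a gene with exactly zero non-CG methylation — the gbM
  signature itself — would be "significantly different" on a two-sided
  test and wrongly vetoed; the filter's purpose is to exclude
  transposon-like elevation;
* "methylated position" means a site where more than half the reads are
  methylated (position counts, not read counts), while the intronic
  non-CG *level* used by the final filter is the pooled
  methylated/total read fraction, because it is a level, not a count.

Per-sample calls are unioned into a liberal candidate set; candidates
at or above the median intronic non-CG level (median over candidates)
are dropped, and candidates without intronic data are retained with a
flag — a gene cannot fail a filter it has no data for.

When the simulated cohort consists *entirely* of gbM genes, the cohort
background equals the gbM level and no gene can test above it; such
degenerate fixtures require an externally supplied reference
background, which the function signature permits.

## The simulator: a stated world

The generator's defaults encode the study system rather than tunable
knobs:

* **Topology** (`make_topology()`): all leaves sampled at the tree age
  (default 200 years, the stand's age class); branch points drawn
  uniformly on $[0.2, 0.95] \times$ age when not supplied, matching
  crowns whose usable branch points span most of the stem's life.
* **Rates**: published per-year values (e.g. $\alpha = 4.69 \times
  10^{-6}$, $\beta = 6.50\times10^{-6}$ per CG per haploid genome per
  year) for parameter-recovery experiments; the ancestor sits at the
  steady state unless stated otherwise.
* **Mitotic coupling**: per-division rates $\epsilon$ with $\kappa$
  divisions per year give $\alpha = 1-(1-\epsilon_g)^\kappa$, linear in
  $\kappa$ for small $\epsilon$ — the hypothesis in executable form.
* **Read counts** (`emit_wgbs_counts()`): negative-binomial totals with
  mean 20 (the study's coverage), binomial methylated counts at
  $\{0+err, 0.5, 1-err\}$ by true state.
* **Stem design** (`simulate_stem_design()`): four moderate and three
  heavy trees, each with two same-side replicates sharing all but a
  handful of terminal divisions and one opposite-side sample diverging
  at the stem core — the replicate-normalised divergence then scales
  with the treatment ratio of $\kappa$.
* **Three-state mode**: two independent alleles per site; the site
  state is u/i/m by allele count, interpreting the intermediate state
  as heterozygous methylation.

Sites are independent (no linkage); that is also the assumption of the
neutral model, so a green test establishes correctness of the
estimation machinery, *not* robustness to genomic autocorrelation,
coverage biases, cell-type mixtures, or mapping artefacts of real WGBS
data. Time is discrete in years with per-year transition probabilities
equal to the rates, valid because the rates are far below one.

Two testing-specific choices deserve note. Topology-recovery checks
use branch points separated by at least ten years (a jittered grid):
real branching events in mature beech crowns are years to decades
apart, and allowing near-tied node depths would turn UPGMA recovery
into a coin flip that reflects the draw, not the method. And
mitotic-coupling checks use symmetric per-division rates at an
effective per-year rate of about $5\times10^{-4}$, large enough for the
combined rate to be curvature-identified, so the doubling prediction is
tested on a well-conditioned fit.

## Numerical and degenerate-input policy

* EM: fixed initialisation, 200 iterations, $10^{-6}$ tolerance;
  all-identical counts yield a single-state labelling without error.
* Fitting requires at least 4 pairs spanning at least 2 distinct
  divergence times; flat divergence collapses to
  $\hat\alpha = \hat\beta \approx 0$, $\hat c = \bar D$.
* Zero pooled SD with unequal means flags an infinite effect size
  rather than dividing silently; a non-positive fold-change denominator
  flags the ratio undefined.
* Writers emit fixed-precision, byte-reproducible TSVs; parsers reject
  malformed lines with line numbers and never silently drop records.
* All randomness flows through explicit integer seeds; identical
  configurations give byte-identical pipeline outputs
  (`run_pipeline()` manifests carry md5 checksums).

## Known limitations

* Region-level (100-bp) rate estimation reuses the site-level
  machinery on window states; no within-window dependence is modelled.
* The chain-mode state caller estimates a homogeneous transition
  matrix; it does not model distance-dependent transitions between
  neighbouring cytosines.
* Separate gain and loss rates are weakly identified at realistic
  rates and time scales (see above); treat per-parameter point
  estimates with the reported standard errors, and prefer rate
  combinations or ratios of paired fits when comparing trees.
* The simulator does not emulate mappability, bisulfite conversion
  heterogeneity along reads, or cell-layer chimerism.
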