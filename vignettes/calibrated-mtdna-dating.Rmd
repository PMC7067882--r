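---
title: "Calibrated mtDNA divergence dating with topology uncertainty"
author: "mitodate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated mtDNA divergence dating with topology uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodate)
```

## The problem

Museum and historical specimens yield short, patchy mtDNA fragments, yet they
are often the only genetic witnesses of extinct populations. Dating the
divergence of such lineages from a handful of kilobases raises three coupled
uncertainties that a single maximum-likelihood tree silently ignores:

1. **Tree depth.** The root height of a clock tree (in expected
   substitutions/site) is estimated with substantial error when sequences are
   short and partially missing.
2. **Calibration.** The fossil-calibrated split used to convert substitutions
   into years (here the puma–cheetah divergence, 4.92 My with a 95% CI of
   3.86–6.92 My) is itself a distribution, and an asymmetric one.
3. **Topology.** With shallow intraspecific splits, several tree topologies
   explain the data almost equally well; dates conditional on a single tree
   understate the real uncertainty.

`mitodate` implements a pipeline that carries all three through to the
reported dates: exhaustive topology enumeration, per-topology maximum
likelihood under TN93+Γ, bp-RELL topology weights, and a probabilistic
mutation-rate construction that multiplies root-height and calibration
densities. A sliding-window mismatch screen for nuclear-mitochondrial
insertions (numts) and a forward sequence simulator complete the toolkit.

## Substitution model

The Tamura–Nei (TN93) model distinguishes the purine transition rate
$\alpha_R$, the pyrimidine transition rate $\alpha_Y$, and a shared
transversion rate $\beta$, with stationary frequencies $\pi$. The generator is
normalized so $-\sum_i \pi_i Q_{ii} = 1$; branch lengths are then expected
substitutions per site. Among-site rate variation uses Yang's
discrete-Gamma approximation: `n_categories` (default 5) equal-probability
classes, each represented by its band-conditional mean, so the class rates
average exactly 1. Transition probabilities come from an eigendecomposition of
the reversible generator in its symmetrized form — exact and stable for a
4×4 matrix.

Base frequencies are empirical by default (counted from the alignment,
missing data ignored), matching common ML-engine practice; the two
transition/transversion ratios and the Gamma shape are free parameters.
Ambiguity codes enter tip partial likelihoods as indicator vectors over their
compatible states; `-`, `N` and `?` are fully missing, so an all-missing
column contributes exactly zero log-likelihood.

## Likelihood engine

Site likelihoods use Felsenstein pruning over compressed site patterns, with
per-node rescaling against underflow, mixed over Gamma categories. The inner
loop is compiled (RcppArmadillo), and branch-length gradients are computed
analytically from inside/outside partials, which is what makes exhaustive
per-topology fitting affordable: a 7-taxon branch-length fit on 5 kb takes
tens of milliseconds.

* `fit_no_clock()` optimizes free branch lengths (log scale, L-BFGS-B) and
  optionally the three model parameters, with two deterministic perturbed
  restarts by default.
* `fit_strict_clock()` parameterizes a rooted tree as a root height times
  nested fractions in (0,1) — ultrametric by construction — and optimizes
  heights the same way. Tips are treated as contemporaneous: the samples are
  at most a couple of centuries old against events of tens of millennia, so
  sample age is negligible.
* `clock_lrt()` compares the two: `2n − 3` branch lengths against `n − 1`
  heights gives `n − 2` degrees of freedom for the chi-square statistic.
* `estimate_root_height_se()` reports the curvature (Wald) standard error
  from a numerical second difference of the *profile* log-likelihood in the
  root height. The profile re-optimizes the other node heights **and, by
  default, the substitution-model parameters**: the Gamma shape in particular
  is strongly correlated with tree depth, and holding it fixed understates
  the root-height uncertainty by a third or more. This matches how the
  reference ML engines report standard errors from a full-parameter Hessian.

Marginal ancestral states come from the standard inside/outside pass; ties in
the maximum-a-posteriori state break alphabetically.

## Topology space and bp-RELL weights

For `n ≤ 10` taxa all `(2n−5)!!` unrooted topologies are generated by
stepwise addition, optionally filtered to those containing a required clade
(constraining the two-taxon outgroup of a 7-taxon set leaves 105
candidates, the `(2·5−3)!!` rooted ingroup shapes). Topologies are identified
by a canonical key — the sorted non-trivial bipartitions — stable across runs
and used as IDs in every output table.

Each candidate is fitted by maximum likelihood and its per-site
log-likelihoods are resampled (bp-RELL): sites are drawn with replacement,
the topology with the highest resampled total wins the replicate, and exact
ties split the win equally. Weights are therefore bootstrap proportions; we
keep the conventional "posterior weight" phrasing for the quantity used to
mix dates, while noting it is not a Bayesian posterior. The default is
10,000 replicates with a mandatory seed (R's Mersenne–Twister; reproducible
across platforms within R). Ties are declared at a 1e-9 absolute / 1e-12
relative tolerance on the resampled totals so that topologies with
numerically identical likelihoods split wins deterministically regardless of
floating-point summation order.

One deliberate economy: the substitution model is fitted once (on a
neighbor-joining starting tree) and shared across the candidate fits, with
per-topology re-optimization available via `reoptimize_model`
(`fit_topology_set()`), mirroring the usual ML-engine practice of evaluating
a fixed model across candidate trees. The dating step, by contrast, re-fits
each top topology under the clock, and its standard errors profile the model
parameters as described above.

## From root height to dates: the calibration machinery

The calibration is stated as a point date with an asymmetric 95% CI. We fit
a skew-normal density $f(x) = \tfrac{2}{\omega}\,
\phi\!\big(\tfrac{x-\xi}{\omega}\big)\,\Phi\!\big(a\tfrac{x-\xi}{\omega}\big)$
by least-squares matching of its (2.5, 50, 97.5)% quantiles to the stated
triple; a symmetric triple recovers a normal ($a \approx 0$), the
puma–cheetah triple gives a clear right skew ($a > 0$).

For each topology's clock fit we lay a grid over root height
$h \sim \mathcal N(\hat h, \mathrm{SE}^2)$ (truncated at
$\hat h - 5\,\mathrm{SE}$, 400 points) and calibration date $d$ (skew-normal
between its 0.001 and 0.999 quantiles, 400 points), weight each cell by the
product of densities, compute the implied rate $\mu = h/d$, and bin the
weighted cells into 2000 log-spaced rate bins. A node of height $h_v$ then
has date distribution $h_v/\mu$ over the rate bins. Node heights other than
the root are fixed at their ML values — only root-height uncertainty enters
the rate construction, which is exactly the published construction this
package re-implements (see *Limitations*).

Dates for a queried clade are mixed across the top-K topologies
(default K = 10) with renormalized RELL weights; topologies in which the
query is not monophyletic contribute through the MRCA of the queried taxa.
Reports give the best-topology and the topology-averaged medians with
equal-tail 95% intervals. The published parenthetical ranges do not state
their definition; we default to equal-tail quantiles and also provide
shortest (highest-density) intervals via `dist_hpd()` so either convention
can be read off the same distributions.

```{r calibration-example}
cal <- fit_skew_normal(4.92e6, 3.86e6, 6.92e6)
cal
rd <- rate_distribution(0.0492, 0.0035, cal)
dist_quantile(rd, c(0.025, 0.5, 0.975))   # subs/site/year
dist_quantile(node_date_distribution(72200e-8, rd), c(0.025, 0.5, 0.975))
```

As a cross-check of a Bayesian-style calibration prior,
`offset_lognormal_quantiles(0.82, 0.33, 2.65)` has median
$2.65 + e^{0.82} = 4.92$ My and an equal-tail interval close to the
calibration CI — the arithmetic used to encode the same calibration as an
offset-lognormal root prior.

## numt screen

Co-amplified nuclear copies of mtDNA produce chimeric assemblies whose
mismatch rate against a trusted reference jumps over the inserted segment.
`mismatch_scan()` slides a 1000 bp window (default step 100 bp; step =
window tiles the sequence) over a pre-aligned pair and reports per-window
mismatch rates over "called" sites — positions where both sequences have an
unambiguous base. Windows with fewer than 200 called positions are masked
rather than reported, so sparse historical sequences do not generate
spurious rates. `flag_numt_candidates()` marks windows above a fold
threshold (default 4×) over a stated background rate and merges overlapping
windows into 0-based half-open intervals (BED-compatible). Pairwise
alignment itself is out of scope; inputs are assumed aligned.

## The synthetic world

`default_cheetah_scenario()` states the generative world used by every
recovery and coverage experiment, chosen once from the study system:

* 7 taxa: an outgroup cherry (puma + jaguarundi) splitting from the cheetahs
  at the calibration point, 4.92 My (intra-outgroup split 4.17 My, the
  published puma–jaguarundi estimate's scale);
* cheetah splits at 138.9 ky (Northeast Africa), 72.2 ky (India vs the
  Southeast-African clade), and 24/10 ky within the three Southeast-African
  sequences — the deposited dataset has three SE-African mtDNAs, and the
  shallow splits sit at the scale of the genomic jubatus diversification;
* 15 kb of coding-like sequence at $10^{-8}$ substitutions/site/year (a
  typical mammalian mtDNA coding rate, giving a root height of ~0.05
  substitutions/site, the observed puma–cheetah scale), under TN93+Γ5 with
  felid-like base frequencies (0.31/0.26/0.13/0.30), transition rates 30/16
  and shape 0.3;
* contiguous missing-data masks leaving the India taxon 3675 called sites
  (the length of the historical Indian specimen's called coding sequence)
  and the historical SE-African taxon about half called.

Simulation is site-wise forward evolution down the tree with per-site Gamma
categories — the exact generative counterpart of the likelihood — and is
byte-reproducible given the seed. What the generator does *not* emulate:
sequencing error, DNA damage, indels, recombination-free but
numt-contaminated reads (contamination is available separately via
`make_numt_chimera()`), or coalescent noise between population divergence
and gene divergence. A green recovery test therefore establishes that the
*inference machinery* is consistent with its own model on data of realistic
depth and missingness — not that real cheetah mtDNA meets the model.

## Numerical choices

* Optimizer: L-BFGS-B on log branch lengths / log root height + logit
  fractions, relative tolerance 1e-9, analytic branch-length gradients,
  restarts from two deterministic perturbed starts (`n_starts` control).
  Non-finite likelihoods at extreme parameter values return a large penalty
  instead of aborting the search.
* Degenerate inputs: identical sequences drive branch lengths/heights to the
  lower bound (1e-9 / 1e-8 substitutions/site ≈ 0); all-missing columns are
  exact zeros of the log-likelihood.
* Profile-SE second difference uses a symmetric step on the log-height scale
  (initial 5% of the root height, refined once toward the estimated SE) and
  refuses to report an SE if the profile is not locally concave.
* Grids: 400 × 400 (height × date), 2000 log-spaced rate bins — quantile
  error well under the 0.1 ky reporting precision; grid defaults were fixed
  before any acceptance measurement and are validated against Monte-Carlo
  sampling oracles to 1% at the 2.5/50/97.5% quantiles.
* RELL resampling draws multinomial site counts in chunks, so memory stays
  bounded for large candidate sets.

## Design decisions taken where the design was open

* **Shared vs per-topology model for RELL fits**: shared by default (see
  above), switchable. The per-site log-likelihood differences that drive
  RELL are dominated by topology, not by the small model-parameter shifts
  between near-identical trees.
* **RELL on no-clock fits**: weights are computed from free (no-clock)
  per-site log-likelihoods, the behavior of the ML engines this mirrors;
  clock fits enter only at the dating step.
* **Outgroup constraint**: enumeration is unconstrained by default; the
  pipeline configuration used in the analyses constrains the outgroup cherry
  (105 of 945 topologies), and non-rootable topologies would in any case be
  dropped at the dating step with a message.
* **Interval convention**: equal-tail 95% by default, HPD available.
* **Config format**: JSON (round-tripping, hash-stamped into every output
  header) rather than YAML, keeping the dependency footprint to packages the
  analysis stack already uses.

## Limitations

The date intervals propagate root-height, calibration and topology
uncertainty — but, by construction (faithful to the method re-implemented
here), *not* the sampling error of the dated node's own height. At
historical-specimen depths (a handful of informative sites on the India
branch) that error is large, and repeated-sampling coverage of the 95%
intervals falls short of nominal: in the package's own 100-replicate
experiment on the default scenario at 5 kb the topology-averaged interval
covers the true India/SE split in roughly 75–80% of replicates rather than
≥ 95%. This is a property of the method, not of the
implementation — the acceptance suite measures and reports it honestly
rather than widening intervals post hoc. Relaxed clocks, tip dating,
partitioned models and Bayesian (MCMC) machinery are likewise out of scope.
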