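---
title: "Modelling sequential Wolbachia invasions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sequential Wolbachia invasions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolbdyn)
```

## The biological problem

*Drosophila simulans* populations in eastern Australia have seen two
maternally inherited *Wolbachia* variants sweep through in succession: first
wAu, which causes no detectable cytoplasmic incompatibility (CI), then wRi,
which causes strong CI and displaced wAu within a few years. `wolbdyn`
implements the deterministic machinery needed to analyse such dynamics: the
discrete-generation recursions for the three cytoplasm classes, their
equilibria and invasion conditions, inference of fitness parameters from
observed frequency changes, the survey statistics used on field data, joint
mtDNA-haplotype tracking, and a one-dimensional lattice for the spatial
contrast between bistable and Fisherian spread.

## The model

Three adult classes are tracked each generation: uninfected (frequency
$p_\varnothing$), wAu-infected ($p_A$) and wRi-infected ($p_R$), with
$p_A + p_R + p_\varnothing = 1$. Assumptions, all standard for this system:

* random mating, females mate once, male class frequencies equal adult
  frequencies;
* fitness differences act through female fecundity only: infected females
  produce $F_A$ (resp. $F_R$) times as many ova as uninfected females;
* imperfect maternal transmission: an infected mother produces a fraction
  $\mu$ of uninfected ova ("leakage"); no paternal transmission, no double
  infections, no horizontal transfer;
* CI: sperm from wRi-infected males reduces the hatch of uninfected *and*
  wAu-infected ova by the common factor $H$ (so $s_h = 1 - H$ is the CI
  strength); wRi-infected ova are compatible with all sperm; wAu males
  cause no CI.

One generation multiplies each class by an ova term and a hatch term and
renormalizes by the mean fitness (see `step_two_strain()`). Setting
$p_R = 0$ collapses to the classic no-CI recursion
$p' = F(1-\mu)p / (1 + (F-1)p)$, and $p_A = 0$ to the single-strain CI
recursion; both reductions are enforced to $10^{-14}$ in the tests.

### Equilibria and regimes

For a non-CI strain, persistence requires $F(1-\mu) > 1$, and the stable
equilibrium is $p_s = 1 - F\mu/(F-1)$ — the haploid mutation–selection
balance with uninfected offspring in the role of recurrent "mutants".
Inverting this for $F$ given an observed equilibrium
(`invert_equilibrium_F()`) is the package's basic inference trick:
$\hat p = 0.6$ and $\mu = 0.023$ give $F \approx 1.061$, and the leakage
interval $(0.003, 0.049)$ maps to $F \in (1.008, 1.140)$.

For a CI strain the interior fixed points solve a quadratic (see
`equilibria_ci()`); regimes are classified as

* **fisherian** ($F(1-\mu) \ge 1$): unstable equilibrium at 0, spread from
  any positive frequency;
* **bistable** ($H < F(1-\mu) < 1$, roots permitting): invasion threshold
  $p_u$ below the stable equilibrium $p_s$;
* **no_invasion**: no interior root and $F(1-\mu) < 1$.

Stability is always verifiable numerically: the recursion slope at the
fixed point is below 1 in magnitude at $p_s$ and above 1 at $p_u$, and an
independent fixed-point grid scan agrees with the quadratic roots to
$10^{-6}$ in the test suite.

A noteworthy boundary case: the mean-field condition $H < F(1-\mu)$ is
*not* sufficient for bistability once $\mu > 0$ — the quadratic can lack
real roots (for example $F = 0.9$, $\mu = 0.045$, $H = 0.75$ is
`no_invasion` despite $H < F(1-\mu)$). The lattice tests therefore verify
the regime with `equilibria_ci()` before using a parameter set, and use
$F = 0.9$, $\mu = 0.01$, $H = 0.78$ (giving $p_u \approx 0.54 > 1/2$) for
the "bistable waves stall" property.

### Two documented numerical discrepancies

* With $F = 0.95$, $\mu = 0.045$, $H = 0.55$ the unstable equilibrium
  computes to $0.2318$; published accounts of this parameter set round it
  to 0.22. We report the computed value and do not force agreement.
* The wRi-into-wAu rare-invasion condition $F_R(1-\mu_R) > F_A(1-\mu_A)$
  is marginally *false* at the point estimates ($1.0314 < 1.0366$), yet
  displacement from $p_R = 0.09$ succeeds because CI already operates at
  that frequency. `invades_when_rare()` and trajectory-based displacement
  checks are deliberately separate functions; the package never asserts
  they coincide.

## Inference

`fit_F()` solves, by bisection on a bracket expanded on demand, for the
fecundity that carries $p_0$ to $p_1$ in a given number of generations —
the final frequency is monotone in $F$, so the root is unique. The
mu-limited ceiling (no $F$ can exceed the $1-\mu$ ceiling on reachable
frequencies) is diagnosed explicitly. `required_FR()` applies the same
idea to the displacement criterion: the minimal $F_R$ such that wAu falls
below a threshold within a horizon; it is non-increasing in the horizon
and increasing in $H$ (weaker CI needs a larger fitness advantage),
both property-tested.

Calendar conversions use roughly 20 generations per year for subtropical
and 15 for temperate coastal populations (`years_to_generations()`); the
1993/94→1999 wAu increase spans about 120 generations, the 2008→2011 wRi
displacement about 45.

A reproducibility subtlety: the published 120-generation endpoints (0.529
for $\mu = 0.023$, 0.229 for $\mu = 0.01$) follow from the *unrounded*
inverted fecundities ($0.4/0.377 = 1.06101$, $0.4/0.39 = 1.02564$), not
from the rounded 1.061/1.026 quoted alongside them (which give 0.528 and
0.236). The acceptance script therefore inverts the equilibrium first and
iterates at full precision, which is also the methodologically natural
pipeline.

Which $(\mu, F)$ combinations "suffice to explain" an observed increase is
not defined numerically in the source material; `trajectory_grid()`
operationalizes it as: predicted final frequency at least the lower 95%
confidence bound of the observed estimate. With the three combinations
$(0.023, 1.061)$, $(0.04, 1.11)$, $(0.01, 1.026)$ — mapped to curves
(a)/(b)/(c) in text order, an inference flagged here because the original
figure does not label them — the first two clear the 1999 lower bound
0.458 and the third does not, reproducing the verbal conclusion.

## Field statistics

* **Binomial intervals** are Clopper–Pearson exact (`binom_ci_exact()`),
  computed from the beta-quantile closed form and tested against an
  independent root-solve of the binomial tail equations. This method — and
  not, say, Wilson — reproduces the printed interval $(0.01, 0.045)$ for
  8 uninfected of 350 progeny. (For 52/92 the exact upper endpoint is
  0.6683, printing as 0.668; a published 0.669 reflects the original
  software's rounding.)
* **G-tests** (`g_test()`) use the plain log-likelihood-ratio statistic,
  no Williams or Yates correction, with empty margins dropped under a
  warning. Calibration is property-tested: type-I error within [3%, 7%]
  at nominal 5% on homogeneous 7×3 site tables with $n = 40$ per site and
  all expected counts above Cochran's minimum of 5. With badly skewed
  compositions (an expected count of 3.6) the uncorrected statistic is
  anti-conservative by a point or two — users testing small rare-class
  surveys should interpret marginal p-values cautiously.
* **Transmission leakage** (`transmission_estimate()`) pools progeny
  counts (total uninfected over total progeny — the weighting implied by
  the 8/350 arithmetic), with two intervals: exact binomial on the pooled
  counts, and a percentile bootstrap that resamples whole isofemale lines,
  which is the appropriate unit when transmission heterogeneity across
  females makes progeny within a line correlated. The published bootstrap
  interval cannot be reproduced exactly because the per-line distribution
  of the 8 uninfected progeny is unpublished; the tests check the
  qualitative signature instead (line bootstrap wider than binomial when
  leakage is clustered, coverage near nominal when it is not).

## mtDNA hitchhiking

`step_cyto()` runs the same dynamics with the uninfected class partitioned
by mitochondrial haplotype. Because leakage offspring of infected mothers
keep the maternal haplotype, the haplotype associated with a spreading
infection is driven toward fixation *even among uninfected flies*: at the
wRi equilibrium the ancestral haplotype contracts each generation by
exactly the share of new uninfecteds contributed by uninfected mothers,
$p_\varnothing / (p_\varnothing + F_R \mu_R p_R) < 1$ — a geometric decay
the tests verify against this closed form. A paternal-leakage rate
parameter exists for sensitivity analysis but defaults to 0, matching the
apparent rarity of paternal transmission. The haplotype alphabet is an
extensible named vector (default A / R / ancestral); rare field variants
are data, not dynamics. Initial haplotype composition is always an input —
the ancestral state of eastern Australian *D. simulans* is unknown and the
package never asserts one.

## Spatial lattice

`lattice_init()` / `run_lattice()` implement deterministic per-deme
dynamics (infinite local populations) with nearest-neighbour migration
($m \le 0.5$, reflecting boundaries) and optional seeded long-distance
jump events — the only stochastic element, included because rare
human-mediated dispersal combined with Fisherian local dynamics is the
plausible explanation for ~100 km/year spread. The simulator is
deliberately illustrative: tests verify the qualitative contrast
(Fisherian parameters establish lattice-wide from one deme at 1%;
bistable parameters with $p_u > 1/2$ neither advance a front nor allow a
half-threshold propagule to establish; a bistable wave with $p_u < 1/2$
travels at a steady speed). No quantitative wave-speed fitting is
attempted — the underlying field data do not support it.

## Synthetic data: what it does and does not emulate

`generate_survey()` draws multinomial samples of the three cytoplasm
classes along deterministic model trajectories, site by site and year by
year — the statistical structure the survey estimators assume.
`generate_lines()` draws per-line leakage from a beta distribution with
mean $\mu$ and intra-class correlation $\rho$ (the `rho = 0` limit is
exactly binomial), then binomial progeny counts. Defaults: 34 lines of
10–12 progeny, matching the scale of the real transmission assay; $\rho$
defaults to 0.15, a free knob chosen once so that roughly 8 leaked progeny
among 350 tend to concentrate in a few lines, which is the regime where
the line bootstrap visibly out-covers the naive binomial interval. All
generators take explicit integer seeds and restore the global RNG state.

What a green test on synthetic data does *not* establish: the generators
contain no genotyping error, no spatial correlation between nearby sites,
no temporal autocorrelation in sampling effort, and no real uncertainty in
the generation calendar. Parameter-recovery results on them bound the
statistical error of the estimators, not the systematic error of applying
the model to real surveys.

## Numerical policy

All recursion arithmetic is double precision; states are renormalized
every generation and conservation is tested to $10^{-12}$. Equilibrium
roots are accepted on the open unit interval with $10^{-12}$ boundary
tolerance; the quadratic solver uses the cancellation-stable form and
degrades gracefully to a linear solve when $F\mu = 1$ makes the leading
coefficient vanish. Bisections run to $10^{-12}$ ($10^{-4}$ for
`required_FR()`, whose answer is only meaningful to ~0.01). Published
values are compared after rounding half-away-from-zero to the printed
precision: 3 decimals for frequencies and fecundities, 2 for equilibria.

## Known limitations

No drift, age structure, overlapping generations or sex-ratio effects; the
lattice is 1-D with a fixed kernel; likelihood-based estimation with full
error propagation is out of scope. Simulation-heavy properties in the test
suite are run at reduced replicate counts (noted inline in the tests) to
keep the default run under a minute.
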