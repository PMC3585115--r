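---
title: "A thermodynamic model of transcriptional control, from sequence to expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A thermodynamic model of transcriptional control, from sequence to expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotrx)
```

## The model

`thermotrx` maps raw DNA sequence plus transcription-factor (TF)
concentration profiles to a predicted spatial profile of transcription
rate, in the setting of the early *Drosophila* blastoderm: a reporter
construct reads a position-specific cocktail of nine maternal and gap
proteins, and every anterior–posterior (A–P) position between 35% and
92% egg length is treated as an independent steady-state experiment with
its own TF concentrations. The pipeline is a chain of small, explicit
physical layers.

**Binding sites.** Each factor is described by a position weight matrix
built from a base-count table: counts are pseudocount-regularized,
normalized per position, divided by genomic background frequencies, and
logged. A window's score is the sum of per-position log-odds, scanned on
both strands; a site enters the calculation when its score exceeds the
factor's threshold. Scores are proportional to binding free energy, so a
site's affinity relative to a perfect site is
$K_i = \exp(\lambda\,(S_i - S_{max}))$, with one fitted proportionality
constant $\lambda$ per factor.

**Occupancy.** The site weight at position $x$ is
$q_i = K_i D_a v_a(x)$, where $v_a$ is the factor's observed relative
fluorescence and $D_a$ a fitted scale to true concentration. Bound
proteins occlude at least 14 bp of DNA (24 bp for the Gt-like factor),
so overlapping footprints exclude each other; paired cooperative sites
multiply their joint configurations by a factor $\omega$. Fractional
occupancies come from an exact partition function: all subsets of sites
with no footprint conflict are enumerated, weighted by
$\prod_{i \in c} q_i \prod_{pairs \subseteq c} \omega$, and
$f_i = \sum_{c \ni i} W(c) / \sum_c W(c)$. Because interactions only
exist inside connected components of the overlap/cooperativity graph,
the partition function factorizes over these "site groups", which is
what makes exact enumeration cheap. Cooperative pairing is homotypic and
greedy: the strongest unpaired site takes the strongest remaining site
within 60 bp (center to center), repeatedly.

**Interaction layers.** Bound factors then act through protein–protein
mechanisms, each with a strength in $[0,1]$ and a bounded trapezoidal
range function of inter-site distance. Coactivation converts a bound
repressor that is a coactivation target (the Hb-like factor) into an
activator: the converted fraction is a complement-product over
coactivator sites, $C_i = 1 - \prod_j (1 - \beta_{co} f_j r(d_{ij}))$,
and the activating and repressing parts always sum to the physical
occupancy. Short-range quenching attenuates each active activator by
every quencher bound within ~150 bp; direct repression applies the same
survival product against the TSS itself.

**Rate law.** Active activators recruit a composite, uniformly expressed
adapter factor with strengths $\alpha$, additively:
$E = \sum_i \alpha_i f^{AQ}_i$. Adapter recruitment lowers an activation
energy barrier $\theta$, and the transcription rate follows a
diffusion-limited Arrhenius law
$R = R_{max}\, K/(1+K)$ with $K = e^{E-\theta}$ — exponential in $E$
while the barrier dominates (allowing greater-than-multiplicative
synergy between activators) and saturating at $R_{max}$ when polymerase
diffusion becomes limiting. The law is derived from a three-state
initiation cycle (empty promoter → stalled polymerase → initiating
polymerase → empty); `three_state_steady_state()` solves that cycle
exactly, and under the substitution $k_2 = k_3$,
$k_1 = (k_{-1}+k_2)e^{E-\theta}/2$ the state-3 occupancy reproduces the
closed form exactly. The extracted source for this derivation does not
pin the constant substitution, so both routes ship and their agreement
is tested on a grid; the mapping is configurable through
`markov_rates_from_energy()`.

## Parameters and their accounting

The default configuration frees exactly 49 parameters:

| group | count | entries |
|---|---|---|
| per TF | 18 | concentration scale $D$, score-to-energy $\lambda$ (9 TFs) |
| per activator | 4 | recruiting strength $\alpha$ (Bcd, Cad, Dst, Dic) |
| per repressor | 10 | quenching $\beta_Q$ and direct repression $\beta_D$ (Kr, Kni, Gt, Tll, Hb) |
| cooperativity | 1 | Bcd $\omega$ |
| coactivation | 4 | $\beta_{co}$ and range $r$ for Bcd and Cad |
| coactivated target | 1 | Hb-as-activator $\alpha$ |
| global | 1 | barrier $\theta$ |
| thresholds | 7 | PWM thresholds free for all factors except Bcd and Hb, whose binding data pin them |
| position effects | 3 | one scale per non-targeted construct |

$R_{max}$ is held fixed in the default configuration — the accounting
above, which the package asserts in its tests, has no slot for it — but
it carries bounds and can be freed. Ranges follow independent
constraints: the Bcd coactivation range is searched in $[150, 200]$ bp
(set by which fusion geometries must and must not coactivate), the Cad
range in $[10, 200]$ bp. Efficiencies live in $[0,1]$; $D$ and $R_{max}$
are searched in log space because they span decades.

Defaults for the *values* (used as generating truth by the synthetic
module) were chosen once to put the system in its scientifically
interesting regime and are not tuned thereafter: $D = 3$ and
$\lambda = 0.4$ give strong sites mid-range occupancies and weak sites
a meaningful but minor role; $\alpha = 4$ with $\theta = 10$ places
peak summed activation near the barrier, so profiles traverse the
exponential regime and peaks approach but do not pin at saturation;
efficiencies of 0.8 make every interaction layer's removal visibly
change predictions; $\omega = 5$ is a moderate homotypic cooperativity.

## Numerical choices

* Coordinates are 0-based, half-open, forward-strand; minus-strand
  sites report forward intervals. Steric footprints are centered on the
  match and clipped at construct ends (the alternative, 5′-anchored
  extension, is not distinguishable from anything the training data
  constrain; centering was chosen and is flagged here).
* All inter-site and site-TSS distances are center-to-center, matching
  the convention in which the cooperativity range precedent (41 bp) is
  itself quoted.
* Windows containing `N` score $-\infty$ and can never become sites.
* Configuration enumeration refuses groups above 20 sites (configurable)
  rather than approximating — exactness is a design commitment; the
  error names the offending interval so the user can raise thresholds.
* Weight sums are computed in log space with weights clamped at
  $10^{-300}$, so zero concentrations give occupancies that are zero to
  well below every tolerance used.
* The quenching range function defaults to a trapezoid with full effect
  to 100 bp and zero beyond 150 bp (the published reach); the shape
  between the knots is linear. The coactivation range uses a single free
  parameter $r$ with a fixed 20 bp shoulder ($r_{zero} = r + 20$), so
  allowing the range to vary adds exactly one parameter per coactivator.
* Greedy pairing breaks affinity ties toward the smaller start
  coordinate, for determinism. Quenching-range proximity deliberately
  does **not** merge occupancy groups: occupancy factorization is exact
  without it, since quenching acts on occupancies downstream of the
  partition function.
* The rate law is evaluated as $R_{max}/(1+e^{\theta-E})$, which stays
  finite for arbitrarily large $E$.

## Fitting

The objective is the plain sum of squared differences between predicted
and observed expression over every construct and position (406
observations in the default 7-construct, 58-position design), reported
alongside its per-observation rms. Three optimizer backends share one
evaluation budget accounting:

* `lam_sa`: simulated annealing with a Lam-style adaptive schedule — the
  inverse temperature tracks a target acceptance ratio decaying from
  0.44, and per-coordinate move widths adapt toward 50% acceptance.
* `generic_sa`: Metropolis annealing with a geometric schedule and
  single-coordinate Gaussian moves.
* `multistart_local`: bounded L-BFGS-B refinements from random starts;
  the budget caps evaluations and the search also stops after eight
  consecutive restarts without relative improvement.

The annealing schedules are performance devices, not science: all
backends minimize the same objective over the same box, and the
package's recovery guarantees are stated for the backend-agnostic
contract. Runs are bit-reproducible given (seed, optimizer, budget), and
`repeats` runs independent seeds and keeps the best, reporting per-run
rms. Free thresholds are bounded by `threshold_range()`, the largest
threshold at which a matrix still recovers more than 70% of its known
footprint sites (evaluated, per the selection rule, at threshold zero
with 5 bp flanks and both strands).

## The synthetic-data generator

Everything the pipeline consumes can be generated in code:
`synthetic_pwms()` builds one sharp 10-column matrix per roster factor;
`generate_profiles()` emits smooth profiles on the 58-position grid —
an anterior exponential gradient (Bcd-like), a posterior gradient
(Cad-like), two broad domains (Dst-, Dic-like), bell-shaped gap domains
(Kr, Kni, Gt), a posterior sigmoid (Tll) and a dual-domain Hb-like
profile; `generate_construct()` plants near-consensus motifs (affinity
tiers = mismatch counts) in random background; `default_constructs()`
assembles a seven-construct panel in the fusion-with-and-without-spacer
geometry, four targeted and three with free position-effect scales; and
`simulate_dataset()` forward-simulates and perturbs observations with
multiplicative Gaussian noise of relative sd 0.075 — inside the 5–10%
accuracy band of the quantitative imaging data the model class was
built for — clipped at zero.

What the generator emulates is the *mechanistic* structure of the real
data: graded and overlapping TF domains, cooperative pairs, coactivation
geometry that switches when a spacer is excised, quenchers near and far
from the TSS, position effects on non-targeted constructs. What it does
not emulate: real *eve* stripe geometry, nucleus-level measurement
artifacts, temporal dynamics, or genuine genomic sequence composition.
Tests passing on these fixtures therefore certify the machinery —
exactness of the partition function, conservation laws, monotonicities,
recoverability — not biological fidelity on real enhancers, which would
require the real TF dataset and fitted parameters on genomic sequence.

Parameter-recovery checks use `recovery_panel()`: four compact
constructs whose geometries separate the mechanisms (a cooperative pair
with an interleaved quencher; a coactivation pair out of quenching
reach; a TSS-parked quencher for direct repression only; one mixed),
with 58 positions each and five freed parameters. At 7.5% noise a
budgeted fit recovers scale-type parameters within two-fold and
efficiencies within 0.15 absolute, with final rms at the injected noise
floor. Problem sizes throughout the test-suite (500 enumeration
cross-checks at up to 12 sites, 1000 conservation and steady-state
draws, 100 knockout constructs, a 2×10⁵-evaluation fitting cap) were
chosen as the smallest sizes that exercise every code path with
comfortable statistical margin.

## Dissection and knockouts

`dissect()` exposes the model's attribution surface: per site and A–P
position, the activation contribution
$\Delta E_i = \alpha_i f^{AQ}_i$, with per-position totals before and
after direct repression, plotted by `autoplot()` as a heatmap over bp 5′
of the TSS versus % egg length. The per-site contributions sum to the
summed activation exactly, so the map is a true decomposition.
`apply_knockout()` removes a mechanism without touching anything else
(ω→1, or the relevant efficiency→0); knockouts commute, are idempotent,
and can only move predictions in the mechanistically implied direction —
removing repressive layers never lowers a rate, removing coactivation
never raises a target site's attributed activation. Expression zones for
comparing construct variants are user-supplied position intervals, by
design: they are defined by inspection, not auto-detected.

## Known limitations

* The model is a steady-state map per time class: no mRNA decay,
  diffusion, or temporal dynamics.
* Heterologous cooperativity and corepression are deliberately absent.
* The multi-coactivator combination uses the saturating
  complement-product; the training-scale data cannot distinguish it
  from alternatives, and it is the only form here that both stays in
  $[0,1]$ and reduces exactly to the single-site case.
* Fitting real data requires the real TF concentration dataset and
  genomic constructs; the package's acceptance surface is the
  self-contained bookkeeping and exactness/recovery guarantees above.
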