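---
title: "Stochastic Boolean signalling models: simulation, personalisation and in-silico dosing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic Boolean signalling models: simulation, personalisation and in-silico dosing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctboolnet)
```

## The model

A Boolean signalling network assigns each molecular species or
phenotype a binary activity $x_i \in \{0,1\}$ and a logical update rule
$B_i(\mathbf{x})$ over its regulators. `ctboolnet` embeds this discrete
logic in continuous time: the joint state $\mathbf{x}$ performs a
Markov jump process on the state transition graph in which node $i$ can
flip

* up, at rate $k^\uparrow_i$, whenever $x_i = 0$ and
  $B_i(\mathbf{x}) = 1$;
* down, at rate $k^\downarrow_i$, whenever $x_i = 1$ and
  $B_i(\mathbf{x}) = 0$.

Rates are expressed per model-time unit and default to 1; they give the
logic its timescales without changing its attractors. States with no
eligible flip are absorbing fixed points. The process is simulated with
the Gillespie algorithm: waiting times are exponential in the total
eligible rate and the flipping node is chosen proportionally to its
rate.

An ensemble of trajectories (default 5000, the conventional ensemble
size for this class of model) is summarised per time window of width
`time_tick` as the trajectory-averaged fraction of time each tracked
node is ON, plus the occupancy distribution over joint tracked states.
The *window occupancy* statistic, rather than the instantaneous state at
the window edge, is used because it converges to the asymptotic
solution smoothly and at lower variance. The *phenotype score* of an
output node is its marginal in the final window; `max_time` should be
chosen so the last two windows agree, and `simulate_ensemble()` warns
when they differ by more than 0.01 in any tracked marginal.

Input nodes are environmental switches. They carry a self-identity rule
internally, so each trajectory holds whatever input value it sampled at
$t = 0$; an input with initial probability $p$ therefore contributes a
$p$/$1-p$ mixture of environments, which is also how growth-condition
presets (`prostate_presets()`) are expressed. The four named media keep
Nutrients ON and the stress inputs (Acidosis, Hypoxia, TGFbeta,
Carcinogen, TNFalpha) OFF while EGF and Androgen vary; FGF is kept OFF
in the base so that the named media differ only in the two varied
growth signals.

Two exact references validate the engine. A single self-inhibiting
"telegraph" node has the closed form
$P(t) = p_\infty + (p_0 - p_\infty) e^{-(u+d)t}$ with
$p_\infty = u/(u+d)$, integrable in closed form over any window. For
networks of up to ~10 nodes, `master_equation_windows()` integrates the
Kolmogorov forward equation of the full $2^n$-state chain (via
`deSolve`) and returns the same window layout, so stochastic and exact
window probabilities can be compared directly. The test-suite holds the
engine to within three Monte-Carlo standard errors of both references.

## Reproducibility

All randomness flows from one root seed. Each trajectory receives its
own substream seed from a SplitMix64 stream keyed on the root, so
results are bit-reproducible for a given configuration and independent
of scheduling, and different root seeds give genuinely independent
ensembles. This matters: deriving substreams as `root + trajectory`
would make consecutive seeds share almost all their substreams, which
is exactly the kind of defect the multinomial checks on drug-mixture
fractions are designed to catch.

## Personalisation

`personalise_cohort()` tailors one generic network to each sample of an
omics cohort following the discrete/continuous recipe convention:

* **Discrete layers** (mutations, copy number) force nodes:
  gain-of-function and amplification force 1, loss-of-function and
  deletion force 0. Mutations take precedence over copy number;
  contradictory calls within one layer are an error, and unknown-effect
  mutations are ignored with a warning. Effect classes come from a
  user-supplied curation table, keeping the tool agnostic about variant
  annotation pipelines.
* **Continuous layers** (expression) are first normalised per gene
  across the cohort (`minmax` or `sigmoid_z`, the logistic of a robust
  median/MAD z-score), aggregated from genes onto nodes (mean, min or
  max, since one node may stand for a complex or family), clamped to
  $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 0.01$, and applied
  as the node's initial ON-probability and through the odds-power rate
  transform
  $$k^\uparrow = \left(\frac{x}{1-x}\right)^{F/2},\qquad
    k^\downarrow = \left(\frac{x}{1-x}\right)^{-F/2}.$$

The transform is neutral at $x = 0.5$, symmetric in the odds, and keeps
$k^\uparrow k^\downarrow = 1$ so expression shifts a node's balance
without inflating the overall event rate. The amplification exponent
$F$ (default 1) sharpens the mapping. The continuous-to-rate convention
is genuinely underdetermined — a reasonable alternative would modulate
rates relative to a reference sample — so the formula is isolated in
`rate_transform()`, the single place to swap for bit-compatibility with
any external convention. Discretely forced nodes never receive
continuous modulation; the per-sample provenance log records every
decision, including those skips.

Asymptotically, rate modulation only matters for regulated nodes
through timescales, whereas forcing and the initial conditions of
unregulated (input-like) nodes move the attractor distribution itself.
This is why driver forcings dominate personalised phenotype scores and
why the package checks forcing dominance exactly.

## Perturbations and in-silico dosing

Genetic perturbations replace a node's rule by a constant (knock-out 0,
gain-of-function 1), leaving rates untouched. `enumerate_mutants()`
generates all $2n$ singles and $4\binom{n}{2}$ doubles — $2n^2$ in
total — over the perturbable set, which by default excludes the output
nodes but keeps the inputs: for a 133-node model with 6 outputs this
gives 127 perturbable nodes and $2 \cdot 127^2 = 32{,}258$
perturbations, the only reading consistent with that published screen
size.

A drug at inhibition level $\alpha$ is a *mixture of trajectories*
(`mixture_ko_wt`, the default): each trajectory knocks the target out
with probability $\alpha$ and keeps the intact rule otherwise, so
$\alpha = 0$ is exactly wild type and $\alpha = 1$ exactly the genetic
knock-out (bit-identical under the same seed, which the tests assert).
Multiple targets are inhibited independently, so two drugs at 50%
split the ensemble 25/25/25/25 over the four joint assignments. The
alternative `frozen_on_off` semantics freezes the target at ON with
probability $1-\alpha$; both modes are recorded in every run manifest
because published descriptions of gradual inhibition support either
reading. Dose grids default to the six-level schedule
$\{0, 0.2, 0.4, 0.6, 0.8, 1\}$; the single + pairwise combination grid
for $t$ targets and $L$ levels has $tL + \binom{t}{2}L^2$ conditions
(17 targets and 6 levels give 4,998 per phenotype).

Rule robustness is scanned by swapping each AND gate for an OR (and
vice versa), one gate at a time across all rules, and reporting the
largest absolute shift in any output score against the unedited model.

## Scoring

Drug efficiency is normalised to $[0,1]$ in the desired direction:
$E = \max(0, (P_{\mathrm{ref}} - P)/P_{\mathrm{ref}})$ for a decrease
and $E = \max(0, (P - P_{\mathrm{ref}})/(1 - P_{\mathrm{ref}}))$ for an
increase, the latter so that promoting an almost-saturated phenotype
still maps onto the unit scale. Synergy uses the Bliss Combination
Index
$$\mathrm{CI} = \frac{E_a + E_b - E_a E_b}{E_{ab}},$$
the standard parenthesisation of the Bliss-independence null;
$\mathrm{CI} < 1$ flags synergy and $\mathrm{CI} = 1$ holds exactly
when the combination acts independently. Efficiencies are computed
against the level-0 rows of the same screen, which under mixture
semantics are identical to a separate untreated run.

Genetic interactions score the double-mutant fitness
$f = P_{\mathrm{mutant}}/P_{\mathrm{WT}}$ (wild type $\equiv 1$;
`NA` when the wild-type probability is below $10^{-4}$, rather than a
clamped value, so interactions are never fabricated from numerical
noise) against four null models:
$\psi_{\mathrm{ADD}} = x + y$,
$\psi_{\mathrm{LOG}} = \log_2((2^x-1)(2^y-1)+1)$,
$\psi_{\mathrm{MLT}} = xy$ and $\psi_{\mathrm{MIN}} = \min(x,y)$, with
$\epsilon = f_{AB} - \psi(f_A, f_B)$. The best $\psi$ is the one whose
predictions correlate most (Pearson) with the observed doubles, ties
broken in the fixed order ADD, LOG, MLT, MIN. Mutant maps are plotted
after centring the condition-by-phenotype matrix on the wild-type row
(not column means), so the wild type sits at the origin and distances
read as perturbation effects.

## Synthetic data

`make_toy_model()` provides the three dynamical references used
throughout: the telegraph node (closed form), a linear cascade (fixed
points by construction) and `mini_tumour`, a 7-node growth/death
caricature whose two Proliferation activators (ERK, driven by the
growth input, and MYC, an unregulated driver switch) are redundant —
single inhibition is buffered while co-inhibition collapses
Proliferation, the canonical synergy signature
($\mathrm{CI} < 1$).

`generate_cohort()` emulates a two-group tumour cohort on a small gene
panel: group B carries a gain-of-function driver with probability 0.8
versus 0.05 in group A, and driver-linked genes are shifted by
$\delta = 2$ standard deviations in group B; expression is otherwise
i.i.d. Gaussian. The default cohort size is 488 samples, matching the
cohort scale the original models were personalised to. This generator
is deliberately simple: it produces the separation structure the
pipeline should recover (rank AUC $> 0.9$ at the strong effect,
$\approx 0.5$ at zero effect) and nothing else. It does not model
RNA-seq count distributions, linked CNA segments, subclonality or
gene-gene correlation, so passing these checks demonstrates that the
personalisation machinery transmits group structure faithfully — not
that it would rank real patients correctly.

`make_synthetic_prostate_model()` builds a *synthetic* stand-in with
the published full-scale dimensions — 133 nodes, the 9 canonical
inputs, the 6 canonical phenotype outputs and exactly 449 influence
arcs — for exercising parsers, influence analysis and enumeration at
scale. It shares only its shape with the curated model, not its
biology. On arc counting: one arc is counted per (regulator, target)
pair, with dual-sign influences counted once; a literal with no
semantic effect yields no arc. Published edge counts may follow a
different curation convention, so the 449 figure is treated as a soft
structural check.

## Numerical choices and problem sizes

* Clamp $\varepsilon = 0.01$ before the odds transform; wild-type
  fitness floor $10^{-4}$.
* Joint-state tracking is kept for up to 12 tracked nodes ($2^{12}$
  occupancy bins); marginals have no such cap.
* Ensemble sizes in the shipped checks range from 400 (per-sample
  cohort scoring) through 2,500–5,000 (dose grids, mixture fractions)
  to 10,000 (closed-form comparisons), with toy models of 1–7 nodes
  and cohorts of 80–120 samples; these sizes give three-standard-error
  resolution of a probability to roughly ±0.015 while keeping the whole
  suite fast.
* Rule parsing accepts both `& | !` and `AND OR NOT` spellings; parsing
  is strict (unsupported MaBoSS-dialect constructs are rejected, not
  ignored) and serialisation re-parses to an identical network.

## Limitations

Exact attractor computation, model checking and network reduction are
out of scope, as are SBML-qual import, pharmacokinetic mapping of
$\alpha$ to physical concentrations, and alternative synergy frameworks
(Loewe, ZIP, HSA). Cohort-dependent clinical quantities (survival
stratification, per-patient treatment recommendations) require external
data and are deliberately not emulated by the synthetic generator.
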