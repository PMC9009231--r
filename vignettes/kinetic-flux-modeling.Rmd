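---
title: "Kinetome-constrained flux modeling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetome-constrained flux modeling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinflux)
```

## The problem

Constraint-based analysis of genome-scale metabolic networks classically
treats gene expression qualitatively: a reaction is "on" or "off", and the
quantitative information in transcript abundance is discarded before the
linear program ever sees it. kinflux takes the quantitative route. Each
enzymatic reaction is capped at its Michaelis–Menten maximum rate,

$$ V \le V_{\max} = K_{cat} \times [E], $$

with the turnover number $K_{cat}$ taken from curated kinetic databases and
the enzyme concentration $[E]$ estimated from transcript abundance. Flux
predictions then respond continuously to expression differences between
samples, which is what makes per-individual modeling and group comparisons
meaningful.

## From transcripts to enzyme concentrations

Enzyme levels follow a synthesis/degradation balance
$dE/dt = \alpha M - \gamma E$, where $M$ is transcript abundance, $\alpha$
the per-transcript synthesis rate and $\gamma$ the degradation rate. At
steady state $E = (\alpha/\gamma)\,M$. `estimate_alpha_gamma()` estimates
the ratio per gene as the median of protein/mRNA across reference tissues
with matched proteome and transcriptome measurements (tissues with zero or
missing mRNA are skipped); genes with no usable tissue fall back to the
global median ratio and are flagged. The FPKM-to-nmol/L bridge is carried
entirely by $\alpha/\gamma$ — protein reference concentrations are already
in nmol/L, so no separate cell-volume factor is introduced.

## GPR aggregation and units

Reactions catalyzed by several gene products aggregate abundance through
their gene–protein–reaction rule: isozymes (`or`) add, complex subunits
(`and`) take the minimum. Genes absent from the abundance vector contribute
zero — conservative for a complex, neutral for isozymes. The unit
convention, fixed throughout the package, is

$$ V_{\max}\,[\mathrm{mmol/L/min}]
   = K_{cat}\,[\mathrm{s^{-1}}] \times 60 \times E\,[\mathrm{nmol/L}]
     \times 10^{-6}, $$

so a reaction with $K_{cat} = 100\,\mathrm{s^{-1}}$ and an effective
abundance of 500 nmol/L is capped at 3.0 mmol/L/min. Reactions without a
Kcat record or without a GPR stay unlimited, as do the eight
oxidative-phosphorylation reactions in `oxphos_whitelist`: these complexes
need 20+ subunits, and one missing abundance or kinetic record would
silence respiration outright, which is a data artifact rather than
biology.

Reversible reactions are capped symmetrically at $\pm V_{\max}$. A
turnover number does not distinguish directions, and an asymmetric cap
would require direction-specific kinetics the input tables do not carry;
the symmetric rule is the conservative reading and is applied everywhere.

Kcat lookup: a record keyed by the reaction id beats records keyed by EC
number; when a reaction carries several EC numbers, all their records are
pooled; multiple records for one key always reduce to their median.

## Model reduction

Before per-sample modeling, the generic network is reduced toward its
kinetically covered core with a GIMME-style linear program
(`gimme_reduce()`): minimize the total absolute flux through reactions
*without* Kcat records, subject to steady state, bounds, and each stated
objective (by convention ATP production and biomass) held at a fraction
$f$ of its optimum. Absolute values enter by the standard split of each
penalized reversible flux into positive and negative parts. Three choices
here were genuinely open:

* **Objective fraction** $f = 0.9$, GIMME's customary setting.
* **Objectives are enforced one at a time** and the retained reaction sets
  unioned. This guarantees each objective is independently attainable at
  $\ge f \times$ its optimum in the reduced model, which a simultaneous
  multi-objective constraint would not.
* **Penalized-reaction retention** uses the support of the minimizing
  solution found for each objective. Keeping the full support of a
  feasible solution that meets the objective floor is what makes the
  preservation guarantee unconditional. Sweeping alternate optima (an
  extra flux-variability pass over the optimal face) would retain more
  parallel routes at roughly twice the LP cost per penalized reaction; it
  is not needed for the guarantee and is left out.

A reaction counts as carrying flux above 1e-6 mmol/L/min, matching the
package-wide zero-flux tolerance.

## Per-sample models and flux sampling

For each sample, kinetic caps plus the exchange configuration (literature
uptake rates for nutrients, a small 0.01 mmol/L/min default for essential
amino acids, unlimited cofactor/iron/oxygen uptake) bound the model;
flux-variability analysis (`fva()`) then identifies reactions that cannot
carry flux, and `prune_zero_flux()` removes them to give the individual
model. Pruning blocked reactions cannot change the attainable flux set, so
the FBA optimum is preserved to solver precision — this is asserted in the
tests rather than assumed.

The flux distribution is explored with an artificial-centering hit-and-run
walker (`achr_sample()`). Warmup points are vertices obtained by
optimizing random directions (alternating maximize/minimize); each step
picks a direction from a stored point through the running center, so
directions stay in the steady-state null space and $Sv = 0$ holds exactly
along the walk, then jumps to a uniform point on the feasible segment.
Defaults are 1000 recorded draws, 200 warmup points, thinning 100; the
source publications for this class of sampler do not report settings, so
these are explicit package choices, configurable everywhere. The test
fixtures use lighter settings (300 draws, warmup 50, thinning 5) — on an
8-reaction network the polytope is low-dimensional and mixing is fast, and
the vignette-scale problem sizes keep the full suite in minutes. On a
one-dimensional polytope every accepted step is an exact uniform draw on
the feasible interval, which gives the sampler a closed-form target: the
test suite checks 5000 draws against the uniform law by a
Kolmogorov–Smirnov test at $\alpha = 0.01$.

Mean fluxes per reaction and sample are assembled by
`summarize_samples()`; a reaction pruned from one sample's model
contributes 0 in that column so cohort matrices stay rectangular.

## The linear-programming core

All of FBA, FVA and the reduction LP run on a single primitive,
`lp_solve()`: a dense two-phase bounded-variable primal simplex with
Bland's smallest-index anti-cycling rule. Flux-variability objectives sit
on degenerate vertices by construction, so the anti-cycling guarantee is
not optional. Linearly dependent stoichiometric rows (duplicated or
conserved metabolite pools) are dropped by QR factorization before the
solve. The implementation is validated against an independent brute-force
oracle — vertex enumeration in null-space coordinates — on 1000 random
networks and on every fixture; agreement is required to 1e-9 on the
fixtures. Bounds must be finite: "unlimited" in model files means the
conventional ±1000 mmol/L/min, which is far above every kinetic cap the
pipeline produces.

## Signature statistics

Group signatures come from two ordinary linear models fitted per feature
(flux or log2 metabolite abundance): model 1, `value ~ group + sex` over
case and control samples, gives the unfiltered case signature; model 2,
`value ~ age + sex` within controls only, gives the aging effect. A
feature is called **up** when model 1 is significant and positive
($p < 0.05$, $\beta > 0$) and model 2 does not show a significant positive
age effect; **down** mirrors this. The exclusion uses the same
$\alpha = 0.05$ as the calls. Sex enters as a single indicator; no
interaction terms. Flux features enter untransformed; metabolite
abundances should be log2-transformed first, reflecting their
multiplicative error structure.

Subsystem-level enrichment uses the differential-abundance score
$DA = (\#\mathrm{up} - \#\mathrm{down}) / \#\mathrm{features}$, in
$[-1, 1]$. Significance comes from shuffling the group labels (ages and
sexes stay attached to their samples) and recomputing the entire dual-model
pipeline per shuffle. The p-value is the fraction of shuffled scores at
least as extreme as the observed one, with $p = 1$ when the observed DA is
0, and Benjamini–Hochberg adjustment across subsystems. Ties count as "at
least as extreme": with small subsystems the DA score is coarsely discrete
and substantial null mass sits exactly at the observed value, so excluding
ties would understate p and inflate the false-positive rate (measured here:
18% at nominal 5% with strict counting, 3% with tie-inclusive counting,
over 25 null cohorts). With many features per subsystem the two
conventions coincide. The raw fraction over B shuffles is reported by
default; a smoothed `(count + 1)/(B + 1)` variant is available but off.

`welch_t_from_summary()` and `fisher_exact_2x2()` cover the cohort-table
statistics computed from printed summaries. The unequal-variance (Welch)
form is used deliberately: recomputing a published two-group glucose
comparison from its printed summaries gives p = 0.14 under Welch and 0.07
under the pooled-variance form, and the published value is 0.14.

## Synthetic data: what it emulates and what it does not

`make_toy_model()` builds an 8-reaction glucose/oxygen core with the
fermentation-versus-respiration trade-off (2 vs 32 ATP per glucose, 6 O2
per respired glucose). With default caps (glucose 10, O2 12 mmol/L/min)
the analytic ATP optimum is 80: two glucose respired at the oxygen limit,
eight fermented. The companion expression profile and Kcat table are tuned
so the fermentation and respiration caps *bind* (Vmax 9.0 and 0.9
mmol/L/min at base expression) — that is what makes flux predictions
responsive to expression noise, which the robustness experiments need.

`make_synthetic_cohort()` emulates the statistical structure the signature
engine assumes: two groups of 40 (defaults), uniform ages in disjoint
old/young ranges, a balanced sex indicator, 200 features in 10 subsystems,
one subsystem shifted multiplicatively (1.5x default) in the case group,
10% of remaining features with an age slope in controls, a log2 sex
offset, and Gaussian log-scale noise (SD 0.3 log2 units, a mid-range
biological CV of ~20%). Noise is Gaussian on the log scale for both
expression and flux-like features — the simplest structure consistent with
the linear models downstream.

What passing these tests shows: the estimators recover planted effects of
realistic size at cohort-scale n, the permutation test is calibrated, and
the pipeline is deterministic under seeds. What they do not show: real
transcriptomes have correlated genes, shared regulation, batch structure
and heavy tails that the generator deliberately omits; subsystems overlap
through shared enzymes; and real kinetic tables are sparse and biased
toward well-studied pathways — a reduced model therefore underrepresents
poorly annotated metabolism by construction.

## Numerical conventions

* Flux unit: mmol/L/min everywhere; `load_model(flux_scale=)` converts
  other unit systems at load.
* Default bounds ±1000 mmol/L/min; exchange convention
  `metabolite -> ∅` with uptake negative.
* Zero-flux/pruning tolerance 1e-6 mmol/L/min; steady-state residual
  tolerance 1e-6; bound tolerance 1e-9; LP pivot tolerance 1e-9.
* Flux-comparison floor 1e-6 mmol/L/min (LP precision noise);
  experimental-flux median floor 1e-3; outlier masking at 3 MAD (the
  "remove outliers" step of the benchmark protocol is unspecified in the
  source literature; 3x MAD per reaction is this package's documented
  choice).
* GPR dialect: `and` binds tighter than `or`; unparenthesized mixtures
  parse accordingly (curated model files parenthesize fully anyway).
* All stochastic steps (sampler, shuffles, noise injection, generators)
  take explicit integer seeds and are bit-reproducible under them.

## Worked example

```{r example, eval = FALSE}
toy <- make_toy_model(n_samples = 4)
flux <- pipeline_mean_fluxes(toy$model, toy$expression, toy$kcats,
                             toy$ratios, seed = 1)
round(flux, 3)

co <- make_synthetic_cohort(seed = 5, effect = 1.5)
f1 <- fit_model1(co$matrix, co$design, "CEN", "F1SP")
f2 <- fit_model2(co$matrix, co$design, "F1SP")
sig <- call_signature(f1, f2)
table(sig$call)
da_bootstrap(co$matrix, co$design, co$grouping, "CEN", "F1SP",
             B = 1000, seed = 11)
```

## Known limitations

* The simplex is dense and happiest below a few hundred reactions; curated
  core networks are its design point, full genome-scale reconstructions
  (10k+ reactions) need a sparse industrial solver behind the same
  `lp_solve()` interface.
* No substrate-saturation (Km) kinetics: only the Vmax cap is modeled.
* No loopless or thermodynamically constrained sampling.
* The cohort models are plain linear models; family structure or repeated
  measures would need mixed models, which are out of scope.
* Knock-in of a reaction absent from the model is a two-step operation
  (`add_reaction()` then `perturb_context(mode = "knockin")`) because a
  kinetic context carries no stoichiometry and the inserted reaction's
  Vmax is necessarily a user input.
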