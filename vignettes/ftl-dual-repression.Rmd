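---
title: "Modelling dual repression of FTL translation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dual repression of FTL translation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftlreg)
```

This vignette records the scientific model behind `ftlreg`, the
numerical choices made where the published description left the design
open, and what the synthetic-data tests do and do not establish.

## The three-state occupancy model

The model partitions the *FTL* mRNA pool into three mutually exclusive
states: bound solely by IRP (fraction $x_1$), bound solely by eIF3
($x_2$), and unbound ($x_3$). Bound states translate with efficiencies
$y_1, y_2 \in [0, 1]$; the unbound state translates at 1, and
mutations are assumed not to change the translation of unbound mRNA.
Disrupting one factor's site redistributes formerly bound mRNA to the
*other* factor by $\alpha$ (eIF3-site disruption) or $\beta$ (IRP-site
disruption), with $0 \le \alpha + \beta \le 1$. The four reporter
constructs then read

$$\mathrm{FTL} = y_1 x_1 + y_2 x_2 + x_3,\qquad
\Delta 3RE = y_1(x_1+\alpha) + x_2 - \alpha + x_3,$$
$$\mathrm{Loop} = x_1 - \beta + y_2(x_2+\beta) + x_3,\qquad
\mathrm{Double} = x_1 + x_2 + x_3 .$$

Normalizing the wild-type readout to 1 and eliminating
$x_3 = 1 - y_1 x_1 - y_2 x_2$ yields `predict_reduced()` and the key
identity

$$\mathrm{Double} - \mathrm{Loop} - \Delta 3RE
  = \alpha + \beta - y_1\alpha - y_2\beta - 1 \in [-1, 0],$$

so exclusive binding bounds Double by Loop $+$ $\Delta 3RE$ from above
regardless of the six free parameters. With the measured readouts
(Double $41.8 \pm 6.5$ vs bound $16.9 \pm 2.9$) the bound is violated
by $z \approx 3.5$ propagated standard deviations, which is the
quantitative basis for concluding that IRP and eIF3 can act in cis.

**A deliberate tension.** The substitution $x_3 = 1 - y_1x_1 - y_2x_2$
comes from setting the *normalized* wild-type readout to 1; it is
incompatible with the simplex constraint $x_1+x_2+x_3 = 1$ whenever
mutant readouts greatly exceed 1. We implement the printed algebra
as-is: the simplex is enforced only on user-constructed
`occupancy_params()` with an explicit `x3`, while the reduced
predictions and `fit_exclusive()` treat $x_1, x_2$ in rescaled units
(box $[0, 2\max(\text{observed mean})]$ by default). "Fixing" the
algebra instead would change the published inequality.

## Error propagation and the consistency test

The "±" values are treated as standard deviations of the mean readouts
(the replicate structure is three biological replicates for most
assays and six independent transfections for the Double comparison;
whether the printed values are SD or SEM is not stated — we take them
as SDs of the mean readout, the conservative reading for a
consistency test). `test_exclusivity()` resamples each construct mean
from an independent normal with its printed SD, truncated at zero by
resampling (luminescence cannot be negative), and reports the fraction
of draws satisfying Double $\le$ Loop $+$ $\Delta 3RE$. Defaults
`n_draws = 100000`, `seed = 2019` give ~0.1% Monte-Carlo error on
`p_consistent` and bit-for-bit reproducibility. The point verdict uses
the analytic bound; "inconsistent" is declared below
`p_consistent < 0.05` (the source states a strict inequality, not a
significance level, so the raw probability is always reported).

`fit_exclusive()` is a multi-start (32 Latin-hypercube starting
points) bounded L-BFGS-B minimization of the SD-weighted squared
residual, with $\beta$ reparameterized as $s(1-\alpha)$ to keep
$\alpha+\beta \le 1$ smooth. Ties are broken by chi-square then
lexicographic parameter order. The parameter-to-prediction map is not
injective (only the products $(1-y_1)x_1$, $(1-y_2)x_2$ and the
bracket combination are identified), so recovery tests assert the
*fitted predictions*, never the parameters. Feasibility is judged
against the 95th percentile of $\chi^2_3$ — three fitted means, a
conventional cut-off in the absence of a stated one.

## Competition EMSA kinetics

The simulator implements simple competitive bimolecular binding with a
shared free-protein pool:

$$\frac{d[R^*P]}{dt} = k_{on}[R^*][P] - k_{off}[R^*P], \qquad
\frac{d[CP]}{dt} = k_{on,c}[C][P] - k_{off,c}[CP],$$

with competitor concentration zero until the end of the 30-min
pre-incubation. Free species come from conservation, so totals are
conserved *exactly* by construction. Heparin (present at 4.5 µg/mL to
suppress nonspecific binding) is not modelled — no kinetics for it are
available. An optional `inert_fraction` (default 0) can sequester part
of the pre-formed labeled complex as non-exchangeable; it exists only
to mimic a speculative explanation of the ~15% residual bound fraction
and is not supported by direct evidence.

**Defaults.** Concentrations follow the protocol (300 pM labeled RNA,
225 nM IRP1); $k_{off} = 0.006\ \mathrm{min}^{-1}$ is the measured
value; $k_{on}$ is not reported and defaults to
$10^6\ \mathrm{M^{-1}min^{-1}}$, which takes the pre-incubation beyond
95% of equilibrium (Kd = 6 nM, consistent with a 1:1 shift at these
concentrations). Dissociation chases use a large competitor excess
(100,000×, the top of the protocol range) because at 1,000× the free
protein remaining at equilibrium (~18 nM with these defaults) inflates
the apparent decay rate by $k_{on}[P]_{free}$; at 100,000× the bias is
below 1%.

**Integration.** No ODE-solver package is available in the supported
toolchain, so the integrator is a local adaptive Cash–Karp
Runge–Kutta 4(5) working in nanomolar units. Tolerances are
`atol = 1e-9` nM ($10^{-18}$ M) and `rtol = 1e-10` — tighter than
strictly needed, chosen so the no-competitor trajectory matches the
closed-form quadratic equilibrium to $10^{-6}$ in bound fraction. The
scheme is explicit; for the concentration/rate ranges of this protocol
(fastest pseudo-first-order rate ≈ 30 min⁻¹ at 100,000× competitor)
step control keeps full trajectories under half a second, and a step
budget converts a genuinely stiff misuse into a clear error rather
than a hang.

**k_off fitting.** `fit_koff()` fits
$F(t) = F_\infty + (F_0 - F_\infty)e^{-k_{off}(t - t_0)}$ to the
post-competitor segment by `nls` (port algorithm; `scaleOffset = 1`
so exact, zero-residual data converge cleanly), with a log-linear
regression start. Flat curves are flagged failed rather than fitted.

**IC50 fitting.** `fit_dose_response()` fits a four-parameter logistic
on $\log_{10}$(fold excess) — matching how the dose axes are drawn —
and reports the inflection dose as the IC50. Two guards mirror the
experimental reporting: a pre-fit check that the spread of per-fold
means clears 3× the replicate scatter, and a post-fit check that the
fitted amplitude clears 3× the residual scale; either failure yields
"IC50 not determinable", the verdict given to the non-competing Loop
mutant. When responses are bound fractions, `response_limits = c(0, 1)`
constrains the asymptotes to the physical scale — the standard remedy
(also used by commercial fitters) when the tested window covers only
part of the transition, as the 1,000–100,000× window does here. The
acceptance-level cross-check compares the fitted IC50 against an
independent oracle: bisection on a dense fold grid of the *algebraic*
competitive equilibrium (`equilibrium_bound()`, solved by root-finding
on free protein), targeting the dose halfway between the
no-competition and full-competition asymptotes.

## The element map and construct building

Coordinates are 1-based inclusive on the mature 5ʹ-UTR (+1 at the
annotated transcription start): PAR-CLIP site [53, 76] (24 nt), 3RE
[58, 90] (33 nt), IRP-contact loop positions {15, 16, 17}, C bulge 18.
The IRE *end* defaults to 57 — the PAR site overlaps the last five IRE
nucleotides — but its start is never stated, so it defaults to `NA`
and interval queries on the IRE require explicit configuration rather
than a guessed value.

Cap distances (native 32 nt, extended 70 nt to the C bulge) are stored
as construct metadata, not derived from the bulge's UTR coordinate:
the reporter constructs carry vector-derived 5ʹ sequence of unstated
length, so C18's UTR position and "32 nt from the cap" are not
numerically reconcilable. The steric rule is strict — repression
becomes partial only *beyond* 60 nt — so `steric_class(60) ==
"full-block"` and `steric_class(61) == "partial-block"`.

`apply_construct()` applies deletions/substitutions/5ʹ insertions in a
single pass over original coordinates (overlapping edits are rejected
at spec construction) and emits a lift-over table; round-tripping
every kept position is property-tested. U and T are interchangeable on
input; output follows the input alphabet. The shipped FASTA is a
**synthetic stand-in** UTR (the real sequence is not reprinted and no
accession is deposited): a seeded random 200-mer with the annotated
anchor bases fixed at positions 15–18 and 51–52 so all construct
recipes validate. It must not be used for sequence or structure
analysis.

## Synthetic data: the stated world

`gen_reporter()` draws replicate luminescence as
mean × mean-one log-normal with CV 10% by default — multiplicative
noise because readouts span a ~40-fold range and are strictly
positive — then renormalizes to the generated wild-type mean, as the
assay does. Defaults encode the published effect sizes (38-fold ΔPAR,
six-fold Δ3RE; fold-override mode) or any exclusive-model parameter
set. Replicates default to 3 (the biological replicate count);
consistency analyses use n = 100. The co-binding alternative adds a
doubly-bound fraction $x_4$ translating at $y_1 y_2$ (independent
repression; `min(y1, y2)` available), with site disruption fully
liberating the factor from singly- and doubly-bound states, and the
$\alpha/\beta$ redistribution not applied. No co-binding mechanism was
ever defined experimentally; this rule is an explicit generator
assumption, used only to show the test *rejects* such data.

Gel-derived fractions get additive Gaussian noise (default SD 0.02,
about the resolution of band quantification) clipped to [0, 1],
because gels are background-subtracted and bounded.

What a green test establishes: the algebra, the estimators and the
decision rules behave correctly on data generated by the stated
mechanisms at the stated effect sizes and noise levels. What it does
not: that real lysates obey simple mass action, that reporter noise is
exactly log-normal, or that the co-binding rule describes the true
joint state — none of which the published data constrain.

## Known limitations

- No thermodynamic link from EMSA affinities to occupancy fractions
  ($x_1, x_2$); the two analyses are deliberately independent.
- The IC50s for the competitor panel are displayed graphically in the
  source and are not available as numbers, so IC50 correctness is
  property-based (against the equilibrium oracle), not value-based.
- The explicit integrator is adequate for the protocol's parameter
  ranges but is not a general stiff solver.
- `fit_exclusive()` is a local multi-start search; with 32 starts on a
  6-dimensional box it has always located the analytic optimum in
  testing, but global optimality is not guaranteed.
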