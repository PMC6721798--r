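# ftlreg

Quantitative analysis of the **dual translational repression of ferritin
light chain (FTL) mRNA** by iron regulatory proteins (IRP) and the
initiation factor eIF3.

Ferritin stores cellular iron; translation of its light-chain subunit is
classically controlled by IRPs binding the iron-responsive element (IRE)
in the *FTL* 5ʹ-UTR. eIF3 was found to act as a second,
iron-independent repressor through a repressive element (3RE, nt 58–90)
immediately adjacent to the IRE, and a subset of hyperferritinemia SNPs
(G51C, G52C) disrupt eIF3 — not IRP — binding. `ftlreg` is for RNA
biologists and modellers who want to re-run, probe, or extend the three
quantitative arguments behind that picture:

1. **Three-state occupancy model.** Each transcript is bound solely by
   IRP (fraction *x₁*, translational efficiency *y₁*), solely by eIF3
   (*x₂*, *y₂*), or unbound (*x₃*, efficiency 1). Site-disrupting
   mutations redistribute bound mRNA by *α* (eIF3 site) or *β* (IRP
   site), with 0 ≤ *α* + *β* ≤ 1. Normalizing the wild-type readout to 1
   and eliminating *x₃* gives

   Double = Loop + Δ3RE + (*α* + *β* − *y₁α* − *y₂β* − 1),

   and the bracketed term lies in [−1, 0], so **mutually exclusive
   binding can never predict Double > Loop + Δ3RE**. The package tests
   that bound with Monte-Carlo error propagation
   (`test_exclusivity()`), and exhibits or refutes a feasible parameter
   set by constrained least squares (`fit_exclusive()`).
2. **Competition EMSA kinetics.** Mass-action simulation of the
   two-phase competition protocol (pre-incubation, then 1,000–100,000×
   unlabeled competitor), dissociation-rate estimation
   (`fit_koff()`), equilibrium checkpoints (`equilibrium_reached()`),
   and four-parameter-logistic IC50 fitting with a
   "not determinable" verdict for non-competing mutants
   (`fit_dose_response()`).
3. **5ʹ-UTR element map.** Interval arithmetic on the annotated
   elements (PAR-CLIP site nt 53–76, 3RE nt 58–90), variant
   annotation (`annotate_variant()`), reporter-construct building with
   coordinate lift-over (`apply_construct()`), and the 60-nt
   cap-distance steric rule (`steric_class()`).

A seeded synthetic-data module (`gen_reporter()`, `gen_timecourse()`,
`gen_dose_response()`) emulates the study's measurements — 38-fold
ΔPAR and six-fold Δ3RE derepression with log-normal reporter noise,
and chase/competition curves at k_off ≈ 0.006 min⁻¹ — so the whole
pipeline is testable without any deposited raw data.

## Worked example

```r
library(ftlreg)

ro <- load_readouts(system.file("extdata", "ftl_readouts.csv",
                                package = "ftlreg"))
test_exclusivity(ro)
#> Exclusive-binding consistency test
#>   Double = 41.8 vs feasible RHS [15.9, 16.9]
#>   point_consistent = FALSE
#>   p_consistent = 0.00027  (n_draws = 100000, seed = 2019)
#>   z_score = 3.493
#>   -> exclusive binding is inconsistent with the readouts;
#>      IRP and eIF3 likely act in cis on the same mRNA
```

The Double-mutant readout (41.8 ± 6.5) exceeds the largest value the
exclusive model can produce (Loop + Δ3RE = 12.5 + 4.4 = 16.9 ± 2.9) by
3.5 propagated standard deviations; only ~0.03% of measurement-error
resamples satisfy the bound, so IRP and eIF3 must be able to act on the
same transcript.

```r
tc <- gen_timecourse(binding_reaction(competitor_fold = 1e5,
                                      duration = 510),
                     noise_sd = 0.02, n_points = 40, seed = 2019)
fit_koff(tc)
#> koff = 0.006041 /min (SE 0.00029); F0 = 0.919, Finf = 0.00498

annotate_variant("G51C", element_map())
#> G51C (position 51, G>C)
#>   no element overlap; 2 nt upstream of PAR
#>   construct steric class: full-block
```

The chase simulation recovers the dissociation rate used to set the
equilibrium incubation times (half-life ≈ 115 min, hence the ≥ 11 h
incubations), and the SNP annotation places G51C two nucleotides
upstream of the eIF3 PAR-CLIP site — adjacent to, not inside, the IRP
footprint.

`run_pipeline(system.file("extdata", "demo_config.yaml", package =
"ftlreg"), out_dir = "demo_out")` chains generation, analysis and
reporting into a deterministic report bundle.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates, from scratch with the installed package, a synthetic
reporter table at the published ΔPAR effect size (38-fold, n = 100,
CV 10%) and re-estimates the ΔPAR fold-derepression with the analysis
stage, writing the estimate as JSON.
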