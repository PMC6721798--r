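# Demo pipeline configuration: generates a reporter table at the
# published effect sizes, tests exclusive binding, simulates a
# dissociation chase and a competition dose-response, and annotates the
# hyperferritinemia SNPs. Runs in well under two minutes on one CPU.
seed: 2019
n_draws: 100000
reporter:
  n: 100
  cv: 0.10
  fold_targets:
    DPAR: 38
    D3RE: 4.4
    LOOP: 12.5
    DOUBLE: 41.8
kinetics:
  koff: 0.006          # per minute
  kon: 1.0e+6          # per molar per minute
  competitor_fold: 100000
  duration: 510        # 30 min pre-incubation + 8 h chase
  n_points: 40
  noise_sd: 0.02
  folds: [1000, 3000, 10000, 30000, 100000]
variants: [G51C, G52C, A15G]
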