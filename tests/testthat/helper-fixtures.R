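# Published reporter summary (normalized luciferase, mean +/- SD, n = 6
# independent transfections): Double 41.8 +/- 6.5, Loop 12.5 +/- 2.9,
# D3RE 4.4 +/- 0.4.
published_readouts <- function() {
  construct_readouts(data.frame(
    construct = c("FTL", "D3RE", "LOOP", "DOUBLE"),
    mean = c(1, 4.4, 12.5, 41.8),
    sd = c(0, 0.4, 2.9, 6.5),
    n = 6
  ))
}

# Random valid occupancy parameters on the simplex, with alpha+beta <= 1.
random_occupancy <- function() {
  x <- diff(c(0, sort(runif(2)), 1))      # simplex triple
  a <- runif(1)
  occupancy_params(x1 = x[1], x2 = x[2], x3 = x[3],
                   y1 = runif(1), y2 = runif(1),
                   alpha = a, beta = runif(1) * (1 - a))
}

# Standard dissociation-chase reaction: printed concentrations and koff,
# 100,000x competitor (within the protocol range) so rebinding is
# negligible, 30 min pre-incubation + 8 h chase.
chase_reaction <- function(koff = 0.006, fold = 1e5, duration = 510) {
  binding_reaction(competitor_fold = fold, koff = koff,
                   duration = duration)
}
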