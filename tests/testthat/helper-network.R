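# shared fixtures: basal parameters and a cached basal network; individual
# tests override fields via modify_params-style rebuilds where needed
basal <- av_params()
basal_net <- av_network(basal)

# steady state for a single auditory/visual pair, silencing the slow-drift
# convergence warning some non-basal regimes emit
steady <- function(net, stims) suppressWarnings(simulate_network(net, stims))

# Gaussian bump profile centered at `center` (degrees) on the basal grid
bump <- function(center, sigma = 5, params = basal) {
  d <- circular_distance(unit_positions(params), center)
  exp(-d^2 / (2 * sigma^2))
}
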