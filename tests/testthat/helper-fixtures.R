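# Shared fixtures: small grids and configurations used across test files.

fast_cfg <- function(...) {
  mm_config(...)
}

# a coarse configuration for short coupled runs (120 m cells keep the domain
# small enough for second-scale tests)
coarse_cfg <- function(...) {
  mm_config(domain = list(resolution = 120), ...)
}

# 1-D channel setup helpers for flow oracles
channel_bed <- function(nx, depth, slope = 0, dx = 60, ny = 1) {
  matrix(rep(-depth - slope * dx * (nx:1), ny), nx, ny)
}

m2_omega <- function() 2 * pi / 43200
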