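# Shared fixtures: the study channel, reference fluids, and small builders.

study_geom <- function() channel_geometry(width = 50e-6, height = 50e-6,
                                          length = 15e-3)

# Case-13-like truth: printed per-case fit (n = 0.9389), slip 2.2e-3 m/s,
# mean 6.9e-3 m/s
case13_fluid <- function() power_law_fluid(K = 1.0, n = 0.9389, u0 = 2.2e-3)
case13_mean <- 6.9e-3

# trapezoid on possibly non-uniform grid
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# line-average over line-max of a normalized profile
mean_over_max_line <- function(np) trapz(np$ystar, np$vnorm) / max(np$vnorm)

# Normalized power-law family parameters with unit integral for a given
# (n, v_0N): v_avgN = (1 - v_0N) (2n+1)/(3n+1)
family_params <- function(n, v_0N) {
  list(n = n, v_avgN = (1 - v_0N) * (2 * n + 1) / (3 * n + 1), v_0N = v_0N)
}
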