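# Small fixture networks built in code.

# one compartment, one windkessel outlet: degenerates to the 0D recurrence
single_comp_net <- function(R = 1500, C = 0.17,
                            sources = list(
                              inlet_source("production", "node",
                                           mean_flow = 6.67e-3),
                              inlet_source("cardiac", "node",
                                           amplitude = 5.16, frequency = 1))) {
  sources <- lapply(sources, function(s) {
    s$node <- "node"
    s
  })
  hydraulic_network(
    compartments = list(compartment("node")),
    conduits = list(),
    outlets = list(windkessel_outlet("out", "node", R = R, C = C)),
    sources = sources
  )
}

# two compartments joined by one conduit, outlet downstream
two_comp_net <- function(r = 5, R = 1500, C = 0.2, Q = 0.01) {
  hydraulic_network(
    compartments = list(compartment("up"), compartment("down")),
    conduits = list(conduit("link", "up", "down", resistance = r, area = 10)),
    outlets = list(windkessel_outlet("out", "down", R = R, C = C)),
    sources = list(inlet_source("src", "up", mean_flow = Q))
  )
}

# closed-form gain of the backward-difference windkessel filter at
# angular frequency w and step dt (independent oracle for the discrete
# steady-cycle amplitude)
discrete_wk_gain <- function(R, C, w, dt) {
  abs(R / (1 + C * R * (1 - exp(-1i * w * dt)) / dt))
}

continuous_wk_gain <- function(R, C, w) R / sqrt(1 + (w * R * C)^2)

# amplitude of the frequency-f harmonic of a sampled trace, by discrete
# Fourier projection over whole periods [t0, t1) -- immune to the sampling
# bias of a max-min readout when the peak falls between samples
harmonic_amplitude <- function(trace, f, window) {
  keep <- trace$time >= window[1] & trace$time < window[2]
  t <- trace$time[keep]
  x <- trace[[setdiff(names(trace), "time")[1]]][keep]
  x <- x - mean(x)
  a <- 2 * mean(x * sin(2 * pi * f * t))
  b <- 2 * mean(x * cos(2 * pi * f * t))
  sqrt(a^2 + b^2)
}
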