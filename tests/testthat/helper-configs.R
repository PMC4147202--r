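# Small, quick configurations for structural tests. Physics-facing tests use
# the full default configuration (4 cycles, RK4 dt = 1e-4 s).
fast_config <- function(...) {
  simulation_config(dt = 1e-3, n_cycles = 2, ...)
}
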