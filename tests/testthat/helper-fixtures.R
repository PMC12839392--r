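# Small configurations used across test files.  All fixtures are built in
# code; sizes are kept small so the default test run stays fast.

# Two input cells (salty, sweet) feeding three hidden layers of 4 neurons.
small_network_config <- function(...) {
  network_config(input_cells = list(salty_cell(), sweet_cell()),
                 hidden_sizes = c(4L, 4L, 4L), ...)
}

# A deterministic mid-concentration salty stimulus.
salty_mid <- function() tastant_stimulus(c_Na = 100)

# Binary output patterns with a prescribed fill pattern.
pattern_of <- function(bits, nrow = 2, ncol = 1) {
  matrix(as.integer(bits), nrow = nrow, ncol = ncol)
}

# All 2-slot binary patterns (2 bins x 1 neuron).
all_two_slot_patterns <- function() {
  lapply(0:3, function(i) pattern_of(c(i %/% 2, i %% 2)))
}

# Reference RK4 receptor-cell run at a finer step, for convergence checks.
reference_trace <- function(stim, cell, dt = 0.01, duration = 300) {
  simulate_receptor_cell(stim, cell, duration = duration, dt = dt)
}
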