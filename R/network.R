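#' Binary spike train
#'
#' A binned binary spike vector: bin `k` (1-based element `k+1`) covers
#' `[t0 + k*dt_bin, t0 + (k+1)*dt_bin)`.
#'
#' @param bins 0/1 vector.
#' @param dt_bin bin width, ms.
#' @param t0 time of the first bin edge, ms.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(bins, dt_bin = 5, t0 = 0) {
  bins <- as.integer(bins)
  if (any(!bins %in% c(0L, 1L))) stop("spike train entries must be 0/1")
  stopifnot(dt_bin > 0)
  structure(list(bins = bins, dt_bin = dt_bin, t0 = t0),
            class = "spike_train")
}

#' Spike times of a binary train
#'
#' Bin-start times of the occupied bins.
#'
#' @param train a [spike_train()].
#' @return Numeric vector of times, ms.
#' @export
spike_times <- function(train) {
  (which(train$bins == 1L) - 1) * train$dt_bin + train$t0
}

#' Binarize a voltage trace into a spike train
#'
#' Bin `k` is set iff any voltage sample in `[k*dt_bin, (k+1)*dt_bin)`
#' reaches `V_threshold` (inclusive comparison).  The trailing sample at
#' `t = duration`, which lies outside the last bin, is ignored.
#'
#' @param trace a `voltage_trace` from [simulate_receptor_cell()], or a bare
#'   numeric vector of voltages (then `dt` must be given).
#' @param dt_bin bin width, ms.
#' @param V_threshold spike detection threshold, mV.
#' @param dt sample spacing for bare numeric traces, ms.
#' @return A [spike_train()].
#' @export
binarize_trace <- function(trace, dt_bin = 5, V_threshold = -50, dt = NULL) {
  if (inherits(trace, "voltage_trace")) {
    v <- trace$Vm_mV
    dt <- trace$dt_ms
  } else {
    v <- as.numeric(trace)
    if (is.null(dt)) stop("dt is required for a bare numeric trace")
  }
  if (length(v) == 0) stop("empty voltage trace")
  stopifnot(dt_bin > 0)
  t <- (seq_along(v) - 1) * dt
  n_bins <- floor((t[length(t)] + 1e-9) / dt_bin)
  if (n_bins < 1) n_bins <- 1
  idx <- floor(t / dt_bin + 1e-9)
  keep <- idx < n_bins
  hit <- tapply(v[keep] >= V_threshold, factor(idx[keep], levels = 0:(n_bins - 1)),
                any)
  bins <- as.integer(!is.na(hit) & hit)
  spike_train(bins, dt_bin = dt_bin)
}

#' Default input-layer cell population
#'
#' Eight taste receptor cells, two per modality: one narrowly tuned cell and
#' one dual-detector cell pairing the modality with a second one, so that
#' mixtures recruit overlapping but distinguishable input populations.
#'
#' @return List of [taste_cell_config()] objects.
#' @export
default_input_cells <- function() {
  dual <- function(a, b, label) {
    taste_cell_config(channels = c(a$channels, b$channels),
                      receptors = c(a$receptors, b$receptors),
                      label = label)
  }
  sa <- salty_cell(); so <- sour_cell(); sw <- sweet_cell(); bi <- bitter_cell()
  list(sa, so, sw, bi,
       dual(sa, sw, "salty+sweet"),
       dual(so, bi, "sour+bitter"),
       dual(sw, bi, "sweet+bitter"),
       dual(sa, so, "salty+sour"))
}

#' Network configuration
#'
#' Architecture and integration settings of the feedforward taste network:
#' an input layer of receptor cells followed by fully connected hidden
#' layers of Izhikevich neurons (default 3 x 20), strictly one-directional.
#'
#' @param input_cells list of [taste_cell_config()]; default
#'   [default_input_cells()].
#' @param hidden_sizes integer vector of hidden layer sizes.
#' @param duration trial duration, ms.
#' @param dt_bin spike binning width, ms.
#' @param V_threshold spike detection threshold for input cells, mV.
#' @param izh Izhikevich parameters shared by all hidden neurons.
#' @param izh_dt forward-Euler step for hidden neurons, ms (guarded at 1 ms).
#' @param hh_dt Runge-Kutta step for input cells, ms.
#' @param synapse synapse parameters.
#' @param output_population `"all_hidden"` (default; every hidden neuron
#'   contributes a column to the output pattern) or `"last_layer"`.
#' @param n_total_init length-2 range for the uniform integer initialization
#'   of per-synapse AMPA receptor counts.
#' @param phos_init initial phosphorylation fraction.
#' @return An object of class `network_config`.
#' @export
network_config <- function(input_cells = default_input_cells(),
                           hidden_sizes = c(20L, 20L, 20L),
                           duration = 300, dt_bin = 5, V_threshold = -50,
                           izh = izhikevich_params(), izh_dt = 0.5,
                           hh_dt = 0.02, synapse = synapse_params(),
                           output_population = c("all_hidden", "last_layer"),
                           n_total_init = c(50L, 150L), phos_init = 0.5) {
  output_population <- match.arg(output_population)
  stopifnot(length(input_cells) >= 1, all(hidden_sizes >= 1),
            duration > 0, dt_bin > 0, izh_dt > 0, izh_dt <= 1, hh_dt > 0,
            phos_init >= 0, phos_init <= 1)
  if (abs(duration %% dt_bin) > 1e-9)
    stop("duration must be a multiple of dt_bin")
  structure(list(input_cells = input_cells,
                 hidden_sizes = as.integer(hidden_sizes),
                 duration = duration, dt_bin = dt_bin,
                 V_threshold = V_threshold, izh = izh, izh_dt = izh_dt,
                 hh_dt = hh_dt, synapse = synapse,
                 output_population = output_population,
                 n_total_init = n_total_init, phos_init = phos_init),
            class = "network_config")
}

#' Build a taste network
#'
#' Instantiates the feedforward network: one weight block per layer gap
#' (input to hidden 1, then hidden to hidden), each holding an integer AMPA
#' receptor count matrix `N` and a phosphorylation fraction matrix `Phos`
#' (rows = postsynaptic, columns = presynaptic).  Receptor counts are drawn
#' uniformly from `cfg$n_total_init`; reproducible under `seed`.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed for the initial receptor counts.
#' @param scale global multiplier on the sampled receptor counts (rounded);
#'   used to initialize genetic-algorithm populations across a range of
#'   overall synaptic densities.
#' @return An object of class `taste_network`.
#' @export
build_network <- function(cfg = network_config(), seed = NULL, scale = 1) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(scale >= 0)
  sizes <- c(length(cfg$input_cells), cfg$hidden_sizes)
  gaps <- length(sizes) - 1
  W <- vector("list", gaps)
  for (l in seq_len(gaps)) {
    n_post <- sizes[l + 1]
    n_pre <- sizes[l]
    N <- matrix(round(scale * sample(cfg$n_total_init[1]:cfg$n_total_init[2],
                                     n_post * n_pre, replace = TRUE)),
                nrow = n_post)
    Phos <- matrix(cfg$phos_init, nrow = n_post, ncol = n_pre)
    W[[l]] <- list(N = N, Phos = Phos)
  }
  izh <- lapply(cfg$hidden_sizes, function(m) {
    list(a = rep(cfg$izh$a, m), b = rep(cfg$izh$b, m),
         c = rep(cfg$izh$c, m), d = rep(cfg$izh$d, m))
  })
  structure(list(cfg = cfg, W = W, izh = izh), class = "taste_network")
}

# Conductance weight matrices (nS) of one layer gap: the phosphorylated and
# unphosphorylated receptor pools enter with separate Michaelis constants.
weight_matrices <- function(net, l) {
  p <- net$cfg$synapse
  N <- net$W[[l]]$N
  Phos <- net$W[[l]]$Phos
  list(Wp = (p$g_AMPA / 1000) * N * Phos,
       Wu = (p$g_AMPA / 1000) * N * (1 - Phos))
}

# Input-layer spike trains (bin-start times, ms) for one stimulus.
# noise_sd > 0 makes trials stochastic; per-cell noise seeds are derived
# from `seed`.
simulate_input_trains <- function(cfg, stim, noise_sd = 0, seed = NULL) {
  cells <- cfg$input_cells
  seeds <- NULL
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    seeds <- sample.int(.Machine$integer.max, length(cells))
  }
  lapply(seq_along(cells), function(i) {
    tr <- simulate_receptor_cell(stim, cells[[i]], duration = cfg$duration,
                                 dt = cfg$hh_dt, noise_sd = noise_sd,
                                 seed = seeds[i])
    spike_times(binarize_trace(tr, dt_bin = cfg$dt_bin,
                               V_threshold = cfg$V_threshold))
  })
}

#' Simulate the full network for one stimulus
#'
#' Runs transduction for every input cell, binarizes the voltage traces at
#' `dt_bin`, propagates the resulting spike trains through the hidden layers
#' (glutamate release, phosphorylation-dependent AMPA conductance,
#' forward-Euler Izhikevich updates), and assembles the binary output
#' pattern from the configured output population.
#'
#' @param net a [taste_network()][build_network].
#' @param stim a [tastant_stimulus()].
#' @param noise_sd input-cell noise current SD, pA (0 = deterministic).
#' @param seed seed for the noise stream.
#' @param input_trains optional precomputed input spike-time list (skips
#'   transduction; used to share input trains across network variants).
#' @return An object of class `network_response`: list with `input_trains`
#'   (spike times per input cell), `rasters` (per hidden layer, spike times
#'   per neuron), `output` (binary `k x m` pattern matrix) and `cfg`.
#' @export
simulate_network <- function(net, stim, noise_sd = 0, seed = NULL,
                             input_trains = NULL) {
  cfg <- net$cfg
  if (is.null(input_trains))
    input_trains <- simulate_input_trains(cfg, stim, noise_sd, seed)
  n_steps <- round(cfg$duration / cfg$izh_dt)
  Wp <- lapply(seq_along(net$W), function(l) weight_matrices(net, l)$Wp)
  Wu <- lapply(seq_along(net$W), function(l) weight_matrices(net, l)$Wu)
  p <- cfg$synapse
  rasters <- cpp_run_hidden(input_trains, Wp, Wu, p$A, p$tau, p$K_phos,
                            p$K_unphos, p$E_AMPA, cfg$izh$input_gain,
                            lapply(net$izh, `[[`, "a"),
                            lapply(net$izh, `[[`, "b"),
                            lapply(net$izh, `[[`, "c"),
                            lapply(net$izh, `[[`, "d"),
                            cfg$izh_dt, n_steps, 500)
  structure(list(input_trains = input_trains, rasters = rasters,
                 output = output_pattern(rasters, cfg), cfg = cfg),
            class = "network_response")
}

# Spike-time vectors of the configured output population.
output_raster <- function(rasters, cfg) {
  if (cfg$output_population == "last_layer")
    rasters[[length(rasters)]]
  else
    do.call(c, rasters)
}

#' Assemble the binary output pattern
#'
#' `k x m` binary matrix over the response period: `k = duration / dt_bin`
#' bins (60 for the defaults), one column per output neuron; entry `(i, j)`
#' marks a spike of neuron `j` during bin `i`.
#'
#' @param rasters per-layer list of per-neuron spike-time vectors, as
#'   returned in a `network_response`.
#' @param cfg the [network_config()].
#' @return Binary integer matrix.
#' @export
output_pattern <- function(rasters, cfg) {
  pop <- output_raster(rasters, cfg)
  k <- round(cfg$duration / cfg$dt_bin)
  Y <- matrix(0L, nrow = k, ncol = length(pop))
  for (j in seq_along(pop)) {
    b <- floor(pop[[j]] / cfg$dt_bin) + 1
    b <- b[b >= 1 & b <= k]
    Y[unique(b), j] <- 1L
  }
  Y
}
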