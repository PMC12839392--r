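test_that("stimulus generation: pure, mixed, sweeps are well-formed", {
  pure <- generate_stimuli(stimulus_spec("pure", level = "mid"))
  expect_length(pure, 4)
  expect_true(all(vapply(pure, is_pure, logical(1))))
  expect_equal(as.numeric(pure[[1]]), c(100, 0, 0, 0))  # mid salty

  mix <- generate_stimuli(stimulus_spec("mixed", c("H", "sweet"),
                                        level = "high"))[[1]]
  expect_equal(which(as.numeric(mix) > 0), c(2, 3))

  sw <- generate_stimuli(stimulus_spec("sweep", "Na", n = 7))
  expect_length(sw, 7)
  conc <- vapply(sw, function(s) s[["c_Na"]], numeric(1))
  expect_true(all(diff(conc) > 0))
  expect_equal(conc[1], 30)
  expect_equal(conc[7], 300)

  set.seed(1); p1 <- random_taste_panel(6)
  set.seed(1); p2 <- random_taste_panel(6)
  expect_identical(p1, p2)
})

test_that("spike-pattern entropy: silent, maximal and bounded cases", {
  cfg <- entropy_config(bin = 3, window = 60)
  silent <- replicate(4, replicate(10, numeric(0), simplify = FALSE),
                      simplify = FALSE)
  expect_equal(spike_pattern_entropy(silent, cfg), 0)

  # every slot firing in exactly half the trials: maximum = slot count
  m <- 60
  n_bins <- 20
  all_bins <- (0:(n_bins - 1)) * 3 + 1      # one spike in every 3 ms bin
  active <- replicate(m, all_bins, simplify = FALSE)
  quiet <- replicate(m, numeric(0), simplify = FALSE)
  trials <- list(active, quiet, active, quiet)
  expect_equal(spike_pattern_entropy(trials, cfg), n_bins * m)  # 1200 bits

  # generic rasters never exceed the slot count
  set.seed(77)
  rnd <- replicate(6, replicate(m, runif(sample(0:8, 1), 0, 60),
                                simplify = FALSE), simplify = FALSE)
  h <- spike_pattern_entropy(rnd, cfg)
  expect_gte(h, 0)
  expect_lte(h, n_bins * m)

  expect_error(spike_pattern_entropy(silent[1], cfg), "two trials")
  expect_error(entropy_config(bin = 3, window = 50), "multiple")
})

test_that("nearest-centroid decoding separates deterministic distinct fingerprints", {
  cfg <- small_network_config()
  net <- build_network(cfg, seed = 2)
  panel <- list(tastant_stimulus(c_Na = 300),
                tastant_stimulus(c_sweet = 45000))
  # noiseless trials: identical fingerprints per class; distinct classes
  acc <- classify_stimuli(net, panel, n_trials = 4, noise_sd = 0)
  r1 <- simulate_network(net, panel[[1]])$output
  r2 <- simulate_network(net, panel[[2]])$output
  expect_false(identical(r1, r2))
  expect_equal(acc, 1.0)
  expect_gte(acc, 0)
  expect_lte(acc, 1)
  expect_error(classify_stimuli(net, panel[1]), "two classes")
})

test_that("decoding accuracy is invariant to trial ordering", {
  cfg <- small_network_config()
  net <- build_network(cfg, seed = 2)
  panel <- list(tastant_stimulus(c_Na = 300),
                tastant_stimulus(c_sweet = 45000))
  trains <- gustnet:::make_trial_trains(cfg, panel, 4, noise_sd = 25,
                                        seed = 9)
  acc1 <- classify_stimuli(net, panel, 4, trial_trains = trains)
  # permuting the class blocks must not change the overall accuracy
  acc2 <- classify_stimuli(net, rev(panel), 4,
                           trial_trains = rev(trains))
  expect_equal(acc1, acc2)
})

test_that("zero perturbation leaves classification exactly unchanged", {
  cfg <- small_network_config()
  net <- build_network(cfg, seed = 4)
  rob <- robustness_experiment(net, robustness_config(
    perturb_fraction = 0, n_draws = 2, n_trials = 4, noise_sd = 20,
    panel = list(tastant_stimulus(c_Na = 300),
                 tastant_stimulus(c_sweet = 45000)),
    seed = 5))
  expect_equal(rob$mean_drop, 0)
  expect_true(all(rob$perturbed == rob$baseline))
  expect_true(all(rob$perturbed >= 0 & rob$perturbed <= 1))
})

test_that("fingerprint summary reports sparsity and separation in range", {
  cfg <- small_network_config()
  net <- build_network(cfg, seed = 6)
  fs <- fingerprint_summary(net, list(tastant_stimulus(c_Na = 300),
                                      tastant_stimulus(c_sweet = 45000)),
                            n_trials = 2, noise_sd = 20, seed = 3)
  expect_gte(fs$sparsity, 0)
  expect_lte(fs$sparsity, 1)
  expect_gte(fs$separation, 0)
  expect_lte(fs$separation, 1)
})

test_that("configuration round-trips through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "network:",
    "  hidden_sizes: [6, 6, 6]",
    "  duration: 200",
    "  izh_dt: 0.5",
    "synapse:",
    "  tau: 2.0",
    "  A: 1.0",
    "izhikevich:",
    "  a: 0.02",
    "  input_gain: 0.2",
    "ga:",
    "  pop_size: 10",
    "  generations: 5"), path)
  cfg <- read_config(path)
  expect_equal(cfg$network$hidden_sizes, c(6L, 6L, 6L))
  expect_equal(cfg$network$duration, 200)
  expect_equal(cfg$network$synapse$tau, 2.0)
  expect_equal(cfg$network$izh$input_gain, 0.2)
  expect_equal(cfg$ga$pop_size, 10)
})

test_that("trace, raster and history exports are well-formed CSV", {
  tr <- simulate_receptor_cell(salty_mid(), salty_cell(), duration = 50)
  f1 <- write_voltage_csv(tr, tempfile(fileext = ".csv"))
  d1 <- read.csv(f1)
  expect_equal(names(d1), c("time_ms", "Vm_mV"))
  expect_equal(nrow(d1), length(tr$Vm_mV))

  net <- build_network(small_network_config(), seed = 1)
  resp <- simulate_network(net, tastant_stimulus(c_Na = 300))
  f2 <- write_raster_csv(resp, tempfile(fileext = ".csv"))
  d2 <- read.csv(f2)
  expect_equal(names(d2), c("layer", "neuron_id", "spike_time_ms"))
  expect_true(all(d2$layer %in% 0:3))
})
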