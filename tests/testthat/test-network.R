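test_that("voltage binarization sets a bin iff a sample reaches threshold", {
  # constant subthreshold trace: all-zero train
  v <- rep(-70, 61)
  st <- binarize_trace(v, dt_bin = 5, V_threshold = -50, dt = 0.5)
  expect_true(all(st$bins == 0))
  expect_length(st$bins, 6)

  # threshold is inclusive: a sample exactly at -50 mV counts
  v[13] <- -50
  st <- binarize_trace(v, dt_bin = 5, V_threshold = -50, dt = 0.5)
  expect_equal(which(st$bins == 1), 2)  # t = 6 ms falls in bin [5, 10)

  # single crossing at t = 7 ms with 5 ms bins sets bin index 1 (0-based)
  v <- rep(-70, 101); v[71] <- -20  # dt = 0.1 ms, t = 7 ms
  st <- binarize_trace(v, dt_bin = 5, V_threshold = -50, dt = 0.1)
  expect_equal(which(st$bins == 1) - 1, 1)
  expect_equal(spike_times(st), 5)
})

test_that("network construction counts edges, is seeded, and is strictly feedforward", {
  cfg <- network_config()
  net <- build_network(cfg, seed = 3)
  expect_length(net$W, 3)
  expect_equal(dim(net$W[[1]]$N), c(20, 8))   # input -> hidden 1
  expect_equal(dim(net$W[[2]]$N), c(20, 20))
  expect_equal(dim(net$W[[3]]$N), c(20, 20))
  expect_true(all(net$W[[1]]$N >= cfg$n_total_init[1] &
                  net$W[[1]]$N <= cfg$n_total_init[2]))
  expect_true(all(vapply(net$W, function(w) all(w$Phos == cfg$phos_init),
                         logical(1))))

  net2 <- build_network(cfg, seed = 3)
  expect_identical(net$W, net2$W)
  net3 <- build_network(cfg, seed = 4)
  expect_false(identical(net$W, net3$W))

  # connectivity is one weight block per consecutive layer gap only:
  # no intra-layer or backward weights exist by construction
  sizes <- c(length(cfg$input_cells), cfg$hidden_sizes)
  for (l in seq_along(net$W))
    expect_equal(dim(net$W[[l]]$N), c(sizes[l + 1], sizes[l]))
})

test_that("Izhikevich step matches an independent regular-spiking reference", {
  p <- izhikevich_params()
  # independent plain-R reference of the published reduced model
  ref_run <- function(I, dur, dt) {
    v <- -65; u <- p$b * v; n <- 0
    for (k in seq_len(round(dur / dt))) {
      vn <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
      un <- u + dt * p$a * (p$b * v - u)
      if (vn >= 30) { n <- n + 1; vn <- p$c; un <- un + p$d }
      v <- vn; u <- un
    }
    n
  }
  run <- function(I, dur, dt) {
    st <- izhikevich_state(p); n <- 0
    for (k in seq_len(round(dur / dt))) {
      st <- step_izhikevich(st, I, dt, p)
      if (st$spiked) n <- n + 1
    }
    n
  }
  expect_equal(run(0, 300, 0.5), 0)
  expect_equal(ref_run(0, 300, 0.5), 0)
  n10 <- run(10, 300, 0.5)
  expect_gt(n10, 3)                      # sustained drive -> periodic firing
  expect_equal(n10, ref_run(10, 300, 0.5))
  expect_equal(run(10, 300, 0.5), n10)   # reproducible

  # reset contract: crossing emits exactly one spike and resets that step
  st <- step_izhikevich(list(v = 29, u = 0), I = 200, dt = 0.5, p)
  expect_true(st$spiked)
  expect_equal(st$v, p$c)
})

test_that("compiled layer propagation agrees with the R-level synapse + neuron path", {
  p <- synapse_params()
  izh <- izhikevich_params()
  dt <- 0.5
  n_steps <- 200
  pre_spikes <- list(c(10, 15, 20, 42.5, 55))
  n_total <- 140; phos <- 0.7
  wp <- matrix(p$g_AMPA / 1000 * n_total * phos, 1, 1)
  wu <- matrix(p$g_AMPA / 1000 * n_total * (1 - phos), 1, 1)

  res <- gustnet:::cpp_layer_propagate(pre_spikes, wp, wu, p$A, p$tau,
                                       p$K_phos, p$K_unphos, p$E_AMPA,
                                       izh$input_gain, izh$a, izh$b, izh$c,
                                       izh$d, dt, n_steps, 500, TRUE)

  st_syn <- synapse_state(n_total, phos, pre_spikes[[1]])
  tgrid <- (seq_len(n_steps) - 1) * dt
  G <- cleft_glutamate(tgrid, st_syn, p)
  st <- izhikevich_state(izh)
  v_r <- numeric(n_steps)
  spk_r <- numeric(0)
  for (k in seq_len(n_steps)) {
    g <- ampa_conductance(G[k], list(st_syn), p)
    I <- izh$input_gain * synaptic_current(g, st$v, p)
    st <- step_izhikevich(st, I, dt, izh)
    if (st$spiked) spk_r <- c(spk_r, k * dt)
    v_r[k] <- st$v
  }
  expect_equal(res$spikes[[1]], spk_r)
  expect_equal(as.numeric(res$v), v_r, tolerance = 1e-10)
})

test_that("full network simulation: causality, determinism, output shape", {
  cfg <- small_network_config()
  net <- build_network(cfg, seed = 9)

  # zero stimulus -> no input spikes -> silent output (feedforward causality)
  r0 <- simulate_network(net, tastant_stimulus())
  expect_equal(sum(vapply(r0$input_trains, length, integer(1))), 0)
  expect_true(all(r0$output == 0))

  r1 <- simulate_network(net, salty_mid())
  r2 <- simulate_network(net, salty_mid())
  expect_identical(r1$output, r2$output)
  expect_identical(r1$rasters, r2$rasters)

  expect_equal(dim(r1$output), c(300 / 5, sum(cfg$hidden_sizes)))

  cfg_last <- small_network_config(output_population = "last_layer")
  net_last <- build_network(cfg_last, seed = 9)
  expect_equal(dim(simulate_network(net_last, salty_mid())$output),
               c(60, 4))
})

test_that("default-architecture output pattern has 60 bins x 60 neurons", {
  net <- build_network(network_config(), seed = 1)
  resp <- simulate_network(net, salty_mid())
  expect_equal(dim(resp$output), c(60, 60))
  expect_true(all(resp$output %in% c(0L, 1L)))
})

test_that("increasing a stimulus component does not decrease input-layer drive", {
  cfg <- small_network_config()
  counts <- vapply(c(0, 50, 100, 200, 400), function(cNa) {
    tr <- simulate_input_trains <- gustnet:::simulate_input_trains(
      cfg, tastant_stimulus(c_Na = cNa))
    sum(vapply(tr, length, integer(1)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
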