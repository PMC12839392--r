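test_that("GHK reversal matches direct arithmetic and its symmetries", {
  consts <- physical_constants()
  na <- ion_channel_spec("Na", z = 1, conc_out = 145, conc_in = 12, g = 1)
  # oracle: RT/F at 310 K = 26.712 mV, times ln(145/12)
  rtf <- 1000 * consts$R * consts$T / consts$F
  expect_equal(rtf, 26.712, tolerance = 1e-4)
  expect_equal(ghk_reversal(na, consts), rtf * log(145 / 12))
  expect_equal(ghk_reversal(na, consts), 66.56, tolerance = 1e-3)

  # equal concentrations give zero for any valence
  eq <- ion_channel_spec("H", z = 2, conc_out = 5, conc_in = 5, g = 1)
  expect_equal(ghk_reversal(eq, consts), 0)

  # negating the valence flips the sign
  neg <- ion_channel_spec("Na", z = -1, conc_out = 145, conc_in = 12, g = 1)
  expect_equal(ghk_reversal(neg, consts), -ghk_reversal(na, consts))

  # antisymmetric under swapping the concentrations
  sw <- ion_channel_spec("Na", z = 1, conc_out = 12, conc_in = 145, g = 1)
  expect_equal(ghk_reversal(sw, consts), -ghk_reversal(na, consts))

  expect_error(ion_channel_spec("Na", conc_out = -1, conc_in = 12, g = 1),
               "positive")
})

test_that("passive ionic current follows the depolarizing-positive convention", {
  expect_equal(passive_ion_current(1, Vm = 66.6, Ex = 66.6), 0)
  expect_equal(passive_ion_current(1, Vm = -50, Ex = 66.6), 116.6)
  expect_gt(passive_ion_current(1, Vm = -50, Ex = 66.6), 0)  # depolarizing
  expect_equal(passive_ion_current(0, Vm = -120, Ex = 80), 0)
})

test_that("Hill open fraction: closed-form cases, bounds and monotonicity", {
  expect_equal(hill_open_fraction(2, Ka = 2, n = 3), 0.5)
  expect_equal(hill_open_fraction(0, Ka = 2, n = 3), 0)
  expect_equal(hill_open_fraction(4, Ka = 2, n = 2), 0.8)
  expect_error(hill_open_fraction(-1, Ka = 2), "nonnegative")

  set.seed(11)
  for (i in 1:20) {
    Ka <- runif(1, 0.01, 100)
    n <- runif(1, 0.2, 4)
    L <- sort(runif(50, 0, 5 * Ka))
    o <- hill_open_fraction(L, Ka, n)
    expect_true(all(o >= 0 & o <= 1))
    expect_true(all(diff(o) >= 0))
  }
})

test_that("metabotropic current: trivial and arithmetic cases", {
  rc <- metabotropic_receptor_spec("sweet_T1R2_T1R3", Ka = 100, g_meta = 1,
                                   E_rev = 60)
  expect_equal(metabotropic_current(rc, O = 0, Vm = -80), 0)
  expect_equal(metabotropic_current(rc, O = 0.5, Vm = -50), 55)
  expect_equal(metabotropic_current(rc, O = 0.7, Vm = 60), 0)
  expect_error(metabotropic_current(rc, O = 1.2, Vm = 0), "\\[0, 1\\]")
})

test_that("total receptor current is additive over detectors", {
  zero <- tastant_stimulus()
  cellNa <- salty_cell()
  cellSw <- sweet_cell()
  both <- taste_cell_config(channels = cellNa$channels,
                            receptors = cellSw$receptors)
  expect_equal(total_receptor_current(zero, both, -65), 0)

  stim <- tastant_stimulus(c_Na = 80, c_sweet = 20000)
  vm <- -58
  # singleton cell equals the per-detector computation done by hand
  ch <- cellNa$channels[[1]]
  gNa <- ch$g * hill_open_fraction(80, ch$K_half, 1)
  iNa <- passive_ion_current(gNa, vm, ghk_reversal(ch))
  rc <- cellSw$receptors[[1]]
  iSw <- metabotropic_current(rc, hill_open_fraction(20000, rc$Ka, rc$n), vm)
  expect_equal(total_receptor_current(stim, cellNa, vm), iNa)
  expect_equal(total_receptor_current(stim, cellSw, vm), iSw)
  expect_equal(total_receptor_current(stim, both, vm), iNa + iSw)
})

test_that("receptor cell at rest stays at rest, without drive or with zero conductances", {
  tr <- simulate_receptor_cell(tastant_stimulus(), salty_cell(),
                               duration = 300)
  expect_length(tr$Vm_mV, 300 / 0.02 + 1)
  expect_true(all(abs(tr$Vm_mV + 65) < 2))
  expect_equal(sum(binarize_trace(tr)$bins), 0)

  # all conductances zero: Vm held exactly constant
  dead <- taste_cell_config(hh = hh_params(g_Na = 0, g_K = 0, g_L = 0))
  tr0 <- simulate_receptor_cell(tastant_stimulus(c_Na = 500), dead,
                                duration = 20, init = membrane_state(-42))
  expect_true(all(tr0$Vm_mV == -42))
})

test_that("strong salty stimulus drives threshold crossings; spike count converges in dt", {
  stim <- tastant_stimulus(c_Na = 300)  # well above the gating midpoint
  tr <- simulate_receptor_cell(stim, salty_cell(), duration = 300)
  expect_gt(max(tr$Vm_mV), -50)
  n_default <- sum(binarize_trace(tr)$bins)
  expect_gt(n_default, 0)

  ref <- reference_trace(stim, salty_cell())           # dt = 0.01 ms
  half <- simulate_receptor_cell(stim, salty_cell(), duration = 300,
                                 dt = 0.01)
  expect_equal(n_default, sum(binarize_trace(ref)$bins))
  expect_equal(sum(binarize_trace(half)$bins), sum(binarize_trace(ref)$bins))
})

test_that("receptor cell simulation is deterministic and rejects bad steps", {
  stim <- salty_mid()
  a <- simulate_receptor_cell(stim, salty_cell(), duration = 100)
  b <- simulate_receptor_cell(stim, salty_cell(), duration = 100)
  expect_identical(a$Vm_mV, b$Vm_mV)
  expect_error(simulate_receptor_cell(stim, salty_cell(), duration = 100,
                                      dt = 0.03),
               "multiple")
})
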