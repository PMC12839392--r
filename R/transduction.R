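#' Physical constants for electrodiffusion
#'
#' Gas constant, Faraday constant and absolute temperature used in the
#' Goldman-Hodgkin-Katz reversal potential.  The default temperature is
#' physiological (310 K).
#'
#' @param R gas constant, J mol^-1 K^-1.
#' @param F Faraday constant, C mol^-1.
#' @param T temperature, K.
#' @return An object of class `physical_constants`.
#' @export
physical_constants <- function(R = 8.314, F = 96485.332, T = 310) {
  stopifnot(R > 0, F > 0, T > 0)
  structure(list(R = R, F = F, T = T), class = "physical_constants")
}

#' Ion channel specification (salty / sour pathway)
#'
#' Describes a non-voltage-gated electrodiffusive channel (ENaC-like Na+
#' channel or proton channel).  The channel conductance is gated by the
#' matching stimulus concentration through a first-order saturation term
#' `c / (c + K_half)` so that a zero stimulus carries no current and the
#' nominal conductance `g` is recovered at saturating concentrations.
#'
#' @param ion_label `"Na"` or `"H"`; selects which stimulus component gates
#'   the channel.
#' @param z integer valence (nonzero).
#' @param conc_out,conc_in extracellular / intracellular ion concentration,
#'   mM.  Both strictly positive.
#' @param g channel conductance, nS.
#' @param K_half half-saturation concentration of the stimulus gating, mM.
#' @return An object of class `ion_channel_spec`.
#' @examples
#' ch <- ion_channel_spec("Na", z = 1, conc_out = 145, conc_in = 12, g = 3)
#' ghk_reversal(ch)
#' @export
ion_channel_spec <- function(ion_label = c("Na", "H"), z = 1L,
                             conc_out, conc_in, g, K_half = NULL) {
  ion_label <- match.arg(ion_label)
  if (conc_out <= 0 || conc_in <= 0)
    stop("ion concentrations must be strictly positive")
  stopifnot(g >= 0, z != 0)
  if (is.null(K_half))
    K_half <- switch(ion_label, Na = 100, H = 0.1)
  stopifnot(K_half > 0)
  structure(list(ion_label = ion_label, z = as.integer(z),
                 conc_out = conc_out, conc_in = conc_in, g = g,
                 K_half = K_half),
            class = "ion_channel_spec")
}

#' Metabotropic receptor specification (sweet / bitter pathway)
#'
#' Hill-type activation of a G-protein-coupled taste receptor driving a
#' depolarizing conductance whose reversal potential defaults to that of
#' voltage-gated Na+ channels.
#'
#' @param receptor_label `"sweet_T1R2_T1R3"` or `"bitter_T2R"`.
#' @param Ka half-maximal activation constant (stimulus units).
#' @param n Hill coefficient.
#' @param g_meta maximal conductance, nS.
#' @param E_rev reversal potential, mV.
#' @return An object of class `metabotropic_receptor_spec`.
#' @export
metabotropic_receptor_spec <- function(receptor_label = c("sweet_T1R2_T1R3",
                                                          "bitter_T2R"),
                                       Ka, n = 1, g_meta, E_rev = 50) {
  receptor_label <- match.arg(receptor_label)
  stopifnot(Ka > 0, n > 0, g_meta >= 0)
  structure(list(receptor_label = receptor_label, Ka = Ka, n = n,
                 g_meta = g_meta, E_rev = E_rev),
            class = "metabotropic_receptor_spec")
}

#' Tastant stimulus
#'
#' The model's sole external input: concentrations of the four modality
#' ligands.  Na+ and H+ are in mM; the sweet and bitter axes are in model
#' units matching the corresponding receptor `Ka`.
#'
#' @param c_Na,c_H,c_sweet,c_bitter nonnegative concentrations.
#' @return An object of class `tastant_stimulus` (named numeric of length 4).
#' @export
tastant_stimulus <- function(c_Na = 0, c_H = 0, c_sweet = 0, c_bitter = 0) {
  v <- c(c_Na = c_Na, c_H = c_H, c_sweet = c_sweet, c_bitter = c_bitter)
  if (any(v < 0)) stop("stimulus concentrations must be nonnegative")
  structure(v, class = "tastant_stimulus")
}

#' Classical membrane parameters for the voltage-dependent current
#'
#' Squid-axon-type maximal conductances and reversal potentials, scaled to a
#' small receptor cell (conductances in nS for a 10 pF cell, i.e. a membrane
#' area of ~1000 um^2 at standard specific conductances).  The resting state
#' of this membrane is approximately -65 mV.
#'
#' @param g_Na,g_K,g_L maximal conductances, nS.
#' @param E_Na,E_K,E_L reversal potentials, mV.
#' @return A list of class `hh_params`.
#' @export
hh_params <- function(g_Na = 1200, g_K = 360, g_L = 3,
                      E_Na = 50, E_K = -77, E_L = -54.387) {
  stopifnot(g_Na >= 0, g_K >= 0, g_L >= 0)
  structure(list(g_Na = g_Na, g_K = g_K, g_L = g_L,
                 E_Na = E_Na, E_K = E_K, E_L = E_L), class = "hh_params")
}

#' Taste receptor cell configuration
#'
#' A cell is a bag of detectors: electrodiffusive channels (salty/sour) and
#' metabotropic receptors (sweet/bitter).  Either list may be empty for a
#' cell lacking that detector.
#'
#' @param channels list of [ion_channel_spec()] objects.
#' @param receptors list of [metabotropic_receptor_spec()] objects.
#' @param Cm membrane capacitance, pF.
#' @param hh classical membrane parameters, see [hh_params()].
#' @param constants physical constants, see [physical_constants()].
#' @param label optional cell label.
#' @return An object of class `taste_cell_config`.
#' @export
taste_cell_config <- function(channels = list(), receptors = list(),
                              Cm = 10, hh = hh_params(),
                              constants = physical_constants(),
                              label = NULL) {
  stopifnot(Cm > 0)
  for (ch in channels)
    if (!inherits(ch, "ion_channel_spec")) stop("invalid channel spec")
  for (rc in receptors)
    if (!inherits(rc, "metabotropic_receptor_spec"))
      stop("invalid receptor spec")
  structure(list(channels = channels, receptors = receptors, Cm = Cm,
                 hh = hh, constants = constants, label = label),
            class = "taste_cell_config")
}

#' Goldman-Hodgkin-Katz reversal potential
#'
#' Computes `(R*T)/(z*F) * ln(conc_out/conc_in)` in millivolts for a single
#' ion species.
#'
#' @param spec an [ion_channel_spec()].
#' @param consts physical constants.
#' @return Reversal potential, mV.
#' @examples
#' # Na+ at physiological 145/12 mM, body temperature: about +66.6 mV
#' ghk_reversal(ion_channel_spec("Na", conc_out = 145, conc_in = 12, g = 1))
#' @export
ghk_reversal <- function(spec, consts = physical_constants()) {
  if (spec$conc_out <= 0 || spec$conc_in <= 0)
    stop("ion concentrations must be strictly positive")
  1000 * (consts$R * consts$T) / (spec$z * consts$F) *
    log(spec$conc_out / spec$conc_in)
}

#' Passive ionic current
#'
#' Ohmic current through a channel of conductance `g` with reversal `Ex`.
#' The package-wide sign convention is depolarizing-positive: the current is
#' `g * (Ex - Vm)`, so an inward (depolarizing) current at `Vm < Ex` enters
#' the membrane equation with a positive sign.
#'
#' @param g conductance, nS.
#' @param Vm membrane potential, mV.
#' @param Ex reversal potential, mV.
#' @return Current, pA.
#' @export
passive_ion_current <- function(g, Vm, Ex) {
  stopifnot(g >= 0)
  g * (Ex - Vm)
}

#' Hill open fraction
#'
#' Fraction of receptors activated at ligand concentration `L`:
#' `L^n / (L^n + Ka^n)`.
#'
#' @param L ligand concentration (vectorized), same units as `Ka`.
#' @param Ka half-maximal activation constant.
#' @param n Hill coefficient.
#' @return Open fraction in \[0, 1\].
#' @export
hill_open_fraction <- function(L, Ka, n = 1) {
  stopifnot(Ka > 0, n > 0)
  if (any(L < 0)) stop("ligand concentration must be nonnegative")
  Ln <- L^n
  Ln / (Ln + Ka^n)
}

#' Metabotropic receptor current
#'
#' Current carried by a metabotropic receptor pathway with open fraction `O`,
#' depolarizing-positive: `g_meta * O * (E_rev - Vm)`.
#'
#' @param spec a [metabotropic_receptor_spec()].
#' @param O open fraction in \[0, 1\].
#' @param Vm membrane potential, mV.
#' @return Current, pA.
#' @export
metabotropic_current <- function(spec, O, Vm) {
  if (any(O < 0 | O > 1)) stop("open fraction must lie in [0, 1]")
  spec$g_meta * O * (spec$E_rev - Vm)
}

# Effective conductance / reversal of every detector for a given stimulus.
# Channel conductances are gated by the matching stimulus component through
# a first-order saturation; receptor conductances by their Hill open
# fraction.  Returns list(g_eff, e_rev) in nS / mV.
receptor_drive <- function(stim, cfg) {
  g <- numeric(0)
  e <- numeric(0)
  for (ch in cfg$channels) {
    conc <- switch(ch$ion_label, Na = stim[["c_Na"]], H = stim[["c_H"]])
    g <- c(g, ch$g * hill_open_fraction(conc, ch$K_half, 1))
    e <- c(e, ghk_reversal(ch, cfg$constants))
  }
  for (rc in cfg$receptors) {
    conc <- switch(rc$receptor_label,
                   sweet_T1R2_T1R3 = stim[["c_sweet"]],
                   bitter_T2R = stim[["c_bitter"]])
    g <- c(g, rc$g_meta * hill_open_fraction(conc, rc$Ka, rc$n))
    e <- c(e, rc$E_rev)
  }
  list(g_eff = g, e_rev = e)
}

#' Total receptor-driven membrane current
#'
#' Sum of the electrodiffusive (salty/sour) and metabotropic (sweet/bitter)
#' currents of a cell for a given stimulus at membrane potential `Vm`.
#' Additive over detectors.
#'
#' @param stim a [tastant_stimulus()].
#' @param cfg a [taste_cell_config()].
#' @param Vm membrane potential, mV.
#' @return Current, pA (depolarizing-positive).
#' @export
total_receptor_current <- function(stim, cfg, Vm) {
  dr <- receptor_drive(stim, cfg)
  if (length(dr$g_eff) == 0) return(0)
  sum(dr$g_eff * (dr$e_rev - Vm))
}

# Steady-state gate values of the classical membrane at potential v.
hh_steady_gates <- function(v) {
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-7, y * (1 - x / y / 2),
                                 x / (1 - exp(-x / y)))
  am <- 0.1 * vtrap(v + 40, 10); bm <- 4 * exp(-(v + 65) / 18)
  ah <- 0.07 * exp(-(v + 65) / 20); bh <- 1 / (1 + exp(-(v + 35) / 10))
  an <- 0.01 * vtrap(v + 55, 10); bn <- 0.125 * exp(-(v + 65) / 80)
  c(m = am / (am + bm), h = ah / (ah + bh), n = an / (an + bn))
}

#' Membrane state of a taste receptor cell
#'
#' @param Vm membrane potential, mV.
#' @param gates named vector `(m, h, n)`; defaults to the steady state at
#'   `Vm`.  Components are clamped to \[0, 1\].
#' @return An object of class `membrane_state`.
#' @export
membrane_state <- function(Vm = -65, gates = NULL) {
  if (is.null(gates)) gates <- hh_steady_gates(Vm)
  gates <- pmin(pmax(gates, 0), 1)
  structure(list(Vm = Vm, gates = gates), class = "membrane_state")
}

#' Simulate a taste receptor cell
#'
#' Integrates `Cm dVm/dt = Itot + Ipd` with fourth-order Runge-Kutta, where
#' `Itot` is the receptor-driven current of [total_receptor_current()] and
#' `Ipd` the classical voltage-dependent membrane current.  Receptor gating
#' is constant over the trial (it depends only on the stimulus), so the
#' per-detector effective conductances are precomputed once.
#'
#' @param stim a [tastant_stimulus()].
#' @param cfg a [taste_cell_config()].
#' @param duration trial duration, ms (must be a multiple of `dt`).
#' @param dt integration step, ms.  The default (0.02 ms) resolves the fast
#'   sodium activation gate during the spike upstroke; see the vignette for
#'   the step-size convergence analysis.
#' @param init initial [membrane_state()]; defaults to rest at -65 mV.
#' @param noise_sd standard deviation of a zero-mean Gaussian noise current
#'   (pA) resampled every 1 ms, used to produce trial-to-trial variability.
#'   0 disables noise.
#' @param seed optional seed for the noise stream.
#' @param v_bound integration guard: |Vm| above this bound (mV) aborts with
#'   an error naming the step.
#' @return An object of class `voltage_trace`: list with `t_ms`, `Vm_mV`
#'   (length `duration/dt + 1`) and `dt_ms`.
#' @examples
#' cell <- salty_cell()
#' tr <- simulate_receptor_cell(tastant_stimulus(c_Na = 100), cell,
#'                              duration = 50)
#' max(tr$Vm_mV)
#' @export
simulate_receptor_cell <- function(stim, cfg, duration = 300, dt = 0.02,
                                   init = NULL, noise_sd = 0, seed = NULL,
                                   v_bound = 150) {
  stopifnot(duration > 0, dt > 0)
  n_steps <- round(duration / dt)
  if (abs(n_steps * dt - duration) > 1e-9)
    stop("duration must be a multiple of dt")
  if (is.null(init)) init <- membrane_state()
  dr <- receptor_drive(stim, cfg)
  noise <- numeric(0)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    noise <- rnorm(ceiling(duration), sd = noise_sd)
  }
  vm <- cpp_hh_rk4(dr$g_eff, dr$e_rev,
                   cfg$hh$g_Na, cfg$hh$g_K, cfg$hh$g_L,
                   cfg$hh$E_Na, cfg$hh$E_K, cfg$hh$E_L,
                   cfg$Cm, n_steps, dt, noise,
                   init$Vm, init$gates[["m"]], init$gates[["h"]],
                   init$gates[["n"]], v_bound)
  structure(list(t_ms = seq(0, by = dt, length.out = n_steps + 1),
                 Vm_mV = vm, dt_ms = dt),
            class = "voltage_trace")
}

#' Prototype taste receptor cells
#'
#' Convenience constructors for narrowly tuned cells, one per modality, with
#' the package's default detector parameters: physiological Na+ gradient
#' (145/12 mM), a proton gradient corresponding to a moderately acidic
#' stimulus against intracellular pH 7.4, and Hill receptors whose
#' half-activation sits at the mid concentration of the corresponding
#' stimulus axis.
#'
#' @param g detector conductance, nS.
#' @return A [taste_cell_config()].
#' @export
salty_cell <- function(g = 3) {
  taste_cell_config(channels = list(
    ion_channel_spec("Na", z = 1, conc_out = 145, conc_in = 12, g = g)),
    label = "salty")
}

#' @rdname salty_cell
#' @export
sour_cell <- function(g = 3) {
  taste_cell_config(channels = list(
    ion_channel_spec("H", z = 1, conc_out = 0.1, conc_in = 10^-7.4 * 1000,
                     g = g)),
    label = "sour")
}

#' @rdname salty_cell
#' @export
sweet_cell <- function(g = 3) {
  taste_cell_config(receptors = list(
    metabotropic_receptor_spec("sweet_T1R2_T1R3", Ka = 15000, g_meta = g)),
    label = "sweet")
}

#' @rdname salty_cell
#' @export
bitter_cell <- function(g = 3) {
  taste_cell_config(receptors = list(
    metabotropic_receptor_spec("bitter_T2R", Ka = 1, g_meta = g)),
    label = "bitter")
}
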