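#' Glutamatergic synapse parameters
#'
#' Kinetic and conductance constants of the AMPA synapse model.  Defaults
#' are the calibrated model constants: glutamate emission time constant
#' tau = 2.5 ms, release amplitude A = 1.2 mM, unitary AMPA conductance
#' 10 pS, Michaelis constants 0.3 mM (phosphorylated) and 1.5 mM
#' (unphosphorylated), AMPA reversal 0 mV.
#'
#' @param tau glutamate emission time constant, ms.
#' @param A glutamate release amplitude per spike, mM.
#' @param g_AMPA unitary AMPA receptor conductance, pS.
#' @param K_phos,K_unphos Michaelis constants of the phosphorylated and
#'   unphosphorylated receptor states, mM (`K_phos <= K_unphos`).
#' @param E_AMPA AMPA reversal potential, mV.
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(tau = 2.5, A = 1.2, g_AMPA = 10,
                           K_phos = 0.3, K_unphos = 1.5, E_AMPA = 0) {
  stopifnot(tau > 0, A >= 0, g_AMPA >= 0, K_phos > 0, K_phos <= K_unphos)
  structure(list(tau = tau, A = A, g_AMPA = g_AMPA, K_phos = K_phos,
                 K_unphos = K_unphos, E_AMPA = E_AMPA),
            class = "synapse_params")
}

#' Synapse state
#'
#' Per-synapse plastic state: the number of AMPA receptors at the
#' postsynaptic density, the fraction of them in the phosphorylated
#' (high-affinity) state, and the presynaptic spike times driving release.
#'
#' @param n_total nonnegative receptor count.
#' @param phos phosphorylation fraction in \[0, 1\].
#' @param spike_times nondecreasing presynaptic spike times, ms.
#' @return An object of class `synapse_state`.
#' @export
synapse_state <- function(n_total, phos = 0.5, spike_times = numeric(0)) {
  stopifnot(n_total >= 0, phos >= 0, phos <= 1)
  if (is.unsorted(spike_times)) stop("spike times must be nondecreasing")
  structure(list(n_total = n_total, phos = phos,
                 spike_times = spike_times), class = "synapse_state")
}

#' Rectified alpha kernel
#'
#' Transient neurotransmitter time course after a spike:
#' `(t/tau) * exp(1 - t/tau)` for `t >= 0`, zero before the spike.  Peaks at
#' exactly 1 when `t = tau`.
#'
#' @param t time since the spike, ms (vectorized).
#' @param tau kernel time constant, ms.
#' @return Dimensionless kernel value(s).
#' @export
alpha_kernel <- function(t, tau) {
  stopifnot(tau > 0)
  ifelse(t >= 0, (t / tau) * exp(1 - t / tau), 0)
}

#' Glutamate concentration in the synaptic cleft
#'
#' Superposition of amplitude-scaled alpha kernels over the presynaptic
#' spike times: `G(t) = A * sum_j alpha(t - t_j)`.  Kernels are truncated
#' `10 * tau` past each spike (below 0.1% of peak amplitude), which bounds
#' the per-step cost of long trains.
#'
#' @param t evaluation time(s), ms.
#' @param state a [synapse_state()] carrying the presynaptic spike times.
#' @param p synapse parameters.
#' @return Glutamate concentration, mM (same length as `t`).
#' @export
cleft_glutamate <- function(t, state, p = synapse_params()) {
  ts <- state$spike_times
  if (length(ts) == 0) return(rep(0, length(t)))
  d <- outer(t, ts, "-")
  k <- alpha_kernel(d, p$tau) * (d <= 10 * p$tau)
  as.numeric(p$A * rowSums(k))
}

#' Phosphorylation-dependent AMPA conductance
#'
#' Total synaptic conductance over a set of converging synapses.  Each
#' synapse contributes its receptor count split between a high-affinity
#' phosphorylated pool and a low-affinity unphosphorylated pool, each
#' saturating in the local glutamate concentration:
#' `sum_i g_AMPA * N_i * (Phos_i * G_i/(G_i + K_phos) +
#' (1 - Phos_i) * G_i/(G_i + K_unphos))`.
#' Bounded above by `g_AMPA * sum(N_i)`.
#'
#' @param G_per_synapse glutamate concentration at each synapse, mM.
#' @param states list of [synapse_state()] objects, one per synapse.
#' @param p synapse parameters (`g_AMPA` in pS).
#' @return Conductance, nS.
#' @examples
#' s <- synapse_state(n_total = 100, phos = 1)
#' ampa_conductance(0.3, list(s), synapse_params())  # 0.5 nS (500 pS)
#' @export
ampa_conductance <- function(G_per_synapse, states, p = synapse_params()) {
  if (length(G_per_synapse) != length(states))
    stop("one glutamate concentration per synapse is required")
  g <- 0
  for (i in seq_along(states)) {
    st <- states[[i]]
    G <- G_per_synapse[i]
    if (G < 0) stop("glutamate concentration must be nonnegative")
    g <- g + (p$g_AMPA / 1000) * st$n_total *
      (st$phos * G / (G + p$K_phos) +
         (1 - st$phos) * G / (G + p$K_unphos))
  }
  g
}

#' Synaptic current
#'
#' AMPA-mediated current under the package's depolarizing-positive sign
#' convention: `g_syn * (E_AMPA - V)`.
#'
#' @param g_syn synaptic conductance, nS.
#' @param V postsynaptic membrane potential, mV.
#' @param p synapse parameters.
#' @return Current, pA.
#' @export
synaptic_current <- function(g_syn, V, p = synapse_params()) {
  stopifnot(all(g_syn >= 0))
  g_syn * (p$E_AMPA - V)
}
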