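#' Izhikevich neuron parameters
#'
#' Two-variable reduced spiking model, `dv/dt = 0.04 v^2 + 5v + 140 - u + I`,
#' `du/dt = a (b v - u)`, with after-spike reset `v <- c`, `u <- u + d` when
#' `v >= 30` mV.  Defaults are the published regular-spiking constants.
#' `input_gain` scales synaptic current (pA) into the model's dimensionless
#' current term; the default is calibrated so that a single saturated
#' 500 pS synapse at rest drives sustained firing.
#'
#' @param a,b,c,d reduced-model parameters.
#' @param input_gain current scaling, 1/pA.
#' @return An object of class `izhikevich_params`.
#' @export
izhikevich_params <- function(a = 0.02, b = 0.2, c = -65, d = 8,
                              input_gain = 0.25) {
  stopifnot(is.finite(c(a, b, c, d, input_gain)))
  structure(list(a = a, b = b, c = c, d = d, input_gain = input_gain),
            class = "izhikevich_params")
}

#' Initial Izhikevich state
#'
#' Rest at `v = -65` mV with the recovery variable at its nullcline value
#' `u = b * v`.
#'
#' @param p Izhikevich parameters.
#' @param v initial membrane potential, mV.
#' @return list with components `v` and `u`.
#' @export
izhikevich_state <- function(p = izhikevich_params(), v = -65) {
  list(v = v, u = p$b * v)
}

#' One forward-Euler Izhikevich step
#'
#' Advances `(v, u)` by `dt` under current drive `I` (model units, i.e.
#' already scaled by `input_gain`) using the same update order as the
#' compiled network kernel: both derivatives are evaluated at the old state,
#' then the spike/reset check is applied.
#'
#' @param state list with `v`, `u`.
#' @param I input current in model units.
#' @param dt step, ms.
#' @param p Izhikevich parameters.
#' @return list with `v`, `u` and logical `spiked`.
#' @export
step_izhikevich <- function(state, I, dt, p = izhikevich_params()) {
  stopifnot(dt > 0)
  v <- state$v; u <- state$u
  vn <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
  un <- u + dt * p$a * (p$b * v - u)
  if (!is.finite(vn) || !is.finite(un))
    stop("Izhikevich state became non-finite")
  spiked <- vn >= 30
  if (spiked) {
    vn <- p$c
    un <- un + p$d
  }
  list(v = vn, u = un, spiked = spiked)
}
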