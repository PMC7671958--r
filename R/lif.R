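#' Parameters for the leaky integrate-and-fire reduction
#'
#' A single leaky integrate-and-fire unit with an inhibitory autapse and two
#' pulse inputs reproduces the slow cell's gating behavior, demonstrating
#' that only four properties matter: firing only immediately after a fast
#' (input-1) pulse, never on consecutive pulses, not firing while inhibited
#' by the slow (input-2) stream, and firing on every pulse not excluded by
#' the previous two rules. The defaults are constructed so that (i) a
#' single input-1 kick from rest crosses threshold, (ii) autapse inhibition
#' blocks firing for between one and two input-1 periods at 40 Hz, and
#' (iii) input-2 inhibition blocks firing for roughly 27 ms after each slow
#' pulse.
#'
#' @param tau_m Membrane time constant in ms.
#' @param V_rest Resting potential in mV.
#' @param V_thresh Spike threshold in mV (must exceed `V_reset`).
#' @param V_reset Post-spike reset potential in mV.
#' @param E_inh Inhibitory reversal potential in mV.
#' @param kick Instantaneous input-1 depolarization in mV.
#' @param g_in2,tau_in2 Conductance increment per input-2 pulse (units of
#'   1/ms, relative to unit capacitance) and its decay time (ms).
#' @param g_aut,tau_aut Autapse conductance increment per own spike and its
#'   decay time (ms).
#' @return An object of class `lif_params`.
#' @export
lifParams <- function(tau_m = 6, V_rest = -65, V_thresh = -50,
                      V_reset = -70, E_inh = -85, kick = 16.5,
                      g_in2 = 4, tau_in2 = 3, g_aut = 1.2,
                      tau_aut = 7) {
  stopifnot(V_thresh > V_reset, tau_m > 0, tau_in2 > 0, tau_aut > 0)
  structure(list(tau_m = tau_m, V_rest = V_rest, V_thresh = V_thresh,
                 V_reset = V_reset, E_inh = E_inh, kick = kick,
                 g_in2 = g_in2, tau_in2 = tau_in2, g_aut = g_aut,
                 tau_aut = tau_aut),
            class = "lif_params")
}

#' Simulate the integrate-and-fire reduction
#'
#' Between events the membrane potential relaxes under the leak and the
#' decaying inhibitory conductances (input-2-triggered and autaptic, both
#' with reversal `E_inh`). Each input-1 pulse adds an instantaneous
#' depolarizing kick; a threshold crossing at a kick fires a spike, resets
#' the potential and increments the autapse conductance. Input-2 pulses
#' increment the input-2 conductance. Since the kicks are the only
#' depolarizing events, spikes can occur only at input-1 pulse times; the
#' inter-event dynamics are integrated with an exponential rule (the linear
#' membrane equation is solved exactly over each substep with the
#' conductances frozen at their substep-midpoint values).
#'
#' @param params A [lifParams()] object.
#' @param input1 `pulse_train` (or numeric times) of the fast excitatory
#'   input.
#' @param input2 `pulse_train` (or numeric times) of the slow inhibitory
#'   input.
#' @param duration Simulation length in ms.
#' @param dt Substep for the inter-event integration in ms (default 0.1).
#' @return List with `spikes` (spike times, ms), `V_at_pulse` (the membrane
#'   potential immediately before each input-1 kick), and the inputs and
#'   parameters used.
#' @export
simulateLIF <- function(params, input1, input2, duration, dt = 0.1) {
  stopifnot(inherits(params, "lif_params"))
  s1 <- if (inherits(input1, "pulse_train")) input1$times else input1
  s2 <- if (inherits(input2, "pulse_train")) input2$times else input2
  s1 <- s1[s1 <= duration]; s2 <- s2[s2 <= duration]

  ev_t <- c(s1, s2)
  ev_k <- c(rep(1L, length(s1)), rep(2L, length(s2)))
  o <- order(ev_t)
  ev_t <- ev_t[o]; ev_k <- ev_k[o]

  inv_tau <- 1 / params$tau_m
  V <- params$V_rest; g2 <- 0; ga <- 0; t <- 0
  spikes <- numeric(length(s1)); ns <- 0L
  vpul <- numeric(length(s1)); np <- 0L
  for (i in seq_along(ev_t)) {
    te <- ev_t[i]
    if (te > t) {
      nst <- max(1L, ceiling((te - t) / dt))
      h <- (te - t) / nst
      d2 <- exp(-h / params$tau_in2); da <- exp(-h / params$tau_aut)
      m2 <- exp(-0.5 * h / params$tau_in2); ma <- exp(-0.5 * h / params$tau_aut)
      for (k in seq_len(nst)) {
        gmid <- g2 * m2 + ga * ma
        a <- inv_tau + gmid
        veq <- (params$V_rest * inv_tau + gmid * params$E_inh) / a
        V <- veq + (V - veq) * exp(-a * h)
        g2 <- g2 * d2; ga <- ga * da
      }
      t <- te
    }
    if (ev_k[i] == 2L) {
      g2 <- g2 + params$g_in2
    } else {
      np <- np + 1L; vpul[np] <- V
      V <- V + params$kick
      if (V >= params$V_thresh) {
        ns <- ns + 1L; spikes[ns] <- te
        V <- params$V_reset
        ga <- ga + params$g_aut
      }
    }
  }
  list(spikes = spikes[seq_len(ns)], V_at_pulse = vpul[seq_len(np)],
       input1 = input1, input2 = input2, params = params)
}
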