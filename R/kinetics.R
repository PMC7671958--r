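# Voltage-dependent gating kinetics. Every gating variable x follows
# dx/dt = (x_inf(V) - x) / tau_x(V); the sodium activation gate is treated
# as instantaneous (m0(V)). Functional forms are the standard published ones
# for these currents (transient Na, delayed-rectifier K, anomalous-rectifier
# h, M-type K, high-threshold Ca); per-compartment half-activation voltages,
# slopes and time-constant scales live in the compartment parameter table.

.sigm <- function(x) 1 / (1 + exp(-x))

#' Gating functions of a compartment
#'
#' Returns the steady-state and time-constant functions for every gating
#' variable of a compartment, plus the instantaneous sodium activation
#' `m0(V)`. These are the exact forms integrated by the compiled simulator.
#'
#' @param p Named numeric vector: one row of a network's compartment
#'   parameter table (see [buildNetwork()]).
#' @return List with elements `m0` (function of V) and, per gating variable
#'   (`hNa`, `mK`, `mAR`, `mKM`, `mCaH`), a list of functions `inf(V)` and
#'   `tau(V)` (ms).
#' @export
gatingFunctions <- function(p) {
  p <- drop(p)
  list(
    m0 = function(V) .sigm((V - p["naf_m_v12"]) / p["naf_m_k"]),
    hNa = list(
      inf = function(V) .sigm(-(V - p["naf_h_v12"]) / p["naf_h_k"]),
      tau = function(V) p["naf_h_t0"] +
        p["naf_h_t1"] * .sigm(-(V - p["naf_h_tv"]) / p["naf_h_tk"])
    ),
    mK = list(
      inf = function(V) .sigm((V - p["kdr_v12"]) / p["kdr_k"]),
      tau = function(V) p["kdr_t0"] +
        p["kdr_t1"] * exp(-abs(V - p["kdr_tv"]) / 10)
    ),
    mAR = list(
      inf = function(V) .sigm(-(V - p["ar_v12"]) / p["ar_k"]),
      tau = function(V) p["ar_tsc"] /
        (exp(-14.59 - 0.086 * V) + exp(-1.87 + 0.0701 * V))
    ),
    mKM = list(
      inf = function(V) {
        a <- p["km_sc"] * 0.02 / (1 + exp((-20 - V) / 5))
        b <- p["km_sc"] * 0.01 * exp((-43 - V) / 18)
        a / (a + b)
      },
      tau = function(V) {
        a <- p["km_sc"] * 0.02 / (1 + exp((-20 - V) / 5))
        b <- p["km_sc"] * 0.01 * exp((-43 - V) / 18)
        1 / (a + b)
      }
    ),
    mCaH = list(
      inf = function(V) .sigm((V - p["cah_v12"]) / p["cah_k"]),
      tau = function(V) rep(p["cah_tau"], length(V))
    )
  )
}

#' First-order gating derivative
#'
#' @param x Current gating value in `[0, 1]`.
#' @param V Membrane potential in mV.
#' @param kin Result of [gatingFunctions()].
#' @param which One of `"hNa"`, `"mK"`, `"mAR"`, `"mKM"`, `"mCaH"`.
#' @return `(x_inf(V) - x) / tau_x(V)` in 1/ms.
#' @export
gatingDerivative <- function(x, V, kin, which) {
  if (any(x < 0 | x > 1)) stop("gating value outside [0, 1]")
  g <- kin[[which]]
  unname((g$inf(V) - x) / g$tau(V))
}

#' Synaptic state derivative
#'
#' `ds/dt = -s/tau_d + ((1 - s)/tau_r) * (1 + tanh(V_pre / 10))`: the state
#' decays with `tau_d` and is driven toward 1 while the presynaptic
#' potential is depolarized.
#'
#' @param s Synaptic state in `[0, 1]`.
#' @param V_pre Presynaptic membrane potential in mV.
#' @param tau_d,tau_r Decay and rise time constants in ms.
#' @return Derivative in 1/ms.
#' @export
synapseDerivative <- function(s, V_pre, tau_d, tau_r) {
  if (any(s < 0 | s > 1)) stop("synaptic state outside [0, 1]")
  -s / tau_d + (1 - s) / tau_r * (1 + tanh(V_pre / 10))
}

#' Electrical (gap-junction) coupling current
#'
#' @param V,V_other Membrane potentials of the two coupled compartments (mV).
#' @param g Coupling conductance.
#' @return `g * (V - V_other)`; the current on the other compartment is its
#'   negative.
#' @export
electricalCurrent <- function(V, V_other, g) g * (V - V_other)

#' Membrane-potential derivative of one compartment
#'
#' Reference (plain-R) implementation of the compartment current balance:
#' `C dV/dt = -J - I_syn - I_el - I_ext - I_L - I_Na - I_K - I_AR - I_KM -
#' I_CaH`, with `I_Na = g_Na m0(V)^3 h (V - V_Na)`, `I_K = g_K m^4 (V -
#' V_K)`, `I_CaH = g_CaH m_CaH^2 (V - V_CaH)` and the remaining ionic terms
#' linear in their gating variable. Matches the compiled integrator's
#' right-hand side to machine precision.
#'
#' @param state Named numeric vector with `V` and the gating values `mK`,
#'   `hNa`, `mAR`, `mKM`, `mCaH`.
#' @param p Named compartment parameter row (see [buildNetwork()]).
#' @param I_syn,I_el,I_ext Synaptic, electrical-coupling and external
#'   currents at the same instant (default 0).
#' @return `dV/dt` in mV/ms.
#' @export
membraneDerivative <- function(state, p, I_syn = 0, I_el = 0, I_ext = 0) {
  p <- drop(p)
  gv <- state[c("mK", "hNa", "mAR", "mKM", "mCaH")]
  if (any(gv < 0 | gv > 1)) stop("gating value outside [0, 1]")
  V <- state[["V"]]
  kin <- gatingFunctions(p)
  I <- p[["J"]] + I_syn + I_el + I_ext +
    p[["gL"]] * (V - p[["VL"]]) +
    p[["gNa"]] * kin$m0(V)^3 * state[["hNa"]] * (V - p[["VNa"]]) +
    p[["gK"]] * state[["mK"]]^4 * (V - p[["VK"]]) +
    p[["gAR"]] * state[["mAR"]] * (V - p[["VAR"]]) +
    p[["gKM"]] * state[["mKM"]] * (V - p[["VKM"]]) +
    p[["gCaH"]] * state[["mCaH"]]^2 * (V - p[["VCaH"]])
  unname(-I / p[["C"]])
}

#' Classify slow state variables of a network
#'
#' A gating variable is "slow" when its time constant exceeds `tau_min` ms
#' throughout the subthreshold voltage range; synaptic states are slow when
#' their decay constant does. These are the variables whose post-burst reset
#' the diagnostics in [resetAlignment()] examine. The default range ends at
#' -50 mV, the inter-event envelope of this parameter set's compartments
#' (the dendritic h-current gates collapse quickly above it, which is
#' exactly the reset property under study).
#'
#' @param spec A `network_spec` from [buildNetwork()].
#' @param V_range Subthreshold voltage range in mV (default `c(-75, -50)`).
#' @param tau_min Slowness threshold in ms (default 10).
#' @return Character vector of slow state-variable names (trace column
#'   names).
#' @export
slowVariables <- function(spec, V_range = c(-75, -50), tau_min = 10) {
  Vs <- seq(V_range[1], V_range[2], by = 0.5)
  out <- character(0)
  for (i in seq_len(nrow(spec$comp))) {
    p <- spec$comp[i, ]
    kin <- gatingFunctions(p)
    for (gvar in c("hNa", "mK", "mAR", "mKM", "mCaH")) {
      gcol <- c(hNa = "gNa", mK = "gK", mAR = "gAR", mKM = "gKM",
                mCaH = "gCaH")[[gvar]]
      if (p[[gcol]] > 0 && all(kin[[gvar]]$tau(Vs) > tau_min))
        out <- c(out, paste0(rownames(spec$comp)[i], ".", gvar))
    }
  }
  slow_syn <- spec$syn$tau_d > tau_min
  c(out, paste0(rownames(spec$syn)[slow_syn], ".s"))
}
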