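# Shipped parameter set, version-tagged. Kinetic functional forms are the
# standard published ones for these currents; conductances, couplings and
# drive strengths are the package's own calibration, chosen so that the
# network expresses the documented regime: a self-sustained beta1 rhythm in
# the four-cell network, pulse-gated SI firing with refractory multiplicity
# m = 2 under a 40 Hz drive, IB interburst intervals in the high-50s to
# low-60s of ms, and 2-4 spikes per IB burst. See the methods vignette for
# the calibration rationale.

.pg_kin_default <- c(
  naf_m_v12 = -38, naf_m_k = 10,
  naf_h_v12 = -58.3, naf_h_k = 6.7,
  naf_h_t0 = 0.225, naf_h_t1 = 1.125, naf_h_tv = -37, naf_h_tk = 15,
  kdr_v12 = -27, kdr_k = 11.5, kdr_t0 = 0.25, kdr_t1 = 4.35, kdr_tv = -10,
  ar_v12 = -87.5, ar_k = 5.5, ar_tsc = 1,
  km_sc = 1,
  cah_v12 = -24.6, cah_k = 11.3, cah_tau = 3
)

.pg_par_cols <- c(
  "C", "J", "gL", "VL", "gNa", "VNa", "gK", "VK", "gAR", "VAR",
  "gKM", "VKM", "gCaH", "VCaH", names(.pg_kin_default)
)

# assemble one compartment parameter row
.pg_comp <- function(C = 1, J = 0, gL = 1, VL = -70, gNa = 0, VNa = 50,
                     gK = 0, VK = -100, gAR = 0, VAR = -35, gKM = 0,
                     VKM = -95, gCaH = 0, VCaH = 125, ...) {
  kin <- .pg_kin_default
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(kin))
    if (length(bad)) stop("unknown kinetics parameter(s): ",
                          paste(bad, collapse = ", "))
    kin[names(dots)] <- dots
  }
  c(C = C, J = J, gL = gL, VL = VL, gNa = gNa, VNa = VNa, gK = gK, VK = VK,
    gAR = gAR, VAR = VAR, gKM = gKM, VKM = VKM, gCaH = gCaH, VCaH = VCaH,
    kin)
}

#' Shipped network parameter set
#'
#' Returns the versioned parameter set used by [buildNetwork()]:
#' per-compartment membrane constants and kinetics, chemical-synapse
#' constants, electrical couplings and drive-synapse strengths. Callers may
#' modify the returned list before passing it to [buildNetwork()].
#'
#' @return Nested list with elements `version`, `cells`, `syn`, `gap`.
#' @export
pgParams <- function() {
  cells <- list(
    RS = .pg_comp(J = -13, gL = 2, VL = -70, gNa = 100, gK = 20,
                  gAR = 3, VAR = -35, ar_v12 = -75, ar_tsc = 0.07),
    FS = .pg_comp(J = 0, gL = 1, VL = -67, gNa = 100, gK = 20),
    # non-spontaneous relay used as the multiplexing output cell
    RSout = .pg_comp(J = 8, gL = 2, VL = -70, gNa = 100, gK = 20,
                     gAR = 3, VAR = -35, ar_v12 = -75, ar_tsc = 0.07),
    SI = .pg_comp(J = 8, gL = 2, VL = -70, gNa = 100, gK = 20,
                  gAR = 3, VAR = -35, ar_v12 = -75, ar_tsc = 0.07),
    IBs = .pg_comp(J = 0, gL = 1, VL = -70, gNa = 100, gK = 15),
    IBa = .pg_comp(J = -7.5, gL = 1, VL = -70, gNa = 100, gK = 20,
                   gKM = 12.5, km_sc = 0.8),
    IBda = .pg_comp(J = 0, gL = 0.15, VL = -70, gNa = 0, gK = 5,
                    gAR = 2, VAR = -35, ar_v12 = -87.5, ar_tsc = 0.05,
                    gKM = 3, km_sc = 1, gCaH = 0.45, cah_tau = 5),
    IBdb = .pg_comp(J = 0, gL = 0.15, VL = -70, gNa = 0, gK = 5,
                    gAR = 2, VAR = -35, ar_v12 = -87.5, ar_tsc = 0.05,
                    gKM = 3, km_sc = 1, gCaH = 0.45, cah_tau = 5)
  )
  syn <- list(
    # excitatory pyramidal-type outputs
    RS_FS  = list(g = 0.15,  V0 = 0,   tau_d = 2,   tau_r = 0.25),
    RS_SI  = list(g = 0.4,  V0 = 0,   tau_d = 2,   tau_r = 0.25),
    # fast-spiking inhibition
    FS_RS  = list(g = 1.2,  V0 = -80, tau_d = 8,   tau_r = 0.5),
    FS_SI  = list(g = 0.8,  V0 = -80, tau_d = 8,   tau_r = 0.5),
    FS_FS  = list(g = 0.2,  V0 = -80, tau_d = 8,   tau_r = 0.5),
    # slow inhibition onto the bursting cell (perisomatic/axonal)
    SI_IB  = list(g = 0.03, V0 = -80, tau_d = 20,  tau_r = 1),
    # bursting-cell outputs; the SI-bound synapse rises more slowly
    IB_FS  = list(g = 0.3,  V0 = 0,   tau_d = 2,   tau_r = 0.25),
    IB_SI  = list(g = 0.3,  V0 = 0,   tau_d = 2,   tau_r = 2.5),
    # intra-cell axon-to-basal-dendrite synapse
    IB_a_db = list(g = 0.4, V0 = 0,   tau_d = 100, tau_r = 0.25),
    # multiplexing demo output (made excitatory)
    SI_RS  = list(g = 0.6,  V0 = 0,   tau_d = 2,   tau_r = 0.25),
    # drive attachments; input-1 inherits the RS-output kinetics,
    # input-2 the IB-output kinetics, inhibitory input-2 the FS-output ones
    IN_RS  = list(g = 0.7,  V0 = 0,   tau_d = 2,   tau_r = 0.25),
    IN1_FS = list(g = 0.15,  V0 = 0,   tau_d = 2,   tau_r = 0.25),
    IN1_SI = list(g = 0.44,  V0 = 0,   tau_d = 2,   tau_r = 0.25),
    IN2_FS = list(g = 0.2,  V0 = 0,   tau_d = 2,   tau_r = 0.25),
    IN2_SI = list(g = 0.3,  V0 = 0,   tau_d = 2,   tau_r = 2.5),
    IN2i_SI = list(g = 2.0, V0 = -80, tau_d = 8,   tau_r = 0.5)
  )
  gap <- list(IBs_IBa = 0.3, IBs_IBda = 0.3, IBs_IBdb = 0.3)
  list(version = "1.0", cells = cells, syn = syn, gap = gap)
}
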