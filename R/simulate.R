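#' Simulate a network with pulsatile drives
#'
#' Integrates all membrane, gating, synaptic and external-potential state
#' variables jointly with a fixed-step 4th-order Runge-Kutta scheme.
#' Integration is segmented at drive pulse times so that the external
#' potential reset (to 25 mV) is applied exactly; between pulses the
#' external potential relaxes toward -70 mV with unit time constant. The
#' result is reproducible bit-for-bit given the same spec, drives, `dt` and
#' initial state.
#'
#' @param spec A `network_spec` from [buildNetwork()].
#' @param drives Named list of drives matching `spec$drives`: each a
#'   `pulse_train`, a numeric vector of pulse times (ms), or `NULL` for a
#'   silent drive.
#' @param duration Simulation length in ms.
#' @param dt Integration step in ms (default 0.02; must be `<= 0.05`).
#' @param init Optional full initial state vector (as produced by
#'   [initialState()]); defaults to the rest-like state: all potentials at
#'   -70 mV, gating variables at their -70 mV equilibria, synapses at 0.
#' @param store_dt Trace storage interval in ms (default 0.05). Spike
#'   detection runs at full integrator resolution regardless.
#' @param spike_threshold Spike detection threshold in mV (default 0).
#' @param spike_min_sep Minimum spike separation in ms (default 2).
#' @return An object of class `sim_result`: list with `time` (stored grid,
#'   ms), `traces` (matrix, one named column per state variable:
#'   `<comp>.V`, `<comp>.<gate>`, `<src>><tgt>.s`, `<drive>.Vext`),
#'   `spikes` (named list of spike-time vectors per compartment), `drives`
#'   (the pulse trains used) and `meta` (dt, store_dt, duration, parameter
#'   set version).
#' @export
simulateNetwork <- function(spec, drives = list(), duration, dt = 0.02,
                            init = NULL, store_dt = 0.05,
                            spike_threshold = 0, spike_min_sep = 2) {
  stopifnot(inherits(spec, "network_spec"))
  if (dt > 0.05 + 1e-12)
    stop("`dt` must be at most 0.05 ms for reliable spike timing")
  store_every <- max(1L, as.integer(round(store_dt / dt)))

  drv_times <- lapply(spec$drives, function(nm) {
    d <- drives[[nm]]
    if (is.null(d)) numeric(0)
    else if (inherits(d, "pulse_train")) d$times
    else as.numeric(d)
  })
  names(drv_times) <- spec$drives

  comp <- spec$comp
  syn_mat <- .syn_matrix(spec)
  gap_mat <- .gap_matrix(spec)
  if (is.null(init)) init <- initialState(spec)

  res <- .hh_simulate(comp, syn_mat, gap_mat, unname(drv_times), init,
                      duration, dt, store_every, spike_threshold,
                      spike_min_sep)
  if (res$fail_time >= 0)
    stop(sprintf("integration fault: |V| exceeded 200 mV at t = %.3f ms",
                 res$fail_time))

  traces <- res$traces
  colnames(traces) <- .state_names(spec)
  keep <- .active_columns(spec)
  spikes <- res$spikes
  names(spikes) <- rownames(comp)
  structure(list(time = res$time, traces = traces[, keep, drop = FALSE],
                 spikes = spikes, drives = drives,
                 meta = list(config = spec$config, dt = dt,
                             store_dt = store_dt, duration = duration,
                             params_version = spec$params_version)),
            class = "sim_result")
}

# synapse table in the integer-coded layout the compiled core expects
.syn_matrix <- function(spec) {
  comp_idx <- function(nm) match(nm, rownames(spec$comp)) - 1L
  drv_idx <- function(nm) match(nm, spec$drives) - 1L
  s <- spec$syn
  cbind(kind = as.numeric(s$is_drive),
        src = ifelse(s$is_drive, drv_idx(s$src), comp_idx(s$src)),
        tgt = comp_idx(s$tgt),
        g = s$g, V0 = s$V0, tau_d = s$tau_d, tau_r = s$tau_r)
}

.gap_matrix <- function(spec) {
  comp_idx <- function(nm) match(nm, rownames(spec$comp)) - 1L
  if (nrow(spec$gap) == 0)
    return(matrix(numeric(0), ncol = 3))
  cbind(i = comp_idx(spec$gap$i), j = comp_idx(spec$gap$j), g = spec$gap$g)
}

.gate_names <- c("mK", "hNa", "mAR", "mKM", "mCaH")

.state_names <- function(spec) {
  cn <- rownames(spec$comp)
  comp_cols <- unlist(lapply(cn, function(nm)
    paste0(nm, ".", c("V", .gate_names))))
  c(comp_cols, paste0(rownames(spec$syn), ".s"),
    paste0(spec$drives, ".Vext"))
}

# columns of the full state that correspond to present currents
.active_columns <- function(spec) {
  gcond <- c(mK = "gK", hNa = "gNa", mAR = "gAR", mKM = "gKM",
             mCaH = "gCaH")
  keep <- unlist(lapply(rownames(spec$comp), function(nm) {
    p <- spec$comp[nm, ]
    act <- names(gcond)[p[gcond] > 0]
    c(paste0(nm, ".V"),
      if (length(act)) paste0(nm, ".", act))
  }))
  c(keep, paste0(rownames(spec$syn), ".s"), paste0(spec$drives, ".Vext"))
}

#' Rest-like initial state for a network
#'
#' All membrane and external potentials start at -70 mV, gating variables at
#' their -70 mV equilibria, and synaptic states at 0.
#'
#' @param spec A `network_spec`.
#' @param V0 Starting potential in mV (default -70).
#' @return Named numeric state vector in integrator layout.
#' @export
initialState <- function(spec, V0 = -70) {
  comp_state <- unlist(lapply(rownames(spec$comp), function(nm) {
    kin <- gatingFunctions(spec$comp[nm, ])
    c(V0, kin$mK$inf(V0), kin$hNa$inf(V0), kin$mAR$inf(V0),
      kin$mKM$inf(V0), kin$mCaH$inf(V0))
  }))
  out <- c(comp_state, rep(0, nrow(spec$syn)), rep(-70, length(spec$drives)))
  names(out) <- .state_names(spec)
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: '%s', %.0f ms at dt = %g ms\n", x$meta$config,
              x$meta$duration, x$meta$dt))
  for (nm in names(x$spikes))
    cat(sprintf("  %-5s %4d spikes\n", nm, length(x$spikes[[nm]])))
  invisible(x)
}

#' Extract a stored trace column
#'
#' @param sim A `sim_result`.
#' @param name Trace column name, e.g. `"SI.V"`.
#' @return Numeric vector over the stored time grid.
#' @export
getTrace <- function(sim, name) {
  if (!name %in% colnames(sim$traces))
    stop("no trace '", name, "'; available: ",
         paste(colnames(sim$traces), collapse = ", "))
  sim$traces[, name]
}

#' Write spike times as two-column delimited text
#'
#' Columns are `compartment` and `time_ms`.
#'
#' @param sim A `sim_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeSpikes <- function(sim, path) {
  df <- do.call(rbind, lapply(names(sim$spikes), function(nm) {
    if (length(sim$spikes[[nm]]) == 0) return(NULL)
    data.frame(compartment = nm, time_ms = sim$spikes[[nm]])
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
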