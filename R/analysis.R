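#' Detect spikes as upward threshold crossings
#'
#' @param time Time grid in ms (regular spacing assumed).
#' @param v Membrane-potential trace in mV, same length as `time`.
#' @param threshold Crossing threshold in mV (default 0).
#' @param min_separation Minimum time between detected spikes in ms
#'   (default 2); crossings closer than this to the previous accepted spike
#'   are discarded.
#' @return Numeric vector of spike times in ms (class `spike_train` is not
#'   used; plain event-time vectors flow through the analysis layer).
#' @export
detectSpikes <- function(time, v, threshold = 0, min_separation = 2) {
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (length(up) == 0) return(numeric(0))
  st <- time[up]
  # enforce separation sequentially (a diff-based filter can readmit chains)
  out <- numeric(length(st)); n <- 0L; last <- -Inf
  for (t in st) {
    if (t - last >= min_separation) {
      n <- n + 1L; out[n] <- t; last <- t
    }
  }
  out[seq_len(n)]
}

#' Group a spike train into bursts
#'
#' Consecutive spikes separated by at most `intra_gap` ms belong to the same
#' burst. The burst onset is the time of its first spike.
#'
#' @param spikes Strictly increasing spike times in ms.
#' @param intra_gap Maximum within-burst interspike interval in ms
#'   (default 15).
#' @return An object of class `burst_train`: list with `onset` (ms) and
#'   `count` (spikes per burst).
#' @export
groupBursts <- function(spikes, intra_gap = 15) {
  if (length(spikes) == 0)
    return(structure(list(onset = numeric(0), count = integer(0)),
                     class = "burst_train"))
  new_burst <- c(TRUE, diff(spikes) > intra_gap)
  id <- cumsum(new_burst)
  structure(list(onset = spikes[new_burst],
                 count = as.integer(tabulate(id))),
            class = "burst_train")
}

#' @export
print.burst_train <- function(x, ...) {
  cat(sprintf("burst_train: %d bursts, spikes/burst %s\n", length(x$onset),
              paste(range(x$count), collapse = "-")))
  invisible(x)
}

#' Mean event rate over a window
#'
#' @param events Event times in ms.
#' @param window Length-2 interval `[start, end]` in ms; defaults to the
#'   event span. The window should exclude the transient.
#' @return Rate in Hz (`count / duration`).
#' @export
firingRate <- function(events, window = range(events)) {
  if (diff(window) <= 0) stop("empty window")
  n <- sum(events >= window[1] & events < window[2])
  1000 * n / diff(window)
}

#' Drop events before a transient cutoff
#'
#' The default analysis policy discards the first
#' `max(floor_ms, K * mean input-2 period)` of every run, with `K` from
#' [transientBoundK()] when the entrainment conditions make it well defined
#' and `K = 3` otherwise.
#'
#' @param events Event times in ms.
#' @param cutoff Cutoff time in ms; events strictly before it are dropped.
#' @return The trimmed event vector.
#' @seealso [transientCutoff()]
#' @export
excludeTransient <- function(events, cutoff) {
  out <- events[events >= cutoff]
  if (length(events) > 0 && length(out) == 0)
    warning("all events fell inside the transient window")
  out
}

#' Default transient cutoff for a run
#'
#' @param T2 Mean input-2 (slow-drive) period in ms; may be `NULL` when no
#'   slow drive exists.
#' @param K Transient bound in input-2 periods (default 3, used when the
#'   analytic bound is unavailable).
#' @param floor_ms Minimum cutoff in ms (default 1000; covers settling of
#'   the conductance-based network from its rest-like initial state).
#' @return Cutoff time in ms.
#' @export
transientCutoff <- function(T2 = NULL, K = 3L, floor_ms = 1000) {
  if (is.null(T2)) floor_ms else max(floor_ms, K * T2)
}

#' Probability of firing after a pulse, by phase of a second input
#'
#' For each pulse of train `trigger`, determines whether an event follows it
#' within `window` ms, and bins the pulses by their phase relative to train
#' `reference` (time since the last reference pulse). The returned histogram
#' gives, per phase bin, the fraction of trigger pulses that were followed by
#' an event.
#'
#' @param events Event (spike) times in ms.
#' @param trigger Pulse times (numeric vector or `pulse_train`) whose
#'   followers are counted.
#' @param reference Pulse times (numeric vector or `pulse_train`) defining
#'   the phase axis.
#' @param bin Phase bin width in ms (default 1).
#' @param window "Immediately after" window in ms (default 5).
#' @return Data frame with `phase` (bin left edge, ms), `n_pulses`,
#'   `n_followed` and `prob`. Bins containing no pulses are reported with
#'   `prob = NA` (undefined), not zero.
#' @export
firingProbabilityVsPhase <- function(events, trigger, reference, bin = 1,
                                     window = 5) {
  trg <- if (inherits(trigger, "pulse_train")) trigger$times else trigger
  ref <- if (inherits(reference, "pulse_train")) reference$times else reference
  trg <- trg[trg >= ref[1]]
  ph <- phaseOf(trg, ref)
  followed <- vapply(trg, function(s)
    any(events >= s & events < s + window), logical(1))
  edges <- seq(0, max(ph) + bin, by = bin)
  bi <- findInterval(ph, edges)
  n_pulses <- tabulate(bi, nbins = length(edges) - 1L)
  n_followed <- vapply(seq_len(length(edges) - 1L),
                       function(i) sum(followed[bi == i]), integer(1))
  prob <- ifelse(n_pulses > 0, n_followed / n_pulses, NA_real_)
  data.frame(phase = edges[-length(edges)], n_pulses = n_pulses,
             n_followed = n_followed, prob = prob)
}

#' Detect p:q mode-locking of events to a periodic input
#'
#' Searches for the smallest `q <= max_q` such that every full window of `q`
#' consecutive input cycles (windows anchored at each input pulse) contains
#' exactly the same number of events `p`. Phase dispersion is the circular
#' standard deviation of event times modulo the input period, converted to
#' ms; the train is flagged phase-locked when the dispersion is below
#' `lock_sd_ms`.
#'
#' @param events Event times in ms (post-transient).
#' @param input Pulse times (numeric vector or `pulse_train`) of the
#'   periodic input.
#' @param max_q Largest cycle denominator considered (default 12).
#' @param min_cycles Minimum number of complete q-cycle windows required to
#'   accept a lock (default 20).
#' @param lock_sd_ms Circular s.d. threshold for the phase-locked verdict in
#'   ms (default 2).
#' @return An object of class `mode_lock_stats`: list with `p`, `q`
#'   (coprime, or `NA` if no lock), `ratio` (`p/q`), `phase_sd_ms`,
#'   `phase_locked`, `n_windows`.
#' @export
modeLockRatio <- function(events, input, max_q = 12L, min_cycles = 20L,
                          lock_sd_ms = 2) {
  s <- if (inherits(input, "pulse_train")) input$times else input
  Tin <- mean(diff(s))
  events <- events[events >= s[1] & events < s[length(s)]]
  # events per single cycle, anchored at each pulse
  per_cycle <- vapply(seq_len(length(s) - 1L), function(i)
    sum(events >= s[i] & events < s[i + 1L]), integer(1))
  p <- NA_integer_; q <- NA_integer_
  for (qq in seq_len(max_q)) {
    nw <- length(per_cycle) - qq + 1L
    if (nw < min_cycles) break
    wc <- vapply(seq_len(nw), function(i) sum(per_cycle[i:(i + qq - 1L)]),
                 integer(1))
    if (length(unique(wc)) == 1L) {
      pp <- wc[1]
      if (pp > 0L) {
        g <- .gcd(pp, qq)
        p <- as.integer(pp / g); q <- as.integer(qq / g)
      }
      break
    }
  }
  ph <- (events - s[1]) %% Tin
  ang <- 2 * pi * ph / Tin
  R <- sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
  sd_ms <- if (R > 0) sqrt(-2 * log(R)) * Tin / (2 * pi) else Inf
  structure(list(p = p, q = q,
                 ratio = if (is.na(p)) NA_real_ else p / q,
                 phase_sd_ms = sd_ms,
                 phase_locked = is.finite(sd_ms) && sd_ms < lock_sd_ms,
                 n_windows = length(per_cycle)),
            class = "mode_lock_stats")
}

#' @export
print.mode_lock_stats <- function(x, ...) {
  if (is.na(x$p)) cat("mode_lock_stats: no p:q lock detected\n")
  else cat(sprintf("mode_lock_stats: %d:%d lock, phase s.d. %.2f ms (%s)\n",
                   x$p, x$q, x$phase_sd_ms,
                   if (x$phase_locked) "phase-locked" else "not phase-locked"))
  invisible(x)
}

#' Interburst-interval map from paired burst and spike trains
#'
#' For each interburst interval of the bursting cell, records the lag from
#' the burst onset to the (unique) slow-cell spike inside the interval
#' (`ib_si`), the interval length itself (`ib_ib`), and the spike counts of
#' the opening and the following burst. Intervals containing zero or more
#' than one spike are excluded and counted.
#'
#' @param bursts A `burst_train` (from [groupBursts()]).
#' @param spikes Spike times of the other cell in ms.
#' @return An object of class `interburst_map`: data frame with columns
#'   `ib_si`, `ib_ib`, `count_open`, `count_next`, plus attribute
#'   `n_excluded`.
#' @export
interburstMap <- function(bursts, spikes) {
  stopifnot(inherits(bursts, "burst_train"))
  on <- bursts$onset
  n <- length(on) - 1L
  rows <- vector("list", n)
  excl <- 0L
  for (i in seq_len(n)) {
    sp <- spikes[spikes >= on[i] & spikes < on[i + 1L]]
    if (length(sp) != 1L) { excl <- excl + 1L; next }
    rows[[i]] <- c(ib_si = sp - on[i], ib_ib = on[i + 1L] - on[i],
                   count_open = bursts$count[i],
                   count_next = bursts$count[i + 1L])
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- as.data.frame(do.call(rbind, rows))
  if (excl > 0)
    warning(excl, " interburst interval(s) without a unique spike excluded")
  structure(df, n_excluded = excl, class = c("interburst_map", "data.frame"))
}

#' Iterate the burst-phase return map
#'
#' Given an empirical interburst-interval function `T_IB(phi)` (the interval
#' length as a function of the lag `phi` of the slow-cell spike after the
#' last burst onset) and a fixed slow-cell interspike interval `T_SI`, the
#' lag evolves as `phi' = phi + T_SI - T_IB(phi)`. The fixed point satisfies
#' `T_IB(phi*) = T_SI` and is linearly stable when the local slope
#' `dT_IB/dphi` lies in `(0, 1)` (the lag is then pulled to equilibrium at
#' geometric rate equal to that slope).
#'
#' @param T_IB Function of one argument giving the interburst interval (ms)
#'   for a spike lag `phi` (ms).
#' @param T_SI Slow-cell interspike interval in ms.
#' @param phi0 Initial lag in ms.
#' @param n Number of iterations (default 100).
#' @param domain Length-2 numeric; iteration stops with a divergence report
#'   if the lag leaves this interval.
#' @return List with `phi` (the iterate sequence), `fixed_point`, `slope`
#'   (numerical derivative of `T_IB` at the fixed point), `stable`
#'   (`0 < slope < 1`) and `diverged`.
#' @export
phaseMapIterate <- function(T_IB, T_SI, phi0, n = 100L,
                            domain = c(0, 100)) {
  phi <- numeric(n + 1L); phi[1] <- phi0
  diverged <- FALSE
  for (i in seq_len(n)) {
    nxt <- phi[i] + T_SI - T_IB(phi[i])
    if (!is.finite(nxt) || nxt < domain[1] || nxt > domain[2]) {
      diverged <- TRUE
      phi <- phi[seq_len(i)]
      break
    }
    phi[i + 1L] <- nxt
  }
  fp <- NA_real_; slope <- NA_real_
  if (!diverged) {
    # fixed point: T_IB(phi*) = T_SI, found from the converged iterate
    fp <- phi[length(phi)]
    h <- 1e-4 * max(1, abs(fp))
    slope <- (T_IB(fp + h) - T_IB(fp - h)) / (2 * h)
  }
  list(phi = phi, fixed_point = fp, slope = slope,
       stable = is.finite(slope) && slope > 0 && slope < 1,
       diverged = diverged)
}

#' Align slow-variable traces on burst onsets
#'
#' Extracts, for each burst, the value of each selected state variable at
#' the burst onset and at a fixed time `t0` after onset, grouped by the
#' number of spikes in the burst. This is the state-reset diagnostic: after
#' a burst the slow variables collapse to (approximately) one value per
#' spike-count class, so the distributions returned here are narrow.
#'
#' @param time Time grid of the traces in ms.
#' @param traces Matrix (time x variables) of state-variable traces; column
#'   names identify the variables.
#' @param bursts A `burst_train`.
#' @param t0 Sampling offset after burst onset in ms; must exceed the
#'   longest burst duration.
#' @param post_window Bursts closer together than this (ms) are excluded
#'   (default `t0`).
#' @return An object of class `reset_alignment`: list with `at_onset` and
#'   `at_t0` (data frames: burst, count, one column per variable), and `t0`.
#' @export
resetAlignment <- function(time, traces, bursts, t0, post_window = t0) {
  stopifnot(inherits(bursts, "burst_train"))
  on <- bursts$onset
  ok <- c(diff(on) >= post_window, TRUE) &
    (on + t0 <= time[length(time)]) & (on >= time[1])
  idx_on <- findInterval(on[ok], time)
  idx_t0 <- findInterval(on[ok] + t0, time)
  mk <- function(idx) {
    df <- as.data.frame(traces[idx, , drop = FALSE])
    df$count <- bursts$count[ok]
    df
  }
  structure(list(at_onset = mk(idx_on), at_t0 = mk(idx_t0), t0 = t0),
            class = "reset_alignment")
}

#' Firing rate as a function of a swept input frequency
#'
#' Runs one simulation per grid point through a caller-supplied runner and
#' collects the post-transient firing rate. Per-point failures are recorded
#' in the result rather than aborting the sweep.
#'
#' @param grid Numeric vector of frequencies in Hz.
#' @param runner Function of one frequency returning a numeric event-time
#'   vector (already transient-trimmed) together with an attribute `span`
#'   (length-2 observation window in ms); or simply a vector, in which case
#'   its range is used as the window.
#' @return Data frame with `freq`, `rate` (Hz; `NA` on failure) and `error`
#'   (message or `NA`).
#' @export
rateVsFrequencySweep <- function(grid, runner) {
  res <- lapply(grid, function(f) {
    ev <- tryCatch(runner(f), error = function(e) e)
    if (inherits(ev, "error"))
      return(c(rate = NA_real_, err = conditionMessage(ev)))
    span <- attr(ev, "span")
    if (is.null(span)) span <- range(ev)
    c(rate = firingRate(ev, span), err = NA_character_)
  })
  data.frame(freq = grid,
             rate = as.numeric(vapply(res, `[[`, character(1), 1)),
             error = vapply(res, `[[`, character(1), 2),
             stringsAsFactors = FALSE)
}
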