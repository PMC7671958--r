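#' Parameters of the discrete pulse-gating model
#'
#' The abstract model reduces the slow cell to a discrete firing rule driven
#' by two pulse streams. Input-1 pulses arrive periodically with period `T1`;
#' input-2 pulses arrive at the (strictly increasing) times `t_seq`. The cell
#' fires at an input-1 pulse iff at least `m` input-1 periods have elapsed
#' since its last firing and the time since the last input-2 pulse (the
#' input-2 *phase*) is at least `c`, the effective inhibition time.
#'
#' @param T1 Input-1 period in ms (`> 0`).
#' @param c Effective inhibition time in ms (`>= 0`).
#' @param m Minimum number of input-1 periods between successive firings
#'   (integer `>= 1`). `m = 2` is the canonical "cannot fire on consecutive
#'   pulses" rule; `m = 1` removes the refractory restriction entirely.
#' @param t_seq Strictly increasing input-2 pulse times in ms with
#'   `t_seq[1] = 0`. Supply either `t_seq` or a period `T2`.
#' @param T2 Input-2 period in ms for a periodic input-2; used to build
#'   `t_seq` when the latter is not given (the sequence is extended as needed
#'   by the simulator).
#' @param s1 First firing time (= first input-1 pulse time) in ms. Must lie
#'   in `[c, t_seq[2])`. Defaults to `c`, the earliest admissible firing.
#' @return An object of class `abstract_params`.
#' @seealso [simulateAbstract()], [checkConditions()], [verifyTheorem()]
#' @export
abstractParams <- function(T1, c, m = 2L, t_seq = NULL, T2 = NULL, s1 = NULL) {
  stopifnot(is.numeric(T1), length(T1) == 1L, T1 > 0,
            is.numeric(c), length(c) == 1L, c >= 0,
            length(m) == 1L, m >= 1, m == as.integer(m))
  if (is.null(t_seq) && is.null(T2))
    stop("supply input-2 either as `t_seq` or as a period `T2`")
  if (!is.null(t_seq)) {
    if (is.unsorted(t_seq, strictly = TRUE))
      stop("`t_seq` must be strictly increasing")
    if (abs(t_seq[1]) > 1e-12)
      stop("`t_seq` must start at 0 (t_1 = 0 by convention)")
  }
  if (is.null(s1)) s1 <- c
  t2 <- if (!is.null(t_seq)) t_seq[2] else T2
  if (s1 < c || s1 >= t2)
    stop(sprintf("`s1` must lie in [c, t_2) = [%g, %g), got %g", c, t2, s1))
  structure(list(T1 = T1, c = c, m = as.integer(m),
                 t_seq = t_seq, T2 = T2, s1 = s1),
            class = "abstract_params")
}

#' @export
print.abstract_params <- function(x, ...) {
  cat(sprintf("abstract_params: T1 = %g ms, c = %g ms, m = %d, input-2 %s\n",
              x$T1, x$c, x$m,
              if (is.null(x$t_seq)) sprintf("periodic T2 = %g ms", x$T2)
              else sprintf("given (%d pulses)", length(x$t_seq))))
  invisible(x)
}

# input-2 pulse times covering [0, horizon]
.t_seq_of <- function(params, horizon) {
  if (!is.null(params$t_seq)) params$t_seq
  else seq(0, horizon + params$T2, by = params$T2)
}

#' Time since the last input-2 pulse
#'
#' For each `x`, returns `x` minus the largest input-2 pulse time not
#' exceeding `x`. For a periodic input-2 of period `T2` this is `x mod T2`.
#'
#' @param x Numeric vector of times in ms; every element must be at or after
#'   the first input-2 pulse.
#' @param t_seq Strictly increasing input-2 pulse times in ms.
#' @return Numeric vector of phases in ms.
#' @export
phaseOf <- function(x, t_seq) {
  if (any(x < t_seq[1]))
    stop("phase undefined before the first input-2 pulse")
  idx <- findInterval(x, t_seq)
  x - t_seq[idx]
}

#' Simulate the discrete pulse-gating model
#'
#' Iterates the firing rule over every input-1 pulse up to `horizon`: the
#' cell fires at pulse time `s` iff `s` is at least `m * T1` after the
#' previous firing and the input-2 phase of `s` is at least `c` (the phase
#' test is closed at `c`; a pulse coinciding with an input-2 pulse has phase
#' 0). The first firing is placed at `params$s1`, which anchors the input-1
#' pulse grid: pulses occur at `s1 + k * T1` for integer `k >= 0`.
#'
#' @param params An [abstractParams()] object.
#' @param horizon Simulation horizon in ms. Must reach past the second
#'   input-2 pulse.
#' @return An object of class `firing_record`: list with `u` (firing times,
#'   ms), `phase` (input-2 phase of each firing, ms), `s` (all input-1 pulse
#'   times), `fired` (logical per pulse), `t_seq` (input-2 pulse times used)
#'   and `params`.
#' @export
simulateAbstract <- function(params, horizon) {
  stopifnot(inherits(params, "abstract_params"))
  t_seq <- .t_seq_of(params, horizon)
  if (horizon < t_seq[2])
    stop("`horizon` ends before the second input-2 pulse; record would be empty")
  s <- seq(params$s1, horizon, by = params$T1)
  ph <- phaseOf(s, t_seq)
  eligible <- ph >= params$c
  fired <- logical(length(s))
  # the refractory test "at least m*T1 since the last firing" is exact on
  # the pulse index (pulses are equally spaced by T1)
  last_l <- -Inf
  for (l in seq_along(s)) {
    if (eligible[l] && l - last_l >= params$m) {
      fired[l] <- TRUE
      last_l <- l
    }
  }
  structure(list(u = s[fired], phase = ph[fired], s = s, fired = fired,
                 t_seq = t_seq, params = params),
            class = "firing_record")
}

#' @export
print.firing_record <- function(x, ...) {
  cat(sprintf("firing_record: %d firings over %d input-1 pulses (%.1f ms)\n",
              length(x$u), length(x$s), x$s[length(x$s)] - x$s[1]))
  if (length(x$u) > 1)
    cat(sprintf("  mean rate %.4f Hz, phases in [%.2f, %.2f] ms\n",
                1000 * (length(x$u) - 1) / (x$u[length(x$u)] - x$u[1]),
                min(x$phase), max(x$phase)))
  invisible(x)
}

#' @export
as.data.frame.firing_record <- function(x, ...) {
  data.frame(firing_time_ms = x$u, phase_ms = x$phase)
}

#' Write a firing record as two-column delimited text
#'
#' Columns are `firing_time_ms` and `phase_ms`, tab-separated.
#'
#' @param record A `firing_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeFiringRecord <- function(record, path) {
  stopifnot(inherits(record, "firing_record"))
  utils::write.table(as.data.frame(record), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sufficient conditions for once-per-period entrainment
#'
#' Checks the two-sided gap condition under which the slow cell is guaranteed
#' to fire exactly once per input-2 period: the smallest input-2 interpulse
#' gap must strictly exceed `max(m * T1, c + T1)` and the largest gap must
#' not exceed `m * T1 + c`.
#'
#' @param params An [abstractParams()] object, or `NULL` if the remaining
#'   arguments are given directly.
#' @param T1,c,m Model parameters (ms, ms, integer); ignored when `params`
#'   is supplied.
#' @param gaps Input-2 interpulse intervals in ms; derived from `params` when
#'   omitted (for a periodic input-2 all gaps equal `T2`).
#' @return List with `ok` (logical), `inf_gap`, `sup_gap`, and the two
#'   margins: `margin_lower = inf_gap - max(m*T1, c+T1)` (must be `> 0`) and
#'   `margin_upper = m*T1 + c - sup_gap` (must be `>= 0`).
#' @export
checkConditions <- function(params = NULL, T1 = NULL, c = NULL, m = NULL,
                            gaps = NULL) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "abstract_params"))
    T1 <- params$T1; c <- params$c; m <- params$m
    if (is.null(gaps))
      gaps <- if (!is.null(params$t_seq)) diff(params$t_seq) else params$T2
  }
  inf_gap <- min(gaps); sup_gap <- max(gaps)
  ml <- inf_gap - max(m * T1, c + T1)
  mu <- m * T1 + c - sup_gap
  list(ok = (ml > 0) && (mu >= 0),
       inf_gap = inf_gap, sup_gap = sup_gap,
       margin_lower = ml, margin_upper = mu)
}

#' Transient bound K
#'
#' Number of input-2 periods after which every firing is guaranteed to fall
#' in the admissible phase window `[c, c + T1)`:
#' `K = ceil((sup_gap - (c + T1)) / (inf_gap - m * T1)) + 1`.
#'
#' @param T1 Input-1 period (ms).
#' @param c Effective inhibition time (ms).
#' @param m Minimum input-1 periods between firings.
#' @param inf_gap,sup_gap Infimum and supremum of the input-2 interpulse
#'   intervals (ms). For a periodic input-2 both equal the period.
#' @return Integer bound `K` (in input-2 cycles).
#' @export
transientBoundK <- function(T1, c, m, inf_gap, sup_gap = inf_gap) {
  if (inf_gap <= m * T1)
    stop("transient bound undefined: inf_gap must exceed m * T1")
  ratio <- (sup_gap - (c + T1)) / (inf_gap - m * T1)
  as.integer(ceiling(ratio - 1e-9)) + 1L
}

# re-anchor a record per the theorem's indexing: pick the first firing as
# u_1, shift time so that the input-2 pulse at or before u_1 is t_1 = 0
.anchor_record <- function(record) {
  u <- record$u
  if (length(u) < 2) stop("record too short to anchor")
  t_seq <- record$t_seq
  i1 <- findInterval(u[1], t_seq)       # pulse index at or before u_1
  shift <- t_seq[i1]
  list(u = u - shift, t_seq = t_seq[t_seq >= shift - 1e-12] - shift,
       s = record$s - shift, fired = record$fired)
}

#' Verify the entrainment theorem on a simulated record
#'
#' Re-anchors the record at its first firing (`u_1 = s_1`, with the input-2
#' pulse at or before it relabelled `t_1 = 0`) and checks the three
#' conclusions that hold whenever [checkConditions()] passes:
#' (a) the n-th firing falls in `[t_n + c, t_{n+1})` — exactly one firing per
#' input-2 period; (b) from period `K` on, every firing phase lies in
#' `[c, c + T1)`; (c) from `t_K` on, an input-1 pulse triggers a firing if
#' and only if its phase lies in `[c, c + T1)`.
#'
#' @param record A `firing_record` from [simulateAbstract()].
#' @param params The [abstractParams()] used (defaults to those stored in
#'   the record).
#' @return An object of class `theorem_report`: list with the transient
#'   bound `K`, logicals `a`, `b`, `c` and `all_pass`, and integer vectors
#'   of violating indices per part.
#' @export
verifyTheorem <- function(record, params = record$params) {
  stopifnot(inherits(record, "firing_record"))
  anc <- .anchor_record(record)
  u <- anc$u; t_seq <- anc$t_seq; s <- anc$s; fired <- anc$fired
  T1 <- params$T1; c <- params$c; m <- params$m
  # only periods fully covered by the record
  n_use <- min(length(u), sum(t_seq <= u[length(u)]))
  gaps <- diff(t_seq[t_seq <= u[length(u)] + max(diff(t_seq))])
  K <- transientBoundK(T1, c, m, min(gaps), max(gaps))
  # (a) u_n in [t_n + c, t_{n+1})
  n_a <- seq_len(min(n_use, length(t_seq) - 1L))
  ok_a <- u[n_a] >= t_seq[n_a] + c - 1e-9 & u[n_a] < t_seq[n_a + 1L] - 1e-9 * 0
  viol_a <- n_a[!ok_a]
  # (b) phases from period K on
  ph_u <- phaseOf(u[seq_len(n_use)], t_seq)
  n_b <- seq_len(n_use); n_b <- n_b[n_b >= K]
  ok_b <- ph_u[n_b] >= c - 1e-9 & ph_u[n_b] < c + T1 - 1e-9 * 0
  viol_b <- n_b[!ok_b]
  # (c) pulses at or after t_K, within the verified span
  if (K <= length(t_seq)) {
    span_end <- u[length(u)]
    keep <- s >= t_seq[K] & s <= span_end & s >= t_seq[1]
    ph_s <- phaseOf(s[keep], t_seq)
    in_win <- ph_s >= c - 1e-9 & ph_s < c + T1 - 1e-12
    ok_c <- fired[keep] == in_win
    viol_c <- which(keep)[!ok_c]
  } else {
    viol_c <- integer(0)
  }
  structure(list(K = K,
                 a = length(viol_a) == 0L, b = length(viol_b) == 0L,
                 c = length(viol_c) == 0L,
                 all_pass = length(viol_a) + length(viol_b) + length(viol_c) == 0L,
                 violations = list(a = viol_a, b = viol_b, c = viol_c)),
            class = "theorem_report")
}

#' @export
print.theorem_report <- function(x, ...) {
  cat(sprintf("theorem_report: K = %d\n", x$K))
  for (p in c("a", "b", "c"))
    cat(sprintf("  part (%s): %s%s\n", p,
                if (x[[p]]) "pass" else "FAIL",
                if (!x[[p]]) sprintf(" (%d violations)", length(x$violations[[p]])) else ""))
  invisible(x)
}

#' Admissible input-2 frequency range
#'
#' Solves the entrainment condition for the input-2 frequency: given the
#' input-1 frequency `f1`, the refractory multiplicity `m` and the effective
#' inhibition time `c`, the slow cell fires once per input-2 period for
#' `f2` in the half-open interval `[f1/(f1*c + m), min(f1/m, f1/(f1*c + 1)))`.
#'
#' @param f1 Input-1 frequency in Hz.
#' @param m Minimum input-1 periods between firings.
#' @param c Effective inhibition time **in seconds** (frequencies are in Hz).
#' @return Named numeric vector `c(lower, upper)`; the interval is
#'   `[lower, upper)`.
#' @export
f2Range <- function(f1, m, c) {
  stopifnot(f1 > 0, c >= 0)
  c(lower = f1 / (f1 * c + m),
    upper = min(f1 / m, f1 / (f1 * c + 1)))
}

#' Admissible input-1 frequency range
#'
#' The dual of [f2Range()]: for fixed input-2 frequency `f2`, entrainment is
#' guaranteed for `f1` in `(max(m*f2, f2/(1 - c*f2)), m*f2/(1 - c*f2)]`
#' (lower endpoint exclusive, upper inclusive). Requires `c * f2 < 1`.
#'
#' @param f2 Input-2 frequency in Hz.
#' @param m Minimum input-1 periods between firings.
#' @param c Effective inhibition time **in seconds**.
#' @return Named numeric vector `c(lower, upper)`; the interval is
#'   `(lower, upper]` and is empty when `lower >= upper` (e.g. `c = 0`).
#' @export
f1Range <- function(f2, m, c) {
  if (c * f2 >= 1)
    stop("f1 range undefined: need c * f2 < 1")
  c(lower = max(m * f2, f2 / (1 - c * f2)),
    upper = m * f2 / (1 - c * f2))
}

#' Asymptotic firing rate in the unrestricted (m = 1) model
#'
#' With the refractory restriction removed the cell fires at every input-1
#' pulse whose input-2 phase is at least `c`; for periodic inputs the
#' long-run firing rate is `(1/T1) * (1 - c/T2)`. When `T1/T2` is a rational
#' `p/q` in lowest terms the empirical limit is only guaranteed to lie
#' within `1/(q*T1)` of this value; the bound is attached whenever a small
#' rational approximation of the period ratio is found.
#'
#' @param T1,T2 Input periods in ms, `T1 < T2`.
#' @param c Effective inhibition time in ms, `0 <= c < T2`.
#' @param max_q Largest denominator searched when testing `T1/T2` for
#'   rationality (default 1000).
#' @return List with `rate_hz`, and when the ratio is (numerically) rational
#'   `p/q`: `p`, `q` and `bound_hz`, the bound `1/(q*T1)` converted to Hz.
#'   Otherwise `p`, `q`, `bound_hz` are `NA`.
#' @export
asymptoticRateM1 <- function(T1, T2, c, max_q = 1000L) {
  stopifnot(T2 > T1, T1 > 0, c >= 0, c < T2)
  rate_khz <- (1 / T1) * (1 - c / T2)
  ratio <- T1 / T2
  p <- q <- NA_integer_; bound <- NA_real_
  for (qq in seq_len(max_q)) {
    pp <- round(ratio * qq)
    if (pp >= 1 && abs(ratio - pp / qq) < 1e-9) {
      g <- .gcd(pp, qq)
      p <- as.integer(pp / g); q <- as.integer(qq / g)
      bound <- 1000 / (q * T1)   # 1/(q*T1) per ms -> Hz
      break
    }
  }
  list(rate_hz = 1000 * rate_khz, p = p, q = q, bound_hz = bound)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Estimate the refractory multiplicity and inhibition time from events
#'
#' Recovers the abstract-model parameters from a simulated spike train:
#' `m_hat` is the minimum number of input-1 periods separating successive
#' firings, and `c_hat` is the left edge of the first occupied bin of the
#' input-2 phase histogram (the end of the contiguous zero-firing prefix).
#'
#' @param firings Firing/spike times in ms (post-transient).
#' @param T1 Input-1 period in ms (used to convert firing gaps to period
#'   counts).
#' @param t_seq Input-2 pulse times in ms.
#' @param bin Histogram bin width in ms (default 1); sets the resolution of
#'   `c_hat`.
#' @param min_events Minimum number of firings required (default 50).
#' @return List with `m_hat` (integer) and `c_hat` (ms).
#' @export
estimateMC <- function(firings, T1, t_seq, bin = 1, min_events = 50L) {
  if (length(firings) < min_events)
    stop("insufficient data: need at least ", min_events, " firings, got ",
         length(firings))
  m_hat <- as.integer(min(round(diff(firings) / T1)))
  ph <- phaseOf(firings, t_seq)
  c_hat <- floor(min(ph) / bin) * bin
  list(m_hat = m_hat, c_hat = c_hat)
}

#' Draw random parameters satisfying the entrainment conditions
#'
#' Generates a jittered input-2 pulse sequence together with `(T1, c, m)`
#' such that the two-sided gap condition of [checkConditions()] holds by
#' construction: gaps are drawn uniformly from
#' `(max(m*T1, c+T1) + eps, m*T1 + c]`. Used by the property-style test
#' suite.
#'
#' @param n_periods Number of input-2 periods to generate.
#' @param T1_range Range to draw `T1` from (ms).
#' @param m_choices Candidate values of `m`.
#' @param eps Strictness margin for the open left endpoint (ms).
#' @return An [abstractParams()] object with a jittered `t_seq`.
#' @export
randomAdmissibleParams <- function(n_periods = 60L, T1_range = c(10, 40),
                                   m_choices = 2:4, eps = 1e-6) {
  T1 <- stats::runif(1, T1_range[1], T1_range[2])
  m <- sample(m_choices, 1)
  # need the gap interval (max(m*T1, c+T1) + eps, m*T1 + c] nonempty: c > 0
  c <- stats::runif(1, 0.1 * T1, (m - 0.05) * T1)
  lo <- max(m * T1, c + T1) + eps
  hi <- m * T1 + c
  gaps <- stats::runif(n_periods, lo, hi)
  t_seq <- cumsum(c(0, gaps))
  s1 <- stats::runif(1, c, t_seq[2])
  abstractParams(T1 = T1, c = c, m = m, t_seq = t_seq, s1 = s1)
}

#' Build a firing record from simulated spike trains
#'
#' Maps a continuous-model spike train (leaky integrate-and-fire or
#' conductance-based) onto the abstract model's bookkeeping so that the
#' entrainment theorem can be checked on it: each spike is snapped to the
#' input-1 pulse that triggered it (the latest pulse at or before the spike,
#' required to be within `window` ms), and `fired` marks the pulses with an
#' attached spike.
#'
#' @param spikes Spike times in ms.
#' @param input1 A `pulse_train` (or numeric vector of pulse times) for the
#'   fast excitatory input.
#' @param input2 A `pulse_train` (or numeric vector of pulse times) for the
#'   slow input.
#' @param params An [abstractParams()] object carrying the (estimated)
#'   `T1`, `c`, `m` to verify against; its `t_seq`/`T2` fields are ignored.
#' @param window Maximum allowed spike latency after its pulse in ms
#'   (default 5). Spikes with no pulse within the window are dropped with a
#'   warning.
#' @return A `firing_record` whose firing times are the triggering pulse
#'   times.
#' @export
asFiringRecord <- function(spikes, input1, input2, params, window = 5) {
  s <- if (inherits(input1, "pulse_train")) input1$times else input1
  t_seq <- if (inherits(input2, "pulse_train")) input2$times else input2
  spikes <- spikes[spikes >= s[1] & spikes >= t_seq[1]]
  idx <- findInterval(spikes, s)
  lat <- spikes - s[idx]
  if (any(lat > window)) {
    warning(sum(lat > window), " spike(s) with latency > ", window,
            " ms after the last input-1 pulse were dropped")
    idx <- idx[lat <= window]
  }
  idx <- unique(idx)
  fired <- logical(length(s))
  fired[idx] <- TRUE
  u <- s[fired]
  # shift so that t_1 = 0 as the abstract-model convention requires
  shift <- t_seq[1]
  t_shift <- t_seq - shift
  structure(list(u = u - shift, phase = phaseOf(u - shift, t_shift),
                 s = s - shift, fired = fired,
                 t_seq = t_shift, params = params),
            class = "firing_record")
}
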