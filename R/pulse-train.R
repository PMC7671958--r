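#' Generate a periodic or jittered pulse train
#'
#' Builds the pulsatile drive used by every network configuration: a train of
#' pulse times with nominal frequency `f` whose interpulse intervals are
#' independent draws from a normal distribution with mean `1000/f` ms and
#' standard deviation `sigma * 1000/f` ms. With `sigma = 0` the train is
#' exactly periodic and independent of the seed.
#'
#' Non-positive interval draws cannot occur on a valid train (pulse times must
#' be strictly increasing), so any such draw is resampled. At the jitter
#' levels used in practice (`sigma` up to ~0.1) the resampling probability is
#' negligible and does not materially distort the mean interval.
#'
#' @param f Nominal pulse frequency in Hz. Must be positive.
#' @param sigma Interpulse-interval standard deviation as a fraction of the
#'   mean interval (dimensionless, `>= 0`). `sigma = 0` gives an exactly
#'   periodic train.
#' @param duration Length of the train in ms. Pulses cover `[t0, duration]`.
#' @param seed Integer seed used when `sigma > 0`; ignored (and may be `NULL`)
#'   for periodic trains.
#' @param t0 Time of the first pulse in ms (default 0). A nonzero offset is
#'   used e.g. for phase-shifted copies of a slow drive in the multiplexing
#'   network.
#' @return An object of class `pulse_train` with fields `times` (ms,
#'   strictly increasing), `f`, `sigma`, `seed`, `t0`.
#' @examples
#' pulseTrain(40, 0, 100)$times     # 0 25 50 75 100
#' pulseTrain(40, 0.05, 1000, seed = 1)
#' @export
pulseTrain <- function(f, sigma = 0, duration, seed = NULL, t0 = 0) {
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0)
    stop("`f` must be a single positive frequency in Hz, got: ", format(f))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("`duration` must be a single positive time in ms, got: ", format(duration))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("`sigma` must be a single non-negative fraction, got: ", format(sigma))
  mean_iv <- 1000 / f
  if (sigma == 0) {
    times <- seq(t0, duration + 1e-9, by = mean_iv)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    sd_iv <- sigma * mean_iv
    # draw in blocks; resample non-positive intervals
    n_guess <- ceiling((duration - t0) / mean_iv * 1.2) + 10L
    ivs <- numeric(0)
    while (sum(ivs) < duration - t0) {
      blk <- stats::rnorm(n_guess, mean_iv, sd_iv)
      while (any(blk <= 0)) {
        bad <- blk <= 0
        blk[bad] <- stats::rnorm(sum(bad), mean_iv, sd_iv)
      }
      ivs <- c(ivs, blk)
    }
    times <- t0 + cumsum(c(0, ivs))
    times <- times[times <= duration + 1e-9]
  }
  structure(
    list(times = times, f = f, sigma = sigma,
         seed = if (sigma > 0) seed else NULL, t0 = t0),
    class = "pulse_train"
  )
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("pulse_train: %d pulses, nominal %.4g Hz, sigma = %.3g%s\n",
              length(x$times), x$f, x$sigma,
              if (!is.null(x$seed)) sprintf(", seed = %d", x$seed) else ""))
  cat(sprintf("  span [%.2f, %.2f] ms, mean interval %.3f ms\n",
              x$times[1], x$times[length(x$times)],
              if (length(x$times) > 1) mean(diff(x$times)) else NA_real_))
  invisible(x)
}

#' @export
as.data.frame.pulse_train <- function(x, ...) {
  data.frame(index = seq_along(x$times), time_ms = x$times)
}

#' Write a pulse train as two-column delimited text
#'
#' Columns are `index` and `time_ms`, tab-separated.
#'
#' @param train A `pulse_train`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePulseTrain <- function(train, path) {
  stopifnot(inherits(train, "pulse_train"))
  utils::write.table(as.data.frame(train), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pulsatile external-potential trace induced by a pulse train
#'
#' Between pulses the external potential relaxes exponentially toward
#' \eqn{-70} mV with unit time constant (1 ms); at each pulse time it is reset
#' to exactly 25 mV (the delta-function drive relaxes the potential to 25 mV
#' regardless of its prior value). Before the first pulse the trace sits at
#' its equilibrium \eqn{-70} mV. The trace is evaluated in closed form:
#' \eqn{V(t) = -70 + 95 e^{-(t - t_i)}} for \eqn{t} in the interval following
#' pulse \eqn{i}.
#'
#' @param train A `pulse_train`.
#' @param grid Increasing numeric vector of evaluation times (ms). If `NULL`,
#'   a regular grid with spacing `dt` from 0 to `until` is used.
#' @param dt Grid spacing in ms when `grid` is `NULL` (default 0.05).
#' @param until End of the default grid in ms; defaults to the last pulse
#'   time plus 5 ms.
#' @return An object of class `external_potential`: list with `time` (ms),
#'   `V_ext` (mV) and the source `train`. At a grid point equal to a pulse
#'   time the post-reset value 25 mV is reported.
#' @export
externalPotential <- function(train, grid = NULL, dt = 0.05, until = NULL) {
  stopifnot(inherits(train, "pulse_train"))
  if (is.null(grid)) {
    if (is.null(until)) until <- max(train$times) + 5
    grid <- seq(0, until, by = dt)
  }
  if (is.unsorted(grid, strictly = TRUE))
    stop("`grid` must be strictly increasing")
  if (length(grid) > 1 && max(diff(grid)) > 1 + 1e-12)
    warning("grid spacing exceeds the 1 ms relaxation time constant; ",
            "the trace is undersampled")
  # index of last pulse at or before each grid point (0 = before first pulse)
  idx <- findInterval(grid, train$times)
  v <- rep(-70, length(grid))
  has <- idx > 0
  v[has] <- -70 + 95 * exp(-(grid[has] - train$times[idx[has]]))
  structure(list(time = grid, V_ext = v, train = train),
            class = "external_potential")
}

#' @export
print.external_potential <- function(x, ...) {
  cat(sprintf("external_potential: %d samples on [%.2f, %.2f] ms, %d pulses\n",
              length(x$time), x$time[1], x$time[length(x$time)],
              length(x$train$times)))
  invisible(x)
}

#' @export
as.data.frame.external_potential <- function(x, ...) {
  data.frame(time_ms = x$time, V_ext_mV = x$V_ext)
}

#' Write an external-potential trace as delimited text
#'
#' Columns are `time_ms` and `V_ext_mV`, tab-separated.
#'
#' @param trace An `external_potential`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeExternalPotential <- function(trace, path) {
  stopifnot(inherits(trace, "external_potential"))
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
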