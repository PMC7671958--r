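# Regime-level behavior of the conductance-based networks at the shipped
# parameter set. These runs are deterministic (exactly periodic drives).

test_that("the gated slow cell fires once per slow period, in phase with the fast drive", {
  fx <- fix_fs2in()
  per <- tabulate(findInterval(fx$si, fx$i2$times), nbins = length(fx$i2$times))
  covered <- fx$i2$times >= 1000 & fx$i2$times < 10000 - 62
  expect_true(all(per[covered] == 1))
  expect_equal(firingRate(fx$si, c(1000, 10000)), 16.357, tolerance = 0.02)
  # in phase with the fast drive, never on consecutive fast pulses
  lat <- fx$si - fx$i1$times[findInterval(fx$si, fx$i1$times)]
  expect_lt(max(lat), 3)
  expect_gte(min(round(diff(fx$si) / 25)), 2)
  # firing confined to a window of slow phase of width at most one fast period
  ph <- phaseOf(fx$si, fx$i2$times)
  expect_lt(max(ph) - min(ph), 25)
  expect_gt(min(ph), 10)
})

test_that("the fast cell answers nearly every pulse except right after the other input", {
  fx <- fix_fs2in()
  p1 <- fx$i1$times[fx$i1$times >= 1000 & fx$i1$times <= 9990]
  foll <- vapply(p1, function(t) any(fx$fs >= t & fx$fs < t + 5), logical(1))
  expect_gt(mean(foll), 0.95)
  # the missed pulses sit within a few ms of a slow-drive pulse
  if (any(!foll))
    expect_lt(max(phaseOf(p1[!foll], fx$i2$times)), 6)
})

test_that("slow-cell entrainment tracks the slow drive across its admissible band", {
  rates <- vapply(c(15.5, 17.5, 19.5), function(f2) {
    spec <- buildNetwork("fs_si_2inputs")
    sim <- simulateNetwork(spec, list(input1 = pulseTrain(40, 0, 6000),
                                      input2 = pulseTrain(f2, 0, 6000)), 6000)
    firingRate(excludeTransient(sim$spikes$SI, 1000), c(1000, 6000))
  }, numeric(1))
  expect_equal(rates, c(15.5, 17.5, 19.5), tolerance = 0.02)
})

test_that("pulse-gating survives 5% timing jitter on both drives", {
  spec <- buildNetwork("fs_si_2inputs")
  i1 <- pulseTrain(40, 0.05, 10000, seed = 7)
  i2 <- pulseTrain(16.357, 0.05, 10000, seed = 8)
  sim <- simulateNetwork(spec, list(input1 = i1, input2 = i2), 10000)
  si <- excludeTransient(sim$spikes$SI, 1000)
  lat <- si - i1$times[findInterval(si, i1$times)]
  expect_lt(max(lat), 3.5)
  expect_equal(firingRate(si, c(1000, 10000)), 16.357, tolerance = 0.05)
})

test_that("slow cell and burster alternate strictly in the three-cell network", {
  fx <- fix_fsib40()
  expect_equal(alternation(fx$si, fx$bursts$onset), 1)
  # equal rates and interburst intervals inside the documented band
  expect_lte(abs(length(fx$si) - length(fx$bursts$onset)), 1)
  ibi <- diff(fx$bursts$onset)
  expect_gt(min(ibi), 55)
  expect_lt(max(ibi), 64)
})

test_that("the interburst map is single-valued with slope strictly inside (0,1)", {
  fx <- fix_fsib40()
  im <- suppressWarnings(interburstMap(fx$bursts, fx$si))
  expect_gt(nrow(im), 100)
  fit <- stats::lm(ib_ib ~ ib_si, data = im)
  slope <- unname(coef(fit)[2])
  expect_gt(slope, 0)
  expect_lt(slope, 1)
  # the fitted map's fixed point predicts the steady lag seen in simulation
  cf <- coef(fit)
  pred <- phaseMapIterate(function(phi) cf[1] + cf[2] * phi,
                          T_SI = mean(diff(fx$si)), phi0 = 30, n = 300,
                          domain = c(0, 80))
  expect_false(pred$diverged)
  expect_equal(pred$fixed_point, mean(im$ib_si), tolerance = 0.25)
})

test_that("the driven four-cell network relays the drive and keeps the slow rhythm", {
  fx <- fix_full40()
  p1 <- fx$i1$times[fx$i1$times >= 2000 & fx$i1$times <= 11990]
  rs_follow <- vapply(p1, function(t) any(fx$rs >= t & fx$rs < t + 5),
                      logical(1))
  expect_equal(mean(rs_follow), 1)
  # slow cells fire three times per seven drive cycles on average
  expect_equal(firingRate(fx$si, c(2000, 12000)), 40 * 3 / 7,
               tolerance = 0.01)
  expect_gt(alternation(fx$si, fx$bursts$onset), 0.95)
  lat <- fx$si - fx$i1$times[findInterval(fx$si, fx$i1$times)]
  expect_lt(max(lat), 4)
})

test_that("the autonomous four-cell network sustains the slow rhythm", {
  spec <- buildNetwork("full4")
  sim <- pg_cached("full0", function() simulateNetwork(spec, list(), 8000))
  rs <- excludeTransient(sim$spikes$RS, 2000)
  si <- excludeTransient(sim$spikes$SI, 2000)
  fs <- excludeTransient(sim$spikes$FS, 2000)
  b <- groupBursts(excludeTransient(sim$spikes$IBa, 2000), 15)
  rates <- c(RS = firingRate(rs, c(2000, 8000)),
             SI = firingRate(si, c(2000, 8000)),
             IB = firingRate(b$onset, c(2000, 8000)))
  # all three slow populations share one beta1-band rhythm
  expect_true(all(rates > 12 & rates < 20))
  expect_lt(diff(range(rates)), 0.5)
  # RS and SI in phase, the burster in anti-phase, FS at a multiple
  lag_si <- median(vapply(rs, function(t) min(abs(si - t)), numeric(1)))
  lag_ib <- median(vapply(rs, function(t) min(abs(b$onset - t)), numeric(1)))
  expect_lt(lag_si, 2)
  expect_gt(lag_ib, 10)
  expect_gt(firingRate(fs, c(2000, 8000)), 1.8 * rates["RS"])
})

test_that("doubling the fast-drive strength removes the refractory gate", {
  spec <- buildNetwork("fs_si_2inputs", variant = "strong_input")
  rates <- vapply(c(35, 45), function(f1) {
    sim <- simulateNetwork(spec, list(input1 = pulseTrain(f1, 0, 6000),
                                      input2 = pulseTrain(16.357, 0, 6000)),
                           6000)
    si <- excludeTransient(sim$spikes$SI, 1000)
    expect_equal(min(round(diff(si) * f1 / 1000)), 1)   # m = 1
    firingRate(si, c(1000, 6000))
  }, numeric(1))
  # rate grows roughly linearly with the fast-drive frequency, below it
  expect_true(all(rates < c(35, 45)))
  expect_gt(rates[2] - rates[1], 3)
})

test_that("the multiplexing network relays each stream in its window", {
  bundle <- pg_cached("multiplex", function() runExperiment("multiplex", seed = 1))
  rs <- bundle$events$RS
  sis <- sort(c(bundle$events$SI1, bundle$events$SI2, bundle$events$SI3))
  # output cell fires in response to the relay cells and only to them
  preceded <- vapply(rs, function(t) any(sis <= t & sis > t - 5), logical(1))
  answered <- vapply(sis, function(t) any(rs >= t & rs < t + 5), logical(1))
  expect_gt(mean(preceded), 0.98)
  expect_gt(mean(answered), 0.9)
  # each relay cell tracks the slow-stream rate
  expect_equal(unname(bundle$stats$rates[c("SI1", "SI2", "SI3")]),
               rep(22, 3), tolerance = 0.05)
})
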