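test_that("spike detection finds injected crossings and nothing else", {
  t <- seq(0, 100, 0.05)
  v <- rep(-65, length(t))
  for (s in c(20, 45, 80)) v[t >= s & t < s + 1] <- 30
  expect_equal(detectSpikes(t, v), c(20, 45, 80), tolerance = 0.06)
  expect_length(detectSpikes(t, rep(-65, length(t))), 0)
  # refractory filter: a burst of near-coincident crossings collapses
  v2 <- rep(-65, length(t))
  for (s in c(20, 20.5, 21, 40)) v2[abs(t - s) < 0.1] <- 30
  expect_equal(length(detectSpikes(t, v2, min_separation = 2)), 2)
})

test_that("spike detection is threshold-robust on simulated traces", {
  fx <- fix_fs2in()
  v <- getTrace(fx$sim, "FS.V")
  n0 <- length(detectSpikes(fx$sim$time, v, threshold = 0))
  n10 <- length(detectSpikes(fx$sim$time, v, threshold = -10))
  expect_equal(n0, n10)
})

test_that("burst grouping follows the gap rule", {
  b <- groupBursts(c(0, 5, 10, 60, 65), intra_gap = 15)
  expect_equal(b$onset, c(0, 60))
  expect_equal(b$count, c(3L, 2L))
  b1 <- groupBursts(42)
  expect_equal(b1$onset, 42)
  expect_equal(b1$count, 1L)
  expect_length(groupBursts(numeric(0))$onset, 0)
})

test_that("burst grouping of IB trains is insensitive to the gap threshold", {
  fx <- fix_fsib40()
  ref <- groupBursts(fx$iba, 15)
  for (gap in c(11, 20, 35, 48))
    expect_identical(groupBursts(fx$iba, gap)$onset, ref$onset)
})

test_that("firing rate is count over duration", {
  ev <- seq(0.5, 999.5, length.out = 10)
  expect_equal(firingRate(ev, c(0, 1000)), 10)
  expect_error(firingRate(ev, c(5, 5)), "empty window")
})

test_that("transient exclusion trims and warns", {
  expect_equal(excludeTransient(c(100, 1100, 2100), 1000), c(1100, 2100))
  expect_equal(excludeTransient(c(1, 2, 3), 0), c(1, 2, 3))
  expect_warning(excludeTransient(c(1, 2), 10), "transient")
  expect_equal(transientCutoff(61.14, K = 3), 1000)   # floor dominates
  expect_equal(transientCutoff(500, K = 4), 2000)
})

test_that("firing probability by phase handles full and empty bins", {
  trg <- seq(0, 1000, 25)
  ref <- seq(0, 1000, 60)
  # events after every trigger pulse: probability one wherever defined
  h <- firingProbabilityVsPhase(trg + 1, trg, ref)
  expect_true(all(h$prob[h$n_pulses > 0] == 1))
  # empty bins are undefined, not zero
  expect_true(all(is.na(h$prob[h$n_pulses == 0])))
})

test_that("mode-locking detection identifies ratios and negative controls", {
  s <- seq(0, 5000, 20)
  ev <- s[seq(1, length(s), 5)] + 1           # every 5th pulse
  ml <- modeLockRatio(ev, s)
  expect_equal(c(ml$p, ml$q), c(1L, 5L))
  expect_true(ml$phase_locked)
  # reducible window counts report coprime p:q
  ev2 <- s[seq(1, length(s), 2)] + 1          # 2 per 4 -> 1:2
  ml2 <- modeLockRatio(ev2, s)
  expect_equal(c(ml2$p, ml2$q), c(1L, 2L))
  # jittered events: no lock
  set.seed(2)
  ev3 <- sort(runif(120, 0, 5000))
  ml3 <- modeLockRatio(ev3, s)
  expect_true(is.na(ml3$p))
  # consistency: a detected p:q pins the rate
  expect_equal(firingRate(ev, range(s)), (1 / 5) * 50, tolerance = 0.01)
})

test_that("interburst map records lags, intervals and counts", {
  b <- groupBursts(c(0, 3, 60, 63, 120, 123, 180), intra_gap = 10)
  sp <- c(20, 80, 140)
  im <- interburstMap(b, sp)
  expect_equal(im$ib_si, c(20, 20, 20))
  expect_equal(im$ib_ib, c(60, 60, 60))
  expect_equal(im$count_open, c(2, 2, 2))
  expect_true(all(im$ib_si < im$ib_ib))
  # intervals with missing or duplicate spikes are dropped with a warning
  expect_warning(im2 <- interburstMap(b, c(20, 25, 140)), "excluded")
  expect_equal(nrow(im2), 1)
})

test_that("phase-map iteration finds fixed points and stability", {
  # constant map: immediate fixed point
  r0 <- phaseMapIterate(function(phi) 58, T_SI = 58, phi0 = 20, n = 5)
  expect_false(r0$diverged)
  expect_equal(r0$fixed_point, 20)
  # linear map: closed-form fixed point and geometric rate
  a <- 40; bslope <- 0.6; T_SI <- 58
  r1 <- phaseMapIterate(function(phi) a + bslope * phi, T_SI, phi0 = 5,
                        n = 200)
  expect_equal(r1$fixed_point, (T_SI - a) / bslope, tolerance = 1e-6)
  expect_equal(r1$slope, bslope, tolerance = 1e-6)
  expect_true(r1$stable)
  # leaving the domain is reported as divergence
  r2 <- phaseMapIterate(function(phi) 10, T_SI = 200, phi0 = 5, n = 10,
                        domain = c(0, 100))
  expect_true(r2$diverged)
})

test_that("reset alignment groups values by burst spike count", {
  t <- seq(0, 1000, 0.5)
  x <- sin(2 * pi * t / 100)                    # synthetic state trace
  traces <- cbind(x = x)
  b <- groupBursts(c(100, 102, 300, 500, 502, 504, 700), intra_gap = 10)
  ra <- resetAlignment(t, traces, b, t0 = 20)
  expect_true(all(c("x", "count") %in% colnames(ra$at_onset)))
  expect_equal(sort(unique(ra$at_onset$count)), c(1, 2, 3))
  expect_equal(ra$at_onset$x, sin(2 * pi * b$onset / 100), tolerance = 1e-2)
})

test_that("rate sweeps record per-point failures without aborting", {
  out <- rateVsFrequencySweep(c(10, 20, 30), function(f) {
    if (f == 20) stop("boom")
    ev <- seq(0, 1000, by = 1000 / f)
    attr(ev, "span") <- c(0, 1000)
    ev
  })
  expect_true(is.na(out$rate[2]))
  expect_match(out$error[2], "boom")
  expect_equal(out$rate[c(1, 3)], c(10, 30), tolerance = 0.11)
})
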