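test_that("phase lookup matches modulo for periodic and scan for jittered", {
  t_per <- seq(0, 600, by = 60)
  expect_equal(phaseOf(130, t_per), 10)
  expect_equal(phaseOf(t_per[3], t_per), 0)
  expect_error(phaseOf(-1, t_per), "undefined")
  set.seed(4)
  t_j <- cumsum(c(0, runif(40, 50, 70)))
  x <- runif(60, 0, max(t_j))
  scan <- vapply(x, function(xx) xx - max(t_j[t_j <= xx]), numeric(1))
  expect_equal(phaseOf(x, t_j), scan)
})

test_that("the gating rule fires exactly as the brute-force scan does", {
  for (cse in list(list(T1 = 25, c = 16, m = 2, T2 = 61.13),
                   list(T1 = 25, c = 17, m = 2, T2 = 61.14),
                   list(T1 = 14, c = 20, m = 3, T2 = 47.3))) {
    par <- abstractParams(cse$T1, cse$c, cse$m, T2 = cse$T2)
    rec <- simulateAbstract(par, horizon = 4000)
    bf <- .brute_force_rule(cse$T1, cse$c, cse$m, rec$t_seq, par$s1, 4000)
    expect_identical(rec$u, bf)
  }
})

test_that("degenerate gating limits behave as stated", {
  # no gating at all: fires on every fast pulse
  par <- abstractParams(25, 0, 1, T2 = 61.14, s1 = 0)
  rec <- simulateAbstract(par, horizon = 3000)
  expect_identical(rec$u, rec$s)
  # horizon before the second slow pulse is an error
  expect_error(simulateAbstract(abstractParams(25, 17, 2, T2 = 61.14), 30),
               "empty")
})

test_that("the canonical record fires once per slow period inside the window", {
  fx <- fix_abstract_ref()
  rec <- fx$rec
  per <- tabulate(findInterval(rec$u, rec$t_seq), nbins = length(rec$t_seq))
  covered <- rec$t_seq < max(rec$u) - 61.14
  expect_true(all(per[covered] == 1))
  expect_true(all(rec$phase >= 17))
  expect_true(all(rec$phase < 17 + 25))
  rep <- verifyTheorem(rec)
  expect_true(rep$all_pass)
  expect_equal(rep$K, 3)
})

test_that("entrainment conditions and margins are computed correctly", {
  expect_true(checkConditions(T1 = 25, c = 16, m = 2, gaps = 61.13)$ok)
  # c = 0 fails the upper condition whenever gaps exceed m*T1
  expect_false(checkConditions(T1 = 25, c = 0, m = 2, gaps = 55)$ok)
  # gap spread of at least (m-1)*T1 admits no c at all
  gaps <- c(51, 51 + 25)
  for (c in seq(0, 60, 0.5))
    expect_false(checkConditions(T1 = 25, c = c, m = 2, gaps = gaps)$ok)
})

test_that("transient bound evaluates its closed form", {
  expect_equal(transientBoundK(25, 16, 2, 61.13), 3L)
  expect_equal(transientBoundK(25, 11, 2, 55, 64), 7L)     # ceil(28/5)+1
  expect_equal(transientBoundK(25, 35, 2, 60, 60), 1L)     # sup = c + T1
  expect_error(transientBoundK(25, 10, 2, 49), "inf_gap")
})

test_that("frequency-range formulas match their published endpoints", {
  expect_equal(round(f2Range(40, 2, 0.016), 2), c(lower = 15.15, upper = 20))
  expect_equal(round(f2Range(45, 2, 0.016), 2), c(lower = 16.54, upper = 22.5))
  expect_equal(round(f2Range(40, 2, 0.01325), 2), c(lower = 15.81, upper = 20))
  r1 <- f1Range(16.357, 2, 0.016)
  expect_equal(round(unname(r1), 2), c(32.71, 44.31))
  # degenerate: c = 0 collapses the interval
  r0 <- f1Range(20, 2, 0)
  expect_true(r0["lower"] >= r0["upper"])
  expect_error(f1Range(20, 2, 0.06), "c \\* f2")
})

test_that("the two frequency ranges are duals of each other", {
  set.seed(9)
  for (i in 1:200) {
    m <- sample(2:4, 1)
    c <- runif(1, 0.005, 0.03)
    f1 <- runif(1, 20, 80)
    f2 <- runif(1, 5, f1)
    if (c * f2 >= 1) next
    r2 <- f2Range(f1, m, c)
    r1 <- f1Range(f2, m, c)
    in2 <- f2 >= r2["lower"] && f2 < r2["upper"]
    in1 <- f1 > r1["lower"] && f1 <= r1["upper"]
    expect_equal(in1, in2,
                 label = sprintf("duality at f1=%.2f f2=%.2f m=%d c=%.4f",
                                 f1, f2, m, c))
  }
})

test_that("unrestricted (m = 1) rate matches the closed form asymptotically", {
  th <- asymptoticRateM1(25, 61.14, 17)
  expect_equal(th$rate_hz, 1000 * (1 / 25) * (1 - 17 / 61.14))
  expect_equal(round(th$rate_hz, 2), 28.88)
  # c = 0: full fast rate
  expect_equal(asymptoticRateM1(25, 61.14, 0)$rate_hz, 40)
  # long-run empirical rate converges (irrational-like ratio)
  par <- abstractParams(25, 17, 1, T2 = 61.14, s1 = 17)
  rec <- simulateAbstract(par, horizon = 5e4 * 25)
  n <- length(rec$u)
  expect_equal(1000 * n / rec$u[n], th$rate_hz, tolerance = 2e-3)
  # rational ratio: empirical limit within 1/(q*T1) of the formula
  thr <- asymptoticRateM1(25, 62.5, 17)            # T1/T2 = 2/5
  expect_equal(c(thr$p, thr$q), c(2L, 5L))
  par_r <- abstractParams(25, 17, 1, T2 = 62.5, s1 = 17)
  rec_r <- simulateAbstract(par_r, horizon = 2e4 * 25)
  n_r <- length(rec_r$u)
  expect_lt(abs(1000 * n_r / rec_r$u[n_r] - thr$rate_hz), thr$bound_hz)
})

test_that("gating parameters are recoverable from a simulated record", {
  fx <- fix_abstract_ref()
  est <- estimateMC(fx$rec$u, 25, fx$rec$t_seq, bin = 1)
  expect_equal(est$m_hat, 2L)
  expect_true(est$c_hat >= 16 && est$c_hat <= 18)
  expect_error(estimateMC(fx$rec$u[1:10], 25, fx$rec$t_seq),
               "insufficient")
})

test_that("theorem conclusions hold over random admissible parameter draws", {
  set.seed(101)
  for (i in 1:200) {
    par <- randomAdmissibleParams(n_periods = 50)
    expect_true(checkConditions(par)$ok)
    rec <- simulateAbstract(par, horizon = max(par$t_seq))
    rep <- verifyTheorem(rec)
    expect_true(rep$all_pass, label = sprintf("draw %d", i))
    # the bound never exceeds its coarser closed-form relaxation
    cc <- checkConditions(par)
    expect_lte(rep$K, ceiling(2 / (1 - par$m * par$T1 / cc$inf_gap)))
  }
})

test_that("a condition violation can break the phase-window conclusion", {
  # slow gaps alternating well outside the admissible band
  t_seq <- cumsum(c(0, rep(c(52, 95), 25)))
  par <- abstractParams(25, 16, 2, t_seq = t_seq, s1 = 16)
  expect_false(checkConditions(par)$ok)
  rec <- simulateAbstract(par, horizon = max(t_seq))
  rep <- verifyTheorem(rec)
  expect_false(rep$all_pass)
})

test_that("records serialize to the two-column text format", {
  fx <- fix_abstract_ref()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeFiringRecord(fx$rec, f)
  back <- read.delim(f)
  expect_equal(back$firing_time_ms, fx$rec$u, tolerance = 1e-8)
  expect_equal(back$phase_ms, fx$rec$phase, tolerance = 1e-8)
})
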