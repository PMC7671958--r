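# Shared simulation fixtures, computed on first use and cached for the
# whole test session (several test files reuse the same runs).
.pg_test_cache <- new.env(parent = emptyenv())

pg_cached <- function(key, fn) {
  if (!exists(key, envir = .pg_test_cache))
    assign(key, fn(), envir = .pg_test_cache)
  get(key, envir = .pg_test_cache)
}

# canonical driven three-cell run: 40 Hz, 12 s
fix_fsib40 <- function() pg_cached("fsib40", function() {
  spec <- buildNetwork("fs_si_ib")
  i1 <- pulseTrain(40, 0, 12000)
  sim <- simulateNetwork(spec, list(input1 = i1), 12000)
  si <- excludeTransient(sim$spikes$SI, 2000)
  iba <- excludeTransient(sim$spikes$IBa, 2000)
  bursts <- groupBursts(iba, 15)
  list(spec = spec, i1 = i1, sim = sim, si = si, iba = iba, bursts = bursts)
})

# two-cell network with independent 40 / 16.357 Hz drives, 10 s
fix_fs2in <- function() pg_cached("fs2in", function() {
  spec <- buildNetwork("fs_si_2inputs")
  i1 <- pulseTrain(40, 0, 10000)
  i2 <- pulseTrain(16.357, 0, 10000)
  sim <- simulateNetwork(spec, list(input1 = i1, input2 = i2), 10000)
  list(spec = spec, i1 = i1, i2 = i2, sim = sim,
       si = excludeTransient(sim$spikes$SI, 1000),
       fs = excludeTransient(sim$spikes$FS, 1000))
})

# driven four-cell network, 12 s
fix_full40 <- function() pg_cached("full40", function() {
  spec <- buildNetwork("full4")
  i1 <- pulseTrain(40, 0, 12000)
  sim <- simulateNetwork(spec, list(input1 = i1), 12000)
  list(spec = spec, i1 = i1, sim = sim,
       rs = excludeTransient(sim$spikes$RS, 2000),
       si = excludeTransient(sim$spikes$SI, 2000),
       bursts = groupBursts(excludeTransient(sim$spikes$IBa, 2000), 15))
})

# reference abstract-model record (canonical gating parameters)
fix_abstract_ref <- function() pg_cached("abs_ref", function() {
  par <- abstractParams(T1 = 25, c = 17, m = 2, T2 = 61.14)
  rec <- simulateAbstract(par, horizon = 500 * 61.14)
  list(par = par, rec = rec)
})

# strict alternation fraction of two event streams
alternation <- function(a, b) {
  ev <- rbind(data.frame(t = a, w = "a"), data.frame(t = b, w = "b"))
  ev <- ev[order(ev$t), ]
  mean(ev$w[-1] != ev$w[-nrow(ev)])
}

# literal per-pulse rule: iterate every fast pulse, track the last firing
.brute_force_rule <- function(T1, c, m, t_seq, s1, horizon) {
  s <- seq(s1, horizon, by = T1)
  fired <- logical(length(s))
  last <- -Inf
  for (l in seq_along(s)) {
    ph <- s[l] - max(t_seq[t_seq <= s[l]])
    if (ph >= c && (l - last) >= m) {
      fired[l] <- TRUE
      last <- l
    }
  }
  s[fired]
}


# Term-by-term oracle: each ionic current computed by its own small
# function, summed independently of membraneDerivative().
.oracle_dvdt <- function(state, p, I_syn = 0, I_el = 0, I_ext = 0) {
  kin <- gatingFunctions(p)
  V <- state[["V"]]
  i_leak <- p[["gL"]] * (V - p[["VL"]])
  i_na <- p[["gNa"]] * kin$m0(V)^3 * state[["hNa"]] * (V - p[["VNa"]])
  i_k <- p[["gK"]] * state[["mK"]]^4 * (V - p[["VK"]])
  i_ar <- p[["gAR"]] * state[["mAR"]] * (V - p[["VAR"]])
  i_km <- p[["gKM"]] * state[["mKM"]] * (V - p[["VKM"]])
  i_cah <- p[["gCaH"]] * state[["mCaH"]]^2 * (V - p[["VCaH"]])
  unname(-(p[["J"]] + I_syn + I_el + I_ext +
             i_leak + i_na + i_k + i_ar + i_km + i_cah) / p[["C"]])
}

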