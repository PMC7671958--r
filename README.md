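# pulsegate

Simulation and analysis of multi-rhythm interaction in a small cortical
network: how a cell driven by two unrelated periodic pulse streams can fire
*in phase with the fast stream but at the rate of the slow one*, and how a
high-dimensional bursting cell becomes describable by a one-dimensional
phase map because its slow state resets at every burst.

The package is aimed at computational neuroscientists studying rhythm
interaction (beta1/gamma range here, but the mechanism is scale-free). It
provides the same system at four levels of description:

1. **`simulateNetwork()`** — a compiled fixed-step integrator for
   Hodgkin–Huxley-type networks of the four cell classes studied (regular
   spiking, fast spiking, slow inhibitory, and a four-compartment
   intrinsically bursting cell), with chemical synapses, gap junctions and
   pulsatile external drives. `buildNetwork()` assembles the full four-cell
   circuit and its successive reductions (`fs_si_ib`, `fs_si_2inputs`,
   `si_only`, `multiplex3`).
2. **`simulateLIF()`** — a leaky integrate-and-fire unit with an inhibitory
   autapse and two pulse inputs: the minimal continuous model with the
   gating behavior.
3. **`simulateAbstract()`** — the discrete pulse-gating rule: with fast
   pulses every `T1` ms, slow pulses at times `t_n`, refractory
   multiplicity `m` and effective inhibition time `c`, the cell fires at
   the earliest fast pulse at least `m*T1` after its last firing whose time
   since the last slow pulse is at least `c`. Whenever
   `inf(t_{n+1}-t_n) > max(m*T1, c+T1)` and `sup(t_{n+1}-t_n) <= m*T1 + c`
   (`checkConditions()`), the cell fires exactly once per slow period, with
   all firing phases in `[c, c+T1)` after at most
   `K = ceil((sup_gap - (c+T1))/(inf_gap - m*T1)) + 1` slow cycles
   (`transientBoundK()`, `verifyTheorem()`). `f2Range()`/`f1Range()` give
   the admissible frequency bands; `asymptoticRateM1()` the unrestricted
   (`m = 1`) rate `(1/T1)(1 - c/T2)`.
4. **Analysis layer** — spike/burst detection, rates, firing-probability
   versus phase, `p:q` mode-lock detection with circular phase dispersion,
   interburst-interval maps and their return-map iteration
   (`phaseMapIterate()`), and slow-variable reset diagnostics
   (`resetAlignment()`, `slowVariables()`).

`pulseTrain()` generates the drives (exactly periodic, or with normally
distributed interpulse intervals), and `runExperiment()`/`runSweep()`
orchestrate the registered end-to-end scenarios (`listScenarios()`).

## Worked example

Drive the three-cell reduction (fast-spiking, slow inhibitory and bursting
cell) with a 40 Hz pulse train and measure the interaction:

```r
library(pulsegate)

i1   <- pulseTrain(40, 0, 12000)          # 40 Hz, exactly periodic, 12 s
spec <- buildNetwork("fs_si_ib")
sim  <- simulateNetwork(spec, list(input1 = i1), duration = 12000)

si <- excludeTransient(sim$spikes$SI, 2000)
ib <- groupBursts(excludeTransient(sim$spikes$IBa, 2000), 15)
sprintf("SI rate: %.2f Hz, IB burst rate: %.2f Hz",
        firingRate(si, c(2000, 12000)), firingRate(ib$onset, c(2000, 12000)))
#> "SI rate: 17.20 Hz, IB burst rate: 17.10 Hz"

modeLockRatio(ib$onset, i1$times[i1$times >= 2000])
#> mode_lock_stats: 3:7 lock, phase s.d. 7.93 ms (not phase-locked)
```

Both cells run at 3/7 of the drive frequency (17.14 Hz): the slow cell
fires in phase with the 40 Hz input but skips cycles, the burster
alternates strictly with it, and although the burst *rate* locks to the
input, the burst *phases* stay dispersed — mode-locking without
phase-locking.

The discrete model shows the same entrainment with everything else
stripped away, and its transient bound and phase window can be certified:

```r
par <- abstractParams(T1 = 25, c = 17, m = 2, T2 = 61.14)
rec <- simulateAbstract(par, horizon = 300 * 61.14)
rec
#> firing_record: 300 firings over 734 input-1 pulses (18325.0 ms)
#>   mean rate 16.3388 Hz, phases in [17.00, 41.98] ms
verifyTheorem(rec)
#> theorem_report: K = 3
#>   part (a): pass
#>   part (b): pass
#>   part (c): pass
f2Range(40, 2, 0.016)     # admissible slow-drive band at a 40 Hz fast drive
#>    lower    upper
#> 15.15152 20.00000
```

One firing per slow period, all phases inside a 25 ms window opening at
`c = 17` ms, guaranteed after `K = 3` slow cycles; the slow-drive frequency
may sit anywhere in [15.15, 20) Hz.

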