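# patrans

Monte Carlo and exact first-passage analysis of **polyampholyte
translocation through the asymmetric alpha-hemolysin pore**.

Most proteins — and essentially all intrinsically disordered proteins
(IDPs) — are polyampholytes: chains carrying both positive and negative
charges. When such a chain is driven through a nanopore by an applied
potential, its fate is controlled not just by its net charge Q but by the
*arrangement* of charges along the sequence: antagonistic blocks build
free-energy barriers inside the pore that can delay or trap the chain
essentially forever. `patrans` is for researchers studying this
sequence-selectivity: it simulates the whole-chain Metropolis hopping
dynamics of a ±1 charge sequence on the one-dimensional free-energy
landscape of alpha-hemolysin under +150 mV, and solves the same dynamics
exactly as an absorbing birth–death Markov chain.

## The model in brief

A chain of N unit charges q_i = ±1 (favorable units; +1 is the species
driven through the pore) occupies sites spaced a = 2 nm along the pore
axis. At chain offset x, monomer i sits at site s = (4 + x) − i
(cis-to-trans engagement); sites −1..5 carry tabulated per-species free
energies, the bulks contribute 0 (cis) or ∓V (trans, V = e·150 mV/kBT =
5.84). The landscape is

    E(x) = Σ_i  f(q_i, s_i(x)),   x = −6 … N+1,

with absorbing states at x = −6 (rejection) and x = N + 1
(translocation). One Monte Carlo time step (MCT) attempts a whole-chain
hop of ±a, accepted with the Metropolis probability min(1, e^(−ΔE)); a
chain still engaged after the waiting time tw = 1.6×10⁵ MCT is *trapped*.
The equivalent birth–death chain with p(x) = ½ min(1, e^(−[E(x+1)−E(x)]))
gives exact splitting probabilities, absorption-time distributions and
first-passage moments against which the Monte Carlo engine is verified.

On top sit ensemble statistics (translocation/rejection-time PDFs and
their power-law tail exponents, trapped-population decay, outcome rates
resolved by Q, the head-window charge Qh and the minimum pore-window
charge Qmin) and the closed-form disorder theory: the disorder parameter
μ solving ⟨e^(−qμU)⟩ = 1, crossover lengths, barrier scales, the diblock
contribution exp(UN/2 − N ln 2) and the net-charge criterion
Q/N > 1 − 2 ln 2/U, with predicted tail exponents −(1+μ).

## Worked example

```r
library(patrans)

# the benchmark panel: N = 20, Q = 8 sequences with different block
# structure, plus the two engagements of the IDP integrase reduction
refs <- reference_sequences()
cfg  <- sim_config(tw = 1.6e5, trials = 10000, seed = 42)

mc <- run_batch(refs, cfg)
mc$summary[, c("id", "Qh", "Qmin", "pct_translocated", "pct_trapped",
               "mean_ttr", "sd_ttr")]
#> id    Qh  Qmin pct_translocated pct_trapped mean_ttr sd_ttr
#> a      3     1            85.7         0.0       67.0    17.7
#> b      1     1            54.7         0.0     1008.8   828.0
#> c      1     1            64.5         0.0      333.9   161.6
#> d      1    -1            54.0         0.0     2121.5  1499.0
#> e      1     1            28.7         0.0     4073.9  2352.2
#> f      1    -1            25.0        53.5    70905.5 45139.3
#> g      3    -1            98.9         0.0     1606.6  1439.6
#> h      3    -1            83.4         0.0     4734.2  4562.4
#> i      1    -1            23.1         0.0     6522.5  5868.1
```

Reading the output: the regular sequence (a) rushes through in ~67 MCT;
one antagonistic pair (b) costs a factor ~15 in time; the same pair
crossed from the other end (c) only a factor ~5 — the pore is asymmetric;
a triple block near the head (f) traps half of all attempts for the whole
1.6×10⁵-MCT waiting time, while the same block met late (g) lets 99%
through. Exactly the same numbers, without sampling noise, come from the
exact solver:

```r
classify_batch(refs, cfg)[, c("id", "P_tr", "P_trap", "mean_ttr")]
#> a 0.848 0.000    66.8
#> f 0.258 0.524 72011.6   # etc.
```

Ensemble work uses the same verbs on generated sequence tables:

```r
seqs <- sample_sequences(20, 5000, seed = 71001)        # unbiased ensemble
b    <- run_batch(seqs, sim_config(trials = 4, seed = 71002))
100 * mean(b$events$outcome == "translocated")          # 8.41 %
pdf  <- time_pdf(b$events, dt = 1600)
glance(tail_exponent(pdf))                              # slope -0.94 +/- 0.10
autoplot(pdf)
percentile_times(b$events, fractions = (1:4)/100)       # 400, 800, ... MCT
theory_table(Q = 12, N = 20, U = 6)                     # mu, n_d, n_c, ...
```

A thin command-line interface wrapping these functions is installed at
`inst/scripts/patrans` (subcommands `simulate`, `exact`, `stats`,
`theory`, `reduce`, `fixtures`).

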