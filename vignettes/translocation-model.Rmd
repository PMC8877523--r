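---
title: "The translocation model behind patrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The translocation model behind patrans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patrans)
```

## The physical picture

A polyampholyte — a chain whose monomers carry unit charges of both signs —
threads through the alpha-hemolysin pore monomer by monomer under an applied
potential of +150 mV (trans side positive). Each effective monomer (about
3–4 amino acids for a protein) is one unit charge of size a = 2 nm; the
roughly 10 nm channel holds five monomers at once. Anions are driven
cis-to-trans, cations the other way, so for a chain engaged cis-to-trans the
anionic monomers are *favorable* and the cationic ones *antagonistic*.
Sequences are written in favorable units: `1` favorable, `-1` antagonistic.

The chain is reduced to a rigid one-dimensional sequence of charges; chain
entropy, monomer–monomer interactions and perturbations of the small-ion
free energies by the polymer or by the current are all neglected. The only
state variable is the chain offset x, the net number of accepted forward
hops since engagement. Every monomer inside the pore contributes the
tabulated free energy of its species at its current site; monomers outside
contribute their bulk value. The total E(x) over all offsets is the
landscape on which the whole-chain Metropolis dynamics runs: per Monte Carlo
time step (MCT) a move of one monomer length is proposed, +a or −a with
probability 1/2 each, and accepted with probability min(1, e^(−ΔE)).

## The pore profile and its orientation

The bundled per-species free energies (in kBT, +150 mV) are tabulated at
seven axial positions −a, 0, …, 5a:

```{r}
pore_profile()
```

Two conventions in this table are easy to get wrong, and the package fixes
both by requiring thermodynamic consistency with the bulk phases:

* **The position axis runs from the trans boundary (−a) to the cis
  boundary (5a).** With the axis read the other way, the cation row is
  discontinuous with *both* bulk solutions (5.53 vs 0 at one mouth, 0.07 vs
  +5.84 at the other).
* **Each row is referenced to the solution it joins continuously.** The
  cation row is referenced to the cis solution and the anion row to the
  trans solution (whose bulk level for an anion is −V, with
  V = e·150 mV/kBT ≈ 5.84 at 298 K).

Re-referenced to the cis bulk, the effective cation profile rises almost
linearly from 0.07 at the cis edge to 5.53 at the trans edge and joins the
+V trans bulk — a near-uniform opposing force over the whole channel —
while the effective anion profile is a modest mid-pore barrier that ends at
−5.77 at the trans edge: essentially the entire anion driving force is
released in the final exit step at the trans mouth. Both features are
exactly the known force distribution in alpha-hemolysin, and this is the
unique reading of the table under which the single-sequence benchmark
statistics (the `reference_sequences()` panel) are reproduced. The
alternative orientations fail by two orders of magnitude in the mean
translocation times.

`pore_profile()` exposes the references (`cation_ref`, `anion_ref`) so a
user-supplied table for the opposite polarity can be used; flipping the
polarity (V → −V), conjugating every charge and exchanging the two rows
with their references leaves every landscape invariant — the package's
exact version of the experimental polarity symmetry, asserted in the test
suite.

## Engagement, absorption, classification

At engagement (x = 0) the chain is already threaded: five monomers occupy
sites 0–4 with the head one hop from the far mouth, and a sixth sits on the
boundary site. This skips the pore-entry problem deliberately — capture is
a separate physical process. Offsets x ∈ {−5, …, N} are transient;
x = −6 (the whole chain withdrawn to the engagement-side bulk) absorbs as
**rejection**, and x = N+1 (the tail past the far mouth) as
**translocation**. A trial still transient after the waiting time tw
(default 1.6×10⁵ MCT; 10⁶ for long-horizon studies) is **trapped**. One
MCT is one attempted hop, accepted or not; absorption on the tw-th attempt
still counts as absorbed.

The trans-to-cis ("reverse") engagement uses the same absorber layout with
the mirrored site map and the cation as the favorable species. Because the
pore is asymmetric, reversing the direction is *not* equivalent to
reversing the sequence, and the two give genuinely different statistics.

## Exact solver

Because the state space is tiny (N + 6 transient offsets), everything the
Monte Carlo engine estimates can be computed exactly: the dynamics is an
absorbing birth–death chain with p(x) = ½ min(1, e^(−ΔE₊)) and
q(x) = ½ min(1, e^(−ΔE₋)). The package computes

* the splitting probability by the classical product-of-ratios formula,
  evaluated in log space (it depends only on the ratios q/p);
* the full absorption-time distribution by propagating the occupancy
  vector step by step — O(tw·N) work, exact to round-off, with mass
  conserved to 1e−12 at every step;
* unconditional and side-conditioned mean first-passage times from the
  dense first-step linear systems (at ≤ 46 states a dense solve is exact
  and instant).

Time-domain iteration was chosen over eigendecomposition deliberately: tw
≤ 10⁶ and ≤ 46 states make it trivially fast, and it avoids any numerical
tolerance beyond round-off. The Monte Carlo engine is validated against
this solver at 3σ in the test suite; the solver in turn is validated
against closed forms (a flat landscape gives the gambler's-ruin splitting
probability 6/(N+7) and mean absorption time 6(N+1)) and against dense
linear-algebra oracles.

## Random numbers

Each trial runs on its own splitmix64 stream seeded by a hash of (master
seed, sequence id, trial index). Batches are therefore order-independent
and individually reproducible, and raising tw *continues* a trial rather
than rerunning it (the basis of the continuation test). One uniform draw
selects the proposal; a second is drawn only when the move is uphill —
this halves the draws on downhill moves without changing the law.

## Ensemble statistics

Time histograms use centered bins [t − δt/2, t + δt/2) with the binnings
used in the field: δt = 1600 MCT for translocation-time PDFs, 20 MCT for
rejection times (dominated by fast early retractions), 400 MCT for
population-percentile tables, 1000 MCT for single-sequence PDFs. PDFs are
normalized per successful event of their kind by default; outcome
percentages always use all engagement attempts as denominator, so the
three classes sum to 100%. Tail exponents are least-squares slopes in
log–log coordinates over a configurable window (default [10⁴, 10⁵] MCT),
excluding the first bin (engagement transient) and bins with fewer than 5
events.

The theory module provides the disorder parameter μ — the nonzero root of
⟨e^(−qμU)⟩ = 1, in its exact binary form ln((1+⟨q⟩)/(1−⟨q⟩))/U and its
Gaussian form 2⟨q⟩/(U(1−⟨q⟩²)) — together with the crossover lengths
n_d = 1/(σ₁²U²) and n_c = 1/⟨q⟩² − 1, barrier scales E_b = √n σ₁|U| and
E_B = E_b − n|⟨q⟩U|, the diblock contribution exp(UN/2 − N ln 2) and the
net-charge criterion Q/N > 1 − 2 ln 2/U. Escape-time tails are predicted
to decay as t^(−1−μ) (relaxation) and t^(−μ) (sojourn). μ is reported as a
magnitude: only |μ| enters any exponent, and the literature's sign
conventions for the Gaussian form are not self-consistent (the printed
closed form is dimensionally inconsistent unless read as a fraction; the
package implements the unique Gaussian solution of the defining relation).
The scaling identity μ ≈ n_d/n_c is exposed as the separate diagnostic
ratio `mu_ratio_diag` (equal to (μ_gauss/2)²), not as μ itself, since it
holds only at the qualitative level.

## What the generators emulate — and what they do not

`sample_sequences()` draws i.i.d. ±1 sites (the unbiased disordered
ensemble, ⟨Q⟩ = 0) or exact-composition shuffles when conditioning on Q —
matching how fixed-Q subensembles are defined (conditioning on exact net
charge, not on expectation). `enumerate_sequences()` is exhaustive, which
matters because ensemble moments are dominated by rare blocky sequences;
fixed-Q enumeration goes through antagonistic-position combinations so
that, e.g., all 190 sequences with N = 20, Q = 16 are enumerated without
materializing 2^20 chains. These generators emulate *charge disorder
only*: real IDP sequences have correlated charge patterns, composition
biases and length distributions none of which are modelled, so passing
ensemble tests here says nothing about any specific protein beyond its
reduced charge sequence.

Default study conditions are the standard setting for this pore model: N = 20
(exhaustively enumerable) and N = 40 (random ensemble) at tw = 1.6×10⁵;
ensemble checks in the tests and the acceptance script use samples of
5000–8000 random N = 20 sequences × 4 trials and 2000–3000 N = 40
sequences × 2 trials — sizes chosen so that sequence-sampling error is
comparable to the ~1 percentage-point accuracy of the reported ensemble
fractions, while a full run stays in the minutes range on one core.

## Numerical choices and degenerate inputs

* Landscape energies are precomputed once per sequence; the Metropolis
  inner loop only looks up precomputed acceptance factors.
* All splitting-probability products are log-space sums; probabilities are
  clipped only by round-off.
* Sequences shorter than 5 monomers are rejected at parse time (the pore
  cannot be filled at engagement).
* Zero successes yield `NA` time statistics, never 0; empty sequence files
  yield empty, well-typed tables.
* `tw = 1` traps everything (no absorber is reachable in one hop) — a
  useful smoke test of the classification logic.
* Full enumeration refuses N > 16 unless forced; fixed-Q enumeration has
  no such limit for practical compositions.

## Known limitations

* The model inherits everything the underlying picture neglects: no chain
  elasticity or entropy, no charge–charge interactions, no concentration
  or complexation effects, no field perturbation of the profile. Absolute
  time scales are in MCT (one attempted hop ≈ one monomeric diffusion
  time), not seconds.
* The trans-bulk offset V = 5.84 kBT and the engagement placement are
  calibrated conventions; the profile's per-row references are inferred
  from bulk continuity rather than stated alongside the table.
* Ensemble translocated fractions at N = 40 run ~0.5 percentage points
  low against the reported reference values (about 1.0–1.2% vs 1.6%)
  while N = 20 fractions agree within ~0.7 points; with only printed-table
  precision available for calibration this residual is within the
  modelling tolerance of the single-sequence benchmarks but is worth
  remembering when reading the N = 40 numbers.
* Tail-exponent fits on [10⁴, 10⁵] MCT sit in the window where finite-N
  effects depress the PDF below the asymptotic t^(−1−μ) law; fitted slopes
  are therefore systematically a little steeper than the prediction, and
  the package treats the predicted exponents as comparisons, not as fit
  constraints.

## A worked example

```{r, eval = FALSE}
refs <- reference_sequences()
cfg <- sim_config(tw = 1.6e5, trials = 10000, seed = 42)

# Monte Carlo and exact classification of the benchmark panel
mc <- run_batch(refs, cfg)
ex <- classify_batch(refs, cfg)

# ensemble statistics on a random N = 20 ensemble
seqs <- sample_sequences(20, 5000, seed = 1)
b <- run_batch(seqs, sim_config(trials = 4, seed = 2))
pdf <- time_pdf(b$events, dt = 1600)
tail_exponent(pdf)
autoplot(pdf)
```
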