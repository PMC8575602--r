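# eegtda

Topological analysis of multichannel EEG evoked by two stimulus conditions
— an ordered Gestalt image (GST) versus a random-sequence diagram (RSD) —
for researchers studying whether the brain's functional network organizes
differently when a coherent contour is perceived.

The package turns band-limited post-stimulus epochs into per-trial
functional-connectivity matrices, sweeps a Vietoris–Rips filtration over
them, and summarizes the resulting persistence barcodes into scalar
topological features that can discriminate the two conditions:

* **Phase-locking connectivity (C-matrix).** Instantaneous phases come
  from the analytic signal; the phase-locking value between electrodes
  *p*, *q* is

      C_pq = | (1/N) Σ_n exp( j (φ_p(n) − φ_q(n)) ) |,   C_pp = 0.

* **Standardized-distance connectivity (D-matrix).**

      d(r, t) = Σ_k ( (r_k − t_k) / s_k )²,

  with `s_k` the cross-channel standard deviation at sample *k*.

* **Vietoris–Rips filtration** on normalized dissimilarity weights
  (`1 − C`, or min–max-scaled distances): a simplex (up to dimension 3)
  enters at the maximum pairwise weight among its vertices, swept over the
  scale ε.

* **Euler characteristic / entropy.** χ(ε) is the alternating simplex
  count, S(ε) = ln |χ(ε)|; the scale ε\* of the negative peak of S (the
  zero crossing of χ) is the *topological phase-transition point* of the
  network.

* **Persistent entropy.** With barcode lengths ℓ_i and p_i = ℓ_i / Σ ℓ_j,
  H = −Σ p_i log p_i, plus the rescalings H/log ℓ_max (as defined; sign
  pathologies surfaced, see the vignette) and H/log n_bars (the default
  classifier feature).

* **Discrimination.** A leave-one-trial-out threshold rule on the per-trial
  entropy yields a per-subject distinguishing rate; the per-condition
  medians of ε\* give the transition ordering.

Persistence is computed by boundary-matrix reduction over GF(2) (Rcpp, with
the clearing optimization), validated in the test suite against an
independent brute-force boundary-rank oracle. A seeded synthetic EEG
generator — amplitude-modulated band-limited oscillators with
condition-dependent shared-phase coupling (coherent 8-channel cluster under
GST, weak diffuse coupling under RSD) — makes the whole pipeline testable
end to end without external recordings, and can export sessions as
delimited text or 16-bit EDF.

## Worked example

```r
library(eegtda)
cfg <- session_config(seed = 1)           # 19 ch, 30 RSD + 10 GST trials
rec <- generate_session(cfg)
rec
#> EEG recording: 19 channels x 480000 samples @ 1000 Hz (480.0 s), 40 markers
#>   conditions: GST x10, RSD x30
fit <- eeg_tda(rec, bands = "alpha", kinds = c("C", "D"), subject_id = "demo")
fit
#> Topological EEG condition analysis [subject demo]
#>   classifier feature: H_alt, window 0-2 s @ 250 Hz
#>  band matrix_kind distinguishing_rate balanced_rate pe_direction  p_value
#> alpha           C                0.75           0.5      GST<RSD 0.000167
#> alpha           D                0.75           0.5      GST>RSD 0.650618
#>  transition_order
#>         GST_first
#>         RSD_first
```

Reading the output: the alpha-band phase-locking entropies separate the two
conditions strongly per trial (rank-test p ≈ 1.7e-4) and the Euler-entropy
transition point of GST trials comes before that of RSD trials
(`GST_first`) — the coherent cluster connects the GST network at smaller
scales. The plain distinguishing rate of 0.75 at balanced accuracy 0.5
shows the fixed-direction threshold rule falling back to the majority
class (30 of 40 trials are RSD); the vignette discusses why rate and
balanced accuracy must be read together. `plot(fit)` shows the per-trial
entropy stripcharts; `fit$features` holds the full per-trial table (H,
H-hat, H-alt, bar counts, ε\*).

## Command line

A thin CLI over the same functions lives at `inst/cli/eegtda.R`:

```sh
Rscript inst/cli/eegtda.R simulate --out session.tsv --seed 1
Rscript inst/cli/eegtda.R run-all --out results/ --seed 1 --bands alpha,theta --kinds C,D
```

## Layout

* `R/synthetic.R` — session configuration and the seeded generator
* `R/preprocess.R` — bands, zero-phase FIR filtering, decimation, epochs
* `R/connectivity.R` — analytic signal, PLV and distance matrices,
  filtration weights
* `R/topology.R`, `src/reduce.cpp` — Vietoris–Rips complexes, persistence,
  Betti/Euler curves, transition points
* `R/features.R` — persistent entropy and its rescalings
* `R/analysis.R` — discrimination, transition comparison, `eeg_tda()`,
  `run_study()`
* `R/io.R` — delimited text and EDF readers/writers
* `vignettes/eeg-topology-methods.Rmd` — the methods vignette
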