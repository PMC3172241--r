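# cpascene

Which known sound sources are present in a mixture? `cpascene` answers
this *recognition* question for auditory scenes: the observed signal at
each time step is a feature vector (typically a short-time magnitude
spectrum) modeled as a superposition of amplitude-modulated templates from
a large learned dictionary,

    s(t) = Σ_k a_k(t) b_k + η(t),

with each dictionary element `b_i` mean-subtracted and unit-normalized.
Instead of tracking the instantaneous amplitudes, the package estimates
one **presence parameter** `c_i` per element, constant over the scene and
ideally binary — 1 for every source that participates, 0 for the rest,
regardless of loudness. The estimate reconstructs each observation with
every element gated by its instantaneous similarity (projection)
`p_i(t) = ⟨s(t), b_i⟩`:

    ŝ(t) = Σ_i c_i p_i(t) b_i,   c = argmin Σ_t ‖s(t) − ŝ(t)‖².

This similarity gating makes the least-squares solution unique without
sparsity constraints and makes the presence parameters insensitive to
source intensity — a quiet source is still detected where loudness-based
template matching fails.

Two estimators expose the same solution:

* `fit_cpa()` — the batch corrected-projections fit (one `n × n` solve,
  with a condition estimate and a minimum-norm fallback for degenerate
  scenes);
* `run_icpa()` — a recursive estimator of the recursive-least-squares /
  Kalman family that processes observations one at a time, maintaining
  the presence parameters together with an uncertainty matrix `P`, and
  `large_n_fit()`, its matrix-free batch equivalent that handles
  dictionaries of tens of thousands of elements via conjugate gradients.

Around the core: synthetic scene and click-train generators, template
matching and PCA baselines, a WAV/spectrogram front end, a decomposition
of the recursive estimator's internals into two predicted classes of
cortical-unit activities (uncertainty units `|K_hi|` and parameter-error
units `|K_hi e_i|`) with adaptation statistics, and a command-line
interface for scripted experiments.

## Worked example

Two sources hidden in a 400-element dictionary, ten noisy observations:

```r
library(cpascene)

d     <- make_random_dictionary(n = 400, f = 200, "uniform01", seed = 42)
scene <- generate_scene(d, active_indices = c(17L, 230L), T_obs = 10,
                        noise_sd = 0.05, seed = 7)
est   <- large_n_fit(scene, d, p0_diag = 1)
est
#> <presence_estimate> 400 parameters | residual SSE 4.437
#>   largest: elem_0230=0.875, elem_0017=0.862, elem_0249=0.080, elem_0141=0.080, elem_0070=0.074
```

The two generating elements (17 and 230) carry presence parameters near 1
while the other 398 stay near 0: the mixture is *recognized*, not merely
reconstructed. The gap between ~0.87 and the ideal 1 is the combined
effect of the prior (`p0_diag`) and the dictionary's residual overlaps;
the ranking is what identification uses. The recursive estimator reaches
the same state one observation at a time:

```r
run_icpa(scene, d, p0_diag = 1)
#> <icpa_trajectory> 10 steps | n = 400, f = 200
#>   final top c: elem_0230=0.875, elem_0017=0.862, elem_0249=0.080
```

The audio pipeline, end to end on synthesized material — two harmonic
tones mixed at 10 dB SNR against a 400-element spectral dictionary:

```r
demo <- audio_demo_experiment(seed = 1, snr_db = 10)
head(demo$ranked, 4)
#>        label          c
#> 1     tone_a 1.05470860
#> 2     tone_b 1.04136907
#> 3 filler_043 0.11363233
#> 4 filler_250 0.09985271
```

Both tone templates top the ranking; the filler elements absorb only
low-level activation.

## Command line

```sh
Rscript inst/cli/cpascene reproduce circuit --seed 1 --out runs/circuit
Rscript inst/cli/cpascene efficiency --replicates 30 --seed 1 --out runs/eff
```

Every command writes its outputs plus a `manifest.json` with all
parameters and seeds; identical seeds give bit-identical outputs.

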