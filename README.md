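# bmsradar

Radar-based image reconstruction for **breast microwave sensing (BMS)** —
an imaging modality that probes the breast with microwaves and exploits the
dielectric contrast between malignant and healthy tissue. The package is
aimed at researchers developing or evaluating radar-style BMS
reconstruction: it implements the standard one-step beamformers, an
optimization-based reconstruction, the image-quality and detection metrics
used to compare them, and a synthetic monostatic scan simulator so the whole
pipeline runs and is testable without any measured data.

## What it computes

A monostatic scan records complex reflection coefficients S11(a, f) at
antenna positions *a* on a circular arc and frequencies *f*. Under a
homogeneous propagation speed *v*, the one-way time of flight is
t(r, a) = |r − a| / v and the first-order forward model for a reflectivity
profile σ(r) is

    S_fwd(a, f; σ) = ΔA Σ_r σ(r) exp(−2πj f · 2 t(r, a))

(midpoint-rule discretization, pixel area ΔA, round-trip factor 2t).

* **DAS** (delay-and-sum): I(r) = Σ_a Σ_f S(a, f) exp(+2πj f · 2t(r, a)) —
  the phase-compensating adjoint of the forward model.
* **DMAS** (delay-multiply-and-sum): per-frequency products of
  delay-compensated signal pairs from distinct antenna positions
  (autoproducts excluded), then summed.
* **ORR** (optimization-based radar reconstruction): gradient descent from
  the zero profile on the complex least-squares loss
  l(σ) = Σ_a Σ_f |S_fwd(a, f; σ) − S_expt(a, f)|², using the Wirtinger
  (conjugate) gradient ΔA·adjoint(residual), Armijo backtracking (or a
  fixed step), and a 0.1% relative-change stopping rule.
* **Evaluation**: signal-to-clutter ratio SCR = 20 log10(Tmax/Cmax) (dB),
  localization error LE = |r_max − r_tum| (m), the rule-based TP/FP/TN/FN
  tumour-detection classifier at a 1.5 dB SCR threshold,
  sensitivity/specificity summaries, and an ROC sweep over 1000 thresholds
  in [0, 30] dB.
* **Simulation**: layered phantoms (adipose disc, fibroglandular
  inclusions, tumours of 10–30 mm diameter), reference-scan triplets
  (healthy / adipose-only / empty), complex Gaussian noise, and an optional
  second-order (double-scattering) forward model used to generate
  controlled model mismatch.

See `vignettes/bmsradar-methods.Rmd` for the full model description,
conventions, and design decisions.

## Worked example

Simulate one scan of a phantom with a 15 mm tumour at (2.0, 1.0) cm using
the scaled circular-arc protocol (24 positions over 355°, 51 frequencies
over 1–9 GHz), subtract the adipose reference to isolate the tumour
response, reconstruct with all three algorithms and classify:

```r
library(bmsradar)

proto <- scan_protocol(scaled = TRUE)
grid <- image_grid(c(-0.08, 0.08), c(-0.08, 0.08), 40, 40)
spec <- phantom_spec(
  breast_radius = 0.055, breast_amplitude = 10,
  tumour = list(centre = c(0.02, 0.01), radius = 0.0075, amplitude = 50))
rec <- simulate_scan(spec, proto$geometry, proto$freqs, grid, seed = 7)
data <- subtract_reference(rec$target, rec$adipose_ref)

for (alg in c("das", "dmas", "orr")) {
  img <- reconstruct(data, grid, alg)
  det <- classify_detection(img, rec$metadata)
  cat(sprintf("%-5s SCR %6.2f dB   LE %4.1f mm   -> %s\n",
              toupper(alg), det$scr_db, 1e3 * det$le_m, det$label))
}
```

```
DAS   SCR  18.75 dB   LE  2.0 mm   -> TP
DMAS  SCR  11.45 dB   LE  2.0 mm   -> TP
ORR   SCR  19.69 dB   LE  2.0 mm   -> TP
```

Each line reports the image contrast (SCR: maximum response inside the
expected tumour disc vs. the maximum elsewhere inside the breast boundary),
the distance from the image peak to the true tumour centre (LE; here well
under the 4 mm pixel size), and the detection label — all three methods
localize and detect this noiseless tumour. The ORR fit itself:

```r
fit <- orr_reconstruct(data, grid)
fit$trace
#> <orr_trace> 21 iterations, loss 0.0185825 -> 0.000240637 (tolerance)
```

The same pipeline is scriptable end to end (simulate → subtract →
reconstruct → evaluate → ROC) via `run_pipeline()` / `run_config()` or the
CLI wrapper `inst/cli/bmsradar.R` with subcommands `simulate`,
`reconstruct`, `evaluate`, `roc`, `all` and a YAML config file (explicit
flags win over the file).

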