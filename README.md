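# ricegru

Detection of persistent (heavy-metal-type) stress in paddy rice from
multitemporal multispectral imagery, as an R analysis pipeline.

## The problem

Heavy metals in paddy soil act on rice through the *whole* growing season.
The canopy symptom — a persistent depression of vigor, deepest in mid
season — is too subtle to classify from any single image, but it leaves a
characteristic shape in the season-long trajectory of red-edge reflectance:
the red-edge indices of stressed rice run below those of unstressed rice at
every date, with the widest gap (a broader, deeper trough) during
June–August. This package classifies that temporal signature per pixel.

The pipeline, for scientists working on crop stress monitoring with
Sentinel-2-like band sets:

1. **Spectral indices** — eight stress-sensitive indices per pixel per date:
   red-edge position `REP = 700 + 40·(((B7−B4)/2 − B5)/(B6−B5))`,
   `CIred_edge = B7/B5 − 1`, `MSR = (B6−B1)/(B5−B1)`,
   `MCARI = ((B5−B4) − 0.2(B5−B3))·(B5/B4)`, `NDVI`, `RDVI = (B7−B4)/(B7+B4)`,
   `NDRE1 = (B6−B5)/(B6+B5)`, `NDRE2 = (B7−B5)/(B7+B5)`.
2. **Masking** — slope from the DEM by Horn's method, removing pixels
   steeper than 8° (rice terrain limit); per-date cloud invalidation from
   the QA band.
3. **Sequences** — per-pixel `n_dates × 8` feature matrices, cloud gaps
   filled by linear interpolation in time; stratified 80/20 train/test
   split; train-fitted standardization.
4. **GRU classifier** — a gated-recurrent-unit sequence model implemented
   from its cell equations, with hand-derived backpropagation through time
   (verified against finite differences), Adam optimization and early
   stopping. Gates: `R_t = σ(X_t·Wxr + H_{t−1}·Whr + br)`,
   `Z_t = σ(X_t·Wxz + H_{t−1}·Whz + bz)`, candidate
   `H̃_t = tanh(X_t·Wxh + (R_t ⊙ H_{t−1})·Whh + bh)`, state
   `H_t = Z_t ⊙ H_{t−1} + (1 − Z_t) ⊙ H̃_t`.
5. **Evaluation** — confusion matrix (rows = classified, columns =
   reference), user's/producer's accuracy, per-class
   accuracy/precision/recall/F1 (harmonic mean), overall accuracy and
   Cohen's Kappa `κ = (p_o − p_e)/(1 − p_e)`.

A synthetic scene generator (double-logistic paddy phenology, persistent
stress depression with a mid-season Gaussian trough, additive noise, random
clouds with QA flags, cosine-field DEM) stands in for satellite downloads, so
the full pipeline runs and is tested end to end on any machine. See the
methods vignette (`vignettes/stress-detection-methods.Rmd`) for the model,
assumptions and design choices.

## Worked example

```r
library(ricegru)

cfg <- pipeline_config(
  scene = scene_config(n_rows = 48, n_cols = 48, seed = 1),
  gru = gru_config(hidden_size = 16, n_classes = 2, max_epochs = 15,
                   patience = 5, seed = 1),
  split_seed = 1, rice_only = TRUE, out_dir = file.path(tempdir(), "demo")
)
res <- run_pipeline(cfg)
print(res$report)
```

```
simulating scene (seed 1)
indices computed; invalid cell fraction 0.04902
slope mask removed 231 of 2304 pixels (> 8 deg)
built 482 sequences (0 pixels dropped for lack of valid observations)
trained 15 epochs; best epoch 15
test overall accuracy 100.00%, Kappa 100.00%
Confusion matrix (rows = classified, columns = reference):
                rice_unstressed rice_stressed Total User's Accuracy
rice_unstressed              35             0    35         100.00%
rice_stressed                 0            62    62         100.00%
Producer's Accuracy: 100.00%  100.00%
Overall Accuracy 100.00%   Kappa 100.00%
```

Reading this: a 48×48 scene was simulated with 33 acquisition dates; ~5% of
index cells were cloud-invalidated and gap-filled; 231 pixels were removed as
steeper than 8°; 482 rice pixels became standardized sequences (80/20
split); and the held-out 97 test pixels were classified without error — the
persistent depression plus mid-season trough built into the synthetic
stressed class is fully recoverable by the GRU. On real imagery, separability
is set by the site, not the generator, so perfect scores should be read as a
statement about the pipeline, not about fieldwork.

The numbered drivers under `analysis/` run the same workflow at study-like
proportions (90×90 scene, three classes at 76.7/8.0/15.3% with ≥500 rice
sequences per class, 50-epoch budget) in five narrated stages, writing tables
under `results/tables/`.

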