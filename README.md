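# adaptorquant

Quantification pipelines for the assays used to characterize dynein
activating adaptors — proteins such as KASH5 that link the dynein motor to
dynactin and cargo and switch it into a processive state. The package is
aimed at labs running single-molecule TIRF motility assays,
immunofluorescence localization experiments, and biophysical binding
measurements on candidate adaptors, and at anyone who wants those analyses
reproducible against synthetic data with known ground truth.

## What it computes

**Single-molecule motility.** From a calibrated movie stack and microtubule
polylines, the pipeline builds kymographs (time x arclength, maximum over a
perpendicular transect), traces particle events, classifies them as
processive / diffusive / immotile, applies the standard run filters (runs
spanning <= 4 frames excluded — 1.2 s at a 300 ms interval; events brighter
than 3x the field's median event intensity excluded as aggregates), and
reports per-event velocity `v = |Δs| / Δt` and run length, plus per-field

    landing rate = N_events / (Σ L_MT [um] · T [min] · [motor] [pM]),
    % processive = 100 · N_proc / (N_proc + N_diff + N_immotile).

**Nuclear-envelope enrichment.** Per cell, the NE score of a channel is the
mean gray value in a 1 um band on either side of the nuclear boundary
divided by the cytoplasmic mean (cell mask minus the nucleus expanded by
1 um), with fixed gray-value inclusion filters per transfection condition
(KASH5 >= 250 for full-length/mutant; SUN1 >= 200 for SUN1-only and
KASH5-dTM; whole-cell KASH5 >= 220 additionally for dTM).

**Telomeric foci.** Focus intensity at SYCP3 axis ends, measured as a disk
aperture mean minus a per-focus local-annulus background, normalized to the
mean of a reference population (GFP-negative cells or wild type).

**Binding.** A single-site ITC isotherm with displacement-volume
bookkeeping, fit by Levenberg-Marquardt for `(N, K_d, ΔH, baseline)`;
SEC-MALS molar mass from `R ∝ c · M · (dn/dc)²` with dn/dc = 0.185 ml/g;
and integer stoichiometry calls ranked by `|M_theo − M_meas| / M_meas`.

**Reporting.** Kruskal-Wallis + tie-corrected Dunn pairwise tests, Welch /
Brown-Forsythe ANOVA + Dunnett-T3-style pairwise tests, significance tiers
at 0.05/0.01/0.001/0.0001, and figure-legend-style summaries (median-IQR,
mean-SEM, mean-SD, mean-CI95).

Every generator exports ground truth (per-event speeds and classes,
per-cell region means, per-focus amplitudes and backgrounds, binding
parameters), so each pipeline is validated by parameter recovery.

## Worked example

```r
library(adaptorquant)

## --- motility: simulate a field, then analyze it blind to the truth ----
cfg <- sim_config(seed = 7, frame_interval = 0.3, movie_duration = 90,
                  field_size = c(64L, 200L), landing_rate_true = 0.3,
                  state_fractions = c(0.7, 0.2, 0.1),
                  speed_distribution = list(family = "normal",
                                            location = 0.5, scale = 0.05))
paths <- lapply(1:4, function(i)
  mt_path(paste0("mt", i), cbind(c(8, 190), c(i * 12, i * 12))))
sim <- simulate_tirf_movie(cfg, paths)
res <- analyze_tirf_movie(sim$movie, paths)
res$summary
#> FOV: 55 events (31 processive, 17 diffusive, 7 immotile)
#>   MT length 116.5 um, 1.50 min; landing rate 0.3148 events/um/min; 56.4% processive
median(res$metrics$velocity_um_s)
#> [1] 0.4870536    # true per-event speeds were drawn around 0.5 um/s

## --- binding: ITC fit and SEC-MALS stoichiometry ----------------------
fit <- fit_isotherm(simulate_itc(binding_model(N = 0.5, K_d = 4.3, dH = -8),
                                 itc_protocol(), noise_sd = 0.05, seed = 1))
fit
#> single-site fit: N = 0.496 (+/- 0.012), K_d = 4.38 uM (+/- 0.26), dH = -8.08 kcal/mol, c = 5.67

mals_mass(simulate_mals_trace(139, 0.5, dn_dc = 0.185))
#> [1] 139
head(infer_stoichiometry(139, monomer_masses(), max_copies = 4), 3)
#>   NCC LIC1 theoretical_mass measured_mass relative_residual consistent
#> 1   2    1           133.50           139        0.03956835       TRUE
#> 2   1    2           151.65           139        0.09100719      FALSE
#> 3   4    0           153.80           139        0.10647482      FALSE
```

The landing rate recovered (0.315 events/um/min) matches the configured
0.3 within Poisson error; the ITC fit recovers the generating
K_d = 4.3 uM and N = 0.5 (two adaptor protomers per LIC); and the
stoichiometry table ranks the 2:1 NCC:LIC complex (133.5 kDa theoretical)
first against the 139 kDa measured mass.

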