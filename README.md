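# ruplaque

Dose calculation and placement planning for concave Ru-106/Rh-106
episcleral plaque applicators, for the scenario where the standard
placement is impossible: a juxtapapillary tumor in a small (infant) eye.
The applicator's radius of curvature (12–14 mm) exceeds the infant eye
radius (~9 mm), so the plaque cannot conform to the globe; a posterior
staphyloma additionally forces the posterior plaque edge to stand off the
eyeball by a distance *d* ≥ 2 mm.  The package is written for medical
physicists who need personalized dosimetry for such tilted placements —
the peripheral dose of these applicators is poorly characterized by
manufacturer certificates, which only certify the central-axis depth dose.

## What it computes

* **Source term** — allowed-shape Fermi beta spectrum of the dominant
  Rh-106 branch, p(E) ∝ F(Z,E)·p·E_tot·(Q−E)², Q = 3.541 MeV, plus the
  Rh-106 gamma lines with per-decay intensity > 0.06%.
* **Monte Carlo dose engine** — condensed-history electron transport in
  water (0.02 mm water-equivalent steps, Highland multiple scattering,
  range-based 0.1 mm cutoff), silver layers by water-equivalent
  path-length scaling, gammas by kerma ray-trace; dose per decay scored on
  a 0.1 mm grid with history-by-history uncertainties; bit-reproducible
  from the seed.
* **Deterministic kernel engine** — monoenergetic beta dose-point kernels
  from a deterministic phase-space transport solver, superposed over the
  spectrum and integrated over the active cap: the independent cross-check
  for the MC engine and the fast backend for planning.
* **Tilted placement** — rigid single-contact placement parameterized by
  the posterior-edge distance *d*, with the pinned-suture/riding regimes
  of a stiff cap on a smaller sphere.
* **Planning chain** — certificate calibration, dose rates at the six
  anatomical reference positions, the *d* sweep, placement selection under
  the staphyloma constraint, required time for a 40 Gy prescription and
  delivered doses, with half-up rounding to the clinical report precision.
* **Synthetic reference data** — manufacturer-style certificates (with
  lognormal measurement scatter) and complete case-geometry bundles, so
  the entire pipeline is testable without external data.

## Worked example

The clinical arithmetic in "printed-rates" mode — position dose rates in
mGy/min, a 40 Gy prescription, and the actual 47.0 h attachment:

```r
library(ruplaque)
plan <- rupl_plan(rates = c(25.5, 75.2, 105.8, 28.0, 21.4, 19.5),
                  attach_time = 47.0)
plan
#> plaque placement plan
#>   position 1: 25.5 mGy/min -> 71.9 Gy delivered
#>   position 2: 75.2 mGy/min -> 212.1 Gy delivered
#>   position 3: 105.8 mGy/min -> 298.4 Gy delivered
#>   position 4: 28.0 mGy/min -> 79.0 Gy delivered
#>   position 5: 21.4 mGy/min -> 60.3 Gy delivered
#>   position 6: 19.5 mGy/min -> 55.0 Gy delivered
#>   limiting position: 1 (25.5 mGy/min)
#>   required time for 40 Gy: 26.1 h; attachment time: 47.0 h
```

The limiting tumor-coverage position (position 1, 1 mm above the temporal
sheath edge) receives 25.5 mGy/min, so 40 Gy needs 26.1 h; over the actual
47.0 h attachment it receives 71.9 Gy and the optic-disc points 60.3 and
55.0 Gy.

The full physics chain on the default synthetic case:

```r
src    <- ru106_source_term()
kernel <- build_point_kernel(src$beta)      # ~20 s
plan   <- rupl_plan(kernel = kernel)        # sweep d = 0..4 mm, kernel backend
plan$chosen_d                               # 2 (smallest feasible d >= d_min)
plan$limiting_position                      # 1
```

The Monte Carlo engine is exercised through the validation workflow,
which compares its central-axis depth dose against the deterministic
kernel engine for the concentric applicator (both normalized at 2 mm,
band 0.5–6.0 mm):

```r
val <- rupl_validate(seed = 1, n_histories = 1e6, kernel = kernel)
val$max_discrepancy    # maximum relative deviation over the band
val$unc_axis           # central-axis statistical uncertainty (<= 5%)
```

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/ruplaque.R gen-data --out data
Rscript inst/cli/ruplaque.R validate --out val --seed 1
Rscript inst/cli/ruplaque.R plan --out plan --case data/case.yaml \
        --certificate data/certificate.tsv
```

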