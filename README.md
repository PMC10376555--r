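# mixrange

Quantifying how bottom temperature, salinity and depth jointly constrain
a fish population's spatial range, from gridded trawl-survey data.

Fisheries surveys often show that the water satisfying a species'
preferred temperature range is far larger than the area the species
actually occupies. `mixrange` implements a mixed
distribution–decomposition pipeline that makes that comparison
quantitative, factor by factor and in combination:

1. **Main range** — the region holding the top 80% of kriged survey
   biomass (a deterministic superlevel-set rule with tie inclusion).
2. **Ordinary kriging** — biomass and factor fields interpolated onto a
   regular lon/lat grid from a WLS-fitted semivariogram
   (exponential/spherical/gaussian; pair-count weights).
3. **Mixture decomposition** — within the main range, each factor's
   distribution is fitted as a normal mixture
   `g(x) = Σ_k π_k φ(x | μ_k, σ_k)` by EM, with k chosen by BIC;
   each component spans the interval `μ_k ± σ_k`.
4. **Envelopes and overlap statistics** — intervals are mapped back to
   space as envelope masks and compared with the main range by
   point-count areas: effective ratio `R_effective = A_eff / A_env`,
   coverage ratio `R_covering = A_eff / A_bio`, composite fitness index
   `I_comp = sqrt(R_effective × R_covering)`, and the relative coverage
   decline `(after − before)/before` under multi-factor intersection.

A synthetic survey generator (half-degree station lattice, seasonal
temperature fields, sub-10‰ river-plume salinity structure,
offshore-deepening bathymetry, hotspot-concentrated biomass) makes every
stage reproducible and testable without confidential survey data.

## Worked example

```r
library(mixrange)

design   <- survey_design(seed = 1)    # 19 x 15 stations, 4 seasons
stations <- generate_survey(design)    # 285 stations x 4 seasons
cfg      <- run_config(resolution = 0.05, fraction = 0.8, k_max = 4, seed = 1)
result   <- run_pipeline(cfg, stations)

subset(result$stats, season == "spring",
       select = c(label, A_env, A_bio, A_effective,
                  R_effective, R_covering, I_comp))
```

```
                          label A_env A_bio A_effective R_effective R_covering I_comp
                    temperature 13961  5247        3994       0.286      0.761  0.467
                       salinity 14698  5247        3739       0.254      0.713  0.426
                          depth  7563  5247        4312       0.570      0.822  0.685
         temperature ∩ salinity  7715  5247        2792       0.362      0.532  0.439
            temperature ∩ depth  4752  5247        3348       0.705      0.638  0.670
               salinity ∩ depth  5469  5247        3190       0.583      0.608  0.595
 temperature ∩ salinity ∩ depth  3335  5247        2420       0.726      0.461  0.579
```

Reading the spring row block: the temperature envelope (13 971 cells)
overlaps the biomass main range (5 247 cells) in 3 994 cells, so it
captures 76% of the habitat (`R_covering`) but only 29% of the envelope
is habitat (`R_effective`); every multi-factor intersection has a
smaller effective area than any of its constituents, and the coverage
declines in `result$declines` are all ≤ 0. `render_tables(result, dir)`
writes the seven report tables (mixture parameters per factor,
single-factor overlaps, multi-factor overlaps, coverage declines,
composite indices) as CSV, and `write_mask()` exports any mask as
GeoJSON.

## Command line

```sh
Rscript inst/cli/mixrange.R generate --seed 1 --out survey.csv
Rscript inst/cli/mixrange.R run --stations survey.csv --outdir run1
```

See `vignettes/range-overlap-methods.Rmd` for the model, the numerical
choices and the generator's scope.
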