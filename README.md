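# ecocoupling

An assessment–coupling–driving pipeline for landscape ecology: quantify
ecosystem health and human activity intensity on a gridded landscape,
measure how the two interact in space, and attribute their variation to
climatic and socio-economic drivers — including nonlinear response
thresholds. The package is aimed at spatial-ecosystem and land-system
researchers who want these three stages as tested, seeded, composable R
functions rather than a chain of GIS menus, and it ships a synthetic
landscape generator so every stage can be validated end-to-end without
any external rasters.

## The models

**Ecosystem health (VORS).** Per analysis unit (a square block of
cells),

    EHI = (EV · EO · ER · ESI)^(1/4)

where EV is min–max-normalized unit-mean NPP; EO combines six
FRAGSTATS-style landscape metrics (SHDI, SHEI, DIVISION, IJI, CONTAG,
area-weighted FRAC) with published weights
`0.1499·SHDI' + 0.1502·SHEI' + 0.1002·DIVISION' + 0.2173·IJI' +
0.1191·CONTAG' + 0.2633·FRAC'`; ER is the area-weighted resistance /
recovery score `Σ A_i (0.4 C_resist,i + 0.6 C_resil,i)` over the
six-class land-cover legend; and ESI is an entropy-weighted sum of five
normalized ecosystem-service indicators.

**Human activity intensity.**

    HAI = (SLUCC' + PD' + NTL') / 3

with SLUCC the ordinal land-use disturbance score (construction 10,
farmland 7, grassland 3, others 0), PD population density and NTL
nighttime lights, each range-normalized; the division by 3 puts HAI on
the same [0, 1] scale as EHI.

**Spatial coupling.** Global and bivariate Moran's I with seeded
permutation inference, Getis–Ord Gi\* hot/cold spots, the coupling
coordination degree `D = sqrt(C·T)` with `C = 2·sqrt(EHI·HAI)/(EHI+HAI)`
and `T = 0.5·EHI + 0.5·HAI`, five coordination bands, and z-score
four-quadrant zoning (coordinated development / ecological management /
risk prevention / potential conservation).

**Drivers.** Gradient-boosted tree regression (xgboost) of EHI, HAI or D
on unit-level covariates with grid-search CV, R²/RMSE/MAE evaluation,
exact TreeSHAP attribution with importance shares, and rolling-median
sign-change extraction of nonlinear thresholds from SHAP dependence
profiles.

See `vignettes/assessment-coupling-driving.Rmd` for the conventions,
parameter meanings and design decisions.

## Worked example

The `analysis/` scripts run the whole workflow on the default synthetic
study conditions (100 × 100 cells, two years, human pressure negatively
coupled to ecological condition at −0.8, 10 × 10-cell analysis units):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_assess_indices.R
Rscript analysis/03_spatial_coupling.R
Rscript analysis/04_drivers.R
```

Stage 2 prints the per-year index summaries:

```
year1: mean EHI 0.569 (poor-or-worse 8.0%), mean HAI 0.128 (good-or-better 1.0%)
year2: mean EHI 0.569 (poor-or-worse 8.0%), mean HAI 0.134 (good-or-better 0.0%)
unit-level correlation between HAI and EHI: -0.600
```

— health and human pressure are strongly anti-correlated across units,
as the generator planted. Stage 3 quantifies the spatial structure:

```
   year  variable      I p_value p_two_sided z_score
1 year1       ehi  0.449   0.001       0.002    8.37
2 year1       hai  0.410   0.001       0.002    8.34
3 year1 hai_x_ehi -0.221   0.001       0.002   -4.18
4 year2       ehi  0.455   0.001       0.002    8.43
5 year2       hai  0.437   0.001       0.002    8.81
6 year2 hai_x_ehi -0.250   0.001       0.002   -4.66
quadrant shares (final year): I 15%, II 22%, III 17%, IV 46%
```

Both indices are spatially clustered (positive univariate I), high-HAI
units sit next to low-EHI units (bivariate I ≈ −0.25, permutation
p = 0.001), and nearly half the landscape falls in the
high-EHI/low-HAI "potential conservation" quadrant. Stage 4 attributes
the indices and checks threshold recovery against the generator's truth:

```
HAI: test R2 0.81, RMSE 0.049; top drivers: elevation 23.4%, temperature 16.8%, pop_density 16.7%
planted PET breakpoint 850 mm; recovered 825 mm (+ -> -), error 25 mm
```

The same computations are available programmatically:

```r
library(ecocoupling)
cfg <- run_config(scenario = scenario_preset("negative_coupling", seed = 1),
                  unit_cells = 10, seed = 1)
rep <- run_pipeline(cfg)
rep$moran          # Moran / bivariate-Moran table
rep$zone_summary   # quadrant shares and mean D per zone
rep$drivers$ehi$importance_share
```

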