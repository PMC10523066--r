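# paleoCMR

Capture–mark–recapture (CMR) estimation of extinction selectivity from
stage-binned fossil occurrence data.

## The problem

Across the Phanerozoic, wide geographic range is the most reliable
insurance a genus has against extinction — except, apparently, during mass
extinctions, when that insurance seems to lapse. Testing this properly is
hard because the fossil record reports only detections: a genus missing
from a stage may be extinct or merely unsampled, and sampling itself is
biased toward large-bodied, widespread taxa. paleoCMR addresses this by
treating genus occurrence histories as capture–mark–recapture data and
estimating survival, origination and detection jointly.

Each genus contributes a 0/1 detection vector over the ordered stages of a
geologic timescale. Three logit-linear parameter families are estimated
with the Pradel seniority model:

- **φ** (survival over each stage boundary), with covariates standardized
  body size (BS, log10 biovolume per class), standardized geographic range
  (GR, log10 maximum great-circle distance per class and stage), and their
  interactions with a 0/1 mass-extinction stage flag (ME);
- **γ** (seniority; its complement measures origination), with recovery-stage
  interactions (Rec);
- **p** (detection), `~time + BS`.

For a history first seen at occasion *f* and last at *l* the likelihood
kernel is ξ_f · p_f · ∏ φ_t p^ω (1−p)^(1−ω) · χ_l, where ξ and χ are the
"never seen before"/"never seen again" recursions; fitting conditions each
history on its genus being detected at least once, which removes the
size-biased-inclusion bias that the bare kernel suffers. Selectivity is
reported on the log-odds-of-extinction scale, ln(q/(1−q)) with q = 1−φ,
per standard deviation of trait: positive means the trait raises
extinction risk.

The canonical candidate set crosses 11 survival structures with 11
seniority structures and one detection structure — 121 models per class,
ranked by AICc; coefficients of all models with Akaike weight ≥ 0.01 are
averaged (weighted, absent terms contributing zero) into per-class,
per-regime selectivity estimates with unconditional standard errors.

The package also ships an Ordovician–Pleistocene stage table (86 stages,
Big Five mass extinctions flagged), a Paleobiology-Database-dialect
occurrence reader with the standard treatment rules (subgenus elevation,
stage resolution, Cambrian exclusion, the 1 km range convention, per-class
standard scores), and a seeded synthetic fossil-record generator so every
stage of the pipeline can be exercised and calibrated without downloads.

## Worked example

Simulate a well-sampled two-regime record (background survival-scale range
coefficient +0.8, erased at three mass-extinction stages; size +0.2), run
the full preparation pipeline, fit a reduced 8-model set, rank and average:

```r
library(paleoCMR)

sim  <- make_fixture("regime_demo", seed = 42)
prep <- prepare_occurrences(sim$occurrences, sim$traits,
                            stage_table = sim$config$stage_table,
                            min_genera = 1)
h <- prep$histories[["Simulata"]]
#> <capture_history_set> Simulata: 1928 genera x 30 occasions (stages S01-S30)

fits <- lapply(reduced_model_set(), fit_model, hist = h, starts = 1,
               hessian = FALSE)
tab <- rank_models(fits, hist = h)
tab[1:3, c("model_id", "phi", "gamma", "dAICc", "weight")]
#>   model_id                       phi gamma     dAICc       weight
#> 1    red08 ~time + BS x ME + GR x ME ~time  0.000000 8.646276e-01
#> 2    red07      ~time + BS + GR x ME ~time  3.708542 1.353722e-01
#> 3    red06           ~time + GR x ME ~time 30.505583 2.054120e-07

fa <- attr(tab, "fits")
for (id in tab$model_id[tab$weight >= 0.01])
  fa[[id]] <- refit_hessian(fa[[id]], h)
attr(tab, "fits") <- fa
average_coefficients(tab, class_name = "Simulata")
#>   trait          regime coefficient     se  ci_low ci_high
#> 1  size      background     -0.1278 0.0280 -0.1827  -0.073
#> 2  size mass_extinction      0.0112 0.0623 -0.1109   0.133
#> 3 range      background     -0.4695 0.0319 -0.5321  -0.407
#> 4 range mass_extinction      0.0381 0.0673 -0.0938   0.170
```

Both top-ranked models carry mass-extinction interactions in survival
(two-regime models). The averaged background range coefficient is
strongly negative — narrow-ranged genera face higher extinction odds —
while the mass-extinction range coefficient is indistinguishable from
zero: range selectivity is erased at the flagged stages, exactly the
pattern the generator encodes. (The background magnitude is attenuated
relative to the generating +0.8 because the range covariate is measured
from occurrence coordinates, with the 1 km convention at unsampled
stages; see the methods vignette.)

For real data, point `prepare_occurrences()` at a PBDB occurrence download
and a `genus,class,log10_volume_mm3` trait table, keep the default
`load_stage_table()`, and fit `enumerate_model_set()` (121 models) via
`run_fit_select()`. A thin command-line wrapper with `prepare`, `fit`,
`simulate` and `recover` subcommands ships in `inst/cli/paleocmr.R`.

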