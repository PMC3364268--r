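# nektonpulse

Quantifying the portion of resident-nekton standing stock on a flooded
estuarine marsh that is attributable to a managed riverine flood pulse.

## The problem

When a river diversion pulses fresh water onto an estuarine marsh, small
resident nekton — grass shrimp, killifishes, poeciliids — assemble onto the
newly flooded surface. Their standing stock (density in ind m⁻², dry-weight
biomass in g DW m⁻², energy density in cal m⁻²) is a potential trophic
subsidy: food that becomes available to pelagic consumers as the water
recedes. But marshes also flood from tides and weather, so the attribution
question is: *how much of that standing stock would not be there without the
pulse?*

`nektonpulse` implements the paired-basin answer for ecologists working with
gauge records and drop-sampler campaigns. An inflow area receives the pulse;
a hydrologically separated reference area floods only meteorologically and
tidally, and serves as the counterfactual. Each 1 m² drop sample from the
inflow marsh is classified **subsidized** when (1) the reference marsh was
not flooded at the sample time, or (2) it was flooded, but the inflow area's
daily mean water level exceeded the maximum daily mean depth of flooding in
the reference area over the pulse window. Per pulse and per metric *X*, the
subsidized proportion is the ratio of totals
*X*(subsidized)/*X*(total); proportions are averaged across pulses into a
percentage *Y* (SE over pulses) and scaled by the pooled inflow mean *X*
(SE over samples):

    Z = X · Y / 100,    Z_err = Z · sqrt((X_err/X)² + (Y_err/Y)²)

Supporting machinery: per-species wet:dry weight conversions by OLS with a
significance-gated intercept (dropped when not distinguishable from zero at
α = 0.05, refitted through the origin), bomb-calorimetry pellet replicates
aggregated to species energy densities, per-sample standing-stock metrics
over the six dominant resident species, environmental summaries, and a
synthetic-data module that generates all inputs (tidal + meteorological
water levels, a trapezoidal pulse hydrograph, negative-binomial catches,
wet/dry weighings, pellets) with independent ground-truth labels, so the
full pipeline runs and validates with no field data.

## Worked example

```r
library(nektonpulse)

study <- run_pulse_study(seed = 1)   # simulate two pulses, analyze end to end
study
#> Flood-pulse nekton subsidy study
#>   samples: 155 (subsidized: 126)
#>   inflow flooded 77% of 'feb'
#>   inflow flooded 85% of 'mar'
#>   reference flooded 8% of 'feb'
#>   reference flooded 13% of 'mar'
#> Nekton standing-stock subsidy (error rule: quadrature)
#>  metric             inflow_mean    subsidized_pct subsidy
#>  density (ind m-2)  37.0 (2.6)     84.8 (7.9)     31.3 (3.7)
#>  biomass (g DW m-2) 0.8 (0.1)      82.3 (9.5)     0.7 (0.1)
#>  energy (cal m-2)   5169.2 (451.6) 82.4 (9.5)     4259.8 (617.9)
```

Reading the table: over this synthetic campaign the inflow marsh held on
average 37 resident nekton m⁻² (SE 2.6); 84.8% of total density was in
pulse-subsidized samples; so an estimated 31.3 ind m⁻² (SE 3.7) of standing
stock — and likewise 0.7 g DW m⁻² of biomass and ~4,260 cal m⁻² of energy —
is attributable to the pulse rather than to background flooding.

The pieces compose with pipes and tidy tools:

```r
models  <- fit_wet_dry(study$inputs$wetdry, alpha = 0.05)   # intercept-gated OLS
tidy(models)                                                # one row per species
energies <- mean_energy_density(study$inputs$pellets)       # cal g-1 DW ± SE
cls <- classify_samples(study$inputs$samples, study$inputs$water_levels,
                        study$inputs$pulses)
autoplot(study)                                             # subsidy vs inflow mean
plot_water_levels(study$inputs$water_levels, study$inputs$pulses)
write_pipeline_outputs(study, "nektonpulse-run")            # CSVs + report.md
```

A thin command-line wrapper lives at `inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R --config cfg.yml --seed 1 --out dir`), driven by a
YAML configuration (`read_run_config()`).

See the vignette (`vignettes/flood-pulse-subsidy.Rmd`) for the model's
assumptions, the interpretation choices in the classification rule, what the
synthetic generator does and does not emulate, and known limitations.

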