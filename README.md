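# cl36soil

Mass-balance modelling of chlorine-36 retention in forest soils, as a
tracer of the age of active soil organic carbon (SOC).

## The problem

Atmospheric deposition of the cosmogenic radionuclide ³⁶Cl spiked by about
three orders of magnitude during the 1952–1972 marine nuclear-bomb tests.
Part of that pulse was fixed into soil organic matter as organochlorine,
which cycles with the organic carbon it is bound to. A soil whose ³⁶Cl/Cl
ratio today exceeds the modern rainfall ratio must therefore still hold
bomb-pulse chlorine — and *how long* each soil layer retains its chlorine
(the retention duration `T′`) proxies the median age of the layer's active
SOC, independently of ¹⁴C or δ¹³C methods.

`cl36soil` is for biogeochemists who want to turn layer-resolved Cl/³⁶Cl
stock and flux measurements into per-layer retained fractions and retention
durations, with full uncertainty propagation, and for methodologists who
want to probe the estimator on truth-known synthetic soils.

## The model

Each layer `k` carries a chlorine stock `S_k,t` (atoms m⁻²) updated yearly:

    S_k,t = (1 − Z_k) S_k,t−1 + X_k I_k,t Δt
    D_k,t = (1 − X_k) I_k,t + Z_k S_k,t−1/Δt − A_k,t

with input `I` (rain + litterfall at the surface, the overlying layer's
drainage below), retained fraction `X_k`, release fraction `Z_k`, root
absorption `A` (exponential depth profile summing to the litterfall).
Chlorine steady state gives the residence time `T_R = S/I`, pins
`Z = X Δt / T_R`, and defines the retention duration `T′ = T_R / X`.
Pre-bomb ³⁶Cl stocks follow from `S₀ = I(³⁶Cl) · T_R(Cl)` (no isotopic
fractionation). The retained fractions are inferred by Monte-Carlo
rejection: 10,000 replicates perturb every measurement at its stated 1σ,
draw `X ~ U(0,1)` per layer, simulate through the bomb pulse, and accept
draws whose 2010 ³⁶Cl stock matches the measured one within measurement
uncertainty, keeping the lowest solution branch (measured fluxes show only
weak retention). See the methods vignette
(`vignettes/cl36-retention-model.Rmd`) for assumptions, parameters and
limitations.

## Worked example

The analysis scripts run the whole study on a truth-known synthetic
Cambisol (five layers to 60 cm, SOC falling ninefold with depth,
bomb-pulse forcing, measurement noise at the stated percentages):

```sh
Rscript analysis/01_build_site.R 42        # site + measured tables + ratios
Rscript analysis/02_forward_simulation.R 42
Rscript analysis/03_fit_retention.R 42     # Monte-Carlo fit of X_k
Rscript analysis/04_soc_relation.R 42      # X vs SOC, durations vs ages
```

Step 1 prints the enrichment diagnostic — soil ³⁶Cl/Cl ratio over the
rainfall ratio — which is ≫ 1 in every layer, so retention reaches back to
the bomb era:

```
  k        ratio rel_sigma enrichment_vs_rainfall
1 1 1.484364e-12 0.1732051              132.18281
...
5 5 8.841395e-13 0.1732051               78.73276
```

Step 3 fits the retained fractions and reports the posterior per layer
(`x_mean` ± `x_sd`, raw-median retention duration `tprime_q50`):

```
  k n_accepted     x_mean       x_sd tprime_q50
1 1       9658 0.02540867 0.01360889   28.52248
2 2       5239 0.03172778 0.01284144   42.99990
3 3       4302 0.03830350 0.01856041   40.66514
4 4       4287 0.02564215 0.02255900  124.18882
5 5       4287 0.01115025 0.01606264  217.73187
```

Read: only a few percent of each layer's chlorine input is fixed into
organic form, and the retention duration grows from decades at the surface
to centuries at 45–60 cm — the generating truth spans 20 → 305 yr, and
every layer's truth falls inside the central 95% posterior interval
(`results/recovery.csv`). Step 4 correlates the fitted durations with a
per-depth age table (r = 0.97 on this run).

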