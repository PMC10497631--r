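# Small fixtures built in code: a hand-written 3-layer profile with round
# numbers (for arithmetic checks) and thin wrappers around the synthetic
# generator.

toy_layers <- function() {
  data.frame(
    k = 1:3,
    top_cm = c(0, 5, 15), bottom_cm = c(5, 15, 30),
    bulk_density = c(1.3, 1.4, 1.5), bd_rel_sigma = 0.05,
    soc_conc = c(40, 20, 10),
    cl_conc = c(2e17, 1e17, 5e16), cl_rel_sigma = 0.05,
    cl36_conc = c(4e5, 2e5, 1e5), cl36_rel_sigma = 0.05
  )
}

toy_fluxes <- function() {
  rbind(
    data.frame(component = "rainfall", species = "cl", year = 2012,
               carrier_amount = 900, carrier_rel_sigma = 0.03,
               concentration = 1e19, conc_rel_sigma = 0.05),
    data.frame(component = "rainfall", species = "cl36", year = 2012,
               carrier_amount = 900, carrier_rel_sigma = 0.03,
               concentration = 2e5, conc_rel_sigma = 0.05),
    data.frame(component = "litterfall", species = "cl", year = 2012,
               carrier_amount = 300, carrier_rel_sigma = 0.10,
               concentration = 3.3e18, conc_rel_sigma = 0.05),
    data.frame(component = "litterfall", species = "cl36", year = 2012,
               carrier_amount = 300, carrier_rel_sigma = 0.10,
               concentration = 6.6e4, conc_rel_sigma = 0.05)
  )
}

toy_dataset <- function() site_dataset(toy_layers(), toy_fluxes())

# single-layer geometry used by the closed-form recursion checks
one_layer <- function() data.frame(k = 1, top_cm = 0, bottom_cm = 60)
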