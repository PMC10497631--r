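test_that("stock computation follows S = C rho d 1e4 and is linear in each factor", {
  lay <- toy_layers()[1, ]
  lay$cl_conc <- 2.0e5
  lay$bulk_density <- 1.3
  # 0-5 cm layer: 2e5 at/g * 1.3 g/cm3 * 5 cm * 1e4 cm2/m2
  s <- compute_stock(lay, species = "cl")
  expect_equal(s$stock, 1.3e10)

  lay0 <- lay
  lay0$cl_conc <- 0
  expect_equal(compute_stock(lay0, species = "cl")$stock, 0)

  lay2 <- lay
  lay2$bottom_cm <- 10 # doubled thickness
  expect_equal(compute_stock(lay2, species = "cl")$stock, 2 * s$stock)

  lay2 <- lay
  lay2$bulk_density <- 2 * lay$bulk_density
  expect_equal(compute_stock(lay2, species = "cl")$stock, 2 * s$stock)

  lay_bad <- lay
  lay_bad$cl_conc <- -1
  expect_error(compute_stock(lay_bad, species = "cl"), "cl_conc")
})

test_that("stock uncertainty combines concentration, density and thickness in quadrature", {
  lay <- toy_layers()[1, ]
  s <- compute_stock(lay, species = "cl", thickness_rel_sigma = 0.10)
  expect_equal(s$rel_sigma, sqrt(0.05^2 + 0.05^2 + 0.10^2))
})

test_that("flux computation follows F = C Phi with quadrature uncertainty", {
  f <- compute_flux(measurement(1e4, 0.05), measurement(300, 0.10))
  expect_equal(f$value, 3e6)
  expect_equal(f$rel_sigma, sqrt(0.05^2 + 0.10^2))

  f0 <- compute_flux(measurement(1e4, 0.05), measurement(0, 0.10))
  expect_equal(f0$value, 0)
  expect_error(measurement(-1, 0.05), "non-negative")
})

test_that("relative uncertainty propagation is root-sum-square", {
  expect_equal(propagate_rel_uncertainty(c(0.02, 0.05, 0.10)),
               sqrt(0.0004 + 0.0025 + 0.01))
  expect_equal(round(propagate_rel_uncertainty(c(0.02, 0.05, 0.10)), 5),
               0.11358)
  expect_equal(propagate_rel_uncertainty(c(0)), 0)
  # single component passes through; permutation invariant
  for (x in c(0.01, 0.07, 0.3)) {
    expect_equal(propagate_rel_uncertainty(x), x)
  }
  set.seed(11)
  for (i in 1:10) {
    v <- runif(5, 0, 0.2)
    expect_equal(propagate_rel_uncertainty(v),
                 propagate_rel_uncertainty(sample(v)))
  }
  expect_error(propagate_rel_uncertainty(c(0.1, -0.1)), "non-negative")
})

test_that("36Cl/Cl ratio profile divides stocks and propagates by quadrature", {
  ds <- toy_dataset()
  rp <- ratio_profile(ds)
  st <- compute_stock(ds$layers)
  s36 <- st[st$species == "cl36", "stock"]
  scl <- st[st$species == "cl", "stock"]
  expect_equal(rp$stock_ratios$ratio, s36 / scl)
  # hand value: layer ratios are conc ratios (same rho, d cancel)
  expect_equal(rp$stock_ratios$ratio[1], 4e5 / 2e17)
  expect_equal(rp$stock_ratios$rel_sigma,
               rep(sqrt(2 * 0.05^2 + 2 * 0.05^2 + 2 * 0.10^2), 3))

  lay0 <- toy_layers()
  lay0$cl_conc[2] <- 0
  expect_error(ratio_profile(site_dataset(lay0, toy_fluxes())),
               "zero Cl stock in layer 2")
})

test_that("stock ratio of 2e8 over 1e14 is 2e-6", {
  lay <- toy_layers()[1, ]
  # choose concentrations whose stocks are 2e8 and 1e14 at m-2
  lay$cl36_conc <- 2e8 / (lay$bulk_density * 5 * 1e4)
  lay$cl_conc <- 1e14 / (lay$bulk_density * 5 * 1e4)
  st <- compute_stock(lay)
  expect_equal(st$stock[st$species == "cl36"] / st$stock[st$species == "cl"],
               2e-6)
})

test_that("layer validation catches gaps, overlaps and bad ordering", {
  lay <- toy_layers()
  lay$top_cm[2] <- 6 # gap between layer 1 (0-5) and layer 2 (6-15)
  expect_error(validate_layers(lay), "layers 1 and 2 are not contiguous")
  lay <- toy_layers()
  lay$bottom_cm[2] <- 14
  expect_error(validate_layers(lay), "layers 2 and 3")
  lay <- toy_layers()
  lay$bottom_cm[1] <- 0
  expect_error(validate_layers(lay), "top_cm < bottom_cm")
  lay <- toy_layers()[, -4]
  expect_error(validate_layers(lay), "missing column")
})

test_that("site tables round-trip through write and read", {
  ds <- toy_dataset()
  lp <- tempfile(fileext = ".csv")
  fp <- tempfile(fileext = ".csv")
  write_site_tables(ds, lp, fp)
  ds2 <- read_site_tables(lp, fp)
  expect_equal(ds2$layers, ds$layers)
  expect_equal(ds2$fluxes, ds$fluxes, tolerance = 1e-12)
  expect_equal(ds2$stock_year, ds$stock_year)

  # unit mismatch is a named, located error
  lines <- readLines(lp)
  lines[2] <- sub("g cm-3", "kg m-3", lines[2])
  writeLines(lines, lp)
  expect_error(read_site_tables(lp, fp), "unit mismatch.*bulk_density")
})

test_that("a 5-layer Cambisol-shaped synthetic site parses to 5 layers", {
  truth <- gen_site(3)
  d <- tempfile()
  gen_observations(truth, out_dir = d)
  ds <- read_site_tables(file.path(d, "layers.csv"), file.path(d, "fluxes.csv"))
  expect_equal(nrow(ds$layers), 5)
  expect_equal(ds$layers$bottom_cm, c(5, 15, 30, 45, 60))
  unlink(d, recursive = TRUE)
})

test_that("flux table must provide rainfall and litterfall for both species", {
  fx <- toy_fluxes()
  expect_error(site_dataset(toy_layers(), fx[fx$component != "litterfall", ]),
               "litterfall")
})
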