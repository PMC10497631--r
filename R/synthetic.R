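# Truth-known virtual sites emulating the statistical structure of a
# temperate-forest Cambisol profile: five layers to 60 cm, exponentially
# decreasing SOC, retained fractions linear in SOC (4.5% at the surface,
# ninefold lower at depth), a 1952-1972 bomb pulse three orders of magnitude
# above the cosmogenic background, litterfall at 11% of the rainfall input,
# and observation noise at the study's stated uncertainty percentages.

#' Configuration of the synthetic-site generator
#'
#' Defaults reproduce the structure of the studied Cambisol profile; see the
#' methods vignette for the rationale behind each value.
#'
#' @param boundaries layer boundaries in cm (default `c(0,5,15,30,45,60)`).
#' @param bulk_density per-layer bulk densities, g cm^-3.
#' @param soc_surface SOC concentration of the surface layer, g C kg^-1.
#' @param soc_efold e-folding depth (cm) of the SOC decrease with layer
#'   mid-depth; the default `50 / log(9)` makes the deepest layer ninefold
#'   below the surface.
#' @param x_per_soc slope of the X-SOC relation (per g kg^-1); the default
#'   0.001 puts the surface retained fraction at 0.045.
#' @param x_jitter_sd lognormal jitter (sd on the log scale) around the
#'   linear X-SOC relation; 0 (default) for an exact relation.
#' @param retention_duration true per-layer retention durations T' (yr);
#'   with `x` they fix the Cl residence times `T_R = X T'`. Default spans
#'   20 yr at the surface to 305 yr at depth.
#' @param rainfall_cl,background_cl36 annual rainfall input fluxes
#'   (atoms m^-2 yr^-1).
#' @param rainfall_mm annual rainfall depth (mm = L m^-2), the water carrier.
#' @param litterfall_mass annual litterfall dry mass (g m^-2), the litter
#'   carrier.
#' @param drainage_mm annual drainage depth at the profile base (mm).
#' @param lambda litterfall fraction of the rainfall input (default 0.11).
#' @param pulse a [pulse_shape()].
#' @param years scenario years (default 1940:2020).
#' @param stock_year,flux_year observation years (defaults 2010, 2012).
#' @param z0 root e-folding depth, cm.
#' @param noise named list of relative 1-sigma observation noises:
#'   `bulk_density` 5%, `thickness` 10%, `litterfall` 10%, `drainage` 10%,
#'   `rainfall` 3%, `concentration` 5% (analytical; configurable because it
#'   is instrument-dependent).
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(boundaries = c(0, 5, 15, 30, 45, 60),
                         bulk_density = c(1.10, 1.25, 1.35, 1.45, 1.50),
                         soc_surface = 45,
                         soc_efold = 50 / log(9),
                         x_per_soc = 0.001,
                         x_jitter_sd = 0,
                         retention_duration = c(20, 45, 90, 180, 305),
                         rainfall_cl = 1.5e22,
                         background_cl36 = 2.0e8,
                         rainfall_mm = 900,
                         litterfall_mass = 300,
                         drainage_mm = 400,
                         lambda = 0.11,
                         pulse = pulse_shape(),
                         years = 1940:2020,
                         stock_year = 2010,
                         flux_year = 2012,
                         z0 = 15,
                         noise = list(bulk_density = 0.05, thickness = 0.10,
                                      litterfall = 0.10, drainage = 0.10,
                                      rainfall = 0.03, concentration = 0.05)) {
  K <- length(boundaries) - 1
  stopifnot(K >= 1, length(bulk_density) == K,
            length(retention_duration) == K,
            all(diff(boundaries) > 0), boundaries[1] == 0)
  structure(
    list(
      boundaries = boundaries, bulk_density = bulk_density,
      soc_surface = soc_surface, soc_efold = soc_efold,
      x_per_soc = x_per_soc, x_jitter_sd = x_jitter_sd,
      retention_duration = retention_duration,
      rainfall_cl = rainfall_cl, background_cl36 = background_cl36,
      rainfall_mm = rainfall_mm, litterfall_mass = litterfall_mass,
      drainage_mm = drainage_mm,
      lambda = lambda, pulse = pulse, years = years,
      stock_year = stock_year, flux_year = flux_year, z0 = z0,
      noise = noise
    ),
    class = "synth_config"
  )
}

#' Generate a truth-known synthetic site
#'
#' Draws (deterministically under `seed`) the true state of a virtual site:
#' layer geometry and densities, an exponential SOC profile, retained
#' fractions linear in SOC (optionally jittered), the Cl input cascade,
#' residence times, and the true stocks of both species at the stock year
#' obtained by forward simulation under the bomb-pulse forcing.
#'
#' @param seed integer seed; identical seeds give identical truths.
#' @param config a [synth_config()].
#' @return list of class `"synthetic_truth"` with the true per-layer
#'   parameters (`x`, `t_r`, `t_prime`, `soc`, stocks), the forcing, and the
#'   generating config/seed.
#' @export
gen_site <- function(seed, config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(as.integer(seed))
  bnd <- config$boundaries
  K <- length(bnd) - 1
  geometry <- data.frame(
    k = seq_len(K),
    top_cm = bnd[-length(bnd)], bottom_cm = bnd[-1]
  )
  mid <- (geometry$top_cm + geometry$bottom_cm) / 2
  soc <- config$soc_surface * exp(-(mid - mid[1]) / config$soc_efold)
  x <- config$x_per_soc * soc
  if (config$x_jitter_sd > 0) {
    x <- x * exp(stats::rnorm(K, 0, config$x_jitter_sd))
    x <- pmin(pmax(x, 1e-6), 1 - 1e-6)
  } else if (any(x <= 0) || any(x >= 1)) {
    stop("configured X-SOC relation yields X outside (0, 1); ",
         "adjust x_per_soc/soc_surface or enable jitter")
  }
  t_prime <- config$retention_duration
  t_r <- x * t_prime

  forcing <- build_forcing(
    background_cl36 = config$background_cl36,
    background_cl = config$rainfall_cl,
    pulse = config$pulse, lambda = config$lambda, years = config$years
  )
  sim <- simulate_profile(geometry, x, t_r, forcing, z0 = config$z0)
  structure(
    list(
      seed = as.integer(seed), config = config,
      geometry = geometry, soc = soc,
      x = x, t_r = t_r, t_prime = t_prime,
      i_cl = sim$params$i_cl,
      stock_cl = sim$params$i_cl * t_r,
      stock_cl36 = stocks_at(sim, config$stock_year, "cl36"),
      drainage_cl36_fluxyear =
        sim$species$cl36$D[K, match(config$flux_year, sim$years)],
      forcing = forcing, simulation = sim
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> seed %d, %d layers; X = %s; T' = %s yr\n",
    x$seed, nrow(x$geometry),
    paste(signif(x$x, 3), collapse = ", "),
    paste(signif(x$t_prime, 3), collapse = ", ")
  ))
  invisible(x)
}

#' Emit noisy observations of a synthetic site
#'
#' Produces the "measured" tables a field campaign would yield: a layer
#' table with noisy bulk densities and Cl/36Cl concentrations (geometry kept
#' nominal; the thickness uncertainty enters the declared error budget), a
#' flux table with noisy carrier amounts and concentrations, and the exact
#' forcing. The observation noise draws are seeded by `truth$seed + 1` and
#' are independent of the perturbation draws used later by the inference
#' engine.
#'
#' @param truth a [gen_site()] result.
#' @param noisy if `FALSE`, observations equal the truth exactly.
#' @param out_dir optional directory; when given, `layers.csv`,
#'   `fluxes.csv`, `forcing.csv` and `truth.json` are written there.
#' @return list with `dataset` (a [site_dataset()]), `forcing`, and `truth`.
#' @export
gen_observations <- function(truth, noisy = TRUE, out_dir = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  ns <- cfg$noise
  K <- nrow(truth$geometry)
  set.seed(truth$seed + 1L)
  jitter1 <- function(value, rel) {
    if (!noisy || rel == 0) return(value)
    perturb_trunc(length(value), value, rel)
  }

  thickness <- truth$geometry$bottom_cm - truth$geometry$top_cm
  conc_cl_true <- truth$stock_cl / (cfg$bulk_density * thickness * 1e4)
  conc_36_true <- truth$stock_cl36 / (cfg$bulk_density * thickness * 1e4)
  layers <- data.frame(
    k = seq_len(K),
    top_cm = truth$geometry$top_cm, bottom_cm = truth$geometry$bottom_cm,
    bulk_density = jitter1(cfg$bulk_density, ns$bulk_density),
    bd_rel_sigma = ns$bulk_density,
    soc_conc = truth$soc,
    cl_conc = jitter1(conc_cl_true, ns$concentration),
    cl_rel_sigma = ns$concentration,
    cl36_conc = jitter1(conc_36_true, ns$concentration),
    cl36_rel_sigma = ns$concentration
  )

  flux_row <- function(component, species, carrier_true, carrier_rel,
                       flux_true) {
    conc_true <- flux_true / carrier_true
    data.frame(
      component = component, species = species, year = cfg$flux_year,
      carrier_amount = jitter1(carrier_true, carrier_rel),
      carrier_rel_sigma = carrier_rel,
      concentration = jitter1(conc_true, ns$concentration),
      conc_rel_sigma = ns$concentration
    )
  }
  r36 <- cfg$background_cl36
  r_cl <- cfg$rainfall_cl
  fluxes <- rbind(
    flux_row("rainfall", "cl", cfg$rainfall_mm, ns$rainfall, r_cl),
    flux_row("rainfall", "cl36", cfg$rainfall_mm, ns$rainfall, r36),
    flux_row("throughfall", "cl", cfg$rainfall_mm, ns$rainfall, r_cl),
    flux_row("throughfall", "cl36", cfg$rainfall_mm, ns$rainfall, r36),
    flux_row("litterfall", "cl", cfg$litterfall_mass, ns$litterfall,
             cfg$lambda * r_cl),
    flux_row("litterfall", "cl36", cfg$litterfall_mass, ns$litterfall,
             cfg$lambda * r36),
    flux_row("drainage", "cl", cfg$drainage_mm, ns$drainage, r_cl),
    flux_row("drainage", "cl36", cfg$drainage_mm, ns$drainage,
             truth$drainage_cl36_fluxyear)
  )

  dataset <- site_dataset(layers, fluxes,
                          stock_year = cfg$stock_year,
                          flux_year = cfg$flux_year)
  out <- list(dataset = dataset, forcing = truth$forcing, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_site_tables(dataset,
                      file.path(out_dir, "layers.csv"),
                      file.path(out_dir, "fluxes.csv"))
    write_forcing_table(truth$forcing, file.path(out_dir, "forcing.csv"))
    jsonlite::write_json(
      list(seed = truth$seed, x = truth$x, t_r = truth$t_r,
           t_prime = truth$t_prime, soc = truth$soc,
           stock_cl = truth$stock_cl, stock_cl36 = truth$stock_cl36,
           synthetic = TRUE),
      file.path(out_dir, "truth.json"), digits = NA, auto_unbox = TRUE
    )
  }
  out
}

#' Score recovery of the truth by a posterior summary
#'
#' @param truth a [gen_site()] result.
#' @param posterior a [summarize_posteriors()] result from fitting the
#'   observations of the same site.
#' @return data.frame, one row per layer: `x_true`, `x_mean`, `x_sd`,
#'   `z_score` = (mean - truth)/sd, `covered95` (truth inside the raw
#'   2.5-97.5% interval of accepted X), `tprime_true`, `tprime_median`,
#'   `tprime_ratio` (median/truth).
#' @export
score_recovery <- function(truth, posterior) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(posterior, "posterior_summary"))
  if (nrow(posterior) != nrow(truth$geometry)) {
    stop("posterior summary and truth have different numbers of layers")
  }
  data.frame(
    k = posterior$k,
    x_true = truth$x,
    x_mean = posterior$x_mean,
    x_sd = posterior$x_sd,
    z_score = (posterior$x_mean - truth$x) / posterior$x_sd,
    covered95 = truth$x >= posterior$x_q025 & truth$x <= posterior$x_q975,
    tprime_true = truth$t_prime,
    tprime_median = posterior$tprime_median,
    tprime_ratio = posterior$tprime_median / truth$t_prime
  )
}
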