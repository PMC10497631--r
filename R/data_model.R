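#' @useDynLib cl36soil, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd quantile lm coef cor pnorm
#' @importFrom utils read.csv write.csv
NULL

# The two chlorine species every stock and flux is tagged with.
CL_SPECIES <- c("cl", "cl36")

# Canonical flux components (throughfall is accepted but the model only
# requires rainfall and litterfall; drainage is a measured output).
FLUX_COMPONENTS <- c("rainfall", "throughfall", "litterfall", "drainage")

assert_species <- function(species) {
  if (!all(species %in% CL_SPECIES)) {
    stop("species must be one of: ", paste(CL_SPECIES, collapse = ", "))
  }
  species
}

#' Validate a soil-layer table
#'
#' A layer table describes one soil profile, ordered from the surface down.
#' Required columns: `k` (1 = surface), `top_cm`, `bottom_cm`, `bulk_density`
#' (g cm^-3), `bd_rel_sigma`, `soc_conc` (g C per kg dry soil), `cl_conc` and
#' `cl36_conc` (atoms per g dry soil) with `cl_rel_sigma`, `cl36_rel_sigma`
#' (relative 1-sigma analytical uncertainties). Depth intervals are
#' closed-open `[top, bottom)` in cm and must be contiguous from 0.
#'
#' @param layers data.frame as above.
#' @return the validated data.frame (invisibly unchanged), with a computed
#'   `thickness_cm` column added if absent.
#' @export
validate_layers <- function(layers) {
  required <- c(
    "k", "top_cm", "bottom_cm", "bulk_density", "bd_rel_sigma",
    "soc_conc", "cl_conc", "cl_rel_sigma", "cl36_conc", "cl36_rel_sigma"
  )
  missing <- setdiff(required, names(layers))
  if (length(missing) > 0) {
    stop("layer table is missing column(s): ", paste(missing, collapse = ", "))
  }
  layers <- layers[order(layers$k), , drop = FALSE]
  if (!identical(as.integer(layers$k), seq_len(nrow(layers)))) {
    stop("layer indices k must be 1..n ordered from the surface")
  }
  if (any(layers$top_cm < 0) || any(layers$bottom_cm <= layers$top_cm)) {
    stop("each layer needs 0 <= top_cm < bottom_cm")
  }
  if (nrow(layers) > 1) {
    tops <- layers$top_cm[-1]
    bottoms <- layers$bottom_cm[-nrow(layers)]
    bad <- which(abs(tops - bottoms) > 1e-9)
    if (length(bad) > 0) {
      stop(sprintf(
        "layers %d and %d are not contiguous (bottom %g cm vs top %g cm)",
        bad[1], bad[1] + 1, bottoms[bad[1]], tops[bad[1]]
      ))
    }
  }
  num_nonneg <- c(
    "bulk_density", "bd_rel_sigma", "soc_conc",
    "cl_conc", "cl_rel_sigma", "cl36_conc", "cl36_rel_sigma"
  )
  for (col in num_nonneg) {
    if (any(is.na(layers[[col]])) || any(layers[[col]] < 0)) {
      stop("layer column '", col, "' must be non-negative and non-missing")
    }
  }
  if (any(layers$bulk_density <= 0)) {
    stop("layer column 'bulk_density' must be strictly positive")
  }
  layers$thickness_cm <- layers$bottom_cm - layers$top_cm
  layers
}

validate_fluxes <- function(fluxes) {
  required <- c(
    "component", "species", "year", "carrier_amount", "carrier_rel_sigma",
    "concentration", "conc_rel_sigma"
  )
  missing <- setdiff(required, names(fluxes))
  if (length(missing) > 0) {
    stop("flux table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(fluxes$component %in% FLUX_COMPONENTS)) {
    stop(
      "flux component must be one of: ",
      paste(FLUX_COMPONENTS, collapse = ", ")
    )
  }
  assert_species(fluxes$species)
  for (col in c("carrier_amount", "carrier_rel_sigma",
                "concentration", "conc_rel_sigma")) {
    if (any(is.na(fluxes[[col]])) || any(fluxes[[col]] < 0)) {
      stop("flux column '", col, "' must be non-negative and non-missing")
    }
  }
  fluxes
}

#' Bundle a site's layer and flux tables into one validated dataset
#'
#' @param layers layer table, see [validate_layers()].
#' @param fluxes flux table with columns `component` (rainfall, throughfall,
#'   litterfall, drainage), `species` (`"cl"`, `"cl36"`), `year`,
#'   `carrier_amount` (L water or g litter per m^2 per yr), `carrier_rel_sigma`,
#'   `concentration` (atoms per carrier unit), `conc_rel_sigma`.
#' @param stock_year calendar year the soil profile was sampled (stocks refer
#'   to this year).
#' @param flux_year calendar year of the flux measurements.
#' @return an object of class `"site_dataset"`.
#' @export
site_dataset <- function(layers, fluxes, stock_year = 2010, flux_year = 2012) {
  layers <- validate_layers(layers)
  fluxes <- validate_fluxes(fluxes)
  for (sp in CL_SPECIES) {
    for (comp in c("rainfall", "litterfall")) {
      if (!any(fluxes$component == comp & fluxes$species == sp)) {
        stop("flux table must contain the '", comp,
             "' component for species '", sp, "'")
      }
    }
  }
  structure(
    list(
      layers = layers, fluxes = fluxes,
      stock_year = as.integer(stock_year), flux_year = as.integer(flux_year)
    ),
    class = "site_dataset"
  )
}

#' @export
print.site_dataset <- function(x, ...) {
  cat(sprintf(
    "<site_dataset> %d soil layers (0-%g cm), %d flux rows; stocks %d, fluxes %d\n",
    nrow(x$layers), max(x$layers$bottom_cm), nrow(x$fluxes),
    x$stock_year, x$flux_year
  ))
  invisible(x)
}

#' Per-layer Cl or 36Cl stock from concentration, bulk density and thickness
#'
#' The stock of a layer is \eqn{S_k = C_k \rho_k d_k \times 10^4} atoms m^-2,
#' with \eqn{C_k} in atoms per g dry soil, \eqn{\rho_k} in g cm^-3 and
#' \eqn{d_k} in cm (the 10^4 converts cm^2 to m^2). The relative uncertainty
#' combines, in quadrature, the analytical concentration uncertainty, the
#' bulk-density uncertainty and the layer-thickness uncertainty.
#'
#' @param layers validated layer table (see [validate_layers()]).
#' @param species `"cl"`, `"cl36"`, or both (the default).
#' @param thickness_rel_sigma relative 1-sigma uncertainty of the layer
#'   thickness (default 0.10).
#' @return data.frame with columns `k`, `species`, `stock` (atoms m^-2) and
#'   `rel_sigma`.
#' @export
compute_stock <- function(layers, species = CL_SPECIES,
                          thickness_rel_sigma = 0.10) {
  layers <- validate_layers(layers)
  assert_species(species)
  if (thickness_rel_sigma < 0) stop("thickness_rel_sigma must be >= 0")
  out <- lapply(species, function(sp) {
    conc <- layers[[paste0(sp, "_conc")]]
    conc_rel <- layers[[paste0(sp, "_rel_sigma")]]
    data.frame(
      k = layers$k,
      species = sp,
      stock = conc * layers$bulk_density * layers$thickness_cm * 1e4,
      rel_sigma = propagate_rel_uncertainty(
        conc_rel, layers$bd_rel_sigma,
        rep_len(thickness_rel_sigma, nrow(layers))
      ),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Annual flux from a concentration and a carrier flux
#'
#' \eqn{F = C \Phi}: atoms per carrier unit times carrier units per m^2 per
#' year gives atoms m^-2 yr^-1. Relative uncertainties combine in quadrature.
#'
#' @param concentration a [measurement()]: atoms per carrier unit (per g
#'   litter or per L water).
#' @param carrier a [measurement()]: carrier flux (g litter or L water per
#'   m^2 per yr).
#' @return a [measurement()] holding the flux in atoms m^-2 yr^-1.
#' @export
compute_flux <- function(concentration, carrier) {
  stopifnot(inherits(concentration, "measurement"), inherits(carrier, "measurement"))
  measurement(
    value = concentration$value * carrier$value,
    rel_sigma = propagate_rel_uncertainty(
      concentration$rel_sigma, carrier$rel_sigma
    )
  )
}

#' All fluxes of a dataset as a flat table
#'
#' Applies [compute_flux()] row-wise to the dataset's flux table.
#'
#' @param dataset a [site_dataset()].
#' @return data.frame with columns `component`, `species`, `year`, `flux`
#'   (atoms m^-2 yr^-1), `rel_sigma`.
#' @export
compute_fluxes <- function(dataset) {
  stopifnot(inherits(dataset, "site_dataset"))
  fx <- dataset$fluxes
  f <- compute_flux(
    measurement(fx$concentration, fx$conc_rel_sigma),
    measurement(fx$carrier_amount, fx$carrier_rel_sigma)
  )
  data.frame(
    component = fx$component, species = fx$species, year = fx$year,
    flux = f$value, rel_sigma = f$rel_sigma, stringsAsFactors = FALSE
  )
}

#' Look up one flux from a computed flux table
#'
#' @param flux_table a [compute_fluxes()] result.
#' @param component,species the flux to extract.
#' @return a [measurement()] (atoms m^-2 yr^-1).
#' @export
get_flux <- function(flux_table, component, species) {
  row <- flux_table[flux_table$component == component &
                      flux_table$species == species, , drop = FALSE]
  if (nrow(row) == 0) {
    stop("no '", component, "' flux for species '", species, "' in dataset")
  }
  measurement(row$flux[1], row$rel_sigma[1])
}

#' 36Cl/Cl ratios of stocks and fluxes, with the enrichment diagnostic
#'
#' Computes the per-layer 36Cl/Cl stock ratio and the per-component flux
#' ratio, each with quadrature-propagated relative uncertainty, plus the
#' enrichment factor of each layer's stock ratio over the rainfall flux
#' ratio. Soil ratios well above the rainfall ratio indicate retention of
#' bomb-pulse 36Cl, i.e. retention durations reaching back to the 1952-1972
#' pulse.
#'
#' @param dataset a [site_dataset()].
#' @param thickness_rel_sigma passed to [compute_stock()].
#' @return list with data.frames `stock_ratios` (`k`, `ratio`, `rel_sigma`,
#'   `enrichment_vs_rainfall`) and `flux_ratios` (`component`, `ratio`,
#'   `rel_sigma`).
#' @export
ratio_profile <- function(dataset, thickness_rel_sigma = 0.10) {
  stopifnot(inherits(dataset, "site_dataset"))
  stocks <- compute_stock(dataset$layers,
                          thickness_rel_sigma = thickness_rel_sigma)
  s_cl <- stocks[stocks$species == "cl", ]
  s_36 <- stocks[stocks$species == "cl36", ]
  if (any(s_cl$stock == 0)) {
    stop("undefined 36Cl/Cl ratio: zero Cl stock in layer ",
         s_cl$k[which(s_cl$stock == 0)[1]])
  }
  stock_ratios <- data.frame(
    k = s_cl$k,
    ratio = s_36$stock / s_cl$stock,
    rel_sigma = propagate_rel_uncertainty(s_36$rel_sigma, s_cl$rel_sigma)
  )

  fx <- compute_fluxes(dataset)
  comps <- unique(fx$component)
  flux_ratios <- do.call(rbind, lapply(comps, function(cp) {
    f_cl <- fx[fx$component == cp & fx$species == "cl", , drop = FALSE]
    f_36 <- fx[fx$component == cp & fx$species == "cl36", , drop = FALSE]
    if (nrow(f_cl) == 0 || nrow(f_36) == 0) return(NULL)
    if (f_cl$flux[1] == 0) {
      stop("undefined 36Cl/Cl ratio: zero Cl flux for component '", cp, "'")
    }
    data.frame(
      component = cp,
      ratio = f_36$flux[1] / f_cl$flux[1],
      rel_sigma = propagate_rel_uncertainty(f_36$rel_sigma[1], f_cl$rel_sigma[1]),
      stringsAsFactors = FALSE
    )
  }))
  rain <- flux_ratios$ratio[flux_ratios$component == "rainfall"]
  stock_ratios$enrichment_vs_rainfall <-
    if (length(rain) == 1 && rain > 0) stock_ratios$ratio / rain else NA_real_
  list(stock_ratios = stock_ratios, flux_ratios = flux_ratios)
}
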