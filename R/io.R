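# Delimited-table IO. Every table carries a units row directly under the
# header so files are self-describing; units are validated on read.

LAYER_UNITS <- c(
  k = "-", top_cm = "cm", bottom_cm = "cm",
  bulk_density = "g cm-3", bd_rel_sigma = "rel 1sigma",
  soc_conc = "g kg-1",
  cl_conc = "at g-1", cl_rel_sigma = "rel 1sigma",
  cl36_conc = "at g-1", cl36_rel_sigma = "rel 1sigma"
)

FLUX_UNITS <- c(
  component = "-", species = "-", year = "yr",
  carrier_amount = "carrier m-2 yr-1", carrier_rel_sigma = "rel 1sigma",
  concentration = "at per carrier unit", conc_rel_sigma = "rel 1sigma"
)

FORCING_UNITS <- c(year = "yr", species = "-", flux = "at m-2 yr-1")

write_units_csv <- function(df, units, path) {
  df <- df[, names(units), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(units), collapse = ","), con)
  writeLines(paste(unname(units), collapse = ","), con)
  utils::write.table(
    df, con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

read_units_csv <- function(path, units, numeric_cols) {
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing <- setdiff(names(units), names(raw))
  if (length(missing) > 0) {
    stop("'", basename(path), "' is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(raw) < 1) {
    stop("'", basename(path), "' has no units row (line 2 must declare units)")
  }
  got_units <- unlist(raw[1, names(units)])
  bad <- which(got_units != unname(units))
  if (length(bad) > 0) {
    stop(sprintf(
      "'%s': unit mismatch in column '%s' (line 2): got '%s', expected '%s'",
      basename(path), names(units)[bad[1]], got_units[bad[1]], units[bad[1]]
    ))
  }
  df <- raw[-1, names(units), drop = FALSE]
  rownames(df) <- NULL
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad) > 0) {
      stop(sprintf(
        "'%s': column '%s', data row %d: cannot parse '%s' as a number",
        basename(path), col, bad[1], df[[col]][bad[1]]
      ))
    }
    df[[col]] <- vals
  }
  df
}

#' Read a site's layer and flux tables
#'
#' Both files are comma-separated with a header line and a mandatory units
#' row (line 2). All invariants (layer contiguity, non-negativity, presence
#' of rainfall and litterfall fluxes for both species) are validated; a
#' violation raises a descriptive error naming the offending column or
#' layers.
#'
#' @param layers_path path to `layers.csv`.
#' @param fluxes_path path to `fluxes.csv`.
#' @param stock_year,flux_year calendar years, see [site_dataset()].
#' @return a [site_dataset()].
#' @export
read_site_tables <- function(layers_path, fluxes_path,
                             stock_year = 2010, flux_year = 2012) {
  layers <- read_units_csv(layers_path, LAYER_UNITS,
                           numeric_cols = setdiff(names(LAYER_UNITS), NULL))
  layers$k <- as.integer(layers$k)
  fluxes <- read_units_csv(
    fluxes_path, FLUX_UNITS,
    numeric_cols = c("year", "carrier_amount", "carrier_rel_sigma",
                     "concentration", "conc_rel_sigma")
  )
  site_dataset(layers, fluxes, stock_year = stock_year, flux_year = flux_year)
}

#' Write a site dataset back to `layers.csv` and `fluxes.csv`
#'
#' Inverse of [read_site_tables()]: `read_site_tables(write_site_tables(d))`
#' reproduces `d` up to float formatting.
#'
#' @param dataset a [site_dataset()].
#' @param layers_path,fluxes_path output paths.
#' @return invisibly, the two paths.
#' @export
write_site_tables <- function(dataset, layers_path, fluxes_path) {
  stopifnot(inherits(dataset, "site_dataset"))
  write_units_csv(dataset$layers, LAYER_UNITS, layers_path)
  write_units_csv(dataset$fluxes, FLUX_UNITS, fluxes_path)
  invisible(c(layers = layers_path, fluxes = fluxes_path))
}
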