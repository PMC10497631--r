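# Annual Cl and 36Cl deposition scenario: constant cosmogenic background,
# plus the 1952-1972 anthropogenic bomb pulse for 36Cl only. Litterfall
# returns a fixed fraction (default 11%) of the same-year rainfall input of
# each species to the soil surface.

#' Parametric shape of the 1952-1972 anthropogenic 36Cl pulse
#'
#' A discretised asymmetric unimodal (gamma-shaped) curve over the bomb-test
#' window, peaking in 1963 by default, with non-negative yearly weights
#' normalised to sum to 1. The amplitude multiplier scales the *window
#' average* of the anthropogenic input relative to the cosmogenic background:
#' with `amplitude = 1000` the mean deposition across the window is three
#' orders of magnitude above background (the peak year higher still).
#'
#' @param window integer length-2, first and last year of the pulse
#'   (default `c(1952, 1972)`).
#' @param peak peak year (default 1963, early-sixties maximum).
#' @param amplitude mean multiplier relative to background over the window
#'   (default 1000).
#' @param rate gamma rate parameter controlling asymmetry/width of the
#'   discretised shape (default 0.35 yr^-1).
#' @return an object of class `"pulse_shape"`: list with `window`, `peak`,
#'   `amplitude`, `years` and normalised `weights`.
#' @export
pulse_shape <- function(window = c(1952, 1972), peak = 1963,
                        amplitude = 1000, rate = 0.35) {
  window <- as.integer(window)
  if (length(window) != 2 || window[2] < window[1]) {
    stop("pulse window must be c(first, last) with first <= last")
  }
  if (peak < window[1] || peak > window[2]) {
    stop("pulse peak year must lie inside the window")
  }
  if (amplitude < 0) stop("pulse amplitude must be >= 0")
  years <- seq(window[1], window[2])
  # gamma density with mode at the peak year; offsets at year mid-points
  shape <- 1 + rate * (peak - window[1])
  w <- stats::dgamma(years - window[1] + 0.5, shape = shape, rate = rate)
  w <- w / sum(w)
  structure(
    list(window = window, peak = as.integer(peak),
         amplitude = amplitude, years = years, weights = w),
    class = "pulse_shape"
  )
}

new_forcing_scenario <- function(series, background, lambda, pulse = NULL) {
  structure(
    list(series = series, background = background,
         lambda = lambda, pulse = pulse),
    class = "forcing_scenario"
  )
}

#' Build the annual deposition scenario
#'
#' Outside the pulse window the 36Cl rainfall input equals the cosmogenic
#' background exactly; inside it is
#' `background * (1 + amplitude * weight_t * n_window)`, so the total
#' anthropogenic deposition equals `amplitude * background * n_window` by
#' construction. The Cl rainfall input is constant (no anthropogenic Cl
#' pulse). Litterfall inputs are `lambda` times the same-year rainfall input
#' of each species.
#'
#' @param background_cl36,background_cl constant rainfall input fluxes
#'   (atoms m^-2 yr^-1), taken from the modern measured rainfall fluxes.
#' @param pulse a [pulse_shape()] (applied to 36Cl only), or `NULL` for a
#'   background-only scenario.
#' @param lambda litterfall fraction of the rainfall input (default 0.11).
#' @param years simulation years (default 1940:2020).
#' @return an object of class `"forcing_scenario"` whose `series` element is
#'   a data.frame with columns `year`, `r_cl36`, `r_cl`, `l_cl36`, `l_cl`
#'   (all atoms m^-2 yr^-1).
#' @export
build_forcing <- function(background_cl36, background_cl,
                          pulse = pulse_shape(), lambda = 0.11,
                          years = 1940:2020) {
  if (background_cl36 < 0 || background_cl < 0) {
    stop("background fluxes must be >= 0")
  }
  if (lambda < 0) stop("litterfall fraction lambda must be >= 0")
  years <- as.integer(years)
  if (any(diff(years) != 1L)) stop("years must be consecutive")
  r36 <- rep(background_cl36, length(years))
  if (!is.null(pulse)) {
    stopifnot(inherits(pulse, "pulse_shape"))
    if (pulse$window[1] < years[1] || pulse$window[2] > years[length(years)]) {
      stop("pulse window must lie within the scenario years")
    }
    idx <- match(pulse$years, years)
    nwin <- length(pulse$years)
    r36[idx] <- background_cl36 * (1 + pulse$amplitude * pulse$weights * nwin)
  }
  r_cl <- rep(background_cl, length(years))
  series <- data.frame(
    year = years,
    r_cl36 = r36, r_cl = r_cl,
    l_cl36 = lambda * r36, l_cl = lambda * r_cl
  )
  new_forcing_scenario(
    series,
    background = c(cl36 = background_cl36, cl = background_cl),
    lambda = lambda, pulse = pulse
  )
}

#' @export
print.forcing_scenario <- function(x, ...) {
  yr <- x$series$year
  cat(sprintf(
    "<forcing_scenario> %d-%d; background 36Cl %.3g, Cl %.3g at m-2 yr-1; lambda %.2f\n",
    yr[1], yr[length(yr)], x$background["cl36"], x$background["cl"], x$lambda
  ))
  if (!is.null(x$pulse)) {
    cat(sprintf(
      "  36Cl pulse %d-%d, peak %d, mean amplitude %g x background\n",
      x$pulse$window[1], x$pulse$window[2], x$pulse$peak, x$pulse$amplitude
    ))
  }
  invisible(x)
}

#' Write a forcing scenario as a long-format table
#'
#' @param scenario a [build_forcing()] scenario.
#' @param path output path (`forcing.csv`: year, species, flux, with a units
#'   row). Only the rainfall series is written; litterfall is derived from
#'   `lambda` on load.
#' @return invisibly, `path`.
#' @export
write_forcing_table <- function(scenario, path) {
  stopifnot(inherits(scenario, "forcing_scenario"))
  s <- scenario$series
  long <- rbind(
    data.frame(year = s$year, species = "cl36", flux = s$r_cl36),
    data.frame(year = s$year, species = "cl", flux = s$r_cl)
  )
  write_units_csv(long, FORCING_UNITS, path)
  invisible(path)
}

#' Load a forcing scenario from a long-format table
#'
#' The table supplies the annual 36Cl (and optionally Cl) rainfall input;
#' missing years are never interpolated silently: with `fill = "error"` a
#' gap raises an error naming the year, with `fill = "background"` gaps are
#' filled by the declared background value.
#'
#' @param path `forcing.csv` (year, species, flux; units row mandatory).
#' @param background named vector `c(cl36 = , cl = )` declaring the
#'   background fluxes; required for gap filling and for species absent from
#'   the table.
#' @param lambda litterfall fraction of the rainfall input (default 0.11).
#' @param years year range of the scenario; default spans the table.
#' @param fill `"error"` (default) or `"background"`.
#' @return a `"forcing_scenario"`.
#' @export
load_forcing_table <- function(path, background, lambda = 0.11, years = NULL,
                               fill = c("error", "background")) {
  fill <- match.arg(fill)
  if (!all(c("cl36", "cl") %in% names(background))) {
    stop("background must be a named vector with entries 'cl36' and 'cl'")
  }
  tab <- read_units_csv(path, FORCING_UNITS,
                        numeric_cols = c("year", "flux"))
  assert_species(tab$species)
  if (any(tab$flux < 0)) stop("forcing fluxes must be >= 0")
  if (is.null(years)) years <- seq(min(tab$year), max(tab$year))
  years <- as.integer(years)
  get_series <- function(sp) {
    sub <- tab[tab$species == sp, , drop = FALSE]
    if (nrow(sub) == 0) return(rep(background[[sp]], length(years)))
    if (any(diff(sub$year) <= 0)) {
      stop("forcing years for species '", sp, "' must be strictly increasing")
    }
    idx <- match(years, sub$year)
    if (anyNA(idx)) {
      if (fill == "error") {
        stop("forcing table is missing year ", years[which(is.na(idx))[1]],
             " for species '", sp, "' (fill policy is 'error')")
      }
      out <- ifelse(is.na(idx), background[[sp]], sub$flux[idx])
      return(out)
    }
    sub$flux[idx]
  }
  r36 <- get_series("cl36")
  r_cl <- get_series("cl")
  series <- data.frame(
    year = years, r_cl36 = r36, r_cl = r_cl,
    l_cl36 = lambda * r36, l_cl = lambda * r_cl
  )
  new_forcing_scenario(series,
                       background = c(cl36 = background[["cl36"]],
                                      cl = background[["cl"]]),
                       lambda = lambda, pulse = NULL)
}
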