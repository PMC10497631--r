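#' First-order (quadrature) propagation of relative uncertainties
#'
#' Combines the relative 1-sigma uncertainties of the multiplicative factors
#' of a product (or quotient) into the relative 1-sigma uncertainty of the
#' result: \eqn{\sigma_{rel} = \sqrt{\sum_i \sigma_{rel,i}^2}}.
#'
#' All stocks and fluxes handled by this package are products of measured
#' factors (concentration x bulk density x thickness; concentration x carrier
#' flux), so relative quadrature is the classical propagation rule for every
#' derived quantity. For sums of independent quantities use
#' [propagate_abs_uncertainty()].
#'
#' @param rel_sigmas numeric vector (or several numeric arguments, recycled to
#'   a common length) of relative 1-sigma uncertainties, all `>= 0`.
#' @return the combined relative 1-sigma uncertainty. When several vector
#'   arguments are given the combination is elementwise.
#' @examples
#' propagate_rel_uncertainty(c(0.02, 0.05, 0.10)) # 0.1135782
#' propagate_rel_uncertainty(0.05, 0.05, 0.10)    # per-element quadrature
#' @export
propagate_rel_uncertainty <- function(...) {
  args <- list(...)
  if (length(args) == 1L) {
    rel <- as.numeric(args[[1L]])
    if (any(is.na(rel)) || any(rel < 0)) {
      stop("relative uncertainties must be non-negative and non-missing")
    }
    return(sqrt(sum(rel^2)))
  }
  for (a in args) {
    if (any(is.na(a)) || any(a < 0)) {
      stop("relative uncertainties must be non-negative and non-missing")
    }
  }
  sqrt(Reduce(`+`, lapply(args, function(a) as.numeric(a)^2)))
}

#' Quadrature propagation of absolute uncertainties (sums/differences)
#'
#' @param abs_sigmas numeric vector of absolute 1-sigma uncertainties, `>= 0`.
#' @return combined absolute 1-sigma uncertainty, `sqrt(sum(abs_sigmas^2))`.
#' @export
propagate_abs_uncertainty <- function(abs_sigmas) {
  abs_sigmas <- as.numeric(abs_sigmas)
  if (any(is.na(abs_sigmas)) || any(abs_sigmas < 0)) {
    stop("absolute uncertainties must be non-negative and non-missing")
  }
  sqrt(sum(abs_sigmas^2))
}

#' A measured quantity with relative 1-sigma uncertainty
#'
#' Light container pairing a non-negative value with its relative 1-sigma
#' uncertainty. Vectorised: `value` and `rel_sigma` are recycled to a common
#' length.
#'
#' @param value numeric, `>= 0`.
#' @param rel_sigma numeric, relative 1-sigma uncertainty, `>= 0`.
#' @return an object of class `"measurement"`: a list with numeric fields
#'   `value` and `rel_sigma` of equal length.
#' @export
measurement <- function(value, rel_sigma = 0) {
  value <- as.numeric(value)
  rel_sigma <- as.numeric(rel_sigma)
  if (any(is.na(value)) || any(value < 0)) {
    stop("measurement 'value' must be non-negative and non-missing")
  }
  if (any(is.na(rel_sigma)) || any(rel_sigma < 0)) {
    stop("measurement 'rel_sigma' must be non-negative and non-missing")
  }
  n <- max(length(value), length(rel_sigma))
  structure(
    list(value = rep_len(value, n), rel_sigma = rep_len(rel_sigma, n)),
    class = "measurement"
  )
}

#' @export
print.measurement <- function(x, ...) {
  cat(sprintf(
    "%g +/- %g%% (1 sigma, relative)\n",
    x$value, 100 * x$rel_sigma
  ), sep = "")
  invisible(x)
}

#' Absolute 1-sigma uncertainty of a measurement
#' @param x a [measurement()].
#' @return numeric vector, `value * rel_sigma`.
#' @export
abs_sigma <- function(x) {
  stopifnot(inherits(x, "measurement"))
  x$value * x$rel_sigma
}
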