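# Annual per-layer mass balance for Cl and 36Cl.
#
# Each soil layer k holds a stock S_k,t (atoms m^-2). Every year a fraction
# X_k of the layer's input I_k,t is retained (chlorination into organic
# matter) and a fraction Z_k of the standing stock is released back to
# solution:
#
#   S_k,t = (1 - Z_k) S_k,t-1 + X_k I_k,t dt
#   D_k,t = (1 - X_k) I_k,t + Z_k S_k,t-1 / dt - A_k,t
#
# The surface layer is fed by rainfall + litterfall; deeper layers by the
# drainage of the layer above (same year). Root absorption A_k,t returns
# chlorine to the canopy; summed over the profile it equals the annual
# litterfall (steady-state vegetation), split over depth by an exponential
# root profile.

#' Exponential root-absorption depth weights
#'
#' Root absorption is distributed over the profile proportionally to the
#' integral of `exp(-z / z0)` over each layer, normalised to sum to 1 over
#' the profile, so that the total annual absorption equals the annual
#' litterfall by construction.
#'
#' @param geometry data.frame with columns `top_cm` and `bottom_cm`
#'   describing contiguous layers from the surface (a layer table works).
#' @param z0 root e-folding depth in cm (default 15); `Inf` gives weights
#'   proportional to layer thickness.
#' @return numeric vector of per-layer weights summing to 1.
#' @export
root_absorption_weights <- function(geometry, z0 = 15) {
  if (!all(c("top_cm", "bottom_cm") %in% names(geometry))) {
    stop("geometry needs columns 'top_cm' and 'bottom_cm'")
  }
  if (is.na(z0) || z0 <= 0) stop("root e-folding depth z0 must be > 0")
  top <- geometry$top_cm
  bottom <- geometry$bottom_cm
  if (is.infinite(z0)) {
    w <- bottom - top
  } else {
    w <- exp(-top / z0) - exp(-bottom / z0)
  }
  w / sum(w)
}

#' Steady-state Cl input cascade down the profile
#'
#' At steady state each layer's drainage equals its input minus what roots
#' absorb, so the input cascades down as `I_1 = R + L`,
#' `I_(k+1) = I_k - A_k`. The total absorption must equal the litterfall
#' (`sum(A) = L`), which makes the deepest drainage equal the rainfall.
#'
#' @param rainfall,litterfall annual fluxes R and L (atoms m^-2 yr^-1).
#' @param absorption per-layer absorption fluxes `A_k` with `sum(A) = L`.
#' @param tol relative tolerance on the closure `sum(A) = L` (default 1e-6).
#' @return per-layer input fluxes `I_k` (atoms m^-2 yr^-1), non-increasing
#'   with depth and independent of the retained fractions.
#' @export
cl_input_cascade <- function(rainfall, litterfall, absorption, tol = 1e-6) {
  if (rainfall < 0 || litterfall < 0 || any(absorption < 0)) {
    stop("fluxes must be >= 0")
  }
  closure <- abs(sum(absorption) - litterfall)
  scale <- max(litterfall, sum(absorption), .Machine$double.xmin)
  if (closure > tol * scale) {
    stop(sprintf(
      "root-absorption closure violated: sum(A) = %g but litterfall = %g",
      sum(absorption), litterfall
    ))
  }
  n <- length(absorption)
  (rainfall + litterfall) - cumsum(c(0, absorption[-n]))
}

#' Residence time of chlorine in a layer
#'
#' `T_R = S / I`: standing stock over total annual input, at steady state.
#'
#' @param stock standing stock S (atoms m^-2).
#' @param input annual input flux I (atoms m^-2 yr^-1), `> 0`.
#' @return residence time in years.
#' @export
residence_time <- function(stock, input) {
  if (any(stock < 0)) stop("stock must be >= 0")
  if (any(input <= 0)) stop("input flux must be > 0 for a residence time")
  stock / input
}

#' Retention duration of chlorine in organic matter
#'
#' `T'_R = S / (X I)`: the stock over the *retained* part of the input.
#' Because only the fraction X of the input feeds the organic stock, the
#' retention duration exceeds the residence time by a factor 1/X; it proxies
#' the median age of the active soil organic carbon the chlorine rides on.
#'
#' @param stock standing stock S (atoms m^-2).
#' @param x retained fraction X in `(0, 1]`.
#' @param input annual input flux I (atoms m^-2 yr^-1), `> 0`.
#' @return retention duration in years; `X = 0` yields `Inf` with a warning
#'   (no retained input: undefined duration).
#' @export
retention_duration <- function(stock, x, input) {
  if (any(x < 0) || any(x > 1)) stop("retained fraction x must lie in [0, 1]")
  if (any(x == 0)) {
    warning("retained fraction x = 0: retention duration is infinite")
  }
  residence_time(stock, input) / x
}

#' Release fraction from the retained fraction and residence time
#'
#' `Z = X dt / T_R`. At steady state the retained input `X I` must balance
#' the released stock `Z S / dt`, which pins Z to X through the residence
#' time and leaves X as the model's only free parameter per layer.
#'
#' @param x retained fraction in `[0, 1]`.
#' @param t_r residence time (yr), `> 0`.
#' @param dt time step (yr), default 1.
#' @return release fraction Z in `[0, 1]`; an error if the implied Z exceeds
#'   1 (the stock turns over faster than one time step allows: X is
#'   infeasibly large for that residence time).
#' @export
z_from_x <- function(x, t_r, dt = 1) {
  if (any(x < 0) || any(x > 1)) stop("retained fraction x must lie in [0, 1]")
  if (any(t_r <= 0)) stop("residence time t_r must be > 0")
  z <- x * dt / t_r
  if (any(z > 1)) {
    stop(sprintf(
      "infeasible release fraction Z = %g > 1 (X = %g too large for T_R = %g yr)",
      max(z), x[which.max(z)], t_r[which.max(z)]
    ))
  }
  z
}

#' Pre-bomb steady-state 36Cl stock
#'
#' Before the bomb tests the cosmogenic 36Cl input was constant, so the
#' profile was at steady state for 36Cl too; absent isotopic fractionation
#' the 36Cl residence time equals the Cl one, giving
#' `S_0(36Cl) = I(36Cl) * T_R(Cl)` per layer.
#'
#' @param input_cl36 pre-bomb per-layer 36Cl input fluxes (atoms m^-2 yr^-1).
#' @param t_r_cl per-layer Cl residence times (yr).
#' @return per-layer initial 36Cl stocks (atoms m^-2).
#' @export
initial_cl36_stock <- function(input_cl36, t_r_cl) {
  if (any(input_cl36 < 0)) stop("input_cl36 must be >= 0")
  if (any(t_r_cl < 0)) stop("t_r_cl must be >= 0")
  input_cl36 * t_r_cl
}

#' One annual update of a single layer
#'
#' Applies the stock update and drainage balance verbatim:
#' `S_new = (1 - Z) S_prev + X I dt` and
#' `D = (1 - X) I + Z S_prev / dt - A`. The conservation identity
#' `I = (S_new - S_prev)/dt + D + A` holds exactly by construction. If the
#' requested absorption exceeds the mobile pool, drainage is clamped at 0
#' and the event flagged (conservation then breaks by the clamped amount,
#' which the caller records).
#'
#' @param s_prev previous-year stock (atoms m^-2).
#' @param input annual input flux I (atoms m^-2 yr^-1).
#' @param x,z retained and release fractions in `[0, 1]`.
#' @param absorption root absorption flux A (atoms m^-2 yr^-1).
#' @param dt time step (yr), default 1.
#' @return list with `stock` (S_new), `drainage` (D) and logical `clamped`.
#' @export
step_layer <- function(s_prev, input, x, z, absorption, dt = 1) {
  if (any(s_prev < 0) || any(input < 0) || any(absorption < 0)) {
    stop("stocks and fluxes must be >= 0")
  }
  if (any(x < 0) || any(x > 1) || any(z < 0) || any(z > 1)) {
    stop("x and z must lie in [0, 1]")
  }
  s_new <- (1 - z) * s_prev + x * input * dt
  d <- (1 - x) * input + z * s_prev / dt - absorption
  clamped <- d < 0
  d[clamped] <- 0
  list(stock = s_new, drainage = d, clamped = clamped)
}

#' Forward-simulate the full profile for both species
#'
#' Runs the annual mass balance for chlorine and chlorine-36 over all layers
#' and all scenario years, top layer downward so the same-year drainage of a
#' layer feeds the one below. Chlorine is at steady state (constant forcing,
#' stocks initialised at `I * T_R`); 36Cl starts from its pre-bomb
#' steady-state stock and responds to the bomb pulse.
#'
#' Root absorption of 36Cl is non-fractionating passive uptake from soil
#' solution: by default (`absorption_mode = "mobile"`) it carries the
#' isotopic ratio of the layer's mobile pool
#' `(1 - X) I + Z S_prev / dt`; the alternative `"rainfall"` mode uses the
#' same-year rainfall ratio.
#'
#' @param geometry layer geometry (`top_cm`, `bottom_cm`), contiguous from 0.
#' @param x per-layer retained fractions X in `[0, 1]`.
#' @param t_r per-layer Cl residence times (yr).
#' @param forcing a [build_forcing()] scenario; its first year must be
#'   pre-bomb (background) so the steady-state initialisation is valid.
#' @param z0 root e-folding depth (cm), default 15.
#' @param absorption_mode `"mobile"` (default) or `"rainfall"`, see above.
#' @param s0_cl36,s0_cl optional initial stocks overriding the steady-state
#'   initialisation (atoms m^-2, one per layer).
#' @param dt time step (yr), default 1.
#' @return an object of class `"cl36_simulation"`: per species, `K x T`
#'   matrices `S`, `D`, `A`, `I` (stock, drainage, absorption, input) over
#'   layers x years, plus `years`, the model parameters and a clamp log.
#' @export
simulate_profile <- function(geometry, x, t_r, forcing, z0 = 15,
                             absorption_mode = c("mobile", "rainfall"),
                             s0_cl36 = NULL, s0_cl = NULL, dt = 1) {
  absorption_mode <- match.arg(absorption_mode)
  stopifnot(inherits(forcing, "forcing_scenario"))
  K <- nrow(geometry)
  if (length(x) != K || length(t_r) != K) {
    stop("x and t_r must have one entry per layer")
  }
  z <- z_from_x(x, t_r, dt)
  w <- root_absorption_weights(geometry, z0)
  ser <- forcing$series
  years <- ser$year
  T_n <- length(years)

  # steady-state Cl cascade from the (constant) Cl forcing
  i_cl <- cl_input_cascade(ser$r_cl[1], ser$l_cl[1], w * ser$l_cl[1])
  if (is.null(s0_cl)) s0_cl <- i_cl * t_r
  # pre-bomb 36Cl cascade shares the Cl attenuation factors (no fractionation)
  i36_0 <- (ser$r_cl36[1] + ser$l_cl36[1]) * i_cl / i_cl[1]
  if (is.null(s0_cl36)) s0_cl36 <- initial_cl36_stock(i36_0, t_r)
  if (length(s0_cl) != K || length(s0_cl36) != K) {
    stop("initial stocks must have one entry per layer")
  }

  mat <- function() matrix(0, nrow = K, ncol = T_n)
  S_cl <- mat(); D_cl <- mat(); A_cl <- mat(); I_cl <- mat()
  S_36 <- mat(); D_36 <- mat(); A_36 <- mat(); I_36 <- mat()
  clamp_log <- list()

  s_prev_cl <- s0_cl
  s_prev_36 <- s0_cl36
  for (t in seq_len(T_n)) {
    for (k in seq_len(K)) {
      in_cl <- if (k == 1) ser$r_cl[t] + ser$l_cl[t] else D_cl[k - 1, t]
      a_cl <- w[k] * ser$l_cl[t]
      st_cl <- step_layer(s_prev_cl[k], in_cl, x[k], z[k], a_cl, dt)

      in_36 <- if (k == 1) ser$r_cl36[t] + ser$l_cl36[t] else D_36[k - 1, t]
      mobile_cl <- (1 - x[k]) * in_cl + z[k] * s_prev_cl[k] / dt
      ratio <- if (absorption_mode == "mobile") {
        mobile_36 <- (1 - x[k]) * in_36 + z[k] * s_prev_36[k] / dt
        if (mobile_cl > 0) mobile_36 / mobile_cl else 0
      } else {
        if (ser$r_cl[t] > 0) ser$r_cl36[t] / ser$r_cl[t] else 0
      }
      a_36 <- a_cl * ratio
      st_36 <- step_layer(s_prev_36[k], in_36, x[k], z[k], a_36, dt)

      if (st_cl$clamped || st_36$clamped) {
        clamp_log[[length(clamp_log) + 1L]] <- data.frame(
          species = c("cl", "cl36")[c(st_cl$clamped, st_36$clamped)],
          k = k, year = years[t]
        )
      }
      S_cl[k, t] <- st_cl$stock; D_cl[k, t] <- st_cl$drainage
      A_cl[k, t] <- a_cl; I_cl[k, t] <- in_cl
      S_36[k, t] <- st_36$stock; D_36[k, t] <- st_36$drainage
      A_36[k, t] <- a_36; I_36[k, t] <- in_36
    }
    s_prev_cl <- S_cl[, t]
    s_prev_36 <- S_36[, t]
  }

  clamp_log <- if (length(clamp_log) > 0) {
    do.call(rbind, clamp_log)
  } else {
    data.frame(species = character(), k = integer(), year = integer())
  }
  if (nrow(clamp_log) > 0) {
    warning(sprintf(
      "drainage clamped at 0 in %d layer-year cell(s); see $clamp_log",
      nrow(clamp_log)
    ))
  }
  structure(
    list(
      species = list(
        cl = list(S = S_cl, D = D_cl, A = A_cl, I = I_cl, S0 = s0_cl),
        cl36 = list(S = S_36, D = D_36, A = A_36, I = I_36, S0 = s0_cl36)
      ),
      years = years,
      params = list(x = x, t_r = t_r, z = z, z0 = z0, dt = dt,
                    absorption_mode = absorption_mode, weights = w,
                    i_cl = i_cl, i36_prebomb = i36_0),
      clamp_log = clamp_log,
      geometry = geometry[, c("top_cm", "bottom_cm")]
    ),
    class = "cl36_simulation"
  )
}

#' @export
print.cl36_simulation <- function(x, ...) {
  cat(sprintf(
    "<cl36_simulation> %d layers x %d years (%d-%d), absorption '%s', %d clamp(s)\n",
    nrow(x$species$cl$S), length(x$years), x$years[1],
    x$years[length(x$years)], x$params$absorption_mode, nrow(x$clamp_log)
  ))
  invisible(x)
}

#' Stocks at a given year
#'
#' @param sim a [simulate_profile()] result.
#' @param year calendar year (must lie in the simulated range).
#' @param species `"cl36"` (default) or `"cl"`.
#' @return per-layer stocks (atoms m^-2) at the end of `year`.
#' @export
stocks_at <- function(sim, year, species = "cl36") {
  stopifnot(inherits(sim, "cl36_simulation"))
  assert_species(species)
  t <- match(year, sim$years)
  if (is.na(t)) stop("year ", year, " is outside the simulated range")
  sim$species[[species]]$S[, t]
}

#' Per-cell conservation residuals of a simulation
#'
#' For every layer and year the update satisfies
#' `I = (S_t - S_t-1)/dt + D + A` algebraically; this returns the residuals
#' relative to the input flux so tests can assert the identity to machine
#' precision. Cells where drainage was clamped are exempt (the clamp
#' deliberately breaks the balance and is logged instead).
#'
#' @param sim a [simulate_profile()] result.
#' @return list with per-species residual matrices and `max_rel`, the
#'   largest relative residual over all non-clamped cells.
#' @export
conservation_residuals <- function(sim) {
  stopifnot(inherits(sim, "cl36_simulation"))
  dt <- sim$params$dt
  out <- list()
  max_rel <- 0
  for (sp in names(sim$species)) {
    m <- sim$species[[sp]]
    s_prev <- cbind(m$S0, m$S[, -ncol(m$S), drop = FALSE])
    res <- m$I - (m$S - s_prev) / dt - m$D - m$A
    scale <- pmax(abs(m$I), max(abs(m$I)) * 1e-12, .Machine$double.xmin)
    rel <- abs(res) / scale
    if (nrow(sim$clamp_log) > 0) {
      cl <- sim$clamp_log[sim$clamp_log$species == sp, , drop = FALSE]
      if (nrow(cl) > 0) {
        rel[cbind(cl$k, match(cl$year, sim$years))] <- 0
      }
    }
    out[[sp]] <- rel
    max_rel <- max(max_rel, rel)
  }
  out$max_rel <- max_rel
  out
}

#' Long-format trajectory export
#'
#' @param sim a [simulate_profile()] result.
#' @return data.frame with columns `species`, `k`, `year`, `S`, `D`, `A`,
#'   `I` — one row per species, layer and year.
#' @export
trajectory_table <- function(sim) {
  stopifnot(inherits(sim, "cl36_simulation"))
  K <- nrow(sim$species$cl$S)
  rows <- lapply(names(sim$species), function(sp) {
    m <- sim$species[[sp]]
    data.frame(
      species = sp,
      k = rep(seq_len(K), times = length(sim$years)),
      year = rep(sim$years, each = K),
      S = as.vector(m$S), D = as.vector(m$D),
      A = as.vector(m$A), I = as.vector(m$I)
    )
  })
  do.call(rbind, rows)
}
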