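# Monte-Carlo rejection inference of the per-layer retained fractions X_k
# against the measured 36Cl stocks, under measurement uncertainty on every
# input.

#' Monte-Carlo configuration
#'
#' @param n number of replicates (default 10000). Each replicate perturbs
#'   every measured quantity with a normal draw (truncated at 0) at its
#'   declared 1-sigma uncertainty.
#' @param seed integer seed, or `NULL` to leave the RNG state alone.
#' @param tolerance acceptance half-width as a multiple `m` of the measured
#'   stock's 1-sigma uncertainty (default 1: accepted simulations fall
#'   within measurement uncertainty of the observed stock).
#' @param gap_threshold X-gap (in X units) used to split disjoint solution
#'   branches, see [select_lowest_branch()]; default 0.05.
#' @param max_tries per replicate and layer, how many uniform X candidates
#'   to evaluate (default 4000; in `"lowest"` mode this sets the resolution
#'   at which narrow solution branches are detected).
#' @param min_draws floor on accepted draws below which a layer summary is
#'   flagged insufficient (default 30).
#' @param absorption_mode `"mobile"` or `"rainfall"`, see
#'   [simulate_profile()].
#' @param method `"sequential"` (default; layers fitted top-down, each
#'   accepted draw's drainage feeding the layer below within the replicate)
#'   or `"joint"` (one X vector drawn per replicate, accepted only if every
#'   layer matches; tractable only for small profiles / large n).
#' @param select how the layer's stored draw is chosen among accepted
#'   candidates within a replicate. `"lowest"` (default) evaluates
#'   `max_tries` uniform candidates, clusters the accepted ones by
#'   `gap_threshold`, and keeps one uniform draw from the lowest contiguous
#'   solution branch — the per-replicate form of preferring the lowest X
#'   values, which the measured input/output fluxes support. `"first"` is
#'   plain rejection: the first accepted uniform candidate is kept, so the
#'   stored draws sample the full (possibly multi-branch) acceptance
#'   region.
#' @return a list of class `"mc_config"`.
#' @export
mc_config <- function(n = 10000, seed = NULL, tolerance = 1,
                      gap_threshold = 0.05, max_tries = 4000,
                      min_draws = 30,
                      absorption_mode = c("mobile", "rainfall"),
                      method = c("sequential", "joint"),
                      select = c("lowest", "first")) {
  stopifnot(n >= 1, tolerance > 0, max_tries >= 1)
  structure(
    list(
      n = as.integer(n), seed = seed, tolerance = tolerance,
      gap_threshold = gap_threshold, max_tries = as.integer(max_tries),
      min_draws = as.integer(min_draws),
      absorption_mode = match.arg(absorption_mode),
      method = match.arg(method),
      select = match.arg(select)
    ),
    class = "mc_config"
  )
}

# normal perturbation truncated at 0 (stocks and fluxes are non-negative)
perturb_trunc <- function(n, value, rel_sigma) {
  v <- stats::rnorm(n, mean = value, sd = value * rel_sigma)
  bad <- which(v < 0)
  while (length(bad) > 0) {
    v[bad] <- stats::rnorm(length(bad), mean = value, sd = value * rel_sigma)
    bad <- bad[v[bad] < 0]
  }
  v
}

#' Fit the retained fractions by Monte-Carlo rejection
#'
#' For each replicate, every measured quantity (per-layer Cl and 36Cl
#' stocks, rainfall and litterfall fluxes of both species) is perturbed by a
#' normal draw at its declared uncertainty (truncated at 0); the Cl input
#' cascade, residence times and pre-bomb 36Cl stocks are rebuilt from the
#' perturbed values; then per layer, top-down, retained fractions
#' `X ~ U(0,1)` are drawn until the forward-simulated 36Cl stock at the
#' sampling year falls within `tolerance` times the measured 1-sigma
#' uncertainty of the (perturbed) observed stock. Accepted upstream draws
#' feed the drainage input of deeper layers within the same replicate.
#'
#' @param dataset a [site_dataset()].
#' @param forcing a [build_forcing()] scenario spanning the pre-bomb period
#'   to (at least) the stock sampling year; its first year must be at
#'   background level.
#' @param config an [mc_config()].
#' @param z0 root e-folding depth in cm (default 15).
#' @param thickness_rel_sigma layer-thickness uncertainty entering the stock
#'   uncertainty budget (default 0.10).
#' @return an object of class `"posterior_sample"`: matrices (`n` replicates
#'   x `K` layers, `NA` where no draw was accepted) `x`, `z`, `t_r`,
#'   `t_prime`, `s_sim`, plus per-layer acceptance counts and diagnostics
#'   (tries, nearest misses, infeasible-draw counts).
#' @export
run_mc <- function(dataset, forcing, config = mc_config(), z0 = 15,
                   thickness_rel_sigma = 0.10) {
  stopifnot(inherits(dataset, "site_dataset"),
            inherits(forcing, "forcing_scenario"),
            inherits(config, "mc_config"))
  ser <- forcing$series
  years <- ser$year
  stock_year <- dataset$stock_year
  t_idx <- match(stock_year, years)
  if (is.na(t_idx)) {
    stop("forcing scenario does not span the stock sampling year ", stock_year)
  }
  bg36_base <- forcing$background[["cl36"]]
  if (bg36_base <= 0) stop("36Cl background must be > 0")
  if (abs(ser$r_cl36[1] - bg36_base) > 1e-9 * bg36_base) {
    stop("forcing must start in the pre-bomb period (first year at background)")
  }
  shape_t <- ser$r_cl36 / bg36_base

  stocks <- compute_stock(dataset$layers,
                          thickness_rel_sigma = thickness_rel_sigma)
  s_cl <- stocks[stocks$species == "cl", ]
  s_36 <- stocks[stocks$species == "cl36", ]
  K <- nrow(s_cl)
  fx <- compute_fluxes(dataset)
  r_cl <- get_flux(fx, "rainfall", "cl")
  l_cl <- get_flux(fx, "litterfall", "cl")
  r_36 <- get_flux(fx, "rainfall", "cl36")
  l_36 <- get_flux(fx, "litterfall", "cl36")

  geometry <- dataset$layers
  w <- root_absorption_weights(geometry, z0)

  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n

  # one perturbed realisation of every measured quantity per replicate
  s_cl_rep <- vapply(seq_len(K), function(k) {
    perturb_trunc(n, s_cl$stock[k], s_cl$rel_sigma[k])
  }, numeric(n))
  s_36_rep <- vapply(seq_len(K), function(k) {
    perturb_trunc(n, s_36$stock[k], s_36$rel_sigma[k])
  }, numeric(n))
  r_cl_rep <- perturb_trunc(n, r_cl$value, r_cl$rel_sigma)
  l_cl_rep <- perturb_trunc(n, l_cl$value, l_cl$rel_sigma)
  r_36_rep <- perturb_trunc(n, r_36$value, r_36$rel_sigma)
  l_36_rep <- perturb_trunc(n, l_36$value, l_36$rel_sigma)

  # Cl cascade and residence times, per replicate (steady state)
  cum_w <- c(0, cumsum(w)[-K])
  i_cl_rep <- matrix(r_cl_rep, n, K) + l_cl_rep %o% (1 - cum_w)
  alpha_rep <- (l_cl_rep %o% w) / i_cl_rep
  t_r_rep <- s_cl_rep / i_cl_rep

  tol_abs <- matrix(config$tolerance * abs_sigma(measurement(
    s_36$stock, s_36$rel_sigma
  )), n, K, byrow = TRUE)

  if (config$method == "sequential") {
    core <- mc_fit_core(
      s_36_rep, tol_abs, t_r_rep, alpha_rep, i_cl_rep,
      r_36_rep, l_36_rep / r_36_rep, r_cl_rep, shape_t,
      as.integer(t_idx - 1L), config$max_tries,
      config$absorption_mode == "rainfall",
      config$select == "lowest", config$gap_threshold
    )
    x_mat <- core$x
    s_sim <- core$s_sim
    tries <- core$tries
    infeasible <- core$infeasible
    nearest_miss <- core$nearest_miss
    accept_n <- core$accept_n
    clamp_count <- core$clamp_count
  } else {
    x_mat <- matrix(NA_real_, n, K)
    s_sim <- matrix(NA_real_, n, K)
    tries <- matrix(1L, n, K)
    infeasible <- matrix(0L, n, K)
    nearest_miss <- matrix(NA_real_, n, K)
    clamp_count <- 0
    x_draws <- matrix(stats::runif(n * K), n, K)
    for (i in seq_len(n)) {
      x_i <- x_draws[i, ]
      z_i <- x_i / t_r_rep[i, ]
      if (any(z_i > 1)) {
        infeasible[i, ] <- 1L
        next
      }
      f_i <- replicate_forcing(forcing, r_36_rep[i], l_36_rep[i],
                               r_cl_rep[i], l_cl_rep[i])
      sim <- suppressWarnings(simulate_profile(
        geometry, x_i, t_r_rep[i, ], f_i, z0 = z0,
        absorption_mode = config$absorption_mode
      ))
      s_i <- stocks_at(sim, stock_year)
      nearest_miss[i, ] <- abs(s_i - s_36_rep[i, ])
      if (all(abs(s_i - s_36_rep[i, ]) <= tol_abs[i, ])) {
        x_mat[i, ] <- x_i
        s_sim[i, ] <- s_i
      }
    }
    accept_n <- colSums(!is.na(x_mat))
  }

  if (all(accept_n == 0)) {
    nm_sigma <- apply(nearest_miss / tol_abs * config$tolerance, 2,
                      function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
    warning(
      "no accepted draws in any layer; per-layer nearest misses (in sigma): ",
      paste(sprintf("%.2f", nm_sigma), collapse = ", ")
    )
  }

  structure(
    list(
      x = x_mat,
      t_r = t_r_rep,
      z = x_mat / t_r_rep,
      t_prime = t_r_rep / x_mat,
      s_sim = s_sim,
      accept_n = as.integer(accept_n),
      tries = tries,
      infeasible = infeasible,
      nearest_miss = nearest_miss,
      clamp_count = clamp_count,
      obs = list(stock = s_36$stock, rel_sigma = s_36$rel_sigma,
                 tol_abs = tol_abs[1, ]),
      layers = geometry,
      stock_year = stock_year,
      config = config,
      z0 = z0
    ),
    class = "posterior_sample"
  )
}

# per-replicate forcing with perturbed background fluxes (same pulse shape)
replicate_forcing <- function(forcing, r36, l36, r_cl, l_cl) {
  ser <- forcing$series
  shape <- ser$r_cl36 / forcing$background[["cl36"]]
  series <- data.frame(
    year = ser$year,
    r_cl36 = r36 * shape, r_cl = rep(r_cl, nrow(ser)),
    l_cl36 = (l36 / r36) * r36 * shape, l_cl = rep(l_cl, nrow(ser))
  )
  new_forcing_scenario(series,
                       background = c(cl36 = r36, cl = r_cl),
                       lambda = forcing$lambda, pulse = forcing$pulse)
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf(
    "<posterior_sample> %d replicates x %d layers (%s method); accepted per layer: %s\n",
    nrow(x$x), ncol(x$x), x$config$method,
    paste(x$accept_n, collapse = ", ")
  ))
  invisible(x)
}

#' Keep only the lowest solution branch of accepted X draws
#'
#' The acceptance region for a layer can be disjoint: a low-X branch (slow
#' turnover, bomb-pulse 36Cl still present at sampling) and a high-X branch
#' (fast turnover that re-matches the observed stock after the pulse has
#' flushed through). Measured input/output fluxes indicate weak retention,
#' so the low branch is the physical one: draws are sorted and cut at the
#' first gap exceeding `gap_threshold`, keeping the lowest contiguous
#' branch. Unimodal sets pass through unchanged.
#'
#' @param x a `"posterior_sample"` or a numeric vector of accepted X draws.
#' @param gap_threshold minimum X-gap splitting two branches (default 0.05).
#' @return same type as `x`, with draws above the first gap removed (set to
#'   `NA` in the matrices of a posterior sample, together with the derived
#'   `z` and `t_prime` entries).
#' @export
select_lowest_branch <- function(x, gap_threshold = 0.05) {
  if (is.numeric(x)) {
    xs <- sort(x[!is.na(x)])
    if (length(xs) <= 1) return(xs)
    gap <- which(diff(xs) > gap_threshold)
    if (length(gap) == 0) return(xs)
    xs[seq_len(gap[1])]
  } else if (inherits(x, "posterior_sample")) {
    for (k in seq_len(ncol(x$x))) {
      keep <- select_lowest_branch(x$x[, k], gap_threshold)
      drop <- !is.na(x$x[, k]) & x$x[, k] > max(keep, -Inf)
      x$x[drop, k] <- NA_real_
      x$z[drop, k] <- NA_real_
      x$t_prime[drop, k] <- NA_real_
      x$s_sim[drop, k] <- NA_real_
    }
    x$accept_n <- as.integer(colSums(!is.na(x$x)))
    x
  } else {
    stop("x must be a numeric vector or a posterior_sample")
  }
}

# number of contiguous branches in a draw set, for diagnostics
count_branches <- function(draws, gap_threshold) {
  xs <- sort(draws[!is.na(draws)])
  if (length(xs) <= 1) return(length(xs))
  1L + sum(diff(xs) > gap_threshold)
}

#' Per-layer posterior summaries
#'
#' X is summarised by its sample mean and standard deviation (the accepted-X
#' distribution is approximately normal); the retention duration by a
#' log-normal fit on the log draws, reported as `exp(mu)` (median) with the
#' `exp(mu +/- sigma)` interval, plus model-free raw quantiles of both.
#'
#' @param sample a `"posterior_sample"` (typically after
#'   [select_lowest_branch()]).
#' @param min_draws floor below which a layer is flagged `insufficient`
#'   (default taken from the sample's config).
#' @return a data.frame of class `"posterior_summary"` with one row per
#'   layer: `k`, `n_accepted`, `x_mean`, `x_sd`, `x_q025`, `x_q975`,
#'   `tprime_median`, `tprime_lo`, `tprime_hi` (log-normal 16-84%),
#'   `tprime_q16`, `tprime_q50`, `tprime_q84` (raw), `n_branches`,
#'   `insufficient`.
#' @export
summarize_posteriors <- function(sample, min_draws = NULL) {
  stopifnot(inherits(sample, "posterior_sample"))
  if (is.null(min_draws)) min_draws <- sample$config$min_draws
  gap <- sample$config$gap_threshold
  K <- ncol(sample$x)
  rows <- lapply(seq_len(K), function(k) {
    xs <- sample$x[, k]
    tp <- sample$t_prime[, k]
    ok <- !is.na(xs)
    xs <- xs[ok]
    tp <- tp[ok]
    n_k <- length(xs)
    if (n_k == 0) {
      return(data.frame(
        k = k, n_accepted = 0L, x_mean = NA_real_, x_sd = NA_real_,
        x_q025 = NA_real_, x_q975 = NA_real_,
        tprime_median = NA_real_, tprime_lo = NA_real_, tprime_hi = NA_real_,
        tprime_q16 = NA_real_, tprime_q50 = NA_real_, tprime_q84 = NA_real_,
        n_branches = 0L, insufficient = TRUE
      ))
    }
    lt <- log(tp)
    mu <- mean(lt)
    sig <- if (n_k > 1) stats::sd(lt) else 0
    qs <- stats::quantile(xs, c(0.025, 0.975), names = FALSE)
    qt <- stats::quantile(tp, c(0.16, 0.50, 0.84), names = FALSE)
    data.frame(
      k = k, n_accepted = n_k,
      x_mean = mean(xs), x_sd = if (n_k > 1) stats::sd(xs) else 0,
      x_q025 = qs[1], x_q975 = qs[2],
      tprime_median = exp(mu), tprime_lo = exp(mu - sig),
      tprime_hi = exp(mu + sig),
      tprime_q16 = qt[1], tprime_q50 = qt[2], tprime_q84 = qt[3],
      n_branches = count_branches(xs, gap),
      insufficient = n_k < min_draws
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("posterior_summary", "data.frame")
  attr(out, "stock_year") <- sample$stock_year
  out
}

#' Linear relation between retained fractions and SOC concentration
#'
#' Ordinary least squares of the per-layer posterior mean retained fraction
#' on the layer's SOC concentration. A strong positive correlation supports
#' chlorination tracking organic-matter dynamics.
#'
#' @param posterior a [summarize_posteriors()] result.
#' @param layers the layer table (column `soc_conc`, g C per kg soil).
#' @return list with `slope`, `intercept`, `r`, `r2`, `p_value`, `n`.
#' @export
soc_correlation <- function(posterior, layers) {
  stopifnot(inherits(posterior, "posterior_summary"))
  layers <- validate_layers(layers)
  d <- merge(as.data.frame(posterior)[, c("k", "x_mean")],
             layers[, c("k", "soc_conc")], by = "k")
  d <- d[!is.na(d$x_mean), ]
  if (nrow(d) < 3) stop("need at least 3 layers with fitted X and SOC values")
  if (stats::sd(d$soc_conc) == 0) {
    stop("SOC concentration is constant across layers: correlation undefined")
  }
  fit <- stats::lm(x_mean ~ soc_conc, data = d)
  r <- stats::cor(d$x_mean, d$soc_conc)
  p <- tryCatch(stats::cor.test(d$x_mean, d$soc_conc)$p.value,
                error = function(e) NA_real_)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = r, r2 = r^2,
    p_value = p,
    n = nrow(d)
  )
}

#' Compare retention durations with an external per-depth age table
#'
#' Reporting utility pairing the per-layer retention-duration medians with
#' user-supplied soil-carbon ages (e.g. stable-isotope or model estimates)
#' matched on depth intervals.
#'
#' @param posterior a [summarize_posteriors()] result.
#' @param layers the layer table the summary refers to.
#' @param ages data.frame with columns `top_cm`, `bottom_cm`, `age_yr`.
#' @return list with the paired `table` (k, depths, duration, age, ratio),
#'   `r` (correlation), and `mean_ratio` (mean duration/age).
#' @export
age_agreement <- function(posterior, layers, ages) {
  stopifnot(inherits(posterior, "posterior_summary"))
  layers <- validate_layers(layers)
  need <- c("top_cm", "bottom_cm", "age_yr")
  if (!all(need %in% names(ages))) {
    stop("age table needs columns: ", paste(need, collapse = ", "))
  }
  idx <- vapply(seq_len(nrow(layers)), function(i) {
    j <- which(abs(ages$top_cm - layers$top_cm[i]) < 1e-9 &
                 abs(ages$bottom_cm - layers$bottom_cm[i]) < 1e-9)
    if (length(j) != 1) {
      stop(sprintf(
        "no unique age entry matching layer %d (%g-%g cm)",
        layers$k[i], layers$top_cm[i], layers$bottom_cm[i]
      ))
    }
    j
  }, integer(1))
  tab <- data.frame(
    k = layers$k,
    top_cm = layers$top_cm, bottom_cm = layers$bottom_cm,
    tprime_median = posterior$tprime_median,
    age_yr = ages$age_yr[idx]
  )
  tab$ratio <- tab$tprime_median / tab$age_yr
  ok <- !is.na(tab$tprime_median)
  list(
    table = tab,
    r = stats::cor(tab$tprime_median[ok], tab$age_yr[ok]),
    mean_ratio = mean(tab$ratio[ok])
  )
}
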