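# fits on small synthetic sites; fixtures generated in code

fit_once <- function(seed_site, seed_fit, n = 1000, ...) {
  truth <- gen_site(seed_site)
  obs <- gen_observations(truth)
  fit <- run_mc(obs$dataset, obs$forcing,
                mc_config(n = n, seed = seed_fit, ...))
  list(truth = truth, obs = obs, fit = fit)
}

test_that("identical seed and config give bit-identical accepted sets", {
  a <- fit_once(5, 77, n = 400)
  b <- fit_once(5, 77, n = 400)
  expect_identical(a$fit$x, b$fit$x)
  expect_identical(a$fit$t_prime, b$fit$t_prime)
  c <- fit_once(5, 77, n = 400, select = "first")
  d <- fit_once(5, 77, n = 400, select = "first")
  expect_identical(c$fit$x, d$fit$x)
  # different seed, different draws
  e <- fit_once(5, 78, n = 400)
  expect_false(identical(a$fit$x, e$fit$x))
})

test_that("derived draws obey T' = T_R / X and Z = X / T_R exactly", {
  r <- fit_once(5, 3, n = 500)
  ok <- !is.na(r$fit$x)
  expect_identical(r$fit$t_prime[ok], (r$fit$t_r / r$fit$x)[ok])
  expect_identical(r$fit$z[ok], (r$fit$x / r$fit$t_r)[ok])
  expect_true(all(r$fit$z[ok] >= 0 & r$fit$z[ok] <= 1))
})

test_that("accepted draws reproduce the observed stock through the R simulator", {
  # dual route: the compiled fit core and the R-level simulate_profile()
  # must agree on the forward model; run a near-noiseless fit and replay an
  # accepted replicate's X vector through the R path
  cfg0 <- synth_config(noise = list(bulk_density = 1e-9, thickness = 1e-9,
                                    litterfall = 1e-9, drainage = 1e-9,
                                    rainfall = 1e-9, concentration = 1e-9))
  t0 <- gen_site(13, cfg0)
  o0 <- gen_observations(t0, noisy = FALSE)
  f0 <- run_mc(o0$dataset, o0$forcing,
               mc_config(n = 40, seed = 2, tolerance = 1e5, max_tries = 500))
  for (r in c(1, 7, 23)) {
    r_sim <- simulate_profile(t0$geometry, f0$x[r, ], f0$t_r[r, ], t0$forcing)
    expect_equal(stocks_at(r_sim, 2010), unname(f0$s_sim[r, ]),
                 tolerance = 1e-6)
  }
})

test_that("noise-free data with tight uncertainties concentrate X at the truth", {
  # shrink every declared uncertainty 25-fold: the acceptance region must
  # collapse onto the generating X (lowest branch; a residual high-X branch
  # exists and is removed by the gap rule)
  tiny <- 0.005
  cfg <- synth_config(
    boundaries = c(0, 60), bulk_density = 1.3,
    retention_duration = 150,
    soc_surface = 45, soc_efold = 1e6,
    noise = list(bulk_density = tiny, thickness = tiny, litterfall = tiny,
                 drainage = tiny, rainfall = tiny, concentration = tiny)
  )
  truth <- gen_site(17, cfg)
  obs <- gen_observations(truth, noisy = FALSE)
  fit <- run_mc(obs$dataset, obs$forcing,
                mc_config(n = 400, seed = 5),
                thickness_rel_sigma = tiny)
  xs <- select_lowest_branch(fit$x[!is.na(fit$x[, 1]), 1])
  expect_gt(length(xs), 50)
  expect_equal(mean(xs), truth$x[1], tolerance = 0.01)
  expect_lt(sd(xs), 0.05 * truth$x[1])
})

test_that("enlarging the tolerance never shrinks the accepted set (joint mode)", {
  truth <- gen_site(9, synth_config(boundaries = c(0, 30, 60),
                                    bulk_density = c(1.2, 1.4),
                                    retention_duration = c(100, 250)))
  obs <- gen_observations(truth)
  acc <- lapply(c(1, 2, 4), function(m) {
    fit <- suppressWarnings(run_mc( # small n: zero acceptance is fine here
      obs$dataset, obs$forcing,
      mc_config(n = 400, seed = 31, tolerance = m, method = "joint")
    ))
    which(!is.na(fit$x[, 1]))
  })
  expect_true(all(acc[[1]] %in% acc[[2]]))
  expect_true(all(acc[[2]] %in% acc[[3]]))
})

test_that("sequential and joint schemes agree on a two-layer toy", {
  truth <- gen_site(9, synth_config(boundaries = c(0, 30, 60),
                                    bulk_density = c(1.2, 1.4),
                                    retention_duration = c(100, 250)))
  obs <- gen_observations(truth)
  fs <- run_mc(obs$dataset, obs$forcing,
               mc_config(n = 3000, seed = 41, select = "first"))
  fj <- run_mc(obs$dataset, obs$forcing,
               mc_config(n = 3000, seed = 42, method = "joint"))
  expect_gt(min(fj$accept_n), 8)
  for (k in 1:2) {
    ms <- mean(fs$x[, k], na.rm = TRUE)
    mj <- mean(fj$x[, k], na.rm = TRUE)
    expect_equal(ms, mj, tolerance = 0.35)
  }
})

test_that("lowest-branch selection cuts at the first large gap", {
  bimodal <- c(seq(0.03, 0.06, by = 0.005), seq(0.25, 0.31, by = 0.01))
  expect_equal(select_lowest_branch(bimodal), seq(0.03, 0.06, by = 0.005))
  unimodal <- seq(0.1, 0.2, by = 0.01)
  expect_equal(select_lowest_branch(unimodal), unimodal)
  # threshold larger than the whole span: identity
  expect_equal(sort(select_lowest_branch(bimodal, gap_threshold = 0.5)),
               sort(bimodal))
  expect_equal(select_lowest_branch(c(0.2)), 0.2)
})

test_that("posterior summaries fit X as normal and T' as log-normal", {
  n <- 10000
  set.seed(8)
  tp <- rlnorm(n, meanlog = 3, sdlog = 0.5)
  x <- rnorm(n, 0.05, 0.005)
  sample <- structure(
    list(x = matrix(x, ncol = 1), t_prime = matrix(tp, ncol = 1),
         t_r = matrix(x * tp, ncol = 1), z = matrix(1 / tp, ncol = 1),
         config = mc_config(n = n), stock_year = 2010),
    class = "posterior_sample"
  )
  s <- summarize_posteriors(sample)
  expect_equal(s$x_mean, 0.05, tolerance = 0.01)
  expect_equal(s$tprime_median, exp(3), tolerance = 0.05)
  expect_equal(s$tprime_hi / s$tprime_median, exp(0.5), tolerance = 0.05)
  expect_false(s$insufficient)

  # degenerate draws: mean x, sd 0
  sample$x <- matrix(rep(0.1, 50), ncol = 1)
  sample$t_prime <- matrix(rep(20, 50), ncol = 1)
  s2 <- summarize_posteriors(sample)
  expect_equal(s2$x_mean, 0.1)
  expect_equal(s2$x_sd, 0)
  expect_equal(s2$tprime_median, 20)
  # draw floor flags the summary
  s3 <- summarize_posteriors(sample, min_draws = 100)
  expect_true(s3$insufficient)
})

test_that("X-SOC regression recovers exact and noisy linear relations", {
  lay <- gen_site(3)$geometry
  layers <- data.frame(
    lay, bulk_density = 1.3, bd_rel_sigma = 0.05,
    soc_conc = c(45, 30, 20, 10, 5),
    cl_conc = 1e17, cl_rel_sigma = 0.05,
    cl36_conc = 1e5, cl36_rel_sigma = 0.05
  )
  mk_summary <- function(x_mean) {
    s <- data.frame(
      k = 1:5, n_accepted = 1000L, x_mean = x_mean, x_sd = 0.01,
      x_q025 = 0, x_q975 = 1, tprime_median = 50, tprime_lo = 40,
      tprime_hi = 60, tprime_q16 = 40, tprime_q50 = 50, tprime_q84 = 60,
      n_branches = 1L, insufficient = FALSE
    )
    class(s) <- c("posterior_summary", "data.frame")
    s
  }
  exact <- mk_summary(0.001 * layers$soc_conc)
  fit <- soc_correlation(exact, layers)
  expect_equal(fit$r, 1)
  expect_equal(fit$slope, 0.001)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)

  set.seed(4)
  slopes <- replicate(20, {
    noisy <- mk_summary(0.001 * layers$soc_conc + rnorm(5, 0, 0.002))
    soc_correlation(noisy, layers)$slope
  })
  expect_equal(mean(slopes), 0.001, tolerance = 0.1)

  # shuffled SOC labels decorrelate on average
  set.seed(9)
  rs <- replicate(200, {
    l2 <- layers
    l2$soc_conc <- sample(l2$soc_conc)
    soc_correlation(exact, l2)$r
  })
  expect_lt(abs(mean(rs)), 0.25)

  flat <- layers
  flat$soc_conc <- 10
  expect_error(soc_correlation(exact, flat), "constant")
})

test_that("age agreement reports unit ratio for identical tables and scales linearly", {
  truth <- gen_site(3)
  layers <- data.frame(
    truth$geometry, bulk_density = 1.3, bd_rel_sigma = 0.05,
    soc_conc = truth$soc, cl_conc = 1e17, cl_rel_sigma = 0.05,
    cl36_conc = 1e5, cl36_rel_sigma = 0.05
  )
  s <- data.frame(
    k = 1:5, n_accepted = 1000L, x_mean = truth$x, x_sd = 0.01,
    x_q025 = 0, x_q975 = 1, tprime_median = truth$t_prime,
    tprime_lo = 1, tprime_hi = 1, tprime_q16 = 1, tprime_q50 = 1,
    tprime_q84 = 1, n_branches = 1L, insufficient = FALSE
  )
  class(s) <- c("posterior_summary", "data.frame")
  ages <- data.frame(top_cm = truth$geometry$top_cm,
                     bottom_cm = truth$geometry$bottom_cm,
                     age_yr = truth$t_prime)
  agr <- age_agreement(s, layers, ages)
  expect_equal(agr$mean_ratio, 1)
  expect_equal(agr$r, 1)

  ages2 <- ages
  ages2$age_yr <- ages$age_yr / 2 # durations twice the ages
  agr2 <- age_agreement(s, layers, ages2)
  expect_equal(agr2$mean_ratio, 2)
  expect_equal(agr2$r, 1)

  ages3 <- ages[-2, ]
  expect_error(age_agreement(s, layers, ages3), "no unique age entry")
})

test_that("an unmatchable stock yields a diagnostic, not silent emptiness", {
  truth <- gen_site(5)
  obs <- gen_observations(truth)
  lay <- obs$dataset$layers
  lay$cl36_conc <- lay$cl36_conc * 1e4 # far beyond any reachable stock
  ds <- site_dataset(lay, obs$dataset$fluxes)
  expect_warning(
    fit <- run_mc(ds, obs$forcing, mc_config(n = 50, seed = 1, max_tries = 200)),
    "nearest misses"
  )
  expect_true(all(fit$accept_n == 0))
  expect_true(all(is.finite(fit$nearest_miss[, 1])))
})
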