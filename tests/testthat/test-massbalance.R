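test_that("root absorption weights integrate an exponential over each layer", {
  geom <- data.frame(top_cm = c(0, 5, 15, 30, 45), bottom_cm = c(5, 15, 30, 45, 60))
  w <- root_absorption_weights(geom, z0 = 15)
  # closed form for the 0-5 cm layer of a 0-60 cm profile
  expect_equal(w[1], (1 - exp(-1 / 3)) / (1 - exp(-4)))
  expect_equal(round(w[1], 4), 0.2888)
  for (z0 in c(1, 7.5, 15, 40, 1e6)) {
    expect_equal(sum(root_absorption_weights(geom, z0)), 1)
  }
  # infinite e-folding depth: proportional to thickness
  expect_equal(root_absorption_weights(geom, Inf),
               c(5, 10, 15, 15, 15) / 60)
  expect_error(root_absorption_weights(geom, 0), "> 0")
})

test_that("the steady Cl cascade subtracts absorption layer by layer", {
  i <- cl_input_cascade(90, 10, c(4, 3, 2, 1, 0))
  expect_equal(i, c(100, 96, 93, 91, 90))
  # deepest drainage returns the rainfall: D5 = I5 - A5
  expect_equal(i[5] - 0, 90)
  expect_equal(cl_input_cascade(90, 0, rep(0, 5)), rep(90, 5))
  expect_error(cl_input_cascade(90, 10, c(4, 3, 2, 1, 5)),
               "closure violated")
})

test_that("residence time, retention duration and release fraction obey the exact algebra", {
  expect_equal(residence_time(50, 50), 1)
  expect_equal(retention_duration(9 * 100, 0.045, 100), 200)
  expect_equal(z_from_x(0.045, 9), 0.005)
  expect_equal(retention_duration(900, 1, 100), residence_time(900, 100))
  expect_warning(out <- retention_duration(900, 0, 100), "infinite")
  expect_identical(out, Inf)
  expect_error(z_from_x(0.9, 0.5), "infeasible")
  expect_error(residence_time(10, 0), "> 0")
})

test_that("pre-bomb 36Cl stock is input times Cl residence time, ratio preserved", {
  expect_equal(initial_cl36_stock(1e5, 50), 5e6)
  expect_equal(initial_cl36_stock(0, 50), 0)
  i36 <- c(2e8, 1e8)
  icl <- c(1e22, 5e21)
  tr <- c(3, 7)
  expect_equal(initial_cl36_stock(i36, tr) / (icl * tr), i36 / icl)
})

test_that("one annual layer update matches the hand-worked balance", {
  st <- step_layer(s_prev = 100, input = 50, x = 0.2, z = 0.1,
                   absorption = 5)
  expect_equal(st$stock, 100)
  expect_equal(st$drainage, 45)
  # conservation: I = dS + D + A -> 50 = 0 + 45 + 5
  expect_equal((st$stock - 100) + st$drainage + 5, 50)

  inert <- step_layer(80, 50, x = 0, z = 0, absorption = 5)
  expect_equal(inert$stock, 80)
  expect_equal(inert$drainage, 45)

  # fixed point S* = X I dt / Z
  fp <- step_layer(0.2 * 50 / 0.1, 50, 0.2, 0.1, 5)
  expect_equal(fp$stock, 0.2 * 50 / 0.1)

  cl <- step_layer(10, 50, x = 0.5, z = 0, absorption = 40)
  expect_true(cl$clamped)
  expect_equal(cl$drainage, 0)
})

test_that("constant background forcing with steady initialisation never drifts", {
  geom <- data.frame(top_cm = c(0, 5, 15), bottom_cm = c(5, 15, 30))
  fc <- build_forcing(100, 1e6, pulse = pulse_shape(amplitude = 0),
                      years = 1940:2020)
  for (x1 in c(0.01, 0.3, 0.95)) {
    x <- c(x1, 0.5 * x1, 0.1 * x1)
    sim <- simulate_profile(geom, x, t_r = c(2, 5, 9), fc)
    for (sp in c("cl", "cl36")) {
      S <- sim$species[[sp]]$S
      drift <- abs(S - S[, 1]) / S[, 1]
      expect_lt(max(drift), 1e-10)
    }
  }
})

test_that("every simulated cell satisfies I = dS/dt + D + A to machine precision", {
  truth <- gen_site(5)
  res <- conservation_residuals(truth$simulation)
  expect_lt(res$max_rel, 1e-9)
  # also under the rainfall-ratio absorption mode
  sim2 <- simulate_profile(truth$geometry, truth$x, truth$t_r,
                           truth$forcing, absorption_mode = "rainfall")
  expect_lt(conservation_residuals(sim2)$max_rel, 1e-9)
})

test_that("a single layer's post-pulse decay matches the closed-form geometric solution", {
  geom <- one_layer()
  x <- 0.05
  t_r <- 2.5
  z <- x / t_r
  fc <- build_forcing(100, 1e6, years = 1940:2020)
  sim <- simulate_profile(geom, x, t_r, fc)
  # independent oracle: S_t = (1-Z)^t S_0 + X sum_j (1-Z)^(t-j) I_j
  i36 <- fc$series$r_cl36 * (1 + fc$lambda)
  s0 <- i36[1] * t_r
  n <- length(i36)
  s_ref <- numeric(n)
  prev <- s0
  for (t in seq_len(n)) {
    prev <- (1 - z) * prev + x * i36[t]
    s_ref[t] <- prev
  }
  # closed form evaluated directly at the last year
  tt <- n
  s_closed <- (1 - z)^tt * s0 + x * sum((1 - z)^(tt - seq_len(n)) * i36)
  expect_equal(s_ref[n], s_closed, tolerance = 1e-12)
  rel <- abs(sim$species$cl36$S[1, ] - s_ref) / s_ref
  expect_lt(max(rel), 1e-9)
})

test_that("the steady attractor S* = I T_R is reached geometrically from any start", {
  geom <- one_layer()
  fc <- build_forcing(100, 1e6, pulse = pulse_shape(amplitude = 0),
                      years = 1900:2020)
  x <- 0.3
  t_r <- 4
  z <- x / t_r
  i36 <- 100 * 1.11
  s_star <- i36 * t_r
  for (s0 in c(0, 0.2 * s_star, 5 * s_star)) {
    sim <- simulate_profile(geom, x, t_r, fc, s0_cl36 = s0)
    dev <- sim$species$cl36$S[1, ] - s_star
    # geometric contraction at rate (1 - Z)
    expect_equal(dev, (s0 - s_star) * (1 - z)^seq_along(dev),
                 tolerance = 1e-9)
  }
})

test_that("relaxation e-folding time approaches the retention duration for small Z", {
  for (tp in c(50, 200, 1000)) { # T' = T_R / X with Z = X / T_R = 1/T'
    z <- 1 / tp
    efold <- -1 / log(1 - z)
    expect_equal(efold / tp, 1, tolerance = 0.05)
  }
})

test_that("2010 stocks are insensitive to a 1910 vs 1940 start year", {
  cfg10 <- synth_config(years = 1910:2020)
  cfg40 <- synth_config(years = 1940:2020)
  t10 <- gen_site(8, cfg10)
  t40 <- gen_site(8, cfg40)
  s10 <- stocks_at(t10$simulation, 2010)
  s40 <- stocks_at(t40$simulation, 2010)
  expect_lt(max(abs(s10 - s40) / s40), 1e-9)
})

test_that("simulation trajectories export in long format", {
  truth <- gen_site(5)
  tab <- trajectory_table(truth$simulation)
  expect_equal(nrow(tab), 2 * 5 * length(truth$simulation$years))
  expect_true(all(tab$S >= 0) && all(tab$D >= 0))
  # stocks_at agrees with the table
  s <- stocks_at(truth$simulation, 2010)
  expect_equal(tab$S[tab$species == "cl36" & tab$year == 2010], s)
})
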