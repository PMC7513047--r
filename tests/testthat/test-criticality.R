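test_that("entropy production follows the two-reservoir heat-flux formula", {
  th <- thermostat_pair(Tc = 1, Th = 3, zeta = 1.5)
  # no net flux when both species sit at their reservoir temperature
  expect_equal(unname(entropy_production(3, 1, th)["per_3zeta"]), 0)
  # direct evaluation: Theff/Th + Tceff/Tc - 2
  s <- entropy_production(2.0, 1.5, th)
  expect_equal(unname(s["per_3zeta"]), 2 / 3 + 1.5 - 2)
  expect_equal(unname(s["per_3zeta"]), 1 / 6, tolerance = 1e-12)
  expect_equal(unname(s["rate"]), 3 * 1.5 / 6)
  # physically admissible steady states produce entropy
  expect_gt(unname(entropy_production(2.6, 1.2, th)["per_3zeta"]), 0)
  expect_error(entropy_production(1, 1, thermostat_pair(Tc = 1, Th = 1, zeta = 0)),
               NA)
})

test_that("crossover estimator recovers a constructed quadratic-to-plateau point", {
  chi <- seq(0.1, 1, by = 0.05)
  a <- 0.8
  cs_true <- 0.5
  y <- ifelse(chi <= cs_true, a * chi^2, a * cs_true^2)
  fit <- crossover_chi_star(critical_curve(chi, y))
  expect_equal(fit$chi_star, cs_true, tolerance = 1e-10)
  expect_equal(fit$uncertainty, 0, tolerance = 1e-10)
  # strictly quadratic data has no plateau: error
  expect_error(crossover_chi_star(critical_curve(chi, a * chi^2)), "crossover")
})

test_that("crossover estimator is accurate under multiplicative noise", {
  chi <- seq(0.1, 1, by = 0.05)
  cs_true <- 0.5
  clean <- ifelse(chi <= cs_true, chi^2, cs_true^2)
  set.seed(7)
  est <- replicate(100, {
    noisy <- clean * (1 + rnorm(length(chi), sd = 0.05))
    tryCatch(crossover_chi_star(critical_curve(chi, noisy))$chi_star,
             error = function(e) NA_real_)
  })
  expect_gt(mean(!is.na(est)), 0.75)
  expect_lt(abs(mean(est, na.rm = TRUE) - cs_true), 0.03)
})

test_that("sub-box cumulant reaches the Gaussian and two-state limits", {
  # two-state limit: half the sub-boxes at rho + d, half at rho - d; realized
  # by filling the 8 octants with exactly c +/- k particles each
  box <- c(8, 8, 8)
  n <- 2
  cellv <- prod(box) / 8
  counts <- rep(c(120, 80), each = 4)
  frames <- lapply(1:3, function(f) {
    set.seed(f)
    pos <- do.call(rbind, lapply(0:7, function(cell) {
      ix <- cell %% 2; iy <- (cell %/% 2) %% 2; iz <- cell %/% 4
      nc <- counts[cell + 1]
      cbind(runif(nc, ix * 4, (ix + 1) * 4 - 1e-9),
            runif(nc, iy * 4, (iy + 1) * 4 - 1e-9),
            runif(nc, iz * 4, (iz + 1) * 4 - 1e-9))
    }))
    np <- nrow(pos)
    system_state(pos, matrix(0, np, 3), rep("hot", np), seq_len(np), box,
                 time = f)
  })
  traj <- trajectory(frames)
  res <- fourth_order_cumulant(traj, cumulant_config(n = 2), "hot")
  expect_equal(res$Un, 1, tolerance = 1e-10)
  # Gaussian-like limit: uniform placement, multinomial counts -> Un ~ 3
  set.seed(9)
  gframes <- lapply(1:40, function(f)
    make_uniform_state(2700, box = c(9, 9, 9), seed = 1000 + f,
                       species = rep("hot", 2700)))
  gres <- fourth_order_cumulant(trajectory(gframes), cumulant_config(n = 3), "hot")
  expect_equal(gres$Un, 3, tolerance = 0.15)
  # degenerate: all sub-boxes exactly at rho_bar
  expect_error(
    fourth_order_cumulant(traj, cumulant_config(n = 2, rho_bar = 0), "cold"),
    "absent|rho_bar|equal")
})

test_that("cumulant is invariant under uniform rescaling of the system", {
  set.seed(11)
  st <- make_uniform_state(1000, box = c(10, 10, 10), seed = 12)
  st2 <- st
  st2$pos <- st$pos * 0.5
  st2$box <- sim_box(as.numeric(st$box) * 0.5)
  u1 <- fourth_order_cumulant(trajectory(list(st)), cumulant_config(2), "hot")$Un
  u2 <- fourth_order_cumulant(trajectory(list(st2)), cumulant_config(2), "hot")$Un
  expect_equal(u1, u2, tolerance = 1e-10)
})

test_that("mean-field cumulant reference helper evaluates the closed form", {
  expect_equal(mean_field_cumulant(), gamma(0.25)^4 / (8 * pi^2), tolerance = 1e-14)
  expect_equal(mean_field_cumulant(), 2.188, tolerance = 1e-3)
})

test_that("cumulant crossings locate a constructed common crossing point", {
  chi <- seq(0.2, 0.9, by = 0.05)
  # two straight lines crossing exactly at 0.46
  c1 <- critical_curve(chi, 2 + 1.0 * (0.46 - chi))
  c2 <- critical_curve(chi, 2 + 2.5 * (0.46 - chi))
  res <- cumulant_crossings(list(c1, c2))
  expect_equal(res$chi_star, 0.46, tolerance = 1e-10)
  expect_equal(res$spread, 0)
  expect_equal(res$level, 2, tolerance = 1e-10)
  # three tanh curves from the generator cross near the constructed point
  fam <- make_critical_curves(chi, noise = 0.01, seed = 3)
  res3 <- cumulant_crossings(fam$cumulants)
  expect_lt(abs(res3$chi_star - fam$truth$cumulant$chi_star),
            max(3 * res3$spread, 0.05))
  # parallel curves never cross
  p1 <- critical_curve(chi, 2 + chi)
  p2 <- critical_curve(chi, 2.5 + chi)
  expect_error(cumulant_crossings(list(p1, p2)), "no crossing")
})

test_that("binodal plateaus are recovered from aligned fixture profiles", {
  spec <- sharp_two_phase(box = c(12, 12, 30), rho_hot = 0.7, rho_cold = 1.0,
                          purity_hot = 0.95, purity_cold = 0.95, width = 1)
  traj <- make_two_phase_trajectory(spec, n_frames = 10, seed = 14)
  grid <- slab_grid(traj_box(traj), n = 60)
  dh <- density_profile(traj, grid, "hot")
  dc <- density_profile(traj, grid, "cold")
  dall <- density_profile(traj, grid, "all")
  phi_h <- dh
  phi_h$value <- dh$value / pmax(dall$value, 1e-12)
  entry <- list(chi = 1.0, density = dall, phi_h = phi_h,
                msv = msv_profile(traj, grid, "all"))
  out <- binodal_from_profiles(list(entry))
  dens_hot <- out$value[out$observable == "density" & out$phase == "hot"]
  dens_cold <- out$value[out$observable == "density" & out$phase == "cold"]
  expect_equal(dens_hot, 0.7, tolerance = 0.04)
  expect_equal(dens_cold, 1.0, tolerance = 0.04)
  # quoted spread is the plateau-slab standard deviation by definition
  expect_true(all(out$sd >= 0))
  # mixed-state (flat) profile is an error
  flat <- phi_h
  flat$value <- rep(0.5, nrow(flat))
  expect_error(binodal_from_profiles(list(list(chi = 0.2, density = dall,
                                               phi_h = flat))),
               "interface|plateau")
})

test_that("power-law fit inverts noiseless binodal data exactly", {
  A <- 0.143; cs <- 0.36; beta <- 0.47
  chi <- seq(0.5, 2, length.out = 9)
  drho <- A * (chi - cs)^beta
  fit <- power_law_fit(chi, drho)
  expect_equal(fit$A, A, tolerance = 1e-6)
  expect_equal(fit$chi_star, cs, tolerance = 1e-6)
  expect_equal(fit$beta, beta, tolerance = 1e-6)
  # two-parameter variant with the exponent pinned to the mean-field 1/2
  fit2 <- power_law_fit(chi, drho, fix = list(beta = 0.5))
  expect_equal(fit2$beta, 0.5)
  expect_lt(abs(fit2$chi_star - cs), 0.05)
  # variant with chi* pinned
  fit3 <- power_law_fit(chi, drho, fix = list(chi_star = 0.36))
  expect_equal(fit3$beta, beta, tolerance = 1e-8)
  # support violation: fixed chi* above data
  expect_error(power_law_fit(chi, drho, fix = list(chi_star = 0.6)), "support")
})

test_that("power-law exponent recovery distribution covers the truth", {
  A <- 0.143; cs <- 0.36; beta <- 0.47
  chi <- seq(0.5, 2, length.out = 9)
  clean <- A * (chi - cs)^beta
  set.seed(21)
  betas <- replicate(200, {
    y <- clean + rnorm(length(chi), sd = 0.02)
    ok <- y > 0
    tryCatch(power_law_fit(chi[ok], y[ok], err = rep(0.02, sum(ok)))$beta,
             error = function(e) NA_real_)
  })
  betas <- betas[is.na(betas) == FALSE]
  expect_gt(length(betas), 150)
  qs <- stats::quantile(betas, c(0.025, 0.975))
  expect_lt(qs[1], beta)
  expect_gt(qs[2], beta)
})
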