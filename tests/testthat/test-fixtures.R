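test_that("fixtures are seed-deterministic and carry their ground truth", {
  spec <- sharp_two_phase()
  a <- make_two_phase(spec, seed = 3)
  b <- make_two_phase(spec, seed = 3)
  expect_identical(a$pos, b$pos)
  expect_identical(a$species, b$species)
  expect_identical(attr(a, "truth"), spec)
  ens1 <- make_height_ensemble(spectrum_spec(20, 1, nB = 8, n_snapshots = 4,
                                             seed = 6))
  ens2 <- make_height_ensemble(spectrum_spec(20, 1, nB = 8, n_snapshots = 4,
                                             seed = 6))
  expect_identical(ens1[[2]]$h, ens2[[2]]$h)
  expect_s3_class(attr(ens1, "truth"), "spectrum_spec")
  s1 <- make_ar1_series(100, 10, 50, seed = 8)
  s2 <- make_ar1_series(100, 10, 50, seed = 8)
  expect_identical(as.numeric(s1), as.numeric(s2))
})

test_that("two-phase generator honors densities, purity and chain topology", {
  spec <- sharp_two_phase(box = c(12, 12, 24), rho_hot = 0.75, rho_cold = 0.95)
  st <- make_two_phase(spec, seed = 4)
  # chains are complete blocks of N with uniform species
  expect_silent(validate_chain_species <- tapply(st$species, st$chain,
                                                 function(s) unique(s)))
  expect_true(all(table(st$chain) == spec$N))
  # phase densities within count rounding
  z <- st$pos[, 3]
  in_hot <- z >= 6 & z < 18
  vol_half <- 12 * 12 * 12
  expect_equal(sum(in_hot) / vol_half, 0.75, tolerance = 0.03)
  expect_equal(sum(!in_hot) / vol_half, 0.95, tolerance = 0.03)
  # pure phases: species matches region exactly
  expect_true(all(st$species[in_hot] == 1L))
  expect_true(all(st$species[!in_hot] == 2L))
})

test_that("two-phase velocities satisfy the bulk mean-square-velocity relation", {
  # species temperatures chosen as the reservoir mix Teff = Th phi + Tc (1-phi)
  Th <- 3; Tc <- 1
  spec <- sharp_two_phase(purity_hot = 0.9, purity_cold = 0.9,
                          T_hot = Th, T_cold = Tc)
  traj <- make_two_phase_trajectory(spec, n_frames = 8, seed = 5)
  grid <- slab_grid(traj_box(traj), n = 24)
  msv <- msv_profile(traj, grid, "all")
  dh <- density_profile(traj, grid, "hot")
  dall <- density_profile(traj, grid, "all")
  phi <- dh$value / pmax(dall$value, 1e-12)
  bulk <- grid$centers > 8 & grid$centers < 16 # deep hot phase
  expect_equal(mean(msv$value[bulk]), mean(Th * phi[bulk] + Tc * (1 - phi[bulk])),
               tolerance = 0.03)
})

test_that("height-field ensemble realizes the prescribed mode variances", {
  L <- 24; gb <- 1.3; nB <- 8
  ens <- make_height_ensemble(spectrum_spec(L, gb, nB = nB, n_snapshots = 4000,
                                            seed = 7))
  amps <- vapply(ens, function(hf) {
    a <- fourier_amplitudes(hf)
    a$A[a$n == 0 & a$m == 1]
  }, 0)
  q01 <- 2 * pi / L
  expect_equal(var(amps), 2 / (gb * L^2 * q01^2), tolerance = 0.05)
  expect_lt(abs(mean(amps)), 3 * sd(amps) / sqrt(length(amps)))
  # stiffness to infinity: flat fields
  flat <- make_height_ensemble(spectrum_spec(L, 1e8, nB = nB, n_snapshots = 5,
                                             seed = 8))
  expect_lt(max(vapply(flat, function(hf) var(as.vector(hf$h)), 0)), 1e-6)
})

test_that("AR(1) generator has the prescribed autocorrelation and is stationary", {
  x <- make_ar1_series(tau_c = 200, spacing = 200, length_out = 20000, seed = 9)
  # lag-1 autocorrelation at spacing = tau_c is 1/e
  r1 <- cor(x[-1], x[-length(x)])
  se <- (1 - exp(-2)) / sqrt(length(x)) # delta-method scale
  expect_lt(abs(r1 - exp(-1)), 3 * se + 0.01)
  # spacing >> tau_c: successive samples uncorrelated
  y <- make_ar1_series(tau_c = 1, spacing = 1000, length_out = 5000, seed = 10)
  expect_lt(abs(cor(y[-1], y[-length(y)])), 3 / sqrt(length(y)) + 0.01)
  # variance stationary along the series
  quarters <- split(as.numeric(x), rep(1:4, each = length(x) / 4))
  vs <- vapply(quarters, var, 0)
  expect_lt(max(vs) / min(vs), 1.2)
})

test_that("critical-curve generator exposes recoverable ground truth", {
  chi <- seq(0.1, 1.2, by = 0.05)
  fam <- make_critical_curves(chi, noise = 0, seed = 11)
  # entropy curve: quadratic below the crossover, flat above
  cross <- crossover_chi_star(fam$entropy)
  expect_equal(cross$chi_star, fam$truth$entropy$chi_star, tolerance = 0.02)
  # cumulant family crosses at the constructed point and level
  # crossings located by linear interpolation on the 0.05-wide chi grid
  cc <- cumulant_crossings(fam$cumulants)
  expect_equal(cc$chi_star, fam$truth$cumulant$chi_star, tolerance = 1e-3)
  expect_equal(cc$level, fam$truth$cumulant$level, tolerance = 1e-3)
  # binodal branch follows the power law
  fit <- power_law_fit(fam$delta_rho$chi, fam$delta_rho$value)
  expect_equal(fit$beta, fam$truth$delta_rho$beta, tolerance = 1e-4)
  expect_equal(fit$chi_star, fam$truth$delta_rho$chi_star, tolerance = 1e-4)
})
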