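test_that("Fourier amplitudes are orthogonal and satisfy Parseval", {
  L <- 32
  nB <- 16
  xs <- (seq_len(nB) - 0.5) * L / nB
  # flat field: no fluctuation in any mode
  flat <- height_field(matrix(4.2, nB, nB), L)
  af <- fourier_amplitudes(flat)
  expect_true(all(af$C2 == 0))
  # single imposed mode: only A_{10} responds
  a <- 0.7
  h1 <- height_field(outer(cos(2 * pi * xs / L), rep(1, nB)), L)
  a1 <- fourier_amplitudes(h1)
  sel <- a1$n == 1 & a1$m == 0
  expect_equal(a1$A[sel], 1, tolerance = 1e-10)
  expect_lt(max(abs(a1$A[!sel])), 1e-10)
  expect_lt(max(abs(a1$B)), 1e-10)
  # band-limited random field: sum C2 equals the grid variance of h exactly
  ens <- make_height_ensemble(spectrum_spec(L = L, gamma_beta = 1, nB = nB,
                                            n_snapshots = 3, seed = 5))
  for (hf in ens) {
    amp <- fourier_amplitudes(hf)
    v <- mean(hf$h^2) - mean(hf$h)^2
    expect_equal(sum(amp$C2), v, tolerance = 1e-12)
  }
})

test_that("interface heights recover planar and corrugated fixtures", {
  spec <- sharp_two_phase(box = c(16, 16, 40),
                          interfaces = c(10, 30), rho_hot = 0.8, rho_cold = 0.9)
  st <- make_two_phase(spec, seed = 6)
  hf <- interface_heights(st, nB = 4, nslab = 80)
  expect_equal(mean(hf$lower$h), 10, tolerance = 0.5)
  expect_equal(mean(hf$upper$h), 30, tolerance = 0.5)
  expect_lt(sd(hf$lower$h), 0.5)
  # sinusoidal corrugation h(x) = 0.8 cos(2 pi x / L) on both surfaces
  corr <- data.frame(n = 1, m = 0, amplitude = 0.8)
  spec2 <- sharp_two_phase(box = c(16, 16, 40), interfaces = c(10, 30),
                           corrugation = corr)
  st2 <- make_two_phase(spec2, seed = 7)
  hf2 <- interface_heights(st2, nB = 8, nslab = 80)
  amp <- fourier_amplitudes(hf2$lower)
  sel <- amp$n == 1 & amp$m == 0
  expect_equal(amp$A[sel], 0.8, tolerance = 0.25) # slab-resolution limited
  expect_lt(max(abs(amp$C2[!sel])), 0.1)
  # mixed state: no interface pair anywhere
  mixed <- make_uniform_state(2000, box = c(16, 16, 40), seed = 8)
  expect_error(interface_heights(mixed, nB = 4), "mixed|interface")
})

test_that("spectrum accumulation matches the q^-2 generator", {
  L <- 32
  gb <- 1.0
  ens <- make_height_ensemble(spectrum_spec(L = L, gamma_beta = gb, nB = 16,
                                            n_snapshots = 400, seed = 9))
  sp <- spectrum_accumulate(ens)
  ref <- 2 / (gb * L^2 * sp$q^2)
  expect_true(all(abs(sp$C2 - ref) < 3 * sp$err + 0.05 * ref))
  # too few snapshots is an error
  expect_error(spectrum_accumulate(ens[1:5]), "snapshots")
  # flat ensemble: zero spectrum
  flatens <- lapply(1:12, function(i) height_field(matrix(1, 8, 8), L))
  spf <- spectrum_accumulate(flatens)
  expect_true(all(spf$C2 == 0))
})

test_that("spectra from different block counts agree on shared modes", {
  L <- 32
  sp16 <- spectrum_accumulate(make_height_ensemble(
    spectrum_spec(L, 1, nB = 16, n_snapshots = 300, seed = 10)))
  sp32 <- spectrum_accumulate(make_height_ensemble(
    spectrum_spec(L, 1, nB = 32, n_snapshots = 300, seed = 11)))
  shared <- intersect(round(sp16$q, 6), round(sp32$q, 6))
  expect_gt(length(shared), 10)
  for (q in shared[1:10]) {
    i <- match(q, round(sp16$q, 6)); j <- match(q, round(sp32$q, 6))
    tol <- 3 * sqrt(sp16$err[i]^2 + sp32$err[j]^2)
    expect_lt(abs(sp16$C2[i] - sp32$C2[j]), tol + 1e-12)
  }
})

test_that("stiffness fit inverts the spectrum generator", {
  L <- 32
  ens1 <- make_height_ensemble(spectrum_spec(L, 1, nB = 16,
                                             n_snapshots = 400, seed = 12))
  est1 <- stiffness_from_spectrum(spectrum_accumulate(ens1))
  expect_equal(est1$gamma_beta, 1, tolerance = 0.05)
  # doubling the stiffness halves <C2>: recovered as 2
  ens2 <- make_height_ensemble(spectrum_spec(L, 2, nB = 16,
                                             n_snapshots = 400, seed = 12))
  est2 <- stiffness_from_spectrum(spectrum_accumulate(ens2))
  expect_equal(est2$gamma_beta / est1$gamma_beta, 2, tolerance = 0.05)
  # dropping the slowest mode moves the estimate by less than the fit spread
  est1x <- stiffness_from_spectrum(spectrum_accumulate(ens1),
                                   exclude_slowest = TRUE)
  expect_lt(abs(est1x$gamma_beta - est1$gamma_beta),
            3 * (est1$uncertainty + est1x$uncertainty) + 0.05)
  # averaging across block counts reports the spread
  ens3 <- make_height_ensemble(spectrum_spec(L, 1, nB = 32,
                                             n_snapshots = 400, seed = 13))
  multi <- stiffness_from_spectrum(list(spectrum_accumulate(ens1),
                                        spectrum_accumulate(ens3)))
  expect_equal(multi$gamma_beta, 1, tolerance = 0.05)
  expect_equal(length(multi$per_nB), 2)
})

test_that("mode autocorrelation recovers AR(1) correlation times", {
  est <- sapply(1:5, function(s) {
    x <- make_ar1_series(tau_c = 5000, spacing = 1000, length_out = 6000,
                         seed = s)
    ac <- mode_autocorrelation(x, spacing = 1000)
    expect_equal(ac$c[1], 1) # exact normalization at zero lag
    expect_equal(ac$tau_c, 5000, tolerance = 0.3) # single-series recovery
    ac$tau_c
  })
  expect_equal(mean(est), 5000, tolerance = 0.1)
  # independent draws decorrelate below the snapshot spacing
  set.seed(15)
  w <- rnorm(3000)
  acw <- mode_autocorrelation(w, spacing = 1000)
  expect_lt(acw$tau_c, 1000)
  expect_lt(max(abs(acw$c[-1])), 0.1)
  expect_error(mode_autocorrelation(rep(1, 100), spacing = 1), "variance")
})

test_that("apparent width grows logarithmically with block count", {
  L <- 32
  # single resolved mode: w^2 = a^2 / 2 at any resolving nB
  a <- 0.9
  mk_mode <- function(nB) {
    xs <- (seq_len(nB) - 0.5) * L / nB
    list(height_field(outer(a * cos(2 * pi * xs / L), rep(1, nB)), L))
  }
  for (nB in c(4, 8, 16)) {
    w2 <- mean(mk_mode(nB)[[1]]$h^2) - mean(mk_mode(nB)[[1]]$h)^2
    expect_equal(w2, a^2 / 2, tolerance = 1e-10)
  }
  # q^-2 surfaces analyzed at several block counts:
  # fitted slope = 1 / (2 pi gamma_beta) within 10%
  blocks <- make_block_ensemble(L, 1, nB_list = c(4, 5, 6, 7, 8, 9, 12, 16),
                                n_snapshots = 400, seed = 19)
  ws <- width_vs_blocks(blocks, nB_list = c(4, 5, 6, 7, 8, 9, 12, 16))
  expect_equal(ws$gamma_beta, 1, tolerance = 0.1)
  expect_true(all(diff(ws$table$w2) > -0.01)) # nondecreasing within noise
  expect_error(width_vs_blocks(blocks, nB_list = c(5, 6)), "fewer than 3")
})

test_that("stiffness root locates the critical asymmetry", {
  # noiseless line gamma_beta = 1.2 (sqrt(chi) - sqrt(0.54))
  chi <- c(0.8, 1.2, 1.7, 2.3)
  gb <- 1.2 * (sqrt(chi) - sqrt(0.54))
  res <- chi_star_from_stiffness(chi, gb)
  expect_equal(res$chi_star, 0.54, tolerance = 1e-10)
  # noisy replicates: distribution covers the root
  set.seed(17)
  roots <- replicate(200, {
    noisy <- gb + rnorm(length(gb), sd = 0.05)
    tryCatch(chi_star_from_stiffness(chi, noisy)$chi_star,
             error = function(e) NA_real_)
  })
  roots <- roots[!is.na(roots)]
  qs <- stats::quantile(roots, c(0.025, 0.975))
  expect_lt(qs[1], 0.54)
  expect_gt(qs[2], 0.54)
  # two exact points define the line exactly
  res2 <- chi_star_from_stiffness(chi[1:2], gb[1:2])
  expect_equal(res2$chi_star, 0.54, tolerance = 1e-10)
  # decreasing trend is unphysical
  expect_error(chi_star_from_stiffness(chi, rev(gb)), "slope")
})

test_that("width times sqrt(chi) flattens for chi^(-1/2) widths", {
  chi <- seq(0.8, 2.4, by = 0.4)
  k <- 1.7
  tab <- data.frame(chi = chi, nB = 8, w = k / sqrt(chi))
  out <- width_chi_scaling(tab)
  expect_equal(out$w_chi_half, rep(k, length(chi)), tolerance = 1e-12)
  # noisy product: regression slope consistent with zero
  set.seed(18)
  noisy <- tab
  noisy$w <- tab$w * (1 + rnorm(length(chi), sd = 0.1))
  out2 <- width_chi_scaling(noisy)
  fit <- summary(lm(w_chi_half ~ chi, data = out2))
  expect_gt(stats::coef(fit)[2, 4], 0.05) # no significant trend
  # single chi passes through
  expect_equal(nrow(width_chi_scaling(tab[1, ])), 1)
})

test_that("spectrum accumulation honors the decorrelation spacing", {
  ens <- make_height_ensemble(spectrum_spec(L = 24, gamma_beta = 1, nB = 8,
                                            n_snapshots = 30, seed = 20))
  spec <- two_phase_spec(box = c(16, 16, 32))
  traj <- make_two_phase_trajectory(spec, n_frames = 20, seed = 21,
                                    spacing = 1000)
  full <- spectrum_accumulate(traj, nB = 4, min_snapshots = 1)
  thinned <- spectrum_accumulate(traj, nB = 4, spacing = 2000,
                                 min_snapshots = 1)
  expect_equal(attr(full, "n_samples"), 40)    # 20 frames x 2 interfaces
  expect_equal(attr(thinned, "n_samples"), 20) # every other frame
})
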