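#' Specification of a synthetic two-phase configuration
#'
#' Describes an idealized separated steady state: two slabs of prescribed
#' density with the hot-rich phase between \code{interfaces[1]} and
#' \code{interfaces[2]}, species assigned by per-phase purity with an
#' optional tanh-smoothed crossover, Maxwell velocities at per-species
#' effective temperatures, and an optional corrugation of the dividing
#' surfaces. Chains are label-topological only (contiguous blocks of N
#' spatially sorted particles per species); they are never mechanically
#' relaxed and carry no meaningful bond lengths.
#'
#' @param box a \code{\link{sim_box}} or numeric length 3.
#' @param rho_hot_phase,rho_cold_phase number densities of the hot-rich and
#'   cold-rich phase (1/sigma^3).
#' @param interfaces z positions of the two dividing surfaces (hot phase
#'   between them).
#' @param width tanh smoothing width of the species crossover (sigma); 0 for
#'   a sharp interface.
#' @param purity_hot,purity_cold probability that a particle deep in each
#'   phase carries the majority species, in [0.5, 1].
#' @param T_hot,T_cold Maxwell temperatures of the hot and cold species
#'   (epsilon).
#' @param corrugation optional data.frame with columns \code{n}, \code{m},
#'   \code{amplitude}: cosine modes displacing both dividing surfaces.
#' @param N monomers per (label-topological) chain.
#' @return An object of class \code{two_phase_spec}.
#' @export
two_phase_spec <- function(box, rho_hot_phase = 0.8, rho_cold_phase = 0.9,
                           interfaces = NULL, width = 0,
                           purity_hot = 1, purity_cold = 1,
                           T_hot = 2.6, T_cold = 1.2,
                           corrugation = NULL, N = 40) {
  box <- sim_box(box)
  if (is.null(interfaces)) interfaces <- c(box[3] / 4, 3 * box[3] / 4)
  stopifnot(rho_hot_phase >= 0, rho_cold_phase >= 0, width >= 0,
            purity_hot >= 0.5, purity_hot <= 1,
            purity_cold >= 0.5, purity_cold <= 1,
            T_hot > 0, T_cold > 0,
            length(interfaces) == 2, interfaces[1] < interfaces[2])
  if (!is.null(corrugation)) {
    stopifnot(all(c("n", "m", "amplitude") %in% names(corrugation)))
  }
  structure(list(box = box, rho_hot_phase = rho_hot_phase,
                 rho_cold_phase = rho_cold_phase, interfaces = interfaces,
                 width = width, purity_hot = purity_hot,
                 purity_cold = purity_cold, T_hot = T_hot, T_cold = T_cold,
                 corrugation = corrugation, N = as.integer(N)),
            class = "two_phase_spec")
}

# corrugation displacement at lateral positions (x, y)
corrugation_height <- function(spec, x, y) {
  if (is.null(spec$corrugation)) return(rep(0, length(x)))
  L <- as.numeric(spec$box)
  h <- rep(0, length(x))
  for (k in seq_len(nrow(spec$corrugation))) {
    qx <- 2 * pi * spec$corrugation$n[k] / L[1]
    qy <- 2 * pi * spec$corrugation$m[k] / L[2]
    h <- h + spec$corrugation$amplitude[k] * cos(qx * x + qy * y)
  }
  h
}

#' Generate a synthetic two-phase configuration
#'
#' Particles are placed uniformly within each phase at its density (the
#' corrugated dividing surface shifts the local phase boundary), species are
#' drawn by phase purity with a tanh crossover of the requested width, and
#' velocities are Maxwell at the species temperature. The emitted state
#' carries the generating spec as attribute \code{"truth"}.
#'
#' @param spec a \code{\link{two_phase_spec}}.
#' @param seed integer RNG seed.
#' @return a \code{\link{system_state}}.
#' @export
make_two_phase <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "two_phase_spec"))
  set.seed(seed)
  L <- as.numeric(spec$box)
  A <- L[1] * L[2]
  gap <- spec$interfaces[2] - spec$interfaces[1]
  n_hotph <- round(spec$rho_hot_phase * A * gap)
  n_coldph <- round(spec$rho_cold_phase * A * (L[3] - gap))

  place <- function(n, lo_fun, span) {
    x <- runif(n) * L[1]
    y <- runif(n) * L[2]
    z <- (lo_fun(x, y) + runif(n) * span) %% L[3]
    cbind(x, y, z)
  }
  corr <- function(x, y) corrugation_height(spec, x, y)
  pos_h <- place(n_hotph, function(x, y) spec$interfaces[1] + corr(x, y), gap)
  pos_c <- place(n_coldph, function(x, y) spec$interfaces[2] + corr(x, y), L[3] - gap)
  pos <- rbind(pos_h, pos_c)
  np <- nrow(pos)

  # hot-membership field: 1 deep in the hot phase, 0 deep in the cold phase
  hshift <- corr(pos[, 1], pos[, 2])
  z1 <- spec$interfaces[1] + hshift
  z2 <- spec$interfaces[2] + hshift
  f <- if (spec$width > 0) {
    (tanh((pos[, 3] - z1) / spec$width) + tanh((z2 - pos[, 3]) / spec$width)) / 2
  } else {
    as.numeric(pos[, 3] >= z1 & pos[, 3] < z2)
  }
  p_hot <- (1 - spec$purity_cold) + (spec$purity_hot - (1 - spec$purity_cold)) * f
  species <- ifelse(rbinom(np, 1, p_hot) == 1, SPECIES_HOT, SPECIES_COLD)

  # drop the per-species remainders so every chain is complete (species are
  # never flipped: purity stays exact)
  N <- spec$N
  keep <- rep(TRUE, np)
  for (sp in c(SPECIES_HOT, SPECIES_COLD)) {
    idx <- which(species == sp)
    drop_n <- length(idx) %% N
    if (drop_n > 0) keep[sample(idx, drop_n)] <- FALSE
  }
  pos <- pos[keep, , drop = FALSE]
  species <- species[keep]
  f <- f[keep]
  np <- nrow(pos)

  # label-topological chains: contiguous blocks of N spatially sorted labels
  chain <- integer(np)
  next_id <- 1L
  for (sp in c(SPECIES_HOT, SPECIES_COLD)) {
    idx <- which(species == sp)
    idx <- idx[order(pos[idx, 3], pos[idx, 2], pos[idx, 1])]
    nch <- length(idx) %/% N
    chain[idx] <- next_id + rep(seq_len(nch) - 1L, each = N)
    next_id <- next_id + nch
  }
  temps <- ifelse(species == SPECIES_HOT, spec$T_hot, spec$T_cold)
  vel <- matrix(rnorm(3 * np), np, 3) * sqrt(temps)
  st <- system_state(pos, vel, species, chain, spec$box, time = 0)
  attr(st, "truth") <- spec
  st
}

#' Ensemble of independent synthetic two-phase snapshots
#'
#' @param spec a \code{\link{two_phase_spec}}.
#' @param n_frames number of independent draws.
#' @param seed integer RNG seed.
#' @param spacing nominal time between frames (tau), stored in the frame
#'   times.
#' @return a \code{\link{trajectory}}.
#' @export
make_two_phase_trajectory <- function(spec, n_frames = 10, seed = 1,
                                      spacing = 5000) {
  frames <- lapply(seq_len(n_frames), function(i) {
    st <- make_two_phase(spec, seed = seed + i - 1L)
    st$time <- (i - 1) * spacing
    st
  })
  trajectory(frames, meta = list(truth = spec, aligned = TRUE))
}

#' Specification of a synthetic capillary height-field ensemble
#'
#' @param L lateral box size (sigma).
#' @param gamma_beta interfacial stiffness (1/sigma^2), positive.
#' @param nB blocks per lateral direction.
#' @param n_snapshots ensemble size.
#' @param seed integer RNG seed.
#' @return An object of class \code{spectrum_spec}.
#' @export
spectrum_spec <- function(L, gamma_beta, nB = 16, n_snapshots = 400, seed = 1) {
  stopifnot(L > 0, gamma_beta > 0, nB >= 4, n_snapshots >= 1)
  structure(list(L = L, gamma_beta = gamma_beta, nB = as.integer(nB),
                 n_snapshots = as.integer(n_snapshots), seed = as.integer(seed)),
            class = "spectrum_spec")
}

#' Generate a capillary-spectrum height-field ensemble
#'
#' Independent Gaussian mode amplitudes with \code{Var(A) = Var(B) =
#' 2 / (gamma_beta L^2 q^2)} for every resolvable mode — the equilibrium-like
#' q^-2 capillary spectrum. Seed-deterministic; the ground truth travels as
#' attribute \code{"truth"}.
#'
#' @param spec a \code{\link{spectrum_spec}}.
#' @return list of \code{\link{height_field}}s.
#' @export
make_height_ensemble <- function(spec) {
  stopifnot(inherits(spec, "spectrum_spec"))
  set.seed(spec$seed)
  L <- c(spec$L, spec$L)
  nB <- spec$nB
  tab <- mode_table(nB, L)
  xs <- (seq_len(nB) - 0.5) * L[1] / nB
  ys <- (seq_len(nB) - 0.5) * L[2] / nB
  nmodes <- nrow(tab)
  sdA <- sqrt(2 / (spec$gamma_beta * L[1] * L[2] * tab$q^2))
  # precompute basis matrices: nB^2 x nmodes
  X <- matrix(rep(xs, nB), nB * nB)
  Y <- matrix(rep(ys, each = nB), nB * nB)
  Cb <- cos(X %*% t(tab$qx) + Y %*% t(tab$qy))
  Sb <- sin(X %*% t(tab$qx) + Y %*% t(tab$qy))
  out <- vector("list", spec$n_snapshots)
  for (s in seq_len(spec$n_snapshots)) {
    Av <- rnorm(nmodes) * sdA
    Bv <- rnorm(nmodes) * sdA
    h <- matrix(Cb %*% Av + Sb %*% Bv, nB, nB)
    out[[s]] <- height_field(h, L, interface = "lower", time = s)
  }
  attr(out, "truth") <- spec
  out
}

#' Block-resolved views of one capillary surface ensemble
#'
#' Draws continuous capillary surfaces (independent Gaussian amplitudes with
#' \code{Var(A) = Var(B) = 2/(gamma_beta L^2 q^2)} for all modes up to
#' \code{K}) and returns, for every requested block count, the block-averaged
#' height fields of the \emph{same} surfaces. Block averaging multiplies each
#' mode by \code{sinc(qx D/2) sinc(qy D/2)} with \code{D = L/nB} — the block
#' filter that suppresses wavevectors beyond \code{2 pi nB / L}. This is the
#' faithful emulation of analyzing one trajectory at several resolutions, so
#' the apparent width \code{w^2(nB)} carries correlated (not independent)
#' noise across \code{nB}, as in real data.
#'
#' @param L lateral box size (sigma).
#' @param gamma_beta interfacial stiffness (1/sigma^2).
#' @param nB_list block counts.
#' @param n_snapshots ensemble size.
#' @param K largest mode index of the underlying surface.
#' @param seed integer RNG seed.
#' @return named list keyed by \code{nB}; each element is a list of
#'   \code{\link{height_field}}s. Ground truth in attribute \code{"truth"}.
#' @export
make_block_ensemble <- function(L, gamma_beta, nB_list, n_snapshots = 400,
                                K = 16, seed = 1) {
  stopifnot(L > 0, gamma_beta > 0, all(nB_list >= 2), K >= 2)
  set.seed(seed)
  nm <- expand.grid(n = -K:K, m = -K:K)
  nm <- nm[nm$n > 0 | (nm$n == 0 & nm$m > 0), ]
  qx <- 2 * pi * nm$n / L
  qy <- 2 * pi * nm$m / L
  q <- sqrt(qx^2 + qy^2)
  sdA <- sqrt(2 / (gamma_beta * L^2 * q^2))
  nmodes <- length(q)
  Amat <- matrix(rnorm(nmodes * n_snapshots), nmodes) * sdA
  Bmat <- matrix(rnorm(nmodes * n_snapshots), nmodes) * sdA
  sinc <- function(t) ifelse(abs(t) < 1e-12, 1, sin(t) / t)
  out <- list()
  for (nB in nB_list) {
    D <- L / nB
    att <- sinc(qx * D / 2) * sinc(qy * D / 2)
    xs <- (seq_len(nB) - 0.5) * D
    X <- matrix(rep(xs, nB), nB * nB)
    Y <- matrix(rep(xs, each = nB), nB * nB)
    phase <- X %*% t(qx) + Y %*% t(qy)
    Cb <- cos(phase) * rep(att, each = nB * nB)
    Sb <- sin(phase) * rep(att, each = nB * nB)
    H <- Cb %*% Amat + Sb %*% Bmat
    out[[as.character(nB)]] <- lapply(seq_len(n_snapshots), function(s)
      height_field(matrix(H[, s], nB, nB), L, time = s))
  }
  attr(out, "truth") <- list(L = L, gamma_beta = gamma_beta, K = K,
                             seed = seed)
  out
}

#' Stationary AR(1) mode-amplitude series
#'
#' First-order autoregressive series with autocorrelation
#' \code{exp(-spacing / tau_c)} per step, unit stationary variance and zero
#' mean — the synthetic analogue of a slow capillary mode sampled at fixed
#' cadence.
#'
#' @param tau_c correlation time (tau), positive.
#' @param spacing sample spacing (tau).
#' @param length_out series length.
#' @param seed integer RNG seed.
#' @return numeric series with attribute \code{"truth"}.
#' @export
make_ar1_series <- function(tau_c, spacing, length_out, seed = 1) {
  stopifnot(tau_c > 0, spacing > 0, length_out >= 2)
  set.seed(seed)
  phi <- exp(-spacing / tau_c)
  x <- numeric(length_out)
  x[1] <- rnorm(1)
  innov <- rnorm(length_out - 1) * sqrt(1 - phi^2)
  for (i in 2:length_out) x[i] <- phi * x[i - 1] + innov[i - 1]
  attr(x, "truth") <- list(tau_c = tau_c, spacing = spacing, phi = phi)
  x
}

#' Synthetic critical-curve families
#'
#' Seeded generators for the three observable-versus-asymmetry shapes the
#' critical-point estimators consume: a power-law binodal density
#' difference, a quadratic-to-plateau entropy-production curve, and a family
#' of cumulant curves pinned to cross at a common point. Ground-truth
#' parameters travel with the output.
#'
#' @param chi increasing asymmetry grid.
#' @param delta_rho_pars list with \code{A}, \code{chi_star}, \code{beta}
#'   for \code{delta_rho = A (chi - chi_star)^beta} (defaults: the fitted
#'   binodal values 0.143, 0.36, 0.47).
#' @param entropy_pars list with \code{a} (quadratic amplitude) and
#'   \code{chi_star} (crossover, default 0.43).
#' @param cumulant_pars list with \code{chi_star} (crossing point, default
#'   0.46), \code{level} (crossing level, default 2.0), \code{n} (sub-box
#'   counts) and \code{width} (sigmoid width).
#' @param noise relative Gaussian noise applied multiplicatively to entropy
#'   and cumulant curves; absolute noise sd for \code{delta_rho}
#'   (1/sigma^3).
#' @param seed integer RNG seed.
#' @return list with \code{delta_rho}, \code{entropy} (both
#'   \code{\link{critical_curve}}s), \code{cumulants} (list of curves) and
#'   \code{truth}.
#' @export
make_critical_curves <- function(chi,
                                 delta_rho_pars = list(A = 0.143, chi_star = 0.36,
                                                       beta = 0.47),
                                 entropy_pars = list(a = 1, chi_star = 0.43),
                                 cumulant_pars = list(chi_star = 0.46, level = 2,
                                                      n = c(4, 6, 8), width = 0.3),
                                 noise = 0, seed = 1) {
  stopifnot(!is.unsorted(chi, strictly = TRUE))
  set.seed(seed)
  dp <- delta_rho_pars
  chi_d <- chi[chi > dp$chi_star]
  drho <- dp$A * (chi_d - dp$chi_star)^dp$beta
  if (noise > 0) {
    drho <- drho + rnorm(length(drho), sd = noise)
    # a noisy draw can push a near-critical point below zero; such points
    # would not appear in a measured binodal either
    chi_d <- chi_d[drho > 0]
    drho <- drho[drho > 0]
  }
  ep <- entropy_pars
  sdot <- ifelse(chi <= ep$chi_star, ep$a * chi^2, ep$a * ep$chi_star^2)
  if (noise > 0) sdot <- sdot * (1 + rnorm(length(chi), sd = noise))
  cp <- cumulant_pars
  amp <- 0.9 * seq_along(cp$n) / length(cp$n)
  cum <- lapply(seq_along(cp$n), function(i) {
    un <- cp$level - amp[i] * tanh((chi - cp$chi_star) / cp$width)
    if (noise > 0) un <- un * (1 + rnorm(length(chi), sd = noise))
    critical_curve(chi, un, observable = sprintf("Un(n=%d)", cp$n[i]))
  })
  list(delta_rho = critical_curve(chi_d, drho, observable = "delta_rho"),
       entropy = critical_curve(chi, sdot, observable = "entropy_production"),
       cumulants = cum,
       truth = list(delta_rho = dp, entropy = ep, cumulant = cp, noise = noise,
                    seed = seed))
}
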