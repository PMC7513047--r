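#' Slab grid along an interface normal
#'
#' Uniform half-open slabs \code{[z, z + width)} covering the box along one
#' axis. The default 100 slabs resolve interfaces a few sigma wide in
#' melt-sized boxes.
#'
#' @param box a \code{\link{sim_box}} or numeric length 3.
#' @param n number of slabs.
#' @param axis interface normal: "x", "y", "z" or 1:3.
#' @return An object of class \code{slab_grid}.
#' @export
slab_grid <- function(box, n = 100, axis = "z") {
  box <- sim_box(box)
  ax <- if (is.character(axis)) match(axis, c("x", "y", "z")) else as.integer(axis)
  if (is.na(ax) || ax < 1 || ax > 3) stop("axis must be 'x', 'y', 'z' or 1:3")
  n <- as.integer(n)
  stopifnot(n >= 2)
  width <- box[ax] / n
  structure(
    list(axis = ax, n = n, width = width,
         centers = (seq_len(n) - 0.5) * width,
         area = prod(box) / box[ax], box = box),
    class = "slab_grid"
  )
}

slab_index <- function(coord, grid) {
  i <- floor((coord %% grid$box[grid$axis]) / grid$width) + 1L
  pmin.int(pmax.int(i, 1L), grid$n)
}

new_slab_profile <- function(grid, value, stderr, count, observable, units) {
  structure(
    data.frame(z = grid$centers, value = value, stderr = stderr, count = count),
    observable = observable, units = units, grid = grid,
    class = c("slab_profile", "data.frame")
  )
}

#' @export
print.slab_profile <- function(x, ...) {
  cat(sprintf("slab profile of %s [%s]: %d slabs, width %.4g sigma\n",
              attr(x, "observable"), attr(x, "units"), nrow(x),
              attr(x, "grid")$width))
  print.data.frame(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("... %d more slabs\n", nrow(x) - 5))
  invisible(x)
}

#' @export
plot.slab_profile <- function(x, ...) {
  graphics::plot(x$z, x$value, type = "l",
                 xlab = "z (sigma)", ylab = attr(x, "observable"), ...)
  ok <- x$count > 0
  graphics::arrows(x$z[ok], x$value[ok] - x$stderr[ok],
                   x$z[ok], x$value[ok] + x$stderr[ok],
                   length = 0.02, angle = 90, code = 3, col = "grey50")
  invisible(x)
}

select_particles <- function(state, select) {
  switch(select,
         all = seq_len(nrow(state$pos)),
         hot = which(state$species == SPECIES_HOT),
         cold = which(state$species == SPECIES_COLD),
         stop("selector must be 'all', 'hot' or 'cold'"))
}

# shared slab accumulator: per-frame per-slab counts and sums of `w`
slab_accumulate <- function(traj, grid, select, wfun = NULL) {
  nf <- length(traj$frames)
  if (nf == 0) stop("empty trajectory")
  counts <- matrix(0, nf, grid$n)
  sums <- matrix(0, nf, grid$n)
  for (f in seq_len(nf)) {
    st <- traj$frames[[f]]
    idx <- select_particles(st, select)
    bins <- slab_index(st$pos[idx, grid$axis], grid)
    counts[f, ] <- tabulate(bins, grid$n)
    if (!is.null(wfun)) {
      w <- wfun(st, idx)
      sums[f, ] <- vapply(seq_len(grid$n), function(k) sum(w[bins == k]), 0)
    }
  }
  list(counts = counts, sums = sums, nf = nf)
}

#' Slab number-density profile
#'
#' Per-slab number density of the selected particles, averaged over frames.
#' The slab integral times the cross-section area recovers the selected
#' particle count exactly per frame.
#'
#' @param traj an aligned \code{\link{trajectory}}.
#' @param grid a \code{\link{slab_grid}}.
#' @param select "all", "hot" or "cold".
#' @return a \code{slab_profile} (units 1/sigma^3).
#' @export
density_profile <- function(traj, grid, select = "all") {
  acc <- slab_accumulate(traj, grid, select)
  vol <- grid$area * grid$width
  dens <- acc$counts / vol
  new_slab_profile(grid,
                   value = colMeans(dens),
                   stderr = apply(dens, 2, sd) / sqrt(acc$nf),
                   count = colSums(acc$counts),
                   observable = paste0("density(", select, ")"),
                   units = "1/sigma^3")
}

#' Mean-square-velocity profile
#'
#' Per-slab \code{<v^2>/3} over the selected particles, pooled over frames
#' (sums of \code{v^2/3} divided by total counts). In a pure-phase slab this
#' is the effective temperature of the species occupying it.
#'
#' @inheritParams density_profile
#' @return a \code{slab_profile} (units epsilon).
#' @export
msv_profile <- function(traj, grid, select = "all") {
  acc <- slab_accumulate(traj, grid, select,
                         wfun = function(st, idx)
                           rowSums(st$vel[idx, , drop = FALSE]^2) / 3)
  tot <- colSums(acc$counts)
  value <- ifelse(tot > 0, colSums(acc$sums) / tot, NA_real_)
  # frame-to-frame spread of the slab mean as the error bar
  fmean <- acc$sums / acc$counts
  stderr <- apply(fmean, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  })
  new_slab_profile(grid, value, stderr, tot,
                   observable = paste0("msv(", select, ")"), units = "epsilon")
}

#' Circular (angular) mean position along a periodic axis
#'
#' @param coord coordinates along the axis.
#' @param L period (box length along the axis).
#' @return mean position in \code{[0, L)}.
#' @export
circular_mean <- function(coord, L) {
  th <- coord / L * 2 * pi
  (atan2(mean(sin(th)), mean(cos(th))) %% (2 * pi)) / (2 * pi) * L
}

# interface detector: amplitude of the first circular harmonic of the
# hot-fraction profile along `ax`. A slab pair of interfaces gives an
# amplitude of order the phase-purity contrast; counting noise in a mixed
# state stays near sqrt(2/nbins) * sd(phi), far below the threshold.
frame_contrast <- function(st, ax, nbins = 24) {
  L <- st$box[ax]
  bins <- pmin.int(floor(st$pos[, ax] / L * nbins) + 1L, nbins)
  nh <- tabulate(bins[st$species == SPECIES_HOT], nbins)
  nc <- tabulate(bins[st$species == SPECIES_COLD], nbins)
  tot <- nh + nc
  ok <- tot > 0
  if (sum(ok) < 4) return(0)
  phi <- nh[ok] / tot[ok]
  theta <- 2 * pi * (which(ok) - 0.5) / nbins
  2 * Mod(mean((phi - mean(phi)) * exp(1i * theta)))
}

#' Center and orient phase-separated snapshots
#'
#' Identifies the interface normal (the axis with the strongest species
#' contrast), rotates coordinates so it becomes z, and shifts each frame so
#' that the circular-mean position of the hot particles maps to the box
#' center. Frames without a detectable interface (mixed states) are skipped
#' with a warning; if every frame is mixed, an error is raised.
#'
#' @param traj a \code{\link{trajectory}} of separated snapshots.
#' @param axis interface normal ("x", "y", "z"); NULL to auto-detect.
#' @param min_contrast minimum first-harmonic amplitude of the hot-fraction
#'   profile for a frame to count as separated.
#' @return the aligned \code{\link{trajectory}}; \code{meta$skipped} counts
#'   the dropped frames.
#' @export
align_snapshots <- function(traj, axis = NULL, min_contrast = 0.2) {
  if (length(traj$frames) == 0) stop("empty trajectory")
  if (is.null(axis)) {
    score <- sapply(1:3, function(ax)
      mean(vapply(traj$frames, frame_contrast, 0, ax = ax)))
    ax <- which.max(score)
  } else {
    ax <- if (is.character(axis)) match(axis, c("x", "y", "z")) else as.integer(axis)
  }
  perm <- c(setdiff(1:3, ax), ax) # chosen axis becomes z
  out <- list()
  skipped <- 0L
  for (st in traj$frames) {
    if (frame_contrast(st, ax) < min_contrast) {
      skipped <- skipped + 1L
      next
    }
    L <- st$box[ax]
    hot_center <- circular_mean(st$pos[st$species == SPECIES_HOT, ax], L)
    z <- (st$pos[, ax] - hot_center + L / 2) %% L
    pos <- st$pos[, perm, drop = FALSE]
    pos[, 3] <- z
    vel <- st$vel[, perm, drop = FALSE]
    st2 <- st
    st2$pos <- pos
    st2$vel <- vel
    st2$box <- sim_box(as.numeric(st$box)[perm])
    out[[length(out) + 1L]] <- st2
  }
  if (length(out) == 0) {
    stop("no detectable interface in any frame (mixed state?)")
  }
  if (skipped > 0) {
    warning(sprintf("skipped %d frame(s) without a detectable interface", skipped))
  }
  trajectory(out, thermo = traj$thermo, ff = traj$ff,
             meta = modifyList(traj$meta,
                               list(aligned = TRUE, axis = ax, skipped = skipped)))
}

#' Effective temperatures of the hot and cold components
#'
#' One third of the mean squared velocity of each species, pooled over all
#' particles and frames; optionally also per-slab profiles.
#'
#' @param traj a \code{\link{trajectory}} with velocities.
#' @param grid optional \code{\link{slab_grid}} for per-slab profiles.
#' @return list with scalars \code{Theff}, \code{Tceff}, the asymmetry
#'   \code{chi}, and (with a grid) \code{profile_hot}, \code{profile_cold}.
#' @export
effective_temperatures <- function(traj, grid = NULL) {
  sums <- c(hot = 0, cold = 0)
  ns <- c(hot = 0, cold = 0)
  for (st in traj$frames) {
    for (sp in SPECIES_LEVELS) {
      idx <- select_particles(st, sp)
      sums[sp] <- sums[sp] + sum(st$vel[idx, , drop = FALSE]^2) / 3
      ns[sp] <- ns[sp] + length(idx)
    }
  }
  if (any(ns == 0)) {
    stop(sprintf("species '%s' absent: effective temperature undefined",
                 names(ns)[ns == 0][1]))
  }
  res <- list(Theff = unname(sums["hot"] / ns["hot"]),
              Tceff = unname(sums["cold"] / ns["cold"]))
  res$chi <- chi_asymmetry(res$Theff, res$Tceff)
  if (!is.null(grid)) {
    res$profile_hot <- msv_profile(traj, grid, "hot")
    res$profile_cold <- msv_profile(traj, grid, "cold")
  }
  class(res) <- "effective_temperatures"
  res
}

#' @export
print.effective_temperatures <- function(x, ...) {
  cat(sprintf("Theff = %.4f, Tceff = %.4f, chi = (Theff - Tceff)/Tceff = %.4f\n",
              x$Theff, x$Tceff, x$chi))
  invisible(x)
}

#' Temperature asymmetry parameter
#'
#' \code{chi = (Theff - Tceff) / Tceff}, the control parameter of the
#' two-temperature phase separation (nearly friction-insensitive).
#'
#' @param Theff hot-species effective temperature (epsilon).
#' @param Tceff cold-species effective temperature (epsilon), positive.
#' @return scalar chi.
#' @export
chi_asymmetry <- function(Theff, Tceff) {
  if (any(Tceff <= 0)) stop("Tceff must be positive")
  (Theff - Tceff) / Tceff
}

#' Decomposition of the msv profile into effective temperatures and fractions
#'
#' Per slab, the mean square velocity obeys the per-snapshot identity
#' \code{<v^2>/3 = <Theff phi_h + Tceff (1 - phi_h)>} with \code{phi_h} the
#' hot number fraction. Comparing it with the uncorrelated combination
#' \code{<Theff><phi_h> + <Tceff>(1 - <phi_h>)} isolates the correlation of
#' composition and particle speeds (positive in the hot phase, negative in
#' the cold phase of separated states).
#'
#' @inheritParams density_profile
#' @return list of three \code{slab_profile}s: \code{msv} (the weighted
#'   decomposition, identical to the msv profile), \code{uncorrelated}, and
#'   their \code{difference}.
#' @export
msv_decomposition <- function(traj, grid) {
  acc_h <- slab_accumulate(traj, grid, "hot",
                           wfun = function(st, idx)
                             rowSums(st$vel[idx, , drop = FALSE]^2) / 3)
  acc_c <- slab_accumulate(traj, grid, "cold",
                           wfun = function(st, idx)
                             rowSums(st$vel[idx, , drop = FALSE]^2) / 3)
  nh <- colSums(acc_h$counts); nc <- colSums(acc_c$counts)
  tot <- nh + nc
  msv <- ifelse(tot > 0, (colSums(acc_h$sums) + colSums(acc_c$sums)) / tot, NA_real_)
  Th_bar <- ifelse(nh > 0, colSums(acc_h$sums) / nh, NA_real_)
  Tc_bar <- ifelse(nc > 0, colSums(acc_c$sums) / nc, NA_real_)
  phi_bar <- ifelse(tot > 0, nh / tot, NA_real_)
  unc <- ifelse(phi_bar > 0 & phi_bar < 1,
                Th_bar * phi_bar + Tc_bar * (1 - phi_bar),
                ifelse(phi_bar == 1, Th_bar, Tc_bar))
  mk <- function(v, obs) new_slab_profile(grid, v, rep(NA_real_, grid$n), tot,
                                          observable = obs, units = "epsilon")
  list(msv = mk(msv, "msv (Teff-weighted decomposition)"),
       uncorrelated = mk(unc, "<Theff><phi_h> + <Tceff>(1-<phi_h>)"),
       difference = mk(msv - unc, "composition-velocity correlation"))
}

#' Like-species contact order parameter
#'
#' \code{Phi = 2 x - 1}, where \code{x} is the mean fraction of same-species
#' neighbors among inter-chain neighbors within the interaction cutoff
#' \code{rc}, averaged over monomers that have at least one inter-chain
#' neighbor. \code{Phi = 1} for complete separation and 0 when like and
#' unlike inter-chain contacts are equally likely.
#'
#' @param state a \code{\link{system_state}}.
#' @param ff a \code{\link{force_field}} supplying the neighborhood radius.
#' @return scalar Phi in [-1, 1] with attributes \code{x} and
#'   \code{n_contributing}.
#' @export
order_parameter_phi <- function(state, ff = force_field()) {
  res <- cpp_contact_fraction(state$pos, state$species, state$chain,
                              as.numeric(state$box), ff$rc)
  if (res$n_contributing == 0) {
    stop("no inter-chain contacts within rc anywhere (dilute degenerate input)")
  }
  structure(2 * res$x - 1, x = res$x, n_contributing = res$n_contributing)
}

#' Slab-resolved pressure tensor
#'
#' Kinetic part \code{rho(z) <v_i v_j>} per slab plus the virial part from
#' pairs whose minimum-image segment crosses the slab mid-plane, each pair
#' contributing \code{(r (x) F) / (2A)}. Also returns the kinetic tangential
#' minus normal anisotropy \code{rho(z) <(v_x^2 + v_y^2)/2 - v_z^2>}, the
#' quantity that is non-monotonic near the interface of separated states.
#' The printed form of the kinetic term in some conventions carries a /3
#' (the trace average); set \code{as_printed = TRUE} to divide the kinetic
#' tensor by 3.
#'
#' @inheritParams density_profile
#' @param ff a \code{\link{force_field}} (virial recomputation).
#' @param as_printed divide the kinetic tensor by 3 (strict printed form).
#' @param include_bonds include FENE bond forces in the virial; disable for
#'   label-topological synthetic states whose bonds are not mechanical.
#' @return An object of class \code{pressure_profile}: slab centers,
#'   kinetic and virial tensor components (columns xx, yy, zz, xy, xz, yz,
#'   units epsilon/sigma^3), their standard errors, the kinetic anisotropy
#'   profile, and per-frame samples of the tension integrand.
#' @export
pressure_profiles <- function(traj, grid, ff = force_field(), as_printed = FALSE,
                              include_bonds = TRUE) {
  nf <- length(traj$frames)
  if (nf == 0) stop("empty trajectory")
  if (grid$width <= 0) stop("slab width must be positive")
  comp <- c("xx", "yy", "zz", "xy", "xz", "yz")
  kin <- array(0, c(nf, grid$n, 6))
  vir <- array(0, c(nf, grid$n, 6))
  ani <- matrix(0, nf, grid$n)
  dens <- matrix(0, nf, grid$n)
  gamma_samples <- numeric(nf)
  vol <- grid$area * grid$width
  for (f in seq_len(nf)) {
    st <- traj$frames[[f]]
    bins <- slab_index(st$pos[, grid$axis], grid)
    v <- st$vel
    prods <- cbind(v[, 1]^2, v[, 2]^2, v[, 3]^2,
                   v[, 1] * v[, 2], v[, 1] * v[, 3], v[, 2] * v[, 3])
    for (k in 1:6) {
      kin[f, , k] <- vapply(seq_len(grid$n),
                            function(s) sum(prods[bins == s, k]), 0) / vol
    }
    ani[f, ] <- vapply(seq_len(grid$n), function(s) {
      sel <- bins == s
      sum((prods[sel, 1] + prods[sel, 2]) / 2 - prods[sel, 3])
    }, 0) / vol
    dens[f, ] <- tabulate(bins, grid$n) / vol
    bonds <- if (include_bonds) chain_bonds(st$chain) else matrix(0L, 0, 2)
    vir[f, , ] <- cpp_virial_profile(st$pos, bonds,
                                     as.numeric(st$box),
                                     ff$epsilon, ff$sigma, ff$rc, ff$K, ff$rmax,
                                     grid$n, grid$axis - 1L)
    kfac <- if (as_printed) 3 else 1
    pN <- kin[f, , 3] / kfac + vir[f, , 3]
    pT <- (kin[f, , 1] + kin[f, , 2]) / (2 * kfac) + (vir[f, , 1] + vir[f, , 2]) / 2
    gamma_samples[f] <- sum(pN - pT) * grid$width / 2
  }
  if (as_printed) kin <- kin / 3
  avg <- function(a) {
    m <- apply(a, c(2, 3), mean)
    colnames(m) <- comp
    m
  }
  sem <- function(a) {
    m <- apply(a, c(2, 3), sd) / sqrt(nf)
    colnames(m) <- comp
    m
  }
  structure(
    list(z = grid$centers,
         kinetic = avg(kin), kinetic_se = sem(kin),
         virial = avg(vir), virial_se = sem(vir),
         anisotropy = colMeans(ani),
         anisotropy_se = apply(ani, 2, sd) / sqrt(nf),
         density = colMeans(dens),
         gamma_samples = gamma_samples,
         grid = grid, as_printed = as_printed, n_frames = nf),
    class = "pressure_profile"
  )
}

#' @export
print.pressure_profile <- function(x, ...) {
  cat(sprintf("pressure profile: %d slabs, %d frames%s\n",
              length(x$z), x$n_frames,
              if (x$as_printed) " (printed /3 kinetic convention)" else ""))
  pN <- x$kinetic[, "zz"] + x$virial[, "zz"]
  cat(sprintf("  mean p_zz = %.4f epsilon/sigma^3\n", mean(pN)))
  invisible(x)
}

#' Interfacial tension integral (diagnostic)
#'
#' \code{gamma = 1/2 integral (p_N - p_T) dz} over the box (two interfaces).
#' For a \code{pressure_profile} the per-frame samples give the mean and its
#' standard error; this estimate is a diagnostic only, since the virial
#' profile of a melt is noisy. For a plain data frame with columns
#' \code{z, pN, pT}, the trapezoidal quadrature of the given profile is
#' returned.
#'
#' @param x a \code{pressure_profile} or data.frame with \code{z, pN, pT}.
#' @return list with \code{gamma} and \code{se} (epsilon/sigma^2; \code{se}
#'   is NA for plain profiles).
#' @export
tension_integral <- function(x) {
  if (inherits(x, "pressure_profile")) {
    g <- x$gamma_samples
    return(list(gamma = mean(g),
                se = if (length(g) > 1) sd(g) / sqrt(length(g)) else NA_real_))
  }
  stopifnot(all(c("z", "pN", "pT") %in% names(x)))
  f <- (x$pN - x$pT) / 2
  z <- x$z
  list(gamma = sum(diff(z) * (head(f, -1) + tail(f, -1)) / 2), se = NA_real_)
}

#' Per-chain squared gyration radius
#'
#' Chains are first made whole across the periodic boundary by walking bond
#' vectors with the minimum-image convention.
#'
#' @param state a \code{\link{system_state}}.
#' @return data.frame with \code{chain}, \code{species}, \code{com_z}
#'   (wrapped into the box) and \code{rg2} (sigma^2).
#' @export
chain_gyration <- function(state) {
  up <- unwrap_chains(state)
  ord <- sort(unique(state$chain))
  rg2 <- vapply(ord, function(ch) {
    idx <- state$chain == ch
    mean(rowSums(sweep(up[idx, , drop = FALSE], 2,
                       colMeans(up[idx, , drop = FALSE]), `-`)^2))
  }, 0)
  comz <- vapply(ord, function(ch) {
    idx <- state$chain == ch
    mean(up[idx, 3]) %% state$box[3]
  }, 0)
  sp <- vapply(ord, function(ch) state$species[which(state$chain == ch)[1]], 0L)
  data.frame(chain = ord, species = species_label(sp), com_z = comz, rg2 = rg2)
}

#' Gyration radii by region
#'
#' Assigns each chain to the hot phase, cold phase or transition region by
#' its center-of-mass z (transition = within \code{width} of either
#' interface), and reports the mean squared gyration radius per region and
#' species.
#'
#' @param traj an aligned \code{\link{trajectory}}.
#' @param interfaces numeric length 2: z positions of the lower and upper
#'   interface bounding the (centered) hot phase.
#' @param width transition-region half-width (sigma).
#' @return data.frame with columns \code{region}, \code{species},
#'   \code{rg2_mean}, \code{rg2_sd}, \code{n_chains}; empty cells carry NA.
#' @export
gyration_by_region <- function(traj, interfaces, width) {
  stopifnot(length(interfaces) == 2, width >= 0)
  interfaces <- sort(interfaces)
  Lz <- traj_box(traj)[3]
  rows <- do.call(rbind, lapply(traj$frames, function(st) {
    g <- chain_gyration(st)
    dlo <- pmin(abs(g$com_z - interfaces[1]), Lz - abs(g$com_z - interfaces[1]))
    dhi <- pmin(abs(g$com_z - interfaces[2]), Lz - abs(g$com_z - interfaces[2]))
    g$region <- ifelse(pmin(dlo, dhi) <= width, "transition",
                       ifelse(g$com_z > interfaces[1] & g$com_z < interfaces[2],
                              "hot", "cold"))
    g
  }))
  grid <- expand.grid(region = c("hot", "cold", "transition"),
                      species = SPECIES_LEVELS, stringsAsFactors = FALSE)
  stats <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- rows$region == grid$region[i] & rows$species == grid$species[i]
    v <- rows$rg2[sel]
    data.frame(region = grid$region[i], species = grid$species[i],
               rg2_mean = if (length(v)) mean(v) else NA_real_,
               rg2_sd = if (length(v) > 1) sd(v) else NA_real_,
               n_chains = length(v))
  })
  do.call(rbind, stats)
}
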