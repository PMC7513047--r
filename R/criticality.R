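#' Steady-state entropy production per hot particle
#'
#' The net heat flux into each reservoir per hot particle, divided by the
#' reservoir temperature: \code{Sdot / (3 zeta) = Theff/Th + Tceff/Tc - 2}.
#' Zero when both effective temperatures equal their reservoirs; strictly
#' positive when heat flows down-gradient through the system.
#'
#' @param Theff hot-species effective temperature (epsilon).
#' @param Tceff cold-species effective temperature (epsilon).
#' @param thermo a \code{\link{thermostat_pair}} providing Th, Tc, zeta.
#' @return named vector: \code{per_3zeta} (dimensionless) and \code{rate}
#'   (the same times 3 zeta, units 1/tau).
#' @export
entropy_production <- function(Theff, Tceff, thermo) {
  if (thermo$Th <= 0 || thermo$Tc <= 0) stop("reservoir temperatures must be positive")
  s <- Theff / thermo$Th + Tceff / thermo$Tc - 2
  c(per_3zeta = s, rate = 3 * thermo$zeta * s)
}

#' Observable-versus-asymmetry curve
#'
#' @param chi strictly increasing asymmetry values.
#' @param value observable values (same length).
#' @param err optional standard errors.
#' @param observable observable name.
#' @param M system size (number of chains), if known.
#' @return An object of class \code{critical_curve} (a data.frame).
#' @export
critical_curve <- function(chi, value, err = NULL, observable = "observable",
                           M = NA_integer_) {
  stopifnot(length(chi) == length(value), !is.unsorted(chi, strictly = TRUE))
  if (is.null(err)) err <- rep(NA_real_, length(chi))
  structure(data.frame(chi = chi, value = value, err = err),
            observable = observable, M = M,
            class = c("critical_curve", "data.frame"))
}

#' Crossover estimate of the critical asymmetry
#'
#' The entropy production grows quadratically in chi below the transition
#' and plateaus once the two-dimensional interface has developed. For every
#' admissible split of the curve into a low-chi and a high-chi window (at
#' least 3 points each), the low branch is fitted by \code{a chi^2} through
#' the origin and the high branch by a constant; the branch intersection
#' \code{chi* = sqrt(c / a)} is kept when it falls between the windows. The
#' estimate is the mean over admissible splits and the uncertainty their
#' spread.
#'
#' @param curve a \code{\link{critical_curve}} (e.g. entropy production vs
#'   chi).
#' @return An object of class \code{crossover_fit}: \code{chi_star},
#'   \code{uncertainty}, and the per-split candidates.
#' @export
crossover_chi_star <- function(curve) {
  chi <- curve$chi
  y <- curve$value
  n <- length(chi)
  if (n < 6) stop("need at least 3 points per branch")
  w <- if (all(is.finite(curve$err)) && all(curve$err > 0)) 1 / curve$err^2 else rep(1, n)
  cands <- data.frame(split = integer(0), chi_star = numeric(0),
                      a = numeric(0), plateau = numeric(0))
  for (k in 3:(n - 3)) {
    lo <- seq_len(k)
    hi <- seq(k + 1, n)
    a <- sum(w[lo] * y[lo] * chi[lo]^2) / sum(w[lo] * chi[lo]^4)
    plateau <- weighted.mean(y[hi], w[hi])
    if (a <= 0 || plateau <= 0) next
    cs <- sqrt(plateau / a)
    # admissible: the intersection sits between the two windows
    if (cs >= chi[k] - 1e-12 && cs <= chi[k + 1] + 1e-12) {
      cands <- rbind(cands, data.frame(split = k, chi_star = cs, a = a,
                                       plateau = plateau))
    }
  }
  if (nrow(cands) == 0) {
    stop("no quadratic-to-plateau crossover found in the sampled chi range")
  }
  structure(list(chi_star = mean(cands$chi_star),
                 uncertainty = if (nrow(cands) > 1) sd(cands$chi_star) else 0,
                 candidates = cands),
            class = "crossover_fit")
}

#' @export
print.crossover_fit <- function(x, ...) {
  cat(sprintf("crossover chi* = %.4f +/- %.4f (%d admissible windows)\n",
              x$chi_star, x$uncertainty, nrow(x$candidates)))
  invisible(x)
}

#' Sub-box configuration for cumulant analysis
#'
#' @param n integer vector of linear sub-box counts (each >= 2); the box is
#'   divided into \code{n^3} equal sub-boxes of edge \code{L/n}.
#' @param rho_bar reference density; NULL uses the global mean species
#'   density of the trajectory.
#' @return An object of class \code{cumulant_config}.
#' @export
cumulant_config <- function(n, rho_bar = NULL) {
  n <- as.integer(n)
  stopifnot(all(n >= 2))
  structure(list(n = n, rho_bar = rho_bar), class = "cumulant_config")
}

# per-snapshot sub-box densities of one species, wrapped coordinates
subbox_densities <- function(st, n, select) {
  idx <- select_particles(st, select)
  L <- as.numeric(st$box)
  ix <- pmin.int(floor(st$pos[idx, 1] / L[1] * n), n - 1)
  iy <- pmin.int(floor(st$pos[idx, 2] / L[2] * n), n - 1)
  iz <- pmin.int(floor(st$pos[idx, 3] / L[3] * n), n - 1)
  cell <- 1L + ix + n * (iy + n * iz)
  tabulate(cell, n^3) / (prod(L) / n^3)
}

#' Fourth-order cumulant of coarse-grained density fluctuations
#'
#' For each snapshot the box is divided into \code{n^3} sub-boxes (wrapped
#' coordinates, no alignment — the statistic must not depend on where the
#' interface sits) and the hot-particle density per sub-box is computed.
#' The cumulant is the ensemble mean of the fourth central moment divided
#' by the squared ensemble mean of the second central moment. Gaussian
#' fluctuations give 3; a symmetric two-state (fully separated) distribution
#' gives 1; curves for different \code{n} cross near the critical point.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param cfg a \code{\link{cumulant_config}}.
#' @param select species whose density is coarse-grained ("hot" or "cold").
#' @return data.frame with columns \code{n}, \code{Un}, \code{rho_bar}.
#' @export
fourth_order_cumulant <- function(traj, cfg, select = "hot") {
  stopifnot(inherits(cfg, "cumulant_config"))
  if (length(traj$frames) == 0) stop("empty trajectory")
  vol <- prod(as.numeric(traj_box(traj)))
  rho_bar <- cfg$rho_bar
  if (is.null(rho_bar)) {
    cnt <- mean(vapply(traj$frames, function(st)
      length(select_particles(st, select)), 0))
    rho_bar <- cnt / vol
  }
  out <- lapply(cfg$n, function(n) {
    m2 <- m4 <- 0
    for (st in traj$frames) {
      d <- subbox_densities(st, n, select) - rho_bar
      m2 <- m2 + mean(d^2)
      m4 <- m4 + mean(d^4)
    }
    m2 <- m2 / length(traj$frames)
    m4 <- m4 / length(traj$frames)
    if (m2 == 0) stop(sprintf("all sub-box densities equal rho_bar at n = %d", n))
    data.frame(n = n, Un = m4 / m2^2, rho_bar = rho_bar)
  })
  do.call(rbind, out)
}

#' Mean-field reference level of the fourth-order cumulant
#'
#' \code{[Gamma(1/4)]^4 / (8 pi^2)}, approximately 2.188 — the cumulant value
#' at the critical point of a mean-field equilibrium transition, used as a
#' reference level for where the curves cross.
#'
#' @return scalar.
#' @export
mean_field_cumulant <- function() gamma(1 / 4)^4 / (8 * pi^2)

#' Critical point from cumulant crossings
#'
#' Curves \code{Un(chi)} for different sub-box counts cross near the
#' critical asymmetry. Pairwise crossings are located by linear
#' interpolation of the curve difference between adjacent chi samples; the
#' estimate is the mean crossing and the quoted error their standard
#' deviation.
#'
#' @param curves list of \code{\link{critical_curve}}s on a common chi grid
#'   (one per sub-box count).
#' @return list with \code{chi_star}, \code{spread}, \code{level} (mean
#'   cumulant value at the crossings) and the per-pair crossing table.
#' @export
cumulant_crossings <- function(curves) {
  stopifnot(length(curves) >= 2)
  chi <- curves[[1]]$chi
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$chi, chi))) stop("curves must share the chi grid")
  }
  cross <- data.frame(i = integer(0), j = integer(0),
                      chi = numeric(0), level = numeric(0))
  for (i in seq_along(curves)) {
    for (j in seq_along(curves)) {
      if (j <= i) next
      d <- curves[[i]]$value - curves[[j]]$value
      sgn <- which(d[-length(d)] * d[-1] < 0 |
                     (d[-length(d)] == 0 & d[-1] != 0))
      if (length(sgn) == 0 && any(d == 0)) {
        k0 <- which(d == 0)[1]
        cross <- rbind(cross, data.frame(i = i, j = j, chi = chi[k0],
                                         level = curves[[i]]$value[k0]))
        next
      }
      if (length(sgn) == 0) next # parallel pair, skipped
      k <- sgn[1]
      t <- d[k] / (d[k] - d[k + 1])
      xc <- chi[k] + t * (chi[k + 1] - chi[k])
      lev <- curves[[i]]$value[k] + t * (curves[[i]]$value[k + 1] - curves[[i]]$value[k])
      cross <- rbind(cross, data.frame(i = i, j = j, chi = xc, level = lev))
    }
  }
  if (nrow(cross) == 0) stop("no crossing found for any curve pair")
  list(chi_star = mean(cross$chi),
       spread = if (nrow(cross) > 1) sd(cross$chi) else 0,
       level = mean(cross$level),
       crossings = cross)
}

# interface locations and tanh-equivalent width from a hot-fraction-like
# profile of an aligned separated state (hot phase centered)
interfaces_from_profile <- function(z, phi, Lz) {
  ok <- is.finite(phi)
  z <- z[ok]; phi <- phi[ok]
  if (length(z) < 8) stop("profile too coarse to locate interfaces")
  mid <- (max(phi) + min(phi)) / 2
  cross_at <- function(level) {
    d <- phi - level
    idx <- which(d[-length(d)] * d[-1] <= 0 & d[-length(d)] != d[-1])
    if (length(idx) == 0) return(numeric(0))
    vapply(idx, function(k) {
      t <- d[k] / (d[k] - d[k + 1])
      z[k] + t * (z[k + 1] - z[k])
    }, 0)
  }
  zm <- cross_at(mid)
  if (length(zm) < 2) stop("no interface pair found (mixed state?)")
  center <- Lz / 2
  lower <- zm[zm < center]
  upper <- zm[zm >= center]
  if (length(lower) == 0 || length(upper) == 0) stop("no interface pair found (mixed state?)")
  zlo <- lower[which.min(center - lower)]
  zhi <- upper[which.min(upper - center)]
  # 25-75% crossing distance; tanh profile has z75 - z25 = 1.0986 w
  lo_level <- min(phi) + 0.25 * (max(phi) - min(phi))
  hi_level <- min(phi) + 0.75 * (max(phi) - min(phi))
  z25 <- cross_at(lo_level); z75 <- cross_at(hi_level)
  width <- NA_real_
  if (length(z25) > 0 && length(z75) > 0) {
    d25 <- min(abs(z25 - zlo)); d75 <- min(abs(z75 - zlo))
    width <- (d25 + d75) / 1.0986
  }
  if (!is.finite(width) || width <= 0) width <- 2 # fallback, a couple of sigma
  list(lower = zlo, upper = zhi, width = width)
}

#' Coexisting-phase (binodal) values from aligned profiles
#'
#' The plateau of each observable is the mean over slabs farther than
#' 1.5 interfacial widths from both interfaces; the quoted error is the
#' sample standard deviation over those slabs. Interfaces and width are
#' located from the hot-fraction profile of each entry.
#'
#' @param profile_sets list of entries, one per thermostat setting; each is a
#'   list with elements \code{chi} (scalar) and named \code{slab_profile}s:
#'   \code{density}, \code{phi_h}, and optionally \code{msv}.
#' @return data.frame with columns \code{chi}, \code{observable},
#'   \code{phase} ("hot"/"cold"), \code{value}, \code{sd}, \code{n_slabs}.
#' @export
binodal_from_profiles <- function(profile_sets) {
  rows <- lapply(profile_sets, function(entry) {
    stopifnot(!is.null(entry$chi), !is.null(entry$phi_h), !is.null(entry$density))
    grid <- attr(entry$phi_h, "grid")
    Lz <- grid$box[grid$axis]
    itf <- tryCatch(
      interfaces_from_profile(entry$phi_h$z, entry$phi_h$value, Lz),
      error = function(e) stop(sprintf("chi = %.3g: %s", entry$chi,
                                       conditionMessage(e))))
    z <- entry$phi_h$z
    dlo <- pmin(abs(z - itf$lower), Lz - abs(z - itf$lower))
    dhi <- pmin(abs(z - itf$upper), Lz - abs(z - itf$upper))
    in_hot <- z > itf$lower & z < itf$upper
    plateau <- pmin(dlo, dhi) > 1.5 * itf$width
    if (sum(plateau & in_hot) == 0 || sum(plateau & !in_hot) == 0) {
      stop(sprintf("chi = %.3g: no plateau region (system too small)", entry$chi))
    }
    obs <- Filter(Negate(is.null),
                  list(density = entry$density, phi_h = entry$phi_h,
                       msv = entry$msv))
    do.call(rbind, lapply(names(obs), function(nm) {
      v <- obs[[nm]]$value
      mk <- function(phase, sel) data.frame(
        chi = entry$chi, observable = nm, phase = phase,
        value = mean(v[sel], na.rm = TRUE),
        sd = sd(v[sel], na.rm = TRUE), n_slabs = sum(sel))
      rbind(mk("hot", plateau & in_hot), mk("cold", plateau & !in_hot))
    }))
  })
  do.call(rbind, rows)
}

#' Power-law fit of the binodal density difference
#'
#' Fits \code{delta_rho = A (chi - chi*)^beta} by weighted least squares in
#' log-log space. Any subset of the parameters may be fixed (the three fit
#' variants used for binodal data: all free; \code{beta = 1/2}; or
#' \code{chi*} pinned to an independent estimate).
#'
#' @param chi asymmetry values.
#' @param delta_rho binodal density differences (1/sigma^3), positive.
#' @param err optional standard errors of \code{delta_rho}.
#' @param fix named list fixing any of \code{A}, \code{chi_star},
#'   \code{beta}.
#' @return An object of class \code{power_law_fit} with elements \code{A},
#'   \code{chi_star}, \code{beta}, \code{fixed}, \code{cov} (covariance of
#'   the free parameters, in the order (log A, chi_star, beta) restricted to
#'   the free ones) and \code{rss}.
#' @export
power_law_fit <- function(chi, delta_rho, err = NULL, fix = list()) {
  stopifnot(length(chi) == length(delta_rho), all(delta_rho > 0))
  bad <- setdiff(names(fix), c("A", "chi_star", "beta"))
  if (length(bad)) stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
  n <- length(chi)
  yl <- log(delta_rho)
  w <- if (!is.null(err)) (delta_rho / err)^2 else rep(1, n) # var(log y) = (err/y)^2
  n_free <- 3 - length(fix)
  if (n - n_free < 1) stop("not enough points for the requested free parameters")

  # profile (log A, beta) at fixed chi_star; returns list(rss, logA, beta)
  prof <- function(cs) {
    if (any(chi <= cs)) return(list(rss = Inf))
    x <- log(chi - cs)
    if (!is.null(fix$beta) && !is.null(fix$A)) {
      r <- yl - log(fix$A) - fix$beta * x
      return(list(rss = sum(w * r^2), logA = log(fix$A), beta = fix$beta))
    }
    if (!is.null(fix$beta)) {
      la <- weighted.mean(yl - fix$beta * x, w)
      r <- yl - la - fix$beta * x
      return(list(rss = sum(w * r^2), logA = la, beta = fix$beta))
    }
    if (!is.null(fix$A)) {
      b <- sum(w * (yl - log(fix$A)) * x) / sum(w * x^2)
      r <- yl - log(fix$A) - b * x
      return(list(rss = sum(w * r^2), logA = log(fix$A), beta = b))
    }
    xm <- weighted.mean(x, w); ym <- weighted.mean(yl, w)
    b <- sum(w * (x - xm) * (yl - ym)) / sum(w * (x - xm)^2)
    la <- ym - b * xm
    r <- yl - la - b * x
    list(rss = sum(w * r^2), logA = la, beta = b)
  }

  if (!is.null(fix$chi_star)) {
    cs <- fix$chi_star
    if (any(chi <= cs)) stop("support violation: all chi must exceed chi_star")
    sol <- prof(cs)
  } else {
    # chi = (Theff - Tceff)/Tceff is nonnegative by construction, so the
    # critical point is searched on [0, min(chi)); without the bound the
    # offset-power-law fit is ill-conditioned (chi* -> -Inf trades against
    # beta)
    lo <- if (min(chi) > 0) 0 else min(chi) - diff(range(chi)) - 1
    hi <- min(chi) - 1e-10
    opt <- optimize(function(cs) prof(cs)$rss, c(lo, hi), tol = 1e-12)
    cs <- opt$minimum
    sol <- prof(cs)
  }

  free <- c(logA = is.null(fix$A), chi_star = is.null(fix$chi_star),
            beta = is.null(fix$beta))
  par0 <- c(logA = sol$logA, chi_star = cs, beta = sol$beta)
  covm <- matrix(NA_real_, sum(free), sum(free),
                 dimnames = list(names(par0)[free], names(par0)[free]))
  if (sum(free) > 0 && n > sum(free)) {
    obj <- function(p) {
      full <- par0
      full[free] <- p
      if (any(chi <= full["chi_star"])) return(1e12)
      x <- log(chi - full["chi_star"])
      sum(w * (yl - full["logA"] - full["beta"] * x)^2)
    }
    h <- tryCatch(stats::optimHess(par0[free], obj), error = function(e) NULL)
    if (!is.null(h)) {
      s2 <- sol$rss / max(1, n - sum(free))
      covm <- tryCatch(2 * s2 * solve(h), error = function(e) covm)
    }
  }
  structure(list(A = exp(sol$logA), chi_star = cs, beta = sol$beta,
                 fixed = fix, cov = covm, rss = sol$rss, n = n),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  fx <- function(nm) if (!is.null(x$fixed[[nm]])) " (fixed)" else ""
  cat(sprintf("delta_rho = A (chi - chi*)^beta\n  A = %.4g%s  chi* = %.4g%s  beta = %.4g%s  (n = %d, rss = %.3g)\n",
              x$A, fx("A"), x$chi_star, fx("chi_star"), x$beta, fx("beta"),
              x$n, x$rss))
  invisible(x)
}
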