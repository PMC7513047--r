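#' Interface height field on a block grid
#'
#' @param h nB x nB matrix of interface heights (sigma) on blocks centered
#'   at ((i-1/2) Lx/nB, (j-1/2) Ly/nB).
#' @param L lateral box lengths, length 2 (or scalar for a square box).
#' @param interface "lower" or "upper".
#' @param time snapshot time (tau).
#' @return An object of class \code{height_field}.
#' @export
height_field <- function(h, L, interface = "lower", time = NA_real_) {
  h <- as.matrix(h)
  stopifnot(nrow(h) == ncol(h), all(is.finite(h)))
  if (length(L) == 1) L <- c(L, L)
  structure(list(h = h, nB = nrow(h), L = as.numeric(L[1:2]),
                 interface = interface, time = time),
            class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  cat(sprintf("height_field: %s interface, %d x %d blocks, mean %.3f sigma, w^2 = %.4f sigma^2\n",
              x$interface, x$nB, x$nB, mean(x$h),
              mean(x$h^2) - mean(x$h)^2))
  invisible(x)
}

# mode table for an nB grid: unique half-plane (n, m), Nyquist-free
# (|n|, |m| <= floor((nB-1)/2)); representatives have n > 0, or n == 0 & m > 0
mode_table <- function(nB, L) {
  K <- (nB - 1) %/% 2
  nm <- expand.grid(n = -K:K, m = -K:K)
  nm <- nm[nm$n > 0 | (nm$n == 0 & nm$m > 0), ]
  nm$qx <- 2 * pi * nm$n / L[1]
  nm$qy <- 2 * pi * nm$m / L[2]
  nm$q <- sqrt(nm$qx^2 + nm$qy^2)
  nm[order(nm$q, nm$n, nm$m), ]
}

#' Fourier amplitudes of a height field
#'
#' Expands \code{h(x, y) = <h> + sum A cos(q r) + B sin(q r)} over the
#' unique (half-plane) modes resolvable on the block grid, excluding the
#' zero mode and the grid Nyquist row/column, with \code{q_nm = 2 pi (n, m)
#' / L}. \code{C^2 = (A^2 + B^2) / 2}; for band-limited fields the mode sum
#' satisfies Parseval exactly: \code{sum C^2} equals the spatial variance of
#' \code{h}.
#'
#' @param hf a \code{\link{height_field}}.
#' @return data.frame with columns \code{n}, \code{m}, \code{q}, \code{A},
#'   \code{B}, \code{C2}; attributes \code{mean_height}, \code{nB},
#'   \code{L}.
#' @export
fourier_amplitudes <- function(hf) {
  nB <- hf$nB
  L <- hf$L
  tab <- mode_table(nB, L)
  xs <- (seq_len(nB) - 0.5) * L[1] / nB
  ys <- (seq_len(nB) - 0.5) * L[2] / nB
  h <- hf$h - mean(hf$h)
  # M_nm = sum_jk h_jk exp(-i (qx x_j + qy y_k)) computed separably
  nuniq <- sort(unique(tab$n))
  muniq <- sort(unique(tab$m))
  Ex <- exp(-1i * outer(xs, 2 * pi * nuniq / L[1]))  # nB x |n|
  Ey <- exp(-1i * outer(ys, 2 * pi * muniq / L[2]))
  M <- t(Ex) %*% h %*% Ey                            # |n| x |m|
  ni <- match(tab$n, nuniq)
  mi <- match(tab$m, muniq)
  Mv <- M[cbind(ni, mi)]
  A <- 2 / nB^2 * Re(Mv)
  B <- -2 / nB^2 * Im(Mv)
  out <- data.frame(n = tab$n, m = tab$m, q = tab$q,
                    A = A, B = B, C2 = (A^2 + B^2) / 2)
  attr(out, "mean_height") <- mean(hf$h)
  attr(out, "nB") <- nB
  attr(out, "L") <- L
  out
}

#' Extract interface heights on a block grid
#'
#' For an aligned separated snapshot (hot phase centered in z), the lateral
#' plane is divided into \code{nB x nB} blocks; within each block the
#' z-profile of the signed species count \code{m(z)} (+1 hot, -1 cold) is
#' histogrammed at \code{nslab} resolution. The interface height is the sign
#' change of \code{m(z)} located by the extremum of its cumulative sum (a
#' CUSUM changepoint) — the zero crossing that maximizes the segregated
#' species mass on either side, which stays well defined for sparse block
#' columns. The two interfaces (periodic boundaries) are resolved by
#' splitting the box at the hot-phase center; blocks whose crossing signal
#' does not exceed the counting-noise scale are rejected.
#'
#' @param state an aligned \code{\link{system_state}}.
#' @param nB blocks per lateral direction.
#' @param nslab z-histogram resolution per block.
#' @param max_rejected maximum tolerated fraction of rejected blocks before
#'   the whole snapshot is rejected.
#' @return list of two \code{\link{height_field}}s (lower, upper).
#' @export
interface_heights <- function(state, nB, nslab = 64, max_rejected = 0.2) {
  L <- as.numeric(state$box)
  Lz <- L[3]
  dz <- Lz / nslab
  if (frame_contrast(state, 3) < 0.15) {
    stop("no interface in the species-difference profile (mixed state?)")
  }
  sgn <- ifelse(state$species == SPECIES_HOT, 1, -1)
  zbin <- pmin.int(floor(state$pos[, 3] / dz) + 1L, nslab)
  mid <- nslab %/% 2

  # CUSUM heights within one block column: the lower interface minimizes the
  # running sum of m below the box center, the upper maximizes it above
  cusum_heights <- function(m, n_half_lo, n_half_hi) {
    Flo <- cumsum(m[seq_len(mid)])
    klo <- which.min(Flo)
    depth_lo <- min(-Flo[klo], Flo[mid] - Flo[klo])
    Fhi <- cumsum(m[seq(mid + 1, nslab)])
    khi <- which.max(Fhi)
    depth_hi <- min(Fhi[khi], Fhi[khi] - Fhi[length(Fhi)])
    out <- c(NA_real_, NA_real_)
    # null (mixed) CUSUM drift scales as sqrt(count); demand twice that
    if (depth_lo > 2 * sqrt(max(1, n_half_lo))) out[1] <- klo * dz
    if (depth_hi > 2 * sqrt(max(1, n_half_hi))) out[2] <- (mid + khi) * dz
    out
  }

  bx <- pmin.int(floor(state$pos[, 1] / L[1] * nB) + 1L, nB)
  by <- pmin.int(floor(state$pos[, 2] / L[2] * nB) + 1L, nB)
  block <- bx + nB * (by - 1L)
  hlow <- matrix(NA_real_, nB, nB)
  hupp <- matrix(NA_real_, nB, nB)
  for (b in seq_len(nB^2)) {
    sel <- which(block == b)
    if (length(sel) == 0) next
    m <- vapply(seq_len(nslab), function(k) sum(sgn[sel][zbin[sel] == k]), 0)
    lo_n <- sum(zbin[sel] <= mid)
    hh <- cusum_heights(m, lo_n, length(sel) - lo_n)
    i <- ((b - 1L) %% nB) + 1L
    j <- ((b - 1L) %/% nB) + 1L
    hlow[i, j] <- hh[1]
    hupp[i, j] <- hh[2]
  }
  nrej <- sum(is.na(hlow)) + sum(is.na(hupp))
  if (nrej > max_rejected * 2 * nB^2) {
    stop(sprintf("snapshot rejected at nB = %d: %d of %d blocks without a resolvable crossing",
                 nB, nrej, 2 * nB^2))
  }
  # isolated missing blocks inherit the interface mean
  hlow[is.na(hlow)] <- mean(hlow, na.rm = TRUE)
  hupp[is.na(hupp)] <- mean(hupp, na.rm = TRUE)
  list(lower = height_field(hlow, L[1:2], "lower", state$time),
       upper = height_field(hupp, L[1:2], "upper", state$time))
}

#' Ensemble-averaged capillary spectrum
#'
#' Accumulates \code{<C^2>} over snapshots and both interfaces, binned by
#' wavevector magnitude. Snapshots should be separated by more than the
#' correlation time of the slowest mode (see
#' \code{\link{mode_autocorrelation}}).
#'
#' @param x a \code{\link{trajectory}} of aligned separated states, or a
#'   list of \code{\link{height_field}}s.
#' @param nB blocks per lateral direction (ignored when height fields are
#'   supplied).
#' @param nslab z resolution passed to \code{\link{interface_heights}}.
#' @param spacing minimum time between used snapshots (tau); frames closer
#'   than this to the previously used one are skipped (decorrelation).
#' @param min_snapshots minimum number of usable snapshots.
#' @return An object of class \code{capillary_spectrum}: a data.frame with
#'   \code{q}, \code{C2}, \code{err} (standard error over samples) and
#'   \code{n_modes}; attributes \code{L}, \code{nB}, \code{n_samples}.
#' @export
spectrum_accumulate <- function(x, nB = 16, nslab = 64, spacing = NULL,
                                min_snapshots = 10) {
  if (inherits(x, "trajectory")) {
    frames <- x$frames
    if (!is.null(spacing)) {
      times <- vapply(frames, `[[`, numeric(1), "time")
      keep <- logical(length(frames))
      last <- -Inf
      for (k in seq_along(times)) {
        if (times[k] - last >= spacing) {
          keep[k] <- TRUE
          last <- times[k]
        }
      }
      frames <- frames[keep]
    }
    fields <- list()
    dropped <- 0L
    for (st in frames) {
      hf <- tryCatch(interface_heights(st, nB, nslab), error = function(e) NULL)
      if (is.null(hf)) { dropped <- dropped + 1L; next }
      fields <- c(fields, hf)
    }
    if (dropped > 0) {
      warning(sprintf("dropped %d snapshot(s) without usable height fields", dropped))
    }
    nsnap <- length(fields) / 2
  } else {
    fields <- x
    nsnap <- length(fields)
  }
  if (length(fields) == 0 || nsnap < min_snapshots) {
    stop(sprintf("need at least %d usable snapshots (have %g)",
                 min_snapshots, nsnap))
  }
  amps <- lapply(fields, fourier_amplitudes)
  qs <- amps[[1]]$q
  c2 <- vapply(amps, `[[`, numeric(length(qs)), "C2")
  if (is.null(dim(c2))) c2 <- matrix(c2, nrow = length(qs))
  qr <- round(qs, 9)
  ubins <- sort(unique(qr))
  val <- err <- nm <- numeric(length(ubins))
  for (i in seq_along(ubins)) {
    sel <- qr == ubins[i]
    samples <- colMeans(c2[sel, , drop = FALSE]) # per-snapshot bin average
    val[i] <- mean(samples)
    err[i] <- if (length(samples) > 1) sd(samples) / sqrt(length(samples)) else NA_real_
    nm[i] <- sum(sel)
  }
  structure(data.frame(q = ubins, C2 = val, err = err, n_modes = nm),
            L = attr(amps[[1]], "L"), nB = attr(amps[[1]], "nB"),
            n_samples = length(fields),
            class = c("capillary_spectrum", "data.frame"))
}

#' @export
print.capillary_spectrum <- function(x, ...) {
  cat(sprintf("capillary spectrum: nB = %d, %d q-bins, %d interface samples\n",
              attr(x, "nB"), nrow(x), attr(x, "n_samples")))
  print.data.frame(head(as.data.frame(x), 5))
  invisible(x)
}

#' @export
plot.capillary_spectrum <- function(x, ...) {
  graphics::plot(x$q, x$C2, log = "xy", xlab = "q (1/sigma)",
                 ylab = expression(C^2), ...)
  invisible(x)
}

#' Interfacial stiffness from the capillary spectrum
#'
#' Weighted fit of the single prefactor in \code{<C^2> = 2 / (gamma_beta L^2
#' q^2)}. When several spectra (different block counts) are supplied the
#' estimate is their mean and the spread is reported.
#'
#' @param spec a \code{capillary_spectrum} or list of them.
#' @param exclude_slowest drop the smallest-q (slowest) modes from the fit,
#'   to guard against their long correlation times.
#' @return An object of class \code{stiffness_estimate} with
#'   \code{gamma_beta} (1/sigma^2), \code{uncertainty}, \code{method},
#'   \code{nB}.
#' @export
stiffness_from_spectrum <- function(spec, exclude_slowest = FALSE) {
  specs <- if (inherits(spec, "capillary_spectrum")) list(spec) else spec
  fits <- vapply(specs, function(sp) {
    L <- attr(sp, "L")
    d <- as.data.frame(sp)
    if (exclude_slowest) d <- d[d$q > min(d$q), ]
    if (nrow(d) < 5) stop("need at least 5 modes to fit the spectrum")
    t <- 2 / (L[1] * L[2] * d$q^2)
    w <- ifelse(is.finite(d$err) & d$err > 0, 1 / d$err^2, 1)
    inv_gb <- sum(w * t * d$C2) / sum(w * t^2) # C2 = t / gamma_beta
    1 / inv_gb
  }, 0)
  gb <- mean(fits)
  unc <- if (length(fits) > 1) sd(fits) else {
    # single spectrum: propagate the WLS prefactor error
    sp <- specs[[1]]
    L <- attr(sp, "L")
    d <- as.data.frame(sp)
    if (exclude_slowest) d <- d[d$q > min(d$q), ]
    t <- 2 / (L[1] * L[2] * d$q^2)
    w <- ifelse(is.finite(d$err) & d$err > 0, 1 / d$err^2, 1)
    r <- d$C2 - t / gb
    s2 <- sum(w * r^2) / max(1, nrow(d) - 1)
    se_inv <- sqrt(s2 / sum(w * t^2))
    gb^2 * se_inv
  }
  if (gb <= 0) {
    warning("nonpositive fitted stiffness (sub-critical or unseparated input)")
  }
  structure(list(gamma_beta = gb, uncertainty = unc, method = "spectrum",
                 nB = vapply(specs, function(sp) attr(sp, "nB"), 0),
                 per_nB = fits, excluded_slowest = exclude_slowest),
            class = "stiffness_estimate")
}

#' @export
print.stiffness_estimate <- function(x, ...) {
  cat(sprintf("interfacial stiffness gamma*beta = %.4f +/- %.4f (1/sigma^2, %s method, nB = %s)\n",
              x$gamma_beta, x$uncertainty, x$method,
              paste(x$nB, collapse = ",")))
  invisible(x)
}

#' Autocorrelation and correlation time of a capillary mode
#'
#' Normalized autocovariance \code{c(t)} of a mode-amplitude series at
#' uniform snapshot spacing; \code{c(0) = 1} by construction. The
#' correlation time comes from a log-linear least-squares fit through the
#' origin of \code{exp(-t / tau_c)}, restricted to lags before the first
#' nonpositive excursion with \code{c(t)} above \code{fit_floor}: the
#' logarithm amplifies sampling noise once the autocorrelation is small, so
#' the default floor of 0.2 keeps the fit in the well-determined regime.
#'
#' @param x numeric series of mode amplitudes (e.g. \code{C_01} per
#'   snapshot), or a list of \code{\link{height_field}}s from which the
#'   (0,1) mode amplitude is extracted.
#' @param spacing time between snapshots (tau).
#' @param mode mode indices used when height fields are supplied.
#' @param fit_floor smallest autocorrelation value admitted to the
#'   correlation-time fit.
#' @return An object of class \code{mode_autocorrelation}: data.frame
#'   \code{lag}, \code{c}; attribute/element \code{tau_c}.
#' @export
mode_autocorrelation <- function(x, spacing, mode = c(0, 1),
                                 fit_floor = 0.2) {
  if (is.list(x) && inherits(x[[1]], "height_field")) {
    x <- vapply(x, function(hf) {
      a <- fourier_amplitudes(hf)
      sel <- a$n == mode[1] & a$m == mode[2]
      if (!any(sel)) stop("requested mode not resolvable on this grid")
      sqrt(a$C2[sel])
    }, 0)
  }
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) stop("series too short")
  if (var(x) == 0) stop("zero variance series: autocorrelation undefined")
  nlag <- min(n - 2, max(10, n %/% 3))
  ac <- acf(x, lag.max = nlag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lags <- (0:nlag) * spacing
  firstneg <- which(ac <= 0)
  cutoff <- if (length(firstneg) > 0) firstneg[1] - 1 else nlag + 1
  use <- which(seq_along(ac) <= cutoff & ac > fit_floor)
  use <- use[use > 1] # positive lags only; c(0)=1 anchors the origin
  tau_c <- if (length(use) == 0) {
    spacing / 2 # decorrelated below the snapshot spacing
  } else {
    -1 / sum(lags[use] * log(ac[use])) * sum(lags[use]^2) # LS through origin
  }
  structure(list(lag = lags, c = ac, tau_c = tau_c, spacing = spacing),
            class = "mode_autocorrelation")
}

#' @export
print.mode_autocorrelation <- function(x, ...) {
  cat(sprintf("mode autocorrelation: tau_c = %.4g tau (spacing %g tau, %d lags)\n",
              x$tau_c, x$spacing, length(x$lag) - 1))
  invisible(x)
}

#' Apparent interface width versus block count
#'
#' The mean square apparent width \code{w^2(nB)} is the variance of the
#' block heights, computed per snapshot and interface and then averaged.
#' Block coarse-graining filters modes above \code{2 pi nB / L}, so
#' \code{w^2} grows logarithmically: \code{w^2 = ln(nB / c) / (2 pi
#' gamma_beta)}. The two-parameter fit (\code{c}, \code{gamma_beta}) uses
#' the log-linear regime, by default \code{nB} in [5, 9].
#'
#' @param x a \code{\link{trajectory}} of aligned separated states, or a
#'   function \code{(nB) -> list of height_field} (e.g. a synthetic
#'   generator), or a named list of height-field lists keyed by nB.
#' @param nB_list integer vector of block counts.
#' @param fit_range numeric length 2, the nB range used in the fit.
#' @param nslab z resolution for height extraction from trajectories.
#' @return An object of class \code{width_scaling}: data.frame \code{nB},
#'   \code{w2}, \code{err}; elements \code{gamma_beta}, \code{c_cut}.
#' @export
width_vs_blocks <- function(x, nB_list, fit_range = c(5, 9), nslab = 64) {
  nB_list <- sort(as.integer(nB_list))
  get_fields <- function(nB) {
    if (inherits(x, "trajectory")) {
      fields <- list()
      for (st in x$frames) {
        hf <- tryCatch(interface_heights(st, nB, nslab), error = function(e) NULL)
        if (!is.null(hf)) fields <- c(fields, hf)
      }
      fields
    } else if (is.function(x)) {
      x(nB)
    } else {
      x[[as.character(nB)]]
    }
  }
  w2 <- err <- numeric(length(nB_list))
  for (i in seq_along(nB_list)) {
    fields <- get_fields(nB_list[i])
    if (length(fields) == 0) {
      stop(sprintf("no usable height fields at nB = %d", nB_list[i]))
    }
    samples <- vapply(fields, function(hf) mean(hf$h^2) - mean(hf$h)^2, 0)
    w2[i] <- mean(samples)
    err[i] <- if (length(samples) > 1) sd(samples) / sqrt(length(samples)) else NA_real_
  }
  in_fit <- nB_list >= fit_range[1] & nB_list <= fit_range[2]
  if (sum(in_fit) < 3) stop("fewer than 3 nB values inside the fit range")
  fit <- lm(w2[in_fit] ~ log(nB_list[in_fit]))
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  structure(list(table = data.frame(nB = nB_list, w2 = w2, err = err),
                 gamma_beta = 1 / (2 * pi * slope),
                 c_cut = exp(-intercept / slope),
                 fit_range = fit_range, slope = slope),
            class = "width_scaling")
}

#' @export
print.width_scaling <- function(x, ...) {
  cat(sprintf("width scaling: gamma*beta = %.4f / sigma^2, c = %.3g (fit nB in [%g, %g])\n",
              x$gamma_beta, x$c_cut, x$fit_range[1], x$fit_range[2]))
  print.data.frame(x$table)
  invisible(x)
}

#' Critical asymmetry from the stiffness trend
#'
#' The interfacial stiffness scales linearly with \code{sqrt(chi)}; its root
#' \code{gamma_beta(chi*) = 0} gives another critical-asymmetry estimate.
#' Weighted linear fit of \code{gamma_beta} on \code{sqrt(chi)}; the root is
#' squared back and its uncertainty propagated to first order.
#'
#' @param chi asymmetry values (>= 3).
#' @param gamma_beta stiffness estimates at each chi (1/sigma^2).
#' @param err optional standard errors of \code{gamma_beta}.
#' @return list with \code{chi_star}, \code{uncertainty}, \code{slope},
#'   \code{intercept}.
#' @export
chi_star_from_stiffness <- function(chi, gamma_beta, err = NULL) {
  stopifnot(length(chi) == length(gamma_beta), length(chi) >= 2)
  s <- sqrt(chi)
  w <- if (!is.null(err)) 1 / err^2 else rep(1, length(chi))
  sm <- weighted.mean(s, w); gm <- weighted.mean(gamma_beta, w)
  sxx <- sum(w * (s - sm)^2)
  b <- sum(w * (s - sm) * (gamma_beta - gm)) / sxx
  a <- gm - b * sm
  if (b <= 0) stop("negative or zero slope: stiffness does not grow with sqrt(chi)")
  root <- -a / b
  cs <- root^2
  n <- length(chi)
  dof <- max(1, n - 2)
  r <- gamma_beta - (a + b * s)
  s2 <- sum(w * r^2) / dof
  var_a <- s2 * (1 / sum(w) + sm^2 / sxx)
  var_b <- s2 / sxx
  cov_ab <- -s2 * sm / sxx
  # delta method on chi* = (a/b)^2
  da <- -2 * root / b
  db <- 2 * root * a / b^2
  var_cs <- da^2 * var_a + db^2 * var_b + 2 * da * db * cov_ab
  list(chi_star = cs, uncertainty = sqrt(max(0, var_cs)),
       slope = b, intercept = a)
}

#' Scaled interfacial width table
#'
#' At large asymmetry the width shrinks as \code{w ~ chi^(-1/2)}, so the
#' product \code{w sqrt(chi)} flattens. This reports the product per block
#' count; flatness is a property to inspect, not a fit.
#'
#' @param widths data.frame with columns \code{chi}, \code{nB}, \code{w}
#'   (width, sigma).
#' @return the same table with \code{w_chi_half = w * sqrt(chi)} appended.
#' @export
width_chi_scaling <- function(widths) {
  stopifnot(all(c("chi", "nB", "w") %in% names(widths)))
  widths$w_chi_half <- widths$w * sqrt(widths$chi)
  widths
}
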