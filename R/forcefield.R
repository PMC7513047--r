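#' Kremer-Grest force field parameters
#'
#' Purely repulsive shifted-truncated Lennard-Jones (WCA) pair interaction
#' cut at \code{rc = 2^(1/6) sigma}, plus FENE bonds between consecutive
#' monomers of a chain. Defaults are the standard bead-spring melt values
#' \code{K = 30 epsilon/sigma^2} and \code{rmax = 1.5 sigma}.
#'
#' @param epsilon LJ energy scale (epsilon).
#' @param sigma LJ length scale (sigma).
#' @param K FENE spring constant (epsilon/sigma^2).
#' @param rmax FENE maximum bond extension (sigma).
#' @return An object of class \code{force_field}.
#' @export
force_field <- function(epsilon = 1, sigma = 1, K = 30, rmax = 1.5) {
  stopifnot(epsilon > 0, sigma > 0, K > 0, rmax > sigma)
  structure(
    list(epsilon = epsilon, sigma = sigma, rc = 2^(1 / 6) * sigma,
         K = K, rmax = rmax),
    class = "force_field"
  )
}

#' @export
print.force_field <- function(x, ...) {
  cat("WCA + FENE force field (reduced LJ units)\n")
  cat(sprintf("  epsilon = %g, sigma = %g, rc = 2^(1/6) sigma = %.6f\n",
              x$epsilon, x$sigma, x$rc))
  cat(sprintf("  FENE: K = %g epsilon/sigma^2, rmax = %g sigma\n", x$K, x$rmax))
  invisible(x)
}

#' Pair of species-specific Langevin thermostats
#'
#' Hot chains couple to temperature \code{Th}, cold chains to \code{Tc},
#' both with the same friction \code{zeta}.
#'
#' @param Tc cold thermostat temperature (epsilon).
#' @param Th hot thermostat temperature (epsilon), \code{Th >= Tc}.
#' @param zeta coupling friction (1/tau).
#' @return An object of class \code{thermostat_pair}.
#' @export
thermostat_pair <- function(Tc = 1, Th = Tc, zeta = 1.5) {
  stopifnot(Tc > 0, Th >= Tc, zeta >= 0)
  structure(list(Tc = Tc, Th = Th, zeta = zeta), class = "thermostat_pair")
}

#' @export
print.thermostat_pair <- function(x, ...) {
  cat(sprintf("Langevin thermostat pair: Tc = %g, Th = %g, zeta = %g/tau\n",
              x$Tc, x$Th, x$zeta))
  invisible(x)
}

#' Integrator configuration
#'
#' @param dt time step (tau); the melt default is 0.005 tau.
#' @param seed integer RNG seed, or NULL to use the current RNG state.
#' @param mass particle mass (fixed at 1 in reduced units).
#' @return An object of class \code{integrator_config}.
#' @export
integrator_config <- function(dt = 0.005, seed = NULL, mass = 1) {
  stopifnot(dt > 0, identical(mass, 1) || mass == 1)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(dt = dt, seed = seed, mass = 1), class = "integrator_config")
}

#' Periodic simulation box
#'
#' @param lengths numeric vector of 3 box lengths (sigma); all sides periodic.
#' @return An object of class \code{sim_box} (numeric length 3).
#' @export
sim_box <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 1) lengths <- rep(lengths, 3)
  stopifnot(length(lengths) == 3, all(lengths > 0))
  structure(lengths, class = "sim_box")
}

#' WCA pair energy and force
#'
#' Shifted truncated Lennard-Jones: for \code{r < rc},
#' \code{U = 4 eps ((s/r)^12 - (s/r)^6) + eps}; zero beyond the cutoff. The
#' shift makes both the potential and the force continuous at \code{rc}.
#'
#' @param r pair distance(s) (sigma), must be positive.
#' @param ff a \code{\link{force_field}}.
#' @return data.frame with columns \code{r}, \code{energy}, \code{force}
#'   (force is the magnitude -dU/dr, repulsive positive).
#' @export
wca_energy_force <- function(r, ff = force_field()) {
  if (any(r <= 0)) stop("particle overlap: pair distance must be positive")
  out <- t(vapply(r, function(ri) cpp_wca(ri, ff$epsilon, ff$sigma, ff$rc),
                  numeric(2)))
  data.frame(r = r, energy = out[, 1], force = out[, 2])
}

#' FENE bond energy and force
#'
#' \code{U = -K rmax^2 / 2 * log(1 - (r/rmax)^2)} for \code{0 <= r < rmax};
#' the bond force is attractive with magnitude \code{K r / (1 - (r/rmax)^2)}.
#' Lengths at or beyond \code{rmax} are an overstretch error.
#'
#' @inheritParams wca_energy_force
#' @return data.frame with columns \code{r}, \code{energy}, \code{force}
#'   (attractive magnitude, positive).
#' @export
fene_energy_force <- function(r, ff = force_field()) {
  out <- t(vapply(r, function(ri) cpp_fene(ri, ff$K, ff$rmax), numeric(2)))
  data.frame(r = r, energy = out[, 1], force = out[, 2])
}
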