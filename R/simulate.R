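#' Forces and potential energy of a configuration
#'
#' Assembles WCA pair forces (linked-cell neighbor search with minimum-image
#' convention) and FENE bond forces. Total force sums to zero and equals the
#' negative gradient of the total potential energy.
#'
#' @param state a \code{\link{system_state}}.
#' @param ff a \code{\link{force_field}}.
#' @return list with \code{forces} (Np x 3 matrix, epsilon/sigma) and
#'   \code{energy} (total potential energy, epsilon).
#' @export
compute_forces <- function(state, ff = force_field()) {
  cpp_forces(state$pos, chain_bonds(state$chain), as.numeric(state$box),
             ff$epsilon, ff$sigma, ff$rc, ff$K, ff$rmax)
}

#' Total energy (potential + kinetic) of a configuration
#'
#' @inheritParams compute_forces
#' @return list with \code{potential}, \code{kinetic} and \code{total}
#'   (epsilon).
#' @export
total_energy <- function(state, ff = force_field()) {
  pot <- cpp_potential_energy(state$pos, chain_bonds(state$chain),
                              as.numeric(state$box),
                              ff$epsilon, ff$sigma, ff$rc, ff$K, ff$rmax)
  kin <- 0.5 * sum(state$vel^2)
  list(potential = pot, kinetic = kin, total = pot + kin)
}

# target temperature per particle under the species-specific thermostats
particle_temperatures <- function(state, thermo) {
  ifelse(state$species == SPECIES_HOT, thermo$Th, thermo$Tc)
}

#' Advance the system by Langevin dynamics
#'
#' Gronbech-Jensen/Farago discretization of Langevin dynamics with the
#' per-particle target temperature set by the particle's species. With
#' \code{zeta = 0} the scheme reduces exactly to velocity Verlet (no noise,
#' no friction).
#'
#' @param state a \code{\link{system_state}}.
#' @param ff a \code{\link{force_field}}.
#' @param thermo a \code{\link{thermostat_pair}}.
#' @param cfg an \code{\link{integrator_config}}; if \code{cfg$seed} is not
#'   NULL the RNG is seeded before stepping.
#' @param nsteps number of time steps to take.
#' @return the advanced \code{system_state}.
#' @export
langevin_step <- function(state, ff = force_field(), thermo = thermostat_pair(),
                          cfg = integrator_config(), nsteps = 1L) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- cpp_run_langevin(state$pos, state$vel, particle_temperatures(state, thermo),
                          chain_bonds(state$chain), as.numeric(state$box),
                          ff$epsilon, ff$sigma, ff$rc, ff$K, ff$rmax,
                          thermo$zeta, cfg$dt, as.integer(nsteps), 0L)
  state$pos <- res$pos
  state$vel <- res$vel
  state$time <- state$time + nsteps * cfg$dt
  state
}

#' Prepare an equilibrated well-mixed melt
#'
#' Builds \code{M} fully flexible chains of \code{N} monomers at the target
#' number density: chains grown as random walks with bond length 0.97 sigma,
#' overlaps removed by a capped soft-potential push-off with a linearly
#' ramped prefactor, then Langevin equilibration with both thermostats at
#' \code{T = 1} (the mixed-state starting point for activity sweeps). Chains
#' with even index are labelled hot and odd ones cold, giving a reproducible
#' 50/50 split.
#'
#' @param M number of chains (even).
#' @param N monomers per chain.
#' @param density target number density (1/sigma^3); the melt value is 0.85.
#' @param box_aspect relative box edge ratios, length 3.
#' @param seed integer RNG seed.
#' @param ff a \code{\link{force_field}}.
#' @param zeta friction used for preparation (1/tau).
#' @param dt time step for preparation (tau).
#' @param pushoff_steps steps of the ramped soft push-off.
#' @param equil_time Langevin equilibration time at T = 1 (tau).
#' @return an equilibrated mixed \code{\link{system_state}} at T = 1.
#' @export
initialize_melt <- function(M, N = 40, density = 0.85, box_aspect = c(1, 1, 1),
                            seed = 1, ff = force_field(), zeta = 1.5,
                            dt = 0.005, pushoff_steps = 1000L,
                            equil_time = 50) {
  if (M %% 2 != 0) stop("M must be even (half the chains couple to each thermostat)")
  stopifnot(M >= 2, N >= 2, density > 0)
  set.seed(seed)
  np <- M * N
  vol <- np / density
  box_aspect <- box_aspect / prod(box_aspect)^(1 / 3)
  box <- sim_box(vol^(1 / 3) * box_aspect)
  if (ff$rmax >= min(box) / 2) {
    stop("density too high / box too small: rmax must be below half the smallest box length")
  }

  # random-walk chain growth, bond length 0.97 sigma
  b <- 0.97 * ff$sigma
  pos <- matrix(0, np, 3)
  for (m in seq_len(M)) {
    i0 <- (m - 1) * N
    pos[i0 + 1, ] <- runif(3) * as.numeric(box)
    u <- matrix(rnorm(3 * (N - 1)), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    steps <- u * b
    pos[i0 + seq(2, N), ] <- matrix(pos[i0 + 1, ], N - 1, 3, byrow = TRUE) +
      apply(steps, 2, cumsum)
  }
  chain <- rep(seq_len(M), each = N)
  species <- ifelse(rep(seq_len(M), each = N) %% 2 == 0, SPECIES_HOT, SPECIES_COLD)

  bonds <- chain_bonds(chain)
  for (k in 1:3) pos[, k] <- pos[, k] %% box[k]

  # push-off: capped soft repulsion ramped to full strength, Langevin at T=1;
  # repeated until no pair remains below 0.9 sigma
  push <- cpp_pushoff(pos, bonds, as.numeric(box), ff$rc, 60 * ff$epsilon,
                      ff$K, ff$rmax, 1.0, zeta, dt, as.integer(pushoff_steps))
  for (round in 2:12) { # escalate the cap until hard-core distances are safe
    if (cpp_min_pair_distance(push$pos, as.numeric(box), ff$rc) >= 0.9 * ff$sigma) break
    push <- cpp_pushoff(push$pos, bonds, as.numeric(box), ff$rc,
                        60 * round * ff$epsilon,
                        ff$K, ff$rmax, 1.0, zeta, dt, as.integer(pushoff_steps))
  }
  if (cpp_min_pair_distance(push$pos, as.numeric(box), ff$rc) < 0.9 * ff$sigma) {
    stop("density too high: push-off could not separate all particle pairs")
  }
  st <- system_state(push$pos, push$vel, species, chain, box, time = 0)

  # equilibrate the mixed melt with both thermostats at T = 1
  st <- langevin_step(st, ff, thermostat_pair(Tc = 1, Th = 1, zeta = zeta),
                      integrator_config(dt = dt),
                      nsteps = max(1L, as.integer(round(equil_time / dt))))
  st$time <- 0
  validate_state(st, ff)
  st
}

#' Run the two-temperature steady-state production
#'
#' Advances the system with the species-specific Langevin thermostats and
#' collects snapshots every \code{sample_interval} tau. Trajectories are
#' deterministic given \code{cfg$seed}. If the integration becomes unstable
#' (bond overstretch), the run aborts with a warning and returns the
#' snapshots collected so far.
#'
#' @inheritParams langevin_step
#' @param duration total simulated time (tau).
#' @param sample_interval snapshot cadence (tau).
#' @param include_initial store the starting state as the first frame.
#' @param verbose log one line per sampled frame.
#' @return a \code{\link{trajectory}} object.
#' @export
run_steady_state <- function(state, ff = force_field(), thermo = thermostat_pair(),
                             cfg = integrator_config(), duration,
                             sample_interval, include_initial = FALSE,
                             verbose = FALSE) {
  stopifnot(duration >= sample_interval, sample_interval > 0)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  steps_per_sample <- as.integer(round(sample_interval / cfg$dt))
  nsamples <- floor(duration / sample_interval)
  frames <- vector("list", nsamples + include_initial)
  if (include_initial) frames[[1]] <- state
  temp <- particle_temperatures(state, thermo)
  bonds <- chain_bonds(state$chain)
  kept <- as.integer(include_initial)
  t0 <- state$time
  for (s in seq_len(nsamples)) {
    res <- tryCatch(
      cpp_run_langevin(state$pos, state$vel, temp, bonds, as.numeric(state$box),
                       ff$epsilon, ff$sigma, ff$rc, ff$K, ff$rmax,
                       thermo$zeta, cfg$dt, steps_per_sample, 0L),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("integration unstable at t = %g tau (%s); returning %d frames",
                      state$time, conditionMessage(res), kept))
      break
    }
    state$pos <- res$pos
    state$vel <- res$vel
    state$time <- t0 + s * sample_interval
    kept <- kept + 1L
    frames[[kept]] <- state
    if (verbose) {
      message(sprintf("[sample] t = %g tau  Theff = %.3f  Tceff = %.3f",
                      state$time, kinetic_temperature(state, "hot"),
                      kinetic_temperature(state, "cold")))
    }
  }
  trajectory(frames[seq_len(kept)], thermo = thermo, ff = ff)
}
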