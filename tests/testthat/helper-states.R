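# shared builders for synthetic states used across test files

# uniform ideal-gas-like state: random positions, Maxwell velocities at `temp`,
# every particle its own single-monomer chain (no bonds)
make_uniform_state <- function(np, box, temp = 1, species = NULL, seed = 1) {
  set.seed(seed)
  box <- activeblend::sim_box(box)
  pos <- cbind(runif(np) * box[1], runif(np) * box[2], runif(np) * box[3])
  vel <- matrix(rnorm(3 * np, sd = sqrt(temp)), np, 3)
  if (is.null(species)) species <- rep(c("hot", "cold"), length.out = np)
  activeblend::system_state(pos, vel, species, chain = seq_len(np), box = box)
}

# jittered-grid configuration with safe pair distances; when bonded, each
# x-row of the grid forms one chain (bond lengths stay near `spacing`)
make_grid_state <- function(n_side = 3, spacing = 1.3, jitter = 0.05,
                            bonded = FALSE, temp = 1, seed = 1) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(n_side), y = seq_len(n_side), z = seq_len(n_side))
  pos <- as.matrix(g) * spacing - spacing / 2 +
    matrix(runif(3 * nrow(g), -jitter, jitter), nrow(g), 3)
  np <- nrow(pos)
  L <- n_side * spacing
  chain <- if (bonded) rep(seq_len(np %/% n_side), each = n_side) else seq_len(np)
  species <- ifelse(chain %% 2 == 0, "hot", "cold")
  vel <- matrix(rnorm(3 * np, sd = sqrt(temp)), np, 3)
  activeblend::system_state(pos, vel, species, chain, box = rep(L, 3))
}

# memoized small equilibrated melts (preparing one takes a second or two)
.melt_cache <- new.env(parent = emptyenv())
cached_melt <- function(M, N, seed = 5, ...) {
  key <- paste(M, N, seed, sep = "_")
  if (is.null(.melt_cache[[key]])) {
    .melt_cache[[key]] <- activeblend::initialize_melt(
      M = M, N = N, density = 0.85, seed = seed,
      pushoff_steps = 500, equil_time = 10, ...)
  }
  .melt_cache[[key]]
}

# standard two-phase fixture: pure phases, sharp interfaces at Lz/4, 3Lz/4
sharp_two_phase <- function(box = c(12, 12, 24), rho_hot = 0.8, rho_cold = 0.9,
                            T_hot = 2.6, T_cold = 1.2, ...) {
  activeblend::two_phase_spec(box = box, rho_hot_phase = rho_hot,
                              rho_cold_phase = rho_cold,
                              T_hot = T_hot, T_cold = T_cold, ...)
}

# scaled-down two-temperature demonstration run (M = 64 chains of N = 40 at
# Th = 3, zeta = 1.5), shared by the acceptance blocks; computed once
.demo_cache <- new.env(parent = emptyenv())
demo_trajectory_state <- function() {
  if (is.null(.demo_cache$state)) {
    .demo_cache$state <- activeblend::initialize_melt(
      M = 64, N = 40, density = 0.85, box_aspect = c(1, 1, 2), seed = 73,
      pushoff_steps = 1000, equil_time = 50)
  }
  .demo_cache$state
}
demo_trajectory <- function() {
  if (is.null(.demo_cache$traj)) {
    .demo_cache$traj <- activeblend::run_steady_state(
      demo_trajectory_state(),
      thermo = activeblend::thermostat_pair(Tc = 1, Th = 3, zeta = 1.5),
      cfg = activeblend::integrator_config(dt = 0.005, seed = 74),
      duration = 2000, sample_interval = 100)
  }
  .demo_cache$traj
}
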