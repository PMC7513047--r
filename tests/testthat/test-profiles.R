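test_that("snapshot alignment restores a known periodic shift", {
  circ_diff <- function(a, b, L) {
    d <- abs(a - b) %% L
    pmin(d, L - d)
  }
  spec <- sharp_two_phase()
  st <- make_two_phase(spec, seed = 2)
  traj <- trajectory(list(st))
  aligned <- align_snapshots(traj)
  Lz <- st$box[3]
  # the fixture is already centered: alignment is a small uniform correction
  expect_lt(max(circ_diff(aligned$frames[[1]]$pos[, 3], st$pos[, 3], Lz)), 0.5)
  # translate across the periodic boundary and realign
  shifted <- st
  shifted$pos[, 3] <- (st$pos[, 3] + 0.4 * Lz) %% Lz
  re <- align_snapshots(trajectory(list(shifted)))
  # restored to the aligned position (inversion of the known shift)
  expect_lt(max(circ_diff(re$frames[[1]]$pos[, 3],
                          aligned$frames[[1]]$pos[, 3], Lz)), 1e-6)
})

test_that("alignment detects the interface normal among the axes", {
  spec <- sharp_two_phase()
  st <- make_two_phase(spec, seed = 3)
  # move the species contrast onto the x axis
  rot <- st
  rot$pos <- st$pos[, c(3, 1, 2)]
  rot$vel <- st$vel[, c(3, 1, 2)]
  rot$box <- sim_box(as.numeric(st$box)[c(3, 1, 2)])
  aligned <- align_snapshots(trajectory(list(rot)))
  expect_equal(aligned$meta$axis, 1)
  expect_equal(as.numeric(traj_box(aligned))[3], as.numeric(st$box)[3])
})

test_that("mixed configurations are flagged as unalignable", {
  st <- make_uniform_state(800, box = c(10, 10, 10), seed = 4)
  expect_error(align_snapshots(trajectory(list(st))), "interface")
})

test_that("density profile is uniform for a gas and conserves mass", {
  np <- 4000
  st <- make_uniform_state(np, box = c(10, 10, 20), seed = 5)
  traj <- trajectory(list(st))
  grid <- slab_grid(st$box, n = 20)
  prof <- density_profile(traj, grid)
  rho <- np / prod(as.numeric(st$box))
  expect_equal(mean(prof$value), rho, tolerance = 1e-10) # exact mass conservation
  expect_lt(max(abs(prof$value - rho)) / rho, 0.2)       # counting noise only
  expect_equal(sum(prof$count), np)
  # per-frame conservation holds exactly: integral x area = particle count
  expect_equal(sum(prof$value) * grid$area * grid$width, np, tolerance = 1e-10)
})

test_that("two-phase fixture reproduces its density plateaus", {
  spec <- sharp_two_phase(box = c(14, 14, 28), rho_hot = 0.7, rho_cold = 1.0)
  traj <- make_two_phase_trajectory(spec, n_frames = 12, seed = 6)
  grid <- slab_grid(traj_box(traj), n = 56)
  hot_phase <- grid$centers > 9 & grid$centers < 19  # away from interfaces
  cold_phase <- grid$centers < 5 | grid$centers > 23
  prof <- density_profile(traj, grid)
  expect_equal(mean(prof$value[hot_phase]), 0.7, tolerance = 0.03)
  expect_equal(mean(prof$value[cold_phase]), 1.0, tolerance = 0.03)
  # selector splits: hot + cold = all
  ph <- density_profile(traj, grid, "hot")
  pc <- density_profile(traj, grid, "cold")
  expect_equal(ph$value + pc$value, prof$value, tolerance = 1e-12)
  expect_error(density_profile(trajectory(list()), grid), "empty")
})

test_that("msv profile recovers Maxwell temperatures per slab", {
  spec <- sharp_two_phase(box = c(14, 14, 28), T_hot = 2.6, T_cold = 1.2)
  traj <- make_two_phase_trajectory(spec, n_frames = 10, seed = 7)
  grid <- slab_grid(traj_box(traj), n = 28)
  hot_sel <- msv_profile(traj, grid, "hot")
  hot_phase <- grid$centers > 9 & grid$centers < 19
  ok <- hot_phase & hot_sel$count > 0
  expect_equal(mean(hot_sel$value[ok]), 2.6, tolerance = 0.05)
  # uniform Maxwell gas at T = 2: every slab within 3 standard errors
  stg <- make_uniform_state(6000, box = c(10, 10, 10), temp = 2, seed = 8)
  pg <- msv_profile(trajectory(list(stg)), slab_grid(stg$box, n = 10))
  expect_true(all(abs(pg$value - 2) < 0.2))
})

test_that("effective temperatures and chi are recovered from fixtures", {
  spec <- sharp_two_phase(T_hot = 2.6, T_cold = 1.3)
  traj <- make_two_phase_trajectory(spec, n_frames = 8, seed = 9)
  et <- effective_temperatures(traj)
  expect_equal(et$Theff, 2.6, tolerance = 0.03)
  expect_equal(et$Tceff, 1.3, tolerance = 0.03)
  expect_equal(et$chi, 1.0, tolerance = 0.05)
  # chi formula exact cases
  expect_equal(chi_asymmetry(3, 1), 2)
  expect_equal(chi_asymmetry(1.7, 1.7), 0)
  expect_equal(chi_asymmetry(2.6, 1.3), 1)
  expect_error(chi_asymmetry(2, 0), "positive")
  # absent species is an error
  allhot <- make_uniform_state(100, c(8, 8, 8), species = rep("hot", 100))
  expect_error(effective_temperatures(trajectory(list(allhot))), "absent")
})

test_that("msv decomposition identity holds to machine precision", {
  spec <- sharp_two_phase(purity_hot = 0.85, purity_cold = 0.9, width = 1.5)
  traj <- make_two_phase_trajectory(spec, n_frames = 6, seed = 10)
  grid <- slab_grid(traj_box(traj), n = 24)
  dec <- msv_decomposition(traj, grid)
  msv <- msv_profile(traj, grid, "all")
  ok <- msv$count > 0
  expect_equal(dec$msv$value[ok], msv$value[ok], tolerance = 1e-12)
  expect_equal(dec$difference$value[ok],
               dec$msv$value[ok] - dec$uncorrelated$value[ok],
               tolerance = 1e-12)
  # species and speeds independent within slabs here, so the correlation
  # term is small
  expect_lt(max(abs(dec$difference$value[ok])), 0.15)
})

test_that("order parameter hits its pure and mixed limits", {
  # fully separated with a vacuum gap wider than rc: no cross-species
  # inter-chain contacts anywhere, so Phi is exactly 1
  set.seed(11)
  nh <- 400
  hot <- cbind(runif(nh) * 10, runif(nh) * 10, runif(nh) * 8 + 2)
  cold <- cbind(runif(nh) * 10, runif(nh) * 10, runif(nh) * 8 + 14)
  gapped <- system_state(pos = rbind(hot, cold),
                         vel = matrix(0, 2 * nh, 3),
                         species = rep(c("hot", "cold"), each = nh),
                         chain = rep(1:20, each = 40),
                         box = c(10, 10, 26))
  expect_equal(as.numeric(order_parameter_phi(gapped)), 1)
  # adjacent pure phases: only interfacial cross-contacts, Phi close to 1
  st <- make_two_phase(sharp_two_phase(), seed = 11)
  expect_gt(as.numeric(order_parameter_phi(st)), 0.8)
  # chain-level species shuffle of a dense melt: Phi ~ 0
  st2 <- cached_melt(M = 10, N = 10)
  M <- length(unique(st2$chain))
  phis <- sapply(1:12, function(k) {
    set.seed(100 + k)
    sh <- st2
    perm <- sample(unique(st2$chain))
    hot_chains <- perm[seq_len(length(perm) / 2)]
    sh$species <- ifelse(st2$chain %in% hot_chains, 1L, 2L)
    as.numeric(order_parameter_phi(sh))
  })
  se <- sd(phis) / sqrt(length(phis))
  # permutation-null expectation is -1/(M-1), vanishing for large M
  expect_lt(abs(mean(phis) - (-1 / (M - 1))), 3 * se + 0.02)
  # dilute degenerate input errors
  iso <- system_state(pos = rbind(c(1, 1, 1), c(5, 5, 5)),
                      vel = matrix(0, 2, 3), species = c("hot", "cold"),
                      chain = 1:2, box = c(10, 10, 10))
  expect_error(order_parameter_phi(iso), "contacts")
})

test_that("gyration statistics match chain closed forms", {
  # rigid rod of N beads with spacing b: Rg^2 = b^2 (N^2 - 1) / 12
  N <- 10; b <- 0.9
  rod <- system_state(pos = cbind(seq(0, by = b, length.out = N), 5, 5),
                      vel = matrix(0, N, 3), species = rep("hot", N),
                      chain = rep(1L, N), box = c(30, 30, 30))
  g <- chain_gyration(rod)
  expect_equal(g$rg2, b^2 * (N^2 - 1) / 12, tolerance = 1e-12)
  # coincident beads: zero
  pt <- system_state(pos = matrix(3, 6, 3), vel = matrix(0, 6, 3),
                     species = rep("cold", 6), chain = rep(1L, 6),
                     box = c(10, 10, 10))
  expect_equal(chain_gyration(pt)$rg2, 0)
  # the rod is unwrapped correctly across the periodic boundary
  rod2 <- rod
  rod2$pos[, 1] <- (rod2$pos[, 1] + 28) %% 30
  expect_equal(chain_gyration(rod2)$rg2, b^2 * (N^2 - 1) / 12, tolerance = 1e-12)
  # ideal random walks: <Rg^2> ~ N b^2 / 6
  set.seed(12)
  Nw <- 40; nch <- 200; bw <- 0.97
  steps <- matrix(rnorm(3 * Nw * nch), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2)) * bw
  chain <- rep(seq_len(nch), each = Nw)
  pos <- do.call(rbind, lapply(split(seq_len(Nw * nch), chain), function(idx) {
    apply(steps[idx, ], 2, cumsum)
  }))
  walks <- system_state(pos = pos %% 200, vel = matrix(0, nrow(pos), 3),
                        species = rep("hot", nrow(pos)), chain = chain,
                        box = c(200, 200, 200))
  mean_rg2 <- mean(chain_gyration(walks)$rg2)
  expect_equal(mean_rg2, Nw * bw^2 / 6, tolerance = 0.1)
})

test_that("region assignment partitions chains around the interfaces", {
  spec <- sharp_two_phase(box = c(12, 12, 24))
  traj <- make_two_phase_trajectory(spec, n_frames = 3, seed = 13)
  out <- gyration_by_region(traj, interfaces = c(6, 18), width = 1.5)
  expect_setequal(out$region, c("hot", "cold", "transition"))
  # every chain lands in exactly one region
  nch <- length(unique(traj$frames[[1]]$chain))
  expect_equal(sum(out$n_chains), nch * 3)
  # hot chains dominate the hot region, cold chains the cold region
  expect_gt(out$n_chains[out$region == "hot" & out$species == "hot"],
            out$n_chains[out$region == "hot" & out$species == "cold"])
})
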