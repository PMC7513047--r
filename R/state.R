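#' Particle system state
#'
#' Container for one configuration of the blend: wrapped positions,
#' velocities, species codes, chain ids and the periodic box.
#'
#' @param pos numeric matrix (Np x 3) of positions (sigma); wrapped into the
#'   box on construction.
#' @param vel numeric matrix (Np x 3) of velocities (sigma/tau).
#' @param species species per particle: "hot"/"cold" labels or codes 1/2.
#' @param chain integer chain id per particle; monomers of a chain must be
#'   contiguous and in order along the chain.
#' @param box a \code{\link{sim_box}} or numeric length 3.
#' @param time simulation time (tau).
#' @return An object of class \code{system_state}.
#' @export
system_state <- function(pos, vel, species, chain, box, time = 0) {
  pos <- as.matrix(pos)
  vel <- as.matrix(vel)
  box <- sim_box(box)
  species <- species_code(species)
  chain <- as.integer(chain)
  np <- nrow(pos)
  stopifnot(ncol(pos) == 3, identical(dim(vel), dim(pos)),
            length(species) == np, length(chain) == np)
  for (k in 1:3) pos[, k] <- pos[, k] %% box[k]
  st <- structure(
    list(pos = pos, vel = vel, species = species, chain = chain,
         box = box, time = time),
    class = "system_state"
  )
  sp_by_chain <- tapply(species, chain, function(s) length(unique(s)))
  if (any(sp_by_chain != 1)) {
    stop("all monomers of a chain must share the chain's species")
  }
  st
}

#' @export
print.system_state <- function(x, ...) {
  nh <- sum(x$species == SPECIES_HOT)
  cat(sprintf(
    "system_state: %d particles (%d hot, %d cold), %d chains, box %.3g x %.3g x %.3g, t = %g tau\n",
    nrow(x$pos), nh, nrow(x$pos) - nh, length(unique(x$chain)),
    x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

# bond list (consecutive monomers within each chain), 1-based 2-column matrix
chain_bonds <- function(chain) {
  n <- length(chain)
  i <- seq_len(n - 1)
  keep <- chain[i] == chain[i + 1]
  cbind(i[keep], i[keep] + 1L)
}

#' @rdname system_state
#' @param state a \code{system_state}.
#' @export
n_particles <- function(state) nrow(state$pos)

#' Validate the invariants of a system state
#'
#' Checks particle count consistency, FENE bond lengths below \code{rmax}
#' and species homogeneity within chains.
#'
#' @param state a \code{\link{system_state}}.
#' @param ff a \code{\link{force_field}} used for the bond-length check.
#' @return \code{state}, invisibly; errors describe the first violation.
#' @export
validate_state <- function(state, ff = force_field()) {
  b <- chain_bonds(state$chain)
  if (nrow(b) > 0) {
    d <- state$pos[b[, 1], , drop = FALSE] - state$pos[b[, 2], , drop = FALSE]
    for (k in 1:3) d[, k] <- d[, k] - state$box[k] * round(d[, k] / state$box[k])
    len <- sqrt(rowSums(d^2))
    if (any(len >= ff$rmax)) {
      bad <- which.max(len)
      stop(sprintf("FENE bond overstretched: chain %d, bond %d-%d, length %.4f >= rmax %.4f",
                   state$chain[b[bad, 1]], b[bad, 1], b[bad, 2], len[bad], ff$rmax))
    }
  }
  invisible(state)
}

# minimum-image displacement matrix
min_image_disp <- function(d, box) {
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Kinetic observables of a state
#'
#' \code{kinetic_temperature} returns one third of the mean squared velocity
#' of the selected particles (the effective temperature of that subset).
#'
#' @param state a \code{\link{system_state}}.
#' @param select "all", "hot" or "cold".
#' @return scalar temperature (epsilon).
#' @export
kinetic_temperature <- function(state, select = "all") {
  idx <- switch(select,
                all = seq_len(n_particles(state)),
                hot = which(state$species == SPECIES_HOT),
                cold = which(state$species == SPECIES_COLD),
                stop("select must be 'all', 'hot' or 'cold'"))
  if (length(idx) == 0) stop(sprintf("no '%s' particles in state", select))
  mean(rowSums(state$vel[idx, , drop = FALSE]^2)) / 3
}

# unwrap chain coordinates by walking bond vectors with minimum image;
# returns Np x 3 matrix of continuous coordinates (chains made whole)
unwrap_chains <- function(state) {
  pos <- state$pos
  out <- pos
  chain <- state$chain
  for (ch in unique(chain)) {
    idx <- which(chain == ch)
    if (length(idx) < 2) next
    dd <- min_image_disp(
      pos[idx[-1], , drop = FALSE] - pos[idx[-length(idx)], , drop = FALSE],
      state$box)
    walked <- apply(dd, 2, cumsum)
    if (is.null(dim(walked))) walked <- matrix(walked, nrow = 1)
    out[idx, ] <- rbind(pos[idx[1], ], sweep(walked, 2, pos[idx[1], ], `+`))
  }
  out
}
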