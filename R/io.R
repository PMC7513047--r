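#' Write a trajectory to the native text container
#'
#' Plain-text frame-based container: a format line, a JSON metadata line
#' (box, particle and frame counts, units tag), then per frame a
#' \code{frame <index> time <t>} line followed by one line per particle:
#' species label (hot/cold), chain id, position and velocity printed with
#' \code{\%.17g} so that the read-back doubles are bitwise identical.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"), length(traj$frames) > 0)
  box <- as.numeric(traj_box(traj))
  np <- nrow(traj$frames[[1]]$pos)
  meta <- jsonlite::toJSON(
    list(box = box, n_particles = np, n_frames = length(traj$frames),
         units = "reduced-LJ (sigma, epsilon, tau, kB=1)"),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("activeblend-trajectory 1", as.character(meta)), con)
  for (i in seq_along(traj$frames)) {
    st <- traj$frames[[i]]
    if (nrow(st$pos) != np) stop("all frames must share the particle count")
    writeLines(sprintf("frame %d time %.17g", i, st$time), con)
    writeLines(sprintf("%s %d %.17g %.17g %.17g %.17g %.17g %.17g",
                       species_label(st$species), st$chain,
                       st$pos[, 1], st$pos[, 2], st$pos[, 3],
                       st$vel[, 1], st$vel[, 2], st$vel[, 3]), con)
  }
  invisible(path)
}

#' Read a trajectory from the native text container
#'
#' @param path file written by \code{\link{write_trajectory}}.
#' @return a \code{\link{trajectory}}.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "activeblend-trajectory")) {
    stop("schema mismatch: missing 'activeblend-trajectory' format line")
  }
  meta <- tryCatch(jsonlite::fromJSON(lines[2]),
                   error = function(e) stop("schema mismatch: unreadable metadata line"))
  for (field in c("box", "n_particles", "n_frames")) {
    if (is.null(meta[[field]])) {
      stop(sprintf("schema mismatch: missing dataset '%s'", field))
    }
  }
  np <- meta$n_particles
  nf <- meta$n_frames
  need <- 2 + nf * (np + 1)
  if (length(lines) < need) {
    stop(sprintf("truncated file: expected %d lines, found %d", need, length(lines)))
  }
  frames <- vector("list", nf)
  cursor <- 3L
  for (f in seq_len(nf)) {
    hdr <- strsplit(lines[cursor], " ", fixed = TRUE)[[1]]
    if (length(hdr) != 4 || hdr[1] != "frame" || hdr[3] != "time") {
      stop(sprintf("schema mismatch: bad frame header at line %d", cursor))
    }
    time <- as.numeric(hdr[4])
    block <- lines[cursor + seq_len(np)]
    parts <- strsplit(block, " ", fixed = TRUE)
    if (any(lengths(parts) != 8)) {
      stop("schema mismatch: particle lines must have 8 fields")
    }
    m <- matrix(unlist(parts), ncol = 8, byrow = TRUE)
    if (!all(m[, 1] %in% SPECIES_LEVELS)) {
      stop("species labels other than {hot, cold} present")
    }
    num <- matrix(as.numeric(m[, 3:8]), ncol = 6)
    frames[[f]] <- system_state(pos = num[, 1:3], vel = num[, 4:6],
                                species = m[, 1],
                                chain = as.integer(m[, 2]),
                                box = meta$box, time = time)
    cursor <- cursor + np + 1L
  }
  trajectory(frames)
}

#' Export a trajectory as extended XYZ
#'
#' One block per frame: particle count, a comment line with
#' \code{Lattice}, \code{Properties} and \code{Time}, then per-particle
#' lines \code{tag x y z vx vy vz chain} with species tags H (hot) / C
#' (cold) and 6-decimal coordinates.
#'
#' @inheritParams write_trajectory
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"), length(traj$frames) > 0)
  con <- file(path, "w")
  on.exit(close(con))
  for (st in traj$frames) {
    box <- as.numeric(st$box)
    writeLines(as.character(nrow(st$pos)), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3:velo:R:3:chain_id:I:1 Time=%g',
      box[1], box[2], box[3], st$time), con)
    tag <- ifelse(st$species == SPECIES_HOT, "H", "C")
    writeLines(sprintf("%s %.6f %.6f %.6f %.6f %.6f %.6f %d",
                       tag, st$pos[, 1], st$pos[, 2], st$pos[, 3],
                       st$vel[, 1], st$vel[, 2], st$vel[, 3], st$chain), con)
  }
  invisible(path)
}

#' Import an extended-XYZ trajectory
#'
#' @param path file in the layout written by \code{\link{write_xyz}}.
#' @return a \code{\link{trajectory}}.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  cursor <- 1L
  while (cursor <= length(lines)) {
    if (!nzchar(trimws(lines[cursor]))) { cursor <- cursor + 1L; next }
    np <- suppressWarnings(as.integer(lines[cursor]))
    if (is.na(np) || np <= 0) stop(sprintf("bad particle count at line %d", cursor))
    if (cursor + 1L + np > length(lines)) {
      stop("truncated file: incomplete frame block")
    }
    comment <- lines[cursor + 1L]
    lat <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
    if (length(lat) == 0) stop("schema mismatch: missing Lattice in comment line")
    latv <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat), " +")[[1]])
    box <- latv[c(1, 5, 9)]
    tm <- regmatches(comment, regexpr("Time=[-0-9.eE+]+", comment))
    time <- if (length(tm)) as.numeric(sub("Time=", "", tm)) else 0
    block <- lines[cursor + 1L + seq_len(np)]
    parts <- strsplit(trimws(block), "[ \t]+")
    if (any(lengths(parts) < 7)) stop("schema mismatch: particle lines need tag + 6 numbers")
    m <- do.call(rbind, lapply(parts, function(p) p[1:8]))
    tag <- m[, 1]
    if (!all(tag %in% c("H", "C"))) stop("species tags other than {H, C} present")
    num <- matrix(as.numeric(m[, 2:7]), ncol = 6)
    chain <- if (all(!is.na(m[, 8]))) as.integer(m[, 8]) else seq_len(np)
    frames[[length(frames) + 1L]] <- system_state(
      pos = num[, 1:3], vel = num[, 4:6],
      species = ifelse(tag == "H", SPECIES_HOT, SPECIES_COLD),
      chain = chain, box = box, time = time)
    cursor <- cursor + 2L + np
  }
  if (length(frames) == 0) stop("no frames found")
  trajectory(frames)
}
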