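#' Trajectory container
#'
#' An ordered collection of \code{\link{system_state}} frames sharing one
#' box, species assignment and chain topology.
#'
#' @param frames list of \code{\link{system_state}} objects.
#' @param thermo optional \code{\link{thermostat_pair}} used to produce them.
#' @param ff optional \code{\link{force_field}}.
#' @param meta optional named list of extra metadata.
#' @return An object of class \code{trajectory}.
#' @export
trajectory <- function(frames, thermo = NULL, ff = NULL, meta = list()) {
  stopifnot(is.list(frames))
  if (length(frames) > 0) {
    stopifnot(all(vapply(frames, inherits, logical(1), "system_state")))
  }
  structure(list(frames = frames, thermo = thermo, ff = ff, meta = meta),
            class = "trajectory")
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' @export
`[.trajectory` <- function(x, i) {
  trajectory(x$frames[i], thermo = x$thermo, ff = x$ff, meta = x$meta)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames", length(x$frames)))
  if (length(x$frames) > 0) {
    st <- x$frames[[1]]
    cat(sprintf(", %d particles, box %.3g x %.3g x %.3g",
                nrow(st$pos), st$box[1], st$box[2], st$box[3]))
    times <- vapply(x$frames, `[[`, numeric(1), "time")
    cat(sprintf(", t in [%g, %g] tau", min(times), max(times)))
  }
  cat("\n")
  invisible(x)
}

#' @rdname trajectory
#' @param traj a \code{trajectory}.
#' @export
traj_box <- function(traj) {
  if (length(traj$frames) == 0) stop("empty trajectory")
  traj$frames[[1]]$box
}

frame_times <- function(traj) vapply(traj$frames, `[[`, numeric(1), "time")
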