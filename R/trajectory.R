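#' Trajectory ensemble
#'
#' Time-ordered particle records in a periodic box. The frame table has one
#' row per (time, particle) with columns `time_ns`, `particle_id`, `species`,
#' `x`, `y`, `z` and optionally a dipole vector (`mu_x`, `mu_y`, `mu_z`, in
#' Debye) and two ring z coordinates (`ring1_z`, `ring2_z`, in Angstrom).
#' The box is periodic in x and y; z is bounded by reflective walls at
#' +/- Lz/2 with the bilayer center at z = 0.
#'
#' @param frames data.frame with at least the required columns above.
#' @param box numeric length-3, box edge lengths (Lx, Ly, Lz) in Angstrom.
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(frames, box) {
  frames <- as.data.frame(frames)
  required <- c("time_ns", "particle_id", "species", "x", "y", "z")
  missing_cols <- setdiff(required, names(frames))
  if (length(missing_cols)) {
    stop("trajectory is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  stopifnot(is.numeric(box), length(box) == 3L, all(box > 0))
  ## time must be monotone within each particle
  ord_ok <- tapply(frames$time_ns, frames$particle_id,
                   function(tv) !is.unsorted(tv))
  if (!all(unlist(ord_ok))) {
    bad <- names(ord_ok)[!unlist(ord_ok)]
    stop("time_ns is not monotone for particle(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(frames = frames, box = as.numeric(box)),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf(
    "Trajectory ensemble: %d records, %d particle(s), t in [%g, %g] ns\n",
    nrow(x$frames), length(unique(x$frames$particle_id)),
    min(x$frames$time_ns), max(x$frames$time_ns)))
  cat(sprintf("  box %g x %g x %g A; columns: %s\n",
              x$box[1], x$box[2], x$box[3],
              paste(names(x$frames), collapse = ", ")))
  invisible(x)
}
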