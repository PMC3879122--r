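# Time-series container shared by both engines.

new_trajectory <- function(times, series, engine, seed = NULL,
                           parameters = NULL, extra = list()) {
  stopifnot(is.matrix(series), nrow(series) == length(times))
  meta <- c(list(engine = engine, seed = seed, parameters = parameters), extra)
  structure(list(times = times, series = series, meta = meta),
            class = "bp_trajectory")
}

#' @export
print.bp_trajectory <- function(x, ...) {
  cat("Trajectory (", x$meta$engine, ")",
      if (!is.null(x$meta$seed)) paste0(", seed ", x$meta$seed), "\n", sep = "")
  cat("  ", length(x$times), " time points on [",
      format(min(x$times)), ", ", format(max(x$times)), "]\n", sep = "")
  cat("  species: ", paste(colnames(x$series), collapse = ", "), "\n", sep = "")
  fin <- x$series[nrow(x$series), ]
  cat("  final state: ",
      paste(sprintf("%s=%s", names(fin), signif(fin, 6)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.bp_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$series, check.names = FALSE)
}

#' Plot a trajectory
#'
#' One line per species on a common time axis.
#'
#' @param x A `bp_trajectory`.
#' @param log Axis log spec passed to [graphics::matplot()].
#' @param ... Further arguments to [graphics::matplot()].
#' @export
plot.bp_trajectory <- function(x, log = "", ...) {
  graphics::matplot(x$times, x$series, type = "l", lty = 1, log = log,
                    xlab = "time", ylab = "quantity", ...)
  graphics::legend("topright", legend = colnames(x$series),
                   col = seq_len(ncol(x$series)), lty = 1, bty = "n")
}

#' Write a trajectory to CSV
#'
#' One `time` column plus one column per species, with a header row.
#'
#' @param trajectory A `bp_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' Average stochastic replicates onto a common grid
#'
#' Each trajectory is resampled onto the grid by last-value-carried-forward
#' and the pointwise mean is returned; averaging many replicates smooths the
#' jumps of single realizations towards the mean behaviour that the ODE
#' semantics describes.
#'
#' @param trajectories Non-empty list of `bp_trajectory` objects sharing a
#'   species set.
#' @param grid Time grid for the result; defaults to the first trajectory's.
#' @return A `bp_trajectory` whose meta records `n_averaged`.
#' @export
average_trajectories <- function(trajectories, grid = NULL) {
  if (!length(trajectories)) stop("empty list of trajectories")
  sp <- colnames(trajectories[[1L]]$series)
  for (tr in trajectories)
    if (!identical(colnames(tr$series), sp))
      stop("trajectories have mismatched species sets")
  if (is.null(grid)) grid <- trajectories[[1L]]$times
  acc <- matrix(0, length(grid), length(sp), dimnames = list(NULL, sp))
  for (tr in trajectories)
    acc <- acc + resample_lvcf(tr, grid)
  new_trajectory(grid, acc / length(trajectories),
                 engine = trajectories[[1L]]$meta$engine,
                 parameters = trajectories[[1L]]$meta$parameters,
                 extra = list(n_averaged = length(trajectories)))
}

resample_lvcf <- function(trajectory, grid) {
  sp <- colnames(trajectory$series)
  out <- matrix(NA_real_, length(grid), length(sp),
                dimnames = list(NULL, sp))
  for (j in seq_along(sp)) {
    out[, j] <- approx(trajectory$times, trajectory$series[, j], xout = grid,
                       method = "constant", f = 0, rule = 2)$y
  }
  out
}
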