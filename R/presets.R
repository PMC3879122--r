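# Named parameter regimes of the (M,R) study and the experiment driver.

mr_preset_table <- function() {
  fig3 <- mr_params(k1 = 0.01, k2 = 100, k3 = 1,
                    l1 = 0.01, l2 = 100, l3 = 1,
                    m1 = 0.01, m2 = 100, m3 = 1,
                    d1 = 0, d2 = 0.05, d3 = 0.02426,
                    A_init = 1000, f_init = 1000)
  fig6 <- fig3
  fig6$d2 <- 0.07
  fig7 <- mr_params(k1 = 1, k2 = 100, k3 = 10,
                    l1 = 1, l2 = 100, l3 = 20,
                    m1 = 1, m2 = 100, m3 = 10,
                    d1 = 0, d2 = 60, d3 = 19.2666666,
                    A_init = 1000, f_init = 1000)
  list(
    fig3 = list(name = "fig3", params = fig3,
                description = "steady-state regime: slow binding, converges to a live steady state"),
    fig6 = list(name = "fig6", params = fig6,
                description = "as fig3 with f degradation raised to d2 = 0.07: the live steady state is lost (collapse)"),
    fig7 = list(name = "fig7", params = fig7,
                description = "fast-binding regime: deterministically live, but stochastic replicates can die")
  )
}

#' Named (M,R) parameter regimes
#'
#' The three studied regimes of the (M,R) network: `"fig3"` (live steady
#' state), `"fig6"` (identical except `d2 = 0.07`, which collapses the
#' network) and `"fig7"` (deterministically live, but with steady-state
#' counts of B, f and p low enough that stochastic replicates can reach
#' deadlock).  All three start from `A = f = 1000` and every other species
#' at zero.
#'
#' @param name One of `"fig3"`, `"fig6"`, `"fig7"`.
#' @return A list with `name`, `params` (an [mr_params()]) and
#'   `description`.
#' @export
mr_preset <- function(name) {
  tab <- mr_preset_table()
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  tab[[name]]
}

#' Experiment configuration
#'
#' @param preset Preset name (see [mr_preset()]); alternatively give
#'   `params` explicitly.
#' @param params An [mr_params()] object (ignored when `preset` is given).
#' @param engine `"ode"`, `"ssa"` or `"both"`.
#' @param t_end End time of every run.
#' @param n_points Recorded grid intervals.
#' @param n_reps Stochastic replicates (>= 1 when the engine includes ssa).
#' @param base_seed Seed of the first replicate.
#' @param out_dir Output directory (created if missing).
#' @param scale Optional volume-scale factor applied with [scale_model()].
#' @param ss_tol Steady-state residual tolerance.
#' @return A validated list of class `bp_experiment_config`.
#' @export
experiment_config <- function(preset = NULL, params = NULL,
                              engine = c("ode", "ssa", "both"),
                              t_end = 1000, n_points = 1000L, n_reps = 1L,
                              base_seed = 1L, out_dir = tempfile("bp_run_"),
                              scale = NULL, ss_tol = 1e-4) {
  engine <- match.arg(engine)
  if (is.null(preset) && is.null(params))
    stop("either a preset name or explicit params must be given")
  if (!is.null(preset)) params <- mr_preset(preset)$params
  if (engine %in% c("ssa", "both") && n_reps < 1)
    stop("n_reps must be >= 1 when the engine includes ssa")
  structure(list(preset = preset, params = params, engine = engine,
                 t_end = t_end, n_points = n_points, n_reps = n_reps,
                 base_seed = base_seed, out_dir = out_dir, scale = scale,
                 ss_tol = ss_tol),
            class = "bp_experiment_config")
}

#' Run an experiment and write its outputs
#'
#' Builds the (M,R) model for the configured parameters (optionally volume
#' scaled), runs the requested engines, and writes trajectory CSVs (columns
#' ordered A, B, f, p, fA, pB, Bf), a steady-state JSON (ODE), per-replicate
#' extinction JSON (SSA) and a `manifest.json` tying the outputs to the
#' parameter snapshot and seeds.  Re-running the same configuration and
#' `base_seed` reproduces identical outputs.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress progress messages (logged to stderr).
#' @return The manifest, invisibly: a list with `files`, `config`, `seeds`.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "bp_experiment_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[biopepa] ", ...)

  model <- build_mr_model(config$params)
  if (!is.null(config$scale)) {
    say("scaling model by factor ", config$scale)
    model <- scale_model(model, config$scale)
  }
  files <- character()
  seeds <- integer()
  rel <- function(f) file.path(config$out_dir, f)

  if (config$engine %in% c("ode", "both")) {
    say("ODE integration to t = ", config$t_end)
    tr <- simulate_ode(model, config$t_end, config$n_points)
    write_trajectory_csv(tr, rel("trajectory_ode.csv"))
    files <- c(files, "trajectory_ode.csv")
    ss <- find_steady_state(model, t_max = max(config$t_end, 5000),
                            abs_tol = config$ss_tol)
    jsonlite::write_json(
      list(converged = ss$converged, t_reached = ss$t_reached,
           residual_norm = ss$residual_norm,
           counts = as.list(ss$counts),
           counts_rounded = as.list(ss$counts_rounded)),
      rel("steady_state.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, "steady_state.json")
  }

  if (config$engine %in% c("ssa", "both")) {
    seeds <- config$base_seed + seq_len(config$n_reps) - 1L
    trajs <- vector("list", config$n_reps)
    reports <- vector("list", config$n_reps)
    for (r in seq_len(config$n_reps)) {
      say("SSA replicate ", r, "/", config$n_reps, " (seed ", seeds[r], ")")
      res <- ssa_simulate(model, config$t_end, seed = seeds[r],
                          n_points = config$n_points)
      f <- sprintf("trajectory_ssa_run%03d.csv", r)
      write_trajectory_csv(res$trajectory, rel(f))
      files <- c(files, f)
      trajs[[r]] <- res$trajectory
      reports[[r]] <- list(seed = seeds[r],
                           extinct = res$extinction$extinct,
                           t_extinct = res$extinction$t_extinct,
                           final_counts = as.list(res$extinction$final_counts))
    }
    if (config$n_reps > 1L) {
      avg <- average_trajectories(trajs)
      write_trajectory_csv(avg, rel("trajectory_ssa_mean.csv"))
      files <- c(files, "trajectory_ssa_mean.csv")
    }
    jsonlite::write_json(list(n_reps = config$n_reps, runs = reports),
                         rel("extinction.json"), auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, "extinction.json")
  }

  manifest <- list(files = files,
                   config = unclass(config)[setdiff(names(config), "params")],
                   params = unclass(config$params),
                   seeds = seeds)
  jsonlite::write_json(manifest, rel("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  say("wrote ", length(files) + 1L, " files to ", config$out_dir)
  invisible(manifest)
}
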