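# Stochastic (CTMC) semantics: Gillespie direct method.

#' Reaction propensities at an integer state
#'
#' Under mass action, the propensity of a reaction is its rate constant
#' times the product over its rate-contributing species (reactants and
#' activators, environment-held species included) of the falling factorial
#' `n (n-1) ... (n-m+1)` of the current count — the number of distinct ways
#' the required molecules can meet.  For a non-mass-action law the
#' expression is evaluated at the counts, guarded to zero whenever a
#' required reactant is exhausted.
#'
#' @param model A `bp_model`.
#' @param counts Named non-negative integer vector covering all species.
#' @return Named non-negative numeric vector, one propensity per reaction.
#' @export
propensities <- function(model, counts) {
  cmp <- bp_compile(model)
  miss <- setdiff(cmp$species, names(counts))
  if (length(miss)) stop("missing species in counts: ", miss[1L])
  counts <- counts[cmp$species]
  if (any(counts < 0))
    stop("negative count for species '", cmp$species[counts < 0][1L], "'")
  a <- setNames(numeric(length(cmp$reactions)), cmp$reactions)
  for (i in seq_along(cmp$reactions)) {
    r <- cmp$reactions[i]
    fac <- cmp$factors[[i]]
    if (!is.na(cmp$mass_action_constant[i])) {
      v <- model$parameters[[cmp$mass_action_constant[i]]]
      for (s in names(fac)) {
        n <- counts[[s]]; m <- fac[[s]]
        v <- v * prod(n - seq_len(m) + 1)
        if (v <= 0) { v <- 0; break }
      }
      a[r] <- v
    } else {
      v <- cmp$eval_laws(counts)[[r]]
      need <- rate_factors(model, r)
      if (any(counts[names(need)] < 1)) v <- 0
      if (v < 0)
        stop("kinetic law of '", r, "' is negative at the given counts")
      a[r] <- v
    }
  }
  a
}

cpp_args <- function(model, cmp, init) {
  if (!cmp$all_mass_action)
    return(NULL)
  idx <- function(s) match(s, cmp$species) - 1L
  list(init = as.integer(round(init)),
       rate_const = unname(model$parameters[cmp$mass_action_constant]),
       factor_species = lapply(cmp$factors, function(f) as.integer(idx(names(f)))),
       factor_mult = lapply(cmp$factors, function(f) as.integer(unname(f))),
       net = cmp$S)
}

check_integer_init <- function(init) {
  if (any(abs(init - round(init)) > 1e-9))
    stop("stochastic simulation requires integer initial counts (species '",
         names(init)[abs(init - round(init)) > 1e-9][1L], "' is not)")
  round(init)
}

#' Stochastic simulation (Gillespie direct method)
#'
#' Simulates the model as a continuous-time Markov chain: exponential
#' waiting times with rate equal to the total propensity, the next reaction
#' chosen with probability proportional to its propensity, the state
#' updated by the reaction's net change.  The trajectory is recorded onto a
#' uniform grid by last-value-carried-forward.  If the total propensity
#' reaches zero before `t_end` the system is dead (deadlock): the report
#' marks extinction at that time and the state is frozen thereafter.
#'
#' @param model A `bp_model` with integer initial counts.
#' @param t_end End time (> 0).
#' @param seed Integer seed; identical (model, t_end, seed) give
#'   bit-identical trajectories.
#' @param n_points Number of grid intervals for the recorded trajectory.
#' @return A `bp_ssa_result`: list with `trajectory` (a `bp_trajectory`,
#'   engine `"ssa"`) and `extinction` (a `bp_extinction` with `extinct`,
#'   `t_extinct`, `final_counts`).
#' @examples
#' m <- build_mr_model(mr_preset("fig3")$params)
#' res <- ssa_simulate(m, t_end = 5, seed = 1, n_points = 50)
#' res$extinction$extinct
#' @export
ssa_simulate <- function(model, t_end, seed, n_points = 1000L) {
  stopifnot(t_end > 0)
  cmp <- bp_compile(model)
  init <- check_integer_init(model$initial[cmp$species])
  grid <- ode_grid(t_end, n_points)
  set.seed(seed)
  args <- cpp_args(model, cmp, init)
  if (!is.null(args)) {
    out <- ssa_run_cpp(args$init, args$rate_const, args$factor_species,
                       args$factor_mult, args$net, grid, t_end)
  } else {
    out <- ssa_run_r(model, cmp, init, grid, t_end)
  }
  series <- out$series
  colnames(series) <- cmp$species
  traj <- new_trajectory(grid, series, engine = "ssa", seed = seed,
                         parameters = model$parameters,
                         extra = list(n_events = out$n_events))
  rep <- structure(list(extinct = out$extinct,
                        t_extinct = if (out$extinct) out$t_extinct else NULL,
                        final_counts = setNames(as.integer(out$final_counts),
                                                cmp$species)),
                   class = "bp_extinction")
  structure(list(trajectory = traj, extinction = rep),
            class = "bp_ssa_result")
}

# pure-R direct method for models with general (non-mass-action) laws
ssa_run_r <- function(model, cmp, init, grid, t_end) {
  x <- setNames(as.numeric(init), cmp$species)
  ng <- length(grid)
  rec <- matrix(0, ng, length(cmp$species))
  t <- 0; g <- 1L; extinct <- FALSE; t_ext <- NA_real_; nev <- 0
  repeat {
    a <- propensities(model, x)
    a0 <- sum(a)
    if (a0 <= 0) { extinct <- TRUE; t_ext <- t; break }
    t_next <- t + stats::rexp(1L, a0)
    while (g <= ng && grid[g] < t_next) { rec[g, ] <- x; g <- g + 1L }
    if (t_next > t_end) break
    j <- sample.int(length(a), 1L, prob = a)
    x <- x + cmp$S[, j]
    t <- t_next; nev <- nev + 1
  }
  while (g <= ng) { rec[g, ] <- x; g <- g + 1L }
  list(series = rec, extinct = extinct, t_extinct = t_ext,
       final_counts = x, n_events = nev)
}

#' @export
print.bp_ssa_result <- function(x, ...) {
  print(x$trajectory)
  print(x$extinction)
  invisible(x)
}

#' @export
print.bp_extinction <- function(x, ...) {
  if (x$extinct)
    cat("Extinct (deadlock) at t = ", format(x$t_extinct), "\n", sep = "")
  else cat("Alive at end of simulation\n")
  cat("  final counts: ",
      paste(sprintf("%s=%d", names(x$final_counts), x$final_counts),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# batch of replicates, single RNG stream seeded once (internal fast path)
ssa_final_states <- function(model, t_end, n_reps, base_seed) {
  cmp <- bp_compile(model)
  init <- check_integer_init(model$initial[cmp$species])
  args <- cpp_args(model, cmp, init)
  if (is.null(args))
    stop("batch simulation requires pure mass-action laws")
  set.seed(base_seed)
  out <- ssa_finals_cpp(args$init, args$rate_const, args$factor_species,
                        args$factor_mult, args$net, t_end, as.integer(n_reps))
  colnames(out$final_counts) <- cmp$species
  out
}

wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Empirical extinction probability
#'
#' Runs `n_reps` independent stochastic replicates (seeds `base_seed`,
#' `base_seed + 1`, ...) and reports the fraction that reach deadlock
#' (total propensity zero) before `t_end`, with a 95% Wilson score
#' interval.
#'
#' @param model A `bp_model` with integer initial counts.
#' @param n_reps Number of replicates (>= 1).
#' @param t_end End time of each replicate.
#' @param base_seed Seed of the first replicate.
#' @return A `bp_extinction_prob`: `fraction`, `ci` (Wilson 95%),
#'   `n_extinct`, `n_reps`, `t_extinct` (per-replicate, `NA` if alive),
#'   `seeds`.
#' @export
extinction_probability <- function(model, n_reps, t_end, base_seed = 1L) {
  stopifnot(n_reps >= 1)
  cmp <- bp_compile(model)
  init <- check_integer_init(model$initial[cmp$species])
  args <- cpp_args(model, cmp, init)
  seeds <- base_seed + seq_len(n_reps) - 1L
  ext <- logical(n_reps)
  t_ext <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seeds[r])
    if (!is.null(args)) {
      out <- ssa_finals_cpp(args$init, args$rate_const, args$factor_species,
                            args$factor_mult, args$net, t_end, 1L)
      ext[r] <- out$extinct[1L]
      t_ext[r] <- out$t_extinct[1L]
    } else {
      out <- ssa_run_r(model, cmp, init, c(0, t_end), t_end)
      ext[r] <- out$extinct
      t_ext[r] <- out$t_extinct
    }
  }
  structure(list(fraction = mean(ext),
                 ci = wilson_interval(sum(ext), n_reps),
                 n_extinct = sum(ext), n_reps = n_reps, t_end = t_end,
                 t_extinct = t_ext, seeds = seeds),
            class = "bp_extinction_prob")
}

#' @export
print.bp_extinction_prob <- function(x, ...) {
  cat(sprintf("Extinction by t = %s in %d / %d replicates (%.3f, 95%% CI %.3f-%.3f)\n",
              format(x$t_end), x$n_extinct, x$n_reps, x$fraction,
              x$ci[["lower"]], x$ci[["upper"]]))
  invisible(x)
}
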