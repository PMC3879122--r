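# Deterministic (ODE) semantics: d state / dt = S %*% law values.

#' Right-hand side of the ODE semantics
#'
#' The time derivative of every species: the net-stoichiometry matrix times
#' the vector of evaluated kinetic laws.  Environment-held species have
#' derivative exactly zero.
#'
#' @param model A `bp_model`.
#' @param state Named numeric vector covering all species, non-negative.
#' @return Named numeric vector of derivatives in species order.
#' @export
ode_rhs <- function(model, state) {
  cmp <- bp_compile(model)
  miss <- setdiff(cmp$species, names(state))
  if (length(miss)) stop("missing species in state: ", miss[1L])
  drop(cmp$S %*% cmp$eval_laws(state[cmp$species]))
}

ode_grid <- function(t_end, n_points) {
  if (n_points <= 0) c(0, t_end) else seq(0, t_end, length.out = n_points + 1L)
}

integrate_model <- function(cmp, y0, times, rel_tol, abs_tol) {
  deriv <- function(t, y, parms) {
    names(y) <- cmp$species
    list(drop(cmp$S %*% cmp$eval_laws(y)))
  }
  out <- deSolve::lsoda(y = setNames(as.numeric(y0), cmp$species),
                        times = times, func = deriv, parms = NULL,
                        rtol = rel_tol, atol = abs_tol, maxsteps = 50000L)
  if (attr(out, "istate")[1L] < 0 || anyNA(out))
    stop("ODE integration failed near t = ",
         format(max(out[stats::complete.cases(out), "time"])))
  out
}

#' Integrate the ODE semantics
#'
#' Adaptive-step, stiff-capable integration (lsoda) of the mass-action ODE
#' system on a uniform output grid.  Tiny negative undershoots within the
#' absolute tolerance are clamped to zero in the reported series; larger
#' ones raise a warning.
#'
#' @param model A `bp_model`.
#' @param t_end End time (> 0), in model time units.
#' @param n_points Number of grid intervals; the grid has `n_points + 1`
#'   times from 0 to `t_end` (with `n_points = 0`, only the initial and
#'   final states are recorded).
#' @param rel_tol,abs_tol Integrator tolerances.
#' @return A `bp_trajectory` with engine tag `"ode"`.
#' @examples
#' m <- build_mr_model(mr_preset("fig3")$params)
#' tr <- simulate_ode(m, t_end = 100, n_points = 100)
#' tail(as.data.frame(tr), 1)
#' @export
simulate_ode <- function(model, t_end, n_points = 1000L,
                         rel_tol = 1e-8, abs_tol = 1e-10) {
  stopifnot(t_end > 0)
  cmp <- bp_compile(model)
  times <- ode_grid(t_end, n_points)
  out <- integrate_model(cmp, model$initial[cmp$species], times,
                         rel_tol, abs_tol)
  series <- out[, cmp$species, drop = FALSE]
  if (any(series < -abs_tol))
    warning("integrator produced values below -abs_tol (largest undershoot ",
            format(min(series)), "); clamped to zero")
  series[series < 0] <- 0
  rownames(series) <- NULL
  new_trajectory(out[, "time"], series, engine = "ode",
                 parameters = model$parameters)
}

#' Find a deterministic steady state by integration
#'
#' Integrates forward in chunks until the largest absolute derivative over
#' the non-constant species drops to `abs_tol` (convergence) or `t_max` is
#' reached.  Non-convergence is reported, not an error.
#'
#' @param model A `bp_model`.
#' @param t_max Maximum integration time.
#' @param abs_tol Convergence threshold on `max |d/dt|`, in quantity per
#'   time unit.  The default, 1e-4, is several orders of magnitude below
#'   the gross one-way fluxes of the regimes studied here while remaining
#'   attainable for systems that relax onto a slow quasi-steady manifold
#'   rather than an isolated fixed point.
#' @param chunk Integration chunk length between convergence checks.
#' @param rel_tol,int_abs_tol Integrator tolerances.
#' @return A `bp_steady_state`: `counts`, `counts_rounded`, `residual_norm`,
#'   `converged`, `t_reached`.
#' @examples
#' ss <- find_steady_state(build_mr_model(mr_preset("fig3")$params))
#' ss$counts_rounded
#' @export
find_steady_state <- function(model, t_max = 5000, abs_tol = 1e-4,
                              chunk = 50, rel_tol = 1e-10,
                              int_abs_tol = 1e-12) {
  stopifnot(t_max > 0, abs_tol > 0)
  cmp <- bp_compile(model)
  free <- setdiff(cmp$species, model$constant_species)
  state <- setNames(as.numeric(model$initial[cmp$species]), cmp$species)
  resid <- function(y) {
    d <- drop(cmp$S %*% cmp$eval_laws(y))
    max(abs(d[match(free, cmp$species)]), 0)
  }
  t_now <- 0
  r <- resid(state)
  while (r > abs_tol && t_now < t_max) {
    step <- min(chunk, t_max - t_now)
    out <- integrate_model(cmp, state, c(0, step), rel_tol, int_abs_tol)
    state <- setNames(pmax(out[nrow(out), cmp$species], 0), cmp$species)
    t_now <- t_now + step
    r <- resid(state)
  }
  structure(list(counts = state,
                 counts_rounded = round(state),
                 residual_norm = r,
                 converged = r <= abs_tol,
                 t_reached = t_now),
            class = "bp_steady_state")
}

#' @export
print.bp_steady_state <- function(x, ...) {
  cat(if (x$converged) "Converged steady state" else "No steady state reached",
      " (t = ", format(x$t_reached),
      ", max |d/dt| = ", format(x$residual_norm, digits = 3), ")\n", sep = "")
  cat("  ", paste(sprintf("%s=%d", names(x$counts_rounded),
                          as.integer(x$counts_rounded)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Volume scaling of a mass-action model
#'
#' Rescales a model to a different molecule-number scale while keeping its
#' deterministic dynamics exactly equivariant: initial quantities are
#' multiplied by `factor` and each mass-action constant is divided by
#' `factor^(order - 1)`, where the order counts the rate-contributing
#' quantity factors (environment-held species included).  Unimolecular and
#' zero-order constants are unchanged; bimolecular constants are divided by
#' `factor`.  The scaled ODE trajectory equals the unscaled one multiplied
#' pointwise by `factor`.
#'
#' @param model A `bp_model` whose laws are all pure mass action.
#' @param factor Positive scale factor.
#' @return The scaled `bp_model`.
#' @export
scale_model <- function(model, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  cmp <- bp_compile(model)
  if (!cmp$all_mass_action)
    stop("cannot scale: reaction '",
         cmp$reactions[is.na(cmp$mass_action_constant)][1L],
         "' does not have a pure mass-action law")
  orders <- vapply(cmp$factors, sum, numeric(1))
  # one division per distinct constant; shared constants must agree on order
  by_const <- split(orders, cmp$mass_action_constant)
  m <- model
  m$initial <- model$initial * factor
  for (const in names(by_const)) {
    o <- unique(by_const[[const]])
    if (length(o) > 1L)
      stop("rate constant '", const,
           "' is shared by reactions of different order; cannot scale")
    if (o > 1)
      m$parameters[[const]] <- m$parameters[[const]] / factor^(o - 1)
  }
  validate_bp_model(m)
  m
}
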