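# Brute-force transient oracle: enumerate the reachable state space
# (truncated), build the CTMC generator, and compute the transient
# distribution by uniformization.  Used to verify the Gillespie engine on
# small instances.

#' Transient state distribution by uniformization
#'
#' Enumerates the states reachable from the initial counts (breadth-first,
#' truncated at `state_cap` states), assembles the sparse CTMC generator
#' from the reaction propensities, and computes the exact transient
#' distribution at time `t` by uniformization.  Transitions into states
#' beyond the truncation are routed to an absorbing overflow state whose
#' probability is reported as leaked mass; the retained probabilities sum
#' to `1 - leaked`.
#'
#' @param model A `bp_model` with integer initial counts.
#' @param t Time at which the distribution is evaluated (>= 0).
#' @param state_cap Maximum number of enumerated states.
#' @param leak_tol Leaked mass above which a warning is raised (the
#'   truncation is then too tight for the requested time).
#' @return A `bp_ctmc_dist`: `states` (integer matrix, one row per state),
#'   `prob` (aligned probabilities), `leaked`, `t`.
#' @examples
#' m <- parse_biopepa("
#'   c1 = 1;
#'   kineticLawOf decay : c1 * X;
#'   X = (decay, 1) <<;
#'   X[3]
#' ")
#' d <- ctmc_transient_oracle(m, t = 0.5, state_cap = 10)
#' sum(d$prob)
#' @export
ctmc_transient_oracle <- function(model, t, state_cap = 10000L,
                                  leak_tol = 1e-6) {
  stopifnot(t >= 0, state_cap >= 1)
  cmp <- bp_compile(model)
  init <- check_integer_init(model$initial[cmp$species])
  nsp <- length(cmp$species)

  # propensity evaluator over the compiled form (avoids re-validation)
  prop <- function(x) {
    a <- numeric(length(cmp$reactions))
    names(x) <- cmp$species
    for (i in seq_along(cmp$reactions)) {
      if (!is.na(cmp$mass_action_constant[i])) {
        v <- model$parameters[[cmp$mass_action_constant[i]]]
        fac <- cmp$factors[[i]]
        for (s in names(fac)) {
          v <- v * prod(x[[s]] - seq_len(fac[[s]]) + 1)
          if (v <= 0) { v <- 0; break }
        }
        a[i] <- v
      } else {
        v <- cmp$eval_laws(x)[[i]]
        need <- cmp$factors[[i]]
        if (length(need) && any(x[names(need)] < 1)) v <- 0
        a[i] <- max(v, 0)
      }
    }
    a
  }

  key <- function(x) paste(x, collapse = ",")
  index <- new.env(parent = emptyenv(), hash = TRUE)
  states <- vector("list", state_cap)
  states[[1L]] <- as.integer(init)
  assign(key(init), 1L, envir = index)
  n_states <- 1L
  frontier <- 1L

  # breadth-first enumeration of reachable states
  while (length(frontier) && n_states < state_cap) {
    nxt <- integer()
    for (si in frontier) {
      x <- states[[si]]
      a <- prop(x)
      for (j in which(a > 0)) {
        y <- x + cmp$S[, j]
        k <- key(y)
        if (!exists(k, envir = index, inherits = FALSE)) {
          if (n_states >= state_cap) next
          n_states <- n_states + 1L
          states[[n_states]] <- as.integer(y)
          assign(k, n_states, envir = index)
          nxt <- c(nxt, n_states)
        }
      }
    }
    frontier <- nxt
  }
  states <- states[seq_len(n_states)]

  # sparse generator over enumerated states + one absorbing overflow state
  trip <- vector("list", n_states)
  overflow <- n_states + 1L
  for (si in seq_len(n_states)) {
    x <- states[[si]]
    a <- prop(x)
    act <- which(a > 0)
    if (!length(act)) next
    ti <- integer(length(act))
    for (q in seq_along(act)) {
      y <- x + cmp$S[, act[q]]
      k <- key(y)
      ti[q] <- if (exists(k, envir = index, inherits = FALSE))
        get(k, envir = index) else overflow
    }
    trip[[si]] <- list(i = c(rep.int(si, length(act)), si),
                       j = c(ti, si),
                       x = c(a[act], -sum(a[act])))
  }
  trip <- trip[!vapply(trip, is.null, logical(1))]
  Q <- Matrix::sparseMatrix(
    i = unlist(lapply(trip, `[[`, "i")),
    j = unlist(lapply(trip, `[[`, "j")),
    x = unlist(lapply(trip, `[[`, "x")),
    dims = c(overflow, overflow))

  p0 <- numeric(overflow); p0[1L] <- 1
  lambda <- max(-Matrix::diag(Q), 0)
  if (lambda == 0 || t == 0) {
    p <- p0
  } else {
    P <- Matrix::Diagonal(overflow) + Q / lambda
    nmax <- qpois(1 - 1e-12, lambda * t) + 10L
    w <- dpois(0:nmax, lambda * t)
    p <- w[1L] * p0
    pn <- p0
    for (n in seq_len(nmax)) {
      pn <- as.numeric(pn %*% P)
      p <- p + w[n + 1L] * pn
    }
  }
  leaked <- p[overflow]
  if (leaked > leak_tol)
    warning("probability mass beyond the state cap: ",
            format(leaked, digits = 3),
            " (increase state_cap or reduce t)")
  structure(list(states = do.call(rbind, states) |>
                   `colnames<-`(cmp$species),
                 prob = p[seq_len(n_states)],
                 leaked = leaked, t = t),
            class = "bp_ctmc_dist")
}

#' @export
print.bp_ctmc_dist <- function(x, n = 10L, ...) {
  cat("Transient CTMC distribution at t = ", format(x$t), " (",
      nrow(x$states), " states, leaked mass ",
      format(x$leaked, digits = 3), ")\n", sep = "")
  ord <- order(x$prob, decreasing = TRUE)
  show <- head(ord, n)
  for (i in show)
    cat(sprintf("  P(%s) = %.6f\n",
                paste(sprintf("%s=%d", colnames(x$states), x$states[i, ]),
                      collapse = ", "),
                x$prob[i]))
  if (nrow(x$states) > n) cat("  ...\n")
  invisible(x)
}
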