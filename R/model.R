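# Reagent-centric model representation.
#
# A model is defined species-by-species: each species carries a list of
# (reaction, stoichiometry, role) terms, the reagent-centric view.  The
# reaction-centric view (reactants / products / modifiers / net change) is
# derived, never stored.

#' Species roles
#'
#' The four roles a species can play in a reaction, and their surface
#' operators in the text format: product `>>`, reactant `<<`, activator
#' (catalyst) `(+)`, inhibitor `(-)`.
#'
#' @format A named character vector mapping role tag to operator.
#' @export
bp_roles <- c(
  product   = ">>",
  reactant  = "<<",
  activator = "(+)",
  inhibitor = "(-)"
)

role_from_op <- function(op) names(bp_roles)[match(op, bp_roles)]

#' Construct a reagent-centric reaction-network model
#'
#' Builds and validates a `bp_model`: the container consumed by both the
#' deterministic (ODE) and stochastic (Gillespie) engines.
#'
#' @param parameters Named numeric vector of rate constants and other
#'   parameters.  Units follow reaction order: per time unit for
#'   unimolecular constants, per (molecule x time unit) for bimolecular.
#' @param behaviours Named list, one entry per species.  Each entry is a
#'   data frame with columns `reaction` (character), `coeff` (positive
#'   integer stoichiometry) and `role` (one of `names(bp_roles)`).
#' @param laws Named list, one entry per reaction, as produced by
#'   [bp_law()]: the kinetic law expression and, when the law is pure mass
#'   action, the name of its rate constant.
#' @param initial Named numeric vector of initial quantities, one per
#'   species (molecule counts for the stochastic engine, continuous
#'   quantities for the ODE engine).
#' @param constant_species Character vector of environment-held species:
#'   their quantity contributes to kinetic laws but never changes (net
#'   stoichiometry forced to zero).
#'
#' @return An object of class `bp_model`.
#' @seealso [parse_biopepa()], [build_mr_model()], [reaction_views()],
#'   [net_stoichiometry()]
#' @examples
#' m <- bp_model(
#'   parameters = c(c1 = 2),
#'   behaviours = list(X = data.frame(reaction = "decay", coeff = 1,
#'                                    role = "reactant")),
#'   laws = list(decay = bp_law("decay", quote(c1 * X), "c1")),
#'   initial = c(X = 5)
#' )
#' net_stoichiometry(m)
#' @export
bp_model <- function(parameters = numeric(), behaviours = list(),
                     laws = list(), initial = numeric(),
                     constant_species = character()) {
  behaviours <- lapply(behaviours, function(b) {
    if (is.data.frame(b) && "coeff" %in% names(b) &&
        all(b$coeff == round(b$coeff)))
      b$coeff <- as.integer(b$coeff)
    b
  })
  m <- structure(
    list(
      parameters = parameters,
      behaviours = behaviours,
      laws = laws,
      initial = initial,
      constant_species = constant_species
    ),
    class = "bp_model"
  )
  validate_bp_model(m)
}

#' Kinetic law
#'
#' @param reaction Reaction identifier the law belongs to.
#' @param expr Kinetic-law expression (an unevaluated R expression over
#'   parameter and species names, e.g. `quote(k1 * A * f)`).
#' @param mass_action_constant Name of the rate constant when the law is
#'   pure mass action, otherwise `NA`.  Pure mass-action laws are required
#'   by [scale_model()] and enable the fast stochastic path.
#' @return A list of class `bp_law`.
#' @export
bp_law <- function(reaction, expr, mass_action_constant = NA_character_) {
  stopifnot(is.character(reaction), length(reaction) == 1L)
  if (is.expression(expr)) expr <- expr[[1L]]
  structure(list(reaction = reaction, expr = expr,
                 mass_action_constant = mass_action_constant),
            class = "bp_law")
}

#' Species declared in a model
#' @param model A `bp_model`.
#' @return Character vector of species names, in declaration order.
#' @export
species_names <- function(model) names(model$behaviours)

#' Reactions declared in a model
#' @param model A `bp_model`.
#' @return Character vector of reaction names, in declaration order.
#' @export
reaction_names <- function(model) names(model$laws)

expr_identifiers <- function(e) {
  if (is.name(e)) return(as.character(e))
  if (is.call(e)) return(unique(unlist(lapply(as.list(e)[-1L], expr_identifiers))))
  character()
}

#' Validate a model
#'
#' Checks the structural invariants: unique (species, reaction) terms,
#' positive integer stoichiometry, a one-to-one match between reactions
#' named in behaviours and kinetic laws, initial quantities for exactly the
#' declared species, constant species among the declared species, and every
#' identifier in a law resolving to a parameter or species.
#'
#' @param model A `bp_model` candidate.
#' @return The model, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_bp_model <- function(model) {
  sp <- names(model$behaviours)
  if (length(sp) && anyDuplicated(sp))
    stop("duplicate species declaration: ", sp[duplicated(sp)][1L])

  for (s in sp) {
    b <- model$behaviours[[s]]
    if (!all(c("reaction", "coeff", "role") %in% names(b)))
      stop("behaviour of species '", s,
           "' must have columns reaction, coeff, role")
    key <- paste(b$reaction, b$role)
    if (anyDuplicated(key))
      stop("species '", s, "' has more than one '",
           b$role[duplicated(key)][1L], "' term for reaction '",
           b$reaction[duplicated(key)][1L], "'")
    if (any(b$coeff < 1) || any(b$coeff != round(b$coeff)))
      stop("stoichiometric coefficients of species '", s,
           "' must be positive integers")
    bad <- setdiff(b$role, names(bp_roles))
    if (length(bad)) stop("unknown role '", bad[1L], "' for species '", s, "'")
  }

  rx_behav <- unique(unlist(lapply(model$behaviours,
                                   function(b) as.character(b$reaction))))
  rx_laws <- names(model$laws)
  if (anyDuplicated(rx_laws))
    stop("duplicate kinetic law for reaction '",
         rx_laws[duplicated(rx_laws)][1L], "'")
  miss <- setdiff(rx_behav, rx_laws)
  if (length(miss))
    stop("no kinetic law for reaction '", miss[1L], "'")
  orphan <- setdiff(rx_laws, rx_behav)
  if (length(orphan))
    stop("kinetic law for reaction '", orphan[1L],
         "' but no species takes part in it")

  if (!setequal(names(model$initial), sp)) {
    miss <- setdiff(sp, names(model$initial))
    if (length(miss)) stop("missing initial quantity for species '", miss[1L], "'")
    stop("initial quantity for undeclared species '",
         setdiff(names(model$initial), sp)[1L], "'")
  }
  if (any(model$initial < 0))
    stop("negative initial quantity for species '",
         names(model$initial)[model$initial < 0][1L], "'")

  bad <- setdiff(model$constant_species, sp)
  if (length(bad))
    stop("constant species '", bad[1L], "' is not declared")

  known <- c(names(model$parameters), sp)
  for (r in rx_laws) {
    ids <- expr_identifiers(model$laws[[r]]$expr)
    bad <- setdiff(ids, known)
    if (length(bad))
      stop("kinetic law of '", r, "' references undeclared identifier '",
           bad[1L], "'")
    mac <- model$laws[[r]]$mass_action_constant
    if (!is.na(mac) && !mac %in% names(model$parameters))
      stop("mass-action constant '", mac, "' of reaction '", r,
           "' is not a declared parameter")
  }
  invisible(model)
}

#' @export
print.bp_model <- function(x, ...) {
  cat("Reagent-centric reaction network (bp_model)\n")
  cat("  species:   ", length(x$behaviours),
      " (", paste(species_names(x), collapse = ", "), ")\n", sep = "")
  cat("  reactions: ", length(x$laws),
      " (", paste(reaction_names(x), collapse = ", "), ")\n", sep = "")
  if (length(x$constant_species))
    cat("  constant (environment-held): ",
        paste(x$constant_species, collapse = ", "), "\n", sep = "")
  ma <- vapply(x$laws, function(l) !is.na(l$mass_action_constant), logical(1))
  cat("  kinetic laws: ", sum(ma), " mass action, ", sum(!ma), " general\n",
      sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# (M,R) instantiation

#' Parameters of the (M,R) model
#'
#' The twelve rate constants and seven initial molecule counts of the
#' compact (M,R) metabolism-replacement network.  Each of the three
#' enzymatic steps (A -> B catalysed by f; B -> f catalysed by p; f -> p
#' catalysed by B) is expanded into binding, unbinding and catalysis, with
#' rate constants (k1,k2,k3), (l1,l2,l3) and (m1,m2,m3) respectively;
#' d1, d2, d3 are first-order degradation constants for B, f and p.
#'
#' @param k1,k2,k3 Binding / unbinding / catalysis constants of the
#'   A + f step (A is held constant by the environment).
#' @param l1,l2,l3 Same for the B + p step.
#' @param m1,m2,m3 Same for the f + B step.
#' @param d1,d2,d3 Degradation constants of B, f and p.
#' @param A_init,B_init,f_init,p_init,fA_init,pB_init,Bf_init Initial
#'   molecule counts.
#' @return A named list of class `mr_params`.
#' @seealso [build_mr_model()], [mr_preset()]
#' @export
mr_params <- function(k1, k2, k3, l1, l2, l3, m1, m2, m3, d1, d2, d3,
                      A_init = 1000, f_init = 1000, B_init = 0, p_init = 0,
                      fA_init = 0, pB_init = 0, Bf_init = 0) {
  p <- list(k1 = k1, k2 = k2, k3 = k3, l1 = l1, l2 = l2, l3 = l3,
            m1 = m1, m2 = m2, m3 = m3, d1 = d1, d2 = d2, d3 = d3,
            A_init = A_init, B_init = B_init, f_init = f_init,
            p_init = p_init, fA_init = fA_init, pB_init = pB_init,
            Bf_init = Bf_init)
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1L && !is.na(v),
                logical(1))
  if (!all(num)) stop("non-numeric value for '", names(p)[!num][1L], "'")
  neg <- vapply(p, function(v) v < 0, logical(1))
  if (any(neg)) stop("negative value for '", names(p)[neg][1L], "'")
  structure(p, class = "mr_params")
}

# reaction-centric description of the (M,R) network; A is environment-held,
# so r_k1 consumes it only formally and r_k2 does not return it
mr_reaction_table <- function() {
  list(
    r_k1 = list(reactants = c(A = 1, f = 1),  products = c(fA = 1),        const = "k1"),
    r_k2 = list(reactants = c(fA = 1),        products = c(f = 1),         const = "k2"),
    r_k3 = list(reactants = c(fA = 1),        products = c(f = 1, B = 1),  const = "k3"),
    r_l1 = list(reactants = c(B = 1, p = 1),  products = c(pB = 1),        const = "l1"),
    r_l2 = list(reactants = c(pB = 1),        products = c(p = 1, B = 1),  const = "l2"),
    r_l3 = list(reactants = c(pB = 1),        products = c(p = 1, f = 1),  const = "l3"),
    r_m1 = list(reactants = c(f = 1, B = 1),  products = c(Bf = 1),        const = "m1"),
    r_m2 = list(reactants = c(Bf = 1),        products = c(B = 1, f = 1),  const = "m2"),
    r_m3 = list(reactants = c(Bf = 1),        products = c(B = 1, p = 1),  const = "m3"),
    r_d1 = list(reactants = c(B = 1),         products = numeric(),        const = "d1"),
    r_d2 = list(reactants = c(f = 1),         products = numeric(),        const = "d2"),
    r_d3 = list(reactants = c(p = 1),         products = numeric(),        const = "d3")
  )
}

mass_action_expr <- function(const, reactants) {
  e <- as.name(const)
  for (s in names(reactants))
    for (i in seq_len(reactants[[s]]))
      e <- call("*", e, as.name(s))
  e
}

#' Build the (M,R) model
#'
#' Assembles the seven-species, twelve-reaction mass-action network of the
#' compact (M,R) system: three enzymatic triples (substrate-enzyme binding,
#' unbinding, catalysis) closing the catalytic cycle f -> B -> p -> f, plus
#' first-order degradation of B, f and p.  The source species A is
#' environment-held: it multiplies the binding rate of the first step but
#' its quantity never changes.
#'
#' @param params An [mr_params()] object.
#' @return A validated `bp_model` with species A, B, f, p, fA, pB, Bf.
#' @examples
#' m <- build_mr_model(mr_preset("fig3")$params)
#' reaction_views(m)$r_l3
#' @export
build_mr_model <- function(params) {
  if (!inherits(params, "mr_params"))
    params <- do.call(mr_params, as.list(params))
  sp <- c("A", "B", "f", "p", "fA", "pB", "Bf")
  tab <- mr_reaction_table()

  behaviours <- setNames(lapply(sp, function(s) {
    rows <- lapply(names(tab), function(r) {
      out <- NULL
      if (s %in% names(tab[[r]]$reactants))
        out <- rbind(out, data.frame(reaction = r,
                                     coeff = tab[[r]]$reactants[[s]],
                                     role = "reactant"))
      if (s %in% names(tab[[r]]$products))
        out <- rbind(out, data.frame(reaction = r,
                                     coeff = tab[[r]]$products[[s]],
                                     role = "product"))
      out
    })
    do.call(rbind, rows)
  }), sp)

  laws <- setNames(lapply(names(tab), function(r) {
    bp_law(r, mass_action_expr(tab[[r]]$const, tab[[r]]$reactants),
           tab[[r]]$const)
  }), names(tab))

  consts <- unlist(params[c("k1", "k2", "k3", "l1", "l2", "l3",
                            "m1", "m2", "m3", "d1", "d2", "d3")])
  init <- c(A = params$A_init, B = params$B_init, f = params$f_init,
            p = params$p_init, fA = params$fA_init, pB = params$pB_init,
            Bf = params$Bf_init)

  bp_model(parameters = consts, behaviours = behaviours, laws = laws,
           initial = init, constant_species = "A")
}

# ---------------------------------------------------------------------------
# Derived reaction-centric views

#' Reaction-centric views of a model
#'
#' Switches from the reagent-centric declaration to the conventional
#' reaction-centric form: per reaction, its reactants, products, modifiers
#' and signed net stoichiometric change.  Environment-held (constant)
#' species enter the kinetic law but never the net change, so they are
#' reported among the modifiers with net change zero.
#'
#' @param model A `bp_model`.
#' @return A named list with one `bp_reaction_view` per reaction, each a
#'   list with elements `reaction`, `reactants`, `products`, `modifiers`,
#'   `net_change` and `law`.
#' @export
reaction_views <- function(model) {
  validate_bp_model(model)
  sp <- species_names(model)
  views <- lapply(reaction_names(model), function(r) {
    reactants <- numeric(); products <- numeric()
    modifiers <- character(); net <- numeric()
    for (s in sp) {
      b <- model$behaviours[[s]]
      i <- which(b$reaction == r)
      if (!length(i)) next
      is_const <- s %in% model$constant_species
      d <- 0
      for (j in i) {
        role <- b$role[j]; k <- b$coeff[j]
        if (role == "reactant") {
          d <- d - k
          if (!is_const) reactants[s] <- k
        } else if (role == "product") {
          d <- d + k
          if (!is_const) products[s] <- k
        } else {
          modifiers <- c(modifiers, s)
        }
      }
      if (is_const) {
        modifiers <- unique(c(modifiers, s))
        net[s] <- 0
      } else {
        net[s] <- d
      }
    }
    # a species that is both reactant and product with equal coefficients
    # still appears on both sides; its net change cancels to zero
    structure(list(reaction = r, reactants = reactants, products = products,
                   modifiers = unique(modifiers), net_change = net,
                   law = model$laws[[r]]),
              class = "bp_reaction_view")
  })
  setNames(views, reaction_names(model))
}

#' @export
print.bp_reaction_view <- function(x, ...) {
  fmt <- function(v) {
    if (!length(v)) return("0")
    paste(ifelse(v == 1, names(v), paste0(v, " ", names(v))), collapse = " + ")
  }
  cat(x$reaction, ": ", fmt(x$reactants), " -> ", fmt(x$products), sep = "")
  if (length(x$modifiers))
    cat("   [modifiers: ", paste(x$modifiers, collapse = ", "), "]", sep = "")
  cat("   rate: ", deparse(x$law$expr), "\n", sep = "")
  invisible(x)
}

#' Net stoichiometry matrix
#'
#' @param model A `bp_model`.
#' @return An integer species-by-reactions matrix of signed net
#'   stoichiometric changes; rows of constant species are identically zero.
#' @export
net_stoichiometry <- function(model) {
  validate_bp_model(model)
  sp <- species_names(model)
  rx <- reaction_names(model)
  S <- matrix(0L, length(sp), length(rx), dimnames = list(sp, rx))
  for (s in sp) {
    if (s %in% model$constant_species) next
    b <- model$behaviours[[s]]
    for (j in seq_len(nrow(b))) {
      if (b$role[j] == "product") S[s, b$reaction[j]] <- S[s, b$reaction[j]] + b$coeff[j]
      else if (b$role[j] == "reactant") S[s, b$reaction[j]] <- S[s, b$reaction[j]] - b$coeff[j]
    }
  }
  S
}

# ---------------------------------------------------------------------------
# Compiled internal form shared by both engines

# Per reaction: the multiset of rate-contributing species (reactants and
# activators, with multiplicity, constant species included) and the
# mass-action constant when the law is pure mass action.
rate_factors <- function(model, reaction) {
  out <- integer()
  for (s in species_names(model)) {
    b <- model$behaviours[[s]]
    i <- which(b$reaction == reaction & b$role %in% c("reactant", "activator"))
    if (length(i)) out[s] <- sum(b$coeff[i])
  }
  out
}

# detect a pure mass-action law in a parsed expression: a product chain of
# one declared parameter and species factors matching the reaction's
# rate-contributing multiset
detect_mass_action <- function(model, reaction) {
  law <- model$laws[[reaction]]
  if (!is.na(law$mass_action_constant)) return(law$mass_action_constant)
  flatten <- function(e) {
    if (is.call(e) && identical(e[[1L]], as.name("*")))
      return(c(flatten(e[[2L]]), flatten(e[[3L]])))
    list(e)
  }
  fac <- flatten(law$expr)
  if (!all(vapply(fac, is.name, logical(1)))) return(NA_character_)
  ids <- vapply(fac, as.character, character(1))
  pars <- ids[ids %in% names(model$parameters)]
  spf <- ids[ids %in% species_names(model)]
  if (length(pars) != 1L || length(spf) + 1L != length(ids)) return(NA_character_)
  want <- rate_factors(model, reaction)
  have <- table(spf)
  if (length(want) != length(have)) return(NA_character_)
  if (!setequal(names(want), names(have))) return(NA_character_)
  if (!all(want[names(have)] == as.integer(have))) return(NA_character_)
  pars
}

bp_compile <- function(model) {
  validate_bp_model(model)
  sp <- species_names(model)
  rx <- reaction_names(model)
  S <- net_stoichiometry(model)
  factors <- lapply(rx, function(r) rate_factors(model, r))
  mac <- vapply(rx, detect_mass_action, character(1), model = model)
  env <- list2env(as.list(model$parameters), parent = baseenv())
  exprs <- lapply(model$laws, `[[`, "expr")
  eval_laws <- function(state) {
    e <- list2env(as.list(state), parent = env)
    vapply(exprs, eval, numeric(1), envir = e)
  }
  list(species = sp, reactions = rx, S = S, factors = factors,
       mass_action_constant = mac,
       all_mass_action = !anyNA(mac),
       constants = if (!anyNA(mac)) unname(model$parameters[mac]) else NULL,
       eval_laws = eval_laws)
}
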