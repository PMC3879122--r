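# Shared fixtures and generators, all built in code.

fig3_model <- function() build_mr_model(mr_preset("fig3")$params)
fig6_model <- function() build_mr_model(mr_preset("fig6")$params)
fig7_model <- function() build_mr_model(mr_preset("fig7")$params)

# printed steady-state molecule counts of the live regime
fig3_printed_ss <- c(A = 1000, p = 577, B = 495, f = 286,
                     pB = 28, fA = 28, Bf = 14)

# single-reaction pure-death model X -> 0 at rate `c1`
decay_model <- function(c1 = 1, x0 = 1) {
  bp_model(
    parameters = c(c1 = c1),
    behaviours = list(X = data.frame(reaction = "decay", coeff = 1L,
                                     role = "reactant")),
    laws = list(decay = bp_law("decay", quote(c1 * X), "c1")),
    initial = c(X = x0)
  )
}

# miniature (M,R) instance small enough for exact CTMC analysis:
# A held at 2, one free enzyme molecule, all rate constants 1, no decay
tiny_mr_model <- function() {
  p <- mr_params(k1 = 1, k2 = 1, k3 = 1, l1 = 1, l2 = 1, l3 = 1,
                 m1 = 1, m2 = 1, m3 = 1, d1 = 0, d2 = 0, d3 = 0,
                 A_init = 2, f_init = 1)
  build_mr_model(p)
}

# random valid model for property-style tests (fixed RNG assumed by caller)
random_model <- function(n_species = NULL, n_reactions = NULL) {
  if (is.null(n_species)) n_species <- sample(2:5, 1)
  if (is.null(n_reactions)) n_reactions <- sample(1:6, 1)
  sp <- paste0("S", seq_len(n_species))
  rx <- paste0("r", seq_len(n_reactions))
  pars <- setNames(round(stats::runif(n_reactions, 0.01, 10), 3),
                   paste0("c", seq_len(n_reactions)))

  terms <- lapply(sp, function(s) NULL)
  names(terms) <- sp
  for (j in seq_along(rx)) {
    k <- sample(seq_len(n_species), sample(1:min(3, n_species), 1))
    roles <- sample(c("reactant", "product", "activator"), length(k),
                    replace = TRUE)
    roles[1] <- sample(c("reactant", "product"), 1)  # at least one real side
    for (q in seq_along(k)) {
      s <- sp[k[q]]
      terms[[s]] <- rbind(terms[[s]],
                          data.frame(reaction = rx[j],
                                     coeff = sample(1:2, 1),
                                     role = roles[q]))
    }
  }
  # species untouched by any reaction still need a behaviour entry: attach
  # them as activators of the first reaction
  for (s in sp)
    if (is.null(terms[[s]]))
      terms[[s]] <- data.frame(reaction = rx[1], coeff = 1L,
                               role = "activator")

  laws <- setNames(lapply(seq_along(rx), function(j) {
    e <- as.name(names(pars)[j])
    for (s in sp) {
      b <- terms[[s]]
      i <- which(b$reaction == rx[j] & b$role %in% c("reactant", "activator"))
      for (q in i)
        for (rep in seq_len(b$coeff[q])) e <- call("*", e, as.name(s))
    }
    bp_law(rx[j], e, names(pars)[j])
  }), rx)

  const <- if (stats::runif(1) < 0.3) sample(sp, 1) else character()
  bp_model(parameters = pars, behaviours = terms, laws = laws,
           initial = setNames(sample(0:20, n_species, replace = TRUE), sp),
           constant_species = const)
}

# structural equality of two models (ignores internal storage order of
# nothing: order is part of the canonical form)
expect_model_equal <- function(a, b) {
  expect_identical(species_names(a), species_names(b))
  expect_identical(reaction_names(a), reaction_names(b))
  expect_equal(a$parameters, b$parameters)
  expect_equal(a$initial, b$initial)
  expect_identical(a$constant_species, b$constant_species)
  for (s in species_names(a)) {
    ba <- a$behaviours[[s]]; bb <- b$behaviours[[s]]
    rownames(ba) <- rownames(bb) <- NULL
    expect_equal(ba, bb, ignore_attr = TRUE)
  }
  for (r in reaction_names(a))
    expect_identical(deparse(a$laws[[r]]$expr), deparse(b$laws[[r]]$expr))
}
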