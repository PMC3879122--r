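test_that("the (M,R) model has the expected network structure", {
  m <- fig3_model()
  expect_length(species_names(m), 7)
  expect_length(reaction_names(m), 12)
  expect_setequal(species_names(m), c("A", "B", "f", "p", "fA", "pB", "Bf"))
  expect_identical(m$constant_species, "A")
  # every kinetic law is pure mass action
  mac <- vapply(m$laws, function(l) l$mass_action_constant, character(1))
  expect_false(anyNA(mac))

  v <- reaction_views(m)
  # catalysis step of the B + p triple: pB is the only reactant, both the
  # enzyme p and the product f are released
  expect_equal(v$r_l3$reactants, c(pB = 1))
  expect_mapequal(v$r_l3$products, c(p = 1, f = 1))
  # the source A multiplies the binding rate but is never consumed
  expect_true("A" %in% v$r_k1$modifiers)
  expect_true("A" %in% all.vars(v$r_k1$law$expr))
  expect_equal(v$r_k1$reactants, c(f = 1))
  expect_equal(v$r_k1$net_change[["f"]], -1)
  expect_equal(v$r_k1$net_change[["fA"]], 1)
  expect_equal(v$r_k1$net_change[["A"]], 0)
})

test_that("the environment-held source has zero net change in all reactions", {
  S <- net_stoichiometry(fig3_model())
  expect_equal(unname(S["A", ]), rep(0L, 12))
  for (v in reaction_views(fig3_model()))
    if ("A" %in% names(v$net_change)) expect_equal(v$net_change[["A"]], 0)
})

test_that("net stoichiometry columns match the reaction list", {
  S <- net_stoichiometry(fig3_model())
  expect_identical(dim(S), c(7L, 12L))
  # catalysis of the f + B triple: Bf -> B + p
  col <- S[, "r_m3"]
  expect_equal(col[["Bf"]], -1L)
  expect_equal(col[["B"]], 1L)
  expect_equal(col[["p"]], 1L)
  expect_equal(sum(col != 0L), 3L)
  # degradation of f: f -> nothing
  expect_equal(S[, "r_d2"], c(A = 0L, B = 0L, f = -1L, p = 0L,
                              fA = 0L, pB = 0L, Bf = 0L))
  # an empty model has an empty matrix
  empty <- bp_model()
  expect_identical(dim(net_stoichiometry(empty)), c(0L, 0L))
})

test_that("degradation-free parameters still build all 12 reactions", {
  p <- mr_preset("fig3")$params
  p$d1 <- p$d2 <- p$d3 <- 0
  m <- build_mr_model(p)
  expect_length(reaction_names(m), 12)
  a <- propensities(m, c(A = 1000, B = 5, f = 5, p = 5, fA = 1, pB = 1, Bf = 1))
  expect_equal(unname(a[c("r_d1", "r_d2", "r_d3")]), c(0, 0, 0))
})

test_that("negative rate constants are rejected with the offending name", {
  expect_error(mr_params(k1 = 0.01, k2 = 100, k3 = 1, l1 = 0.01, l2 = 100,
                         l3 = 1, m1 = 0.01, m2 = 100, m3 = -1, d1 = 0,
                         d2 = 0.05, d3 = 0.02426),
               "m3")
  expect_error(mr_params(k1 = 0.01, k2 = 100, k3 = 1, l1 = 0.01, l2 = 100,
                         l3 = 1, m1 = 0.01, m2 = 100, m3 = 1, d1 = 0,
                         d2 = 0.05, d3 = 0.02426, f_init = -5),
               "f_init")
})

test_that("model validation rejects inconsistent declarations", {
  b <- list(X = data.frame(reaction = "r1", coeff = 1L, role = "reactant"))
  law <- list(r1 = bp_law("r1", quote(c1 * X), "c1"))
  # missing kinetic law names the reaction
  expect_error(bp_model(c(c1 = 1), b, laws = list(), initial = c(X = 1)),
               "r1")
  # law for a reaction no species takes part in
  expect_error(bp_model(c(c1 = 1), b,
                        laws = c(law, list(r2 = bp_law("r2", quote(c1 * X), "c1"))),
                        initial = c(X = 1)),
               "r2")
  # undeclared identifier in a law
  expect_error(bp_model(c(c1 = 1), b,
                        laws = list(r1 = bp_law("r1", quote(c9 * X))),
                        initial = c(X = 1)),
               "c9")
  # missing initial quantity
  expect_error(bp_model(c(c1 = 1), b, law, initial = numeric()), "X")
  # constant species must be declared
  expect_error(bp_model(c(c1 = 1), b, law, initial = c(X = 1),
                        constant_species = "Y"),
               "Y")
  # non-integer stoichiometry
  b2 <- list(X = data.frame(reaction = "r1", coeff = 0.5, role = "reactant"))
  expect_error(bp_model(c(c1 = 1), b2, law, initial = c(X = 1)),
               "positive integer")
})

test_that("a species on both sides of a reaction cancels in the net change", {
  m <- bp_model(
    parameters = c(c1 = 1),
    behaviours = list(
      X = data.frame(reaction = "r1", coeff = c(1L, 1L),
                     role = c("reactant", "product")),
      Y = data.frame(reaction = "r1", coeff = 1L, role = "product")),
    laws = list(r1 = bp_law("r1", quote(c1 * X), "c1")),
    initial = c(X = 3, Y = 0))
  v <- reaction_views(m)$r1
  expect_equal(v$net_change[["X"]], 0)
  expect_equal(v$net_change[["Y"]], 1)
  expect_equal(net_stoichiometry(m)["X", "r1"], 0L)
})

test_that("reaction views and the stoichiometry matrix agree on random models", {
  set.seed(401)
  for (i in 1:20) {
    m <- random_model()
    S <- net_stoichiometry(m)
    views <- reaction_views(m)
    for (r in reaction_names(m)) {
      nc <- views[[r]]$net_change
      for (s in species_names(m)) {
        expected <- if (s %in% names(nc)) nc[[s]] else 0
        expect_equal(unname(S[s, r]), expected)
      }
    }
  }
})
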