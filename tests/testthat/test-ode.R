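test_that("the initial derivative of the live regime is pure binding", {
  m <- fig3_model()
  r <- ode_rhs(m, m$initial)
  # only A + f -> fA can fire: fA grows at k1*A*f = 0.01*1000*1000, f is
  # consumed by it and by its own degradation d2*f
  expect_equal(unname(r[["fA"]]), 10000)
  expect_equal(unname(r[["f"]]), -10000 - 0.05 * 1000)
  expect_equal(unname(r[c("A", "B", "p", "pB", "Bf")]), rep(0, 5))
})

test_that("the all-exhausted state is absorbing for the ODE too", {
  m <- fig3_model()
  st <- c(A = 1000, B = 0, f = 0, p = 0, fA = 0, pB = 0, Bf = 0)
  expect_equal(unname(ode_rhs(m, st)), rep(0, 7))
})

test_that("rhs equals stoichiometry times law values on random states", {
  set.seed(403)
  m <- fig3_model()
  S <- net_stoichiometry(m)
  env <- as.list(m$parameters)
  for (i in 1:10) {
    st <- setNames(stats::runif(7, 0, 500), species_names(m))
    # independent evaluation: substitute into each law expression directly
    laws <- vapply(reaction_names(m), function(r)
      eval(m$laws[[r]]$expr, c(env, as.list(st))), numeric(1))
    expect_equal(ode_rhs(m, st), drop(S %*% laws))
  }
  expect_error(ode_rhs(m, c(A = 1, B = 2)), "missing species")
})

test_that("the printed steady state has small residuals relative to flux", {
  m <- fig3_model()
  st <- c(A = 1000, p = 577, B = 495, f = 286, pB = 28, fA = 28, Bf = 14)
  r <- ode_rhs(m, st)
  # per-species largest one-way flux at this state
  laws <- vapply(reaction_names(m), function(rx)
    eval(m$laws[[rx]]$expr, c(as.list(m$parameters), as.list(st))), numeric(1))
  S <- net_stoichiometry(m)
  for (s in setdiff(species_names(m), "A")) {
    gross <- max(abs(S[s, ] * laws))
    expect_lt(abs(r[[s]]), 0.02 * gross)
  }
})

test_that("ODE trajectory and steady-state finder agree on the live regime", {
  m <- fig3_model()
  tr <- simulate_ode(m, t_end = 1000, n_points = 200)
  ss <- find_steady_state(m)
  expect_true(ss$converged)
  expect_lte(ss$residual_norm, 1e-4)
  final <- tr$series[nrow(tr$series), ]
  expect_true(all(abs(final - ss$counts[names(final)]) < 1))
  # paper presentation: integer counts
  expect_equal(unname(ss$counts_rounded[names(fig3_printed_ss)]),
               unname(fig3_printed_ss))
})

test_that("a rate-free model never moves and converges at t = 0", {
  p <- mr_preset("fig3")$params
  for (nm in c("k1","k2","k3","l1","l2","l3","m1","m2","m3","d1","d2","d3"))
    p[[nm]] <- 0
  m <- build_mr_model(p)
  tr <- simulate_ode(m, t_end = 10, n_points = 5)
  for (s in species_names(m))
    expect_equal(unname(tr$series[, s]), rep(m$initial[[s]], 6))
  ss <- find_steady_state(m)
  expect_true(ss$converged)
  expect_equal(ss$t_reached, 0)
  expect_equal(ss$counts, m$initial[names(ss$counts)])
})

test_that("raising f degradation to 0.07 abolishes the live steady state", {
  tr <- simulate_ode(fig6_model(), t_end = 1000, n_points = 100)
  final <- tr$series[nrow(tr$series), ]
  rel <- abs(final[c("f", "B", "p")] - fig3_printed_ss[c("f", "B", "p")]) /
    fig3_printed_ss[c("f", "B", "p")]
  expect_gt(max(rel), 0.10)
})

test_that("the constant species never moves in the ODE semantics", {
  for (nm in c("fig3", "fig7")) {
    tr <- simulate_ode(build_mr_model(mr_preset(nm)$params),
                       t_end = 50, n_points = 50)
    expect_equal(unname(tr$series[, "A"]), rep(1000, 51))
  }
})

test_that("volume scaling rescales constants by reaction order", {
  m <- fig3_model()
  ms <- scale_model(m, 1e4)
  # bimolecular constants divided by the factor, all others untouched
  expect_equal(ms$parameters[["k1"]], 1e-6)
  expect_equal(ms$parameters[["l1"]], 1e-6)
  expect_equal(ms$parameters[["m1"]], 1e-6)
  for (nm in c("k2", "k3", "l2", "l3", "m2", "m3", "d1", "d2", "d3"))
    expect_equal(ms$parameters[[nm]], m$parameters[[nm]])
  expect_equal(ms$initial[["A"]], 1e7)
  expect_equal(ms$initial[["f"]], 1e7)
  # identity at factor 1
  expect_equal(scale_model(m, 1)$parameters, m$parameters)
  expect_equal(scale_model(m, 1)$initial, m$initial)
})

test_that("scaled dynamics are exactly the unscaled dynamics magnified", {
  m <- fig3_model()
  f <- 10
  tr1 <- simulate_ode(m, t_end = 200, n_points = 50)
  tr2 <- simulate_ode(scale_model(m, f), t_end = 200, n_points = 50)
  expect_equal(tr2$series, tr1$series * f, tolerance = 1e-6)
})

test_that("scaling refuses laws it cannot interpret", {
  m <- parse_biopepa("
    vmax = 10;
    km = 5;
    kineticLawOf uptake : vmax * S / (km + S);
    S = (uptake, 1) <<;
    S[20]
  ")
  expect_error(scale_model(m, 10), "mass-action")
})
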