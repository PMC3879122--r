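test_that("mass-action propensities follow the combinatorial form", {
  m <- fig3_model()
  a <- propensities(m, m$initial)
  expect_equal(unname(a[["r_k1"]]), 10000)  # 0.01 * 1000 * 1000
  expect_equal(unname(a[["r_d2"]]), 50)     # 0.05 * 1000
  expect_equal(unname(a[setdiff(names(a), c("r_k1", "r_d2"))]), rep(0, 10))

  # exhausted mobile species: every propensity zero (deadlock state)
  dead <- c(A = 1000, B = 0, f = 0, p = 0, fA = 0, pB = 0, Bf = 0)
  expect_equal(unname(propensities(m, dead)), rep(0, 12))

  expect_error(propensities(m, c(A = 1000, B = -1, f = 0, p = 0, fA = 0,
                                 pB = 0, Bf = 0)),
               "negative")

  # a doubled reactant counts ordered pairs: n * (n - 1)
  dimer <- bp_model(
    parameters = c(c1 = 2),
    behaviours = list(X = data.frame(reaction = "dim", coeff = 2L,
                                     role = "reactant"),
                      Y = data.frame(reaction = "dim", coeff = 1L,
                                     role = "product")),
    laws = list(dim = bp_law("dim", quote(c1 * X * X), "c1")),
    initial = c(X = 5, Y = 0))
  expect_equal(unname(propensities(dimer, c(X = 5, Y = 0))[["dim"]]), 2 * 5 * 4)
  expect_equal(unname(propensities(dimer, c(X = 1, Y = 0))[["dim"]]), 0)
})

test_that("total propensity at the steady state matches the ODE fluxes", {
  m <- fig3_model()
  st <- round(find_steady_state(m)$counts)
  a <- propensities(m, st)
  laws <- vapply(reaction_names(m), function(r)
    eval(m$laws[[r]]$expr, c(as.list(m$parameters), as.list(st))), numeric(1))
  expect_equal(sum(a), sum(abs(laws)), tolerance = 1e-10)
})

test_that("identical seeds give bit-identical trajectories", {
  m <- fig3_model()
  r1 <- ssa_simulate(m, t_end = 2, seed = 7, n_points = 40)
  r2 <- ssa_simulate(m, t_end = 2, seed = 7, n_points = 40)
  expect_identical(r1$trajectory$series, r2$trajectory$series)
  r3 <- ssa_simulate(m, t_end = 2, seed = 8, n_points = 40)
  expect_false(identical(r1$trajectory$series, r3$trajectory$series))
})

test_that("states stay non-negative integers and A never moves", {
  m <- fig3_model()
  res <- ssa_simulate(m, t_end = 5, seed = 11, n_points = 200)
  s <- res$trajectory$series
  expect_true(all(s >= 0))
  expect_true(all(s == round(s)))
  expect_equal(unname(s[, "A"]), rep(1000, nrow(s)))
})

test_that("non-integer initial counts are rejected for the stochastic engine", {
  m <- fig3_model()
  m$initial[["f"]] <- 10.5
  expect_error(ssa_simulate(m, t_end = 1, seed = 1), "integer")
})

test_that("an empty-propensity start is immediate extinction", {
  p <- mr_preset("fig3")$params
  p$f_init <- 0  # nothing can bind, nothing can degrade
  m <- build_mr_model(p)
  res <- ssa_simulate(m, t_end = 10, seed = 3, n_points = 10)
  expect_true(res$extinction$extinct)
  expect_equal(res$extinction$t_extinct, 0)
  # extinction is absorbing: the recorded series never changes
  expect_equal(unname(res$trajectory$series[, "f"]), rep(0, 11))

  # a model with no reactions at all is dead at t = 0
  empty <- bp_model(parameters = c(c1 = 1),
                    behaviours = list(X = data.frame(reaction = character(),
                                                     coeff = integer(),
                                                     role = character())),
                    laws = list(), initial = c(X = 5))
  ep <- extinction_probability(empty, n_reps = 5, t_end = 1, base_seed = 1)
  expect_equal(ep$fraction, 1)
})

test_that("single-molecule decay dies like an exponential clock", {
  c1 <- 0.8; t_end <- 1
  m <- decay_model(c1 = c1, x0 = 1)
  ep <- extinction_probability(m, n_reps = 400, t_end = t_end, base_seed = 500)
  p_true <- 1 - exp(-c1 * t_end)
  # within the 95% Wilson interval of the empirical fraction
  expect_gte(p_true, ep$ci[["lower"]])
  expect_lte(p_true, ep$ci[["upper"]])
})

test_that("the live regime survives the full horizon in stochastic runs", {
  m <- fig3_model()
  ep <- extinction_probability(m, n_reps = 20, t_end = 1000, base_seed = 300)
  expect_lt(ep$fraction, 0.2)
})

test_that("averaging replicates is a pointwise mean with LVCF resampling", {
  m <- fig3_model()
  r1 <- ssa_simulate(m, t_end = 2, seed = 21, n_points = 20)$trajectory
  # averaging a trajectory with itself returns itself
  avg <- average_trajectories(list(r1, r1))
  expect_equal(avg$series, r1$series)
  expect_equal(avg$meta$n_averaged, 2)

  # constant trajectories average to the mean of their levels
  mk <- function(v) new_trajectory <- structure(
    list(times = 0:5,
         series = matrix(v, 6, 2, dimnames = list(NULL, c("X", "Y"))),
         meta = list(engine = "ssa")), class = "bp_trajectory")
  avg2 <- average_trajectories(list(mk(1), mk(2), mk(6)))
  expect_equal(unname(avg2$series[, "X"]), rep(3, 6))

  expect_error(average_trajectories(list()), "empty")
  bad <- structure(list(times = 0:5,
                        series = matrix(0, 6, 1,
                                        dimnames = list(NULL, "Z")),
                        meta = list(engine = "ssa")),
                   class = "bp_trajectory")
  expect_error(average_trajectories(list(r1, bad)), "mismatched")
})

test_that("ten averaged replicates land on the deterministic steady state", {
  m <- fig3_model()
  trs <- lapply(1:10, function(s)
    ssa_simulate(m, t_end = 1000, seed = 100 + s, n_points = 100)$trajectory)
  avg <- average_trajectories(trs)
  ss <- find_steady_state(m)
  fin <- avg$series[nrow(avg$series), ]
  # single-run fluctuations are ~sqrt(count); the mean of 10 shrinks them
  for (s in c("B", "f", "p")) {
    se <- stats::sd(vapply(trs, function(tr)
      tr$series[nrow(tr$series), s], numeric(1))) / sqrt(10)
    expect_lt(abs(fin[[s]] - ss$counts[[s]]), 3 * max(se, 1))
  }
  # the average is smoother than a single run: smaller mean step-to-step jump
  jump <- function(x) mean(abs(diff(x[, "B"])))
  expect_lt(jump(avg$series[50:101, , drop = FALSE]),
            jump(trs[[1]]$series[50:101, , drop = FALSE]))
})
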