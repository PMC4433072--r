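test_that("Michaelis-Menten rate matches its closed form and limits", {
  expect_equal(mm_rate(1, 1, kcat = 2, km = 1), 1.0)
  expect_equal(mm_rate(0, 5, kcat = 2, km = 1), 0.0)
  # saturation limit kcat * e
  expect_equal(mm_rate(3, 1e6, kcat = 1, km = 1), 3.0, tolerance = 1e-5)
  expect_error(mm_rate(-1, 1, 1, 1), "non-negative")
  expect_error(mm_rate(1, 1, 0, 1), "strictly positive")
})

test_that("rate is monotone in enzyme, substrate and turnover", {
  set.seed(11)
  for (i in 1:50) {
    e <- runif(1, 0, 3); s <- runif(1, 0, 3)
    kcat <- runif(1, 0.1, 3); km <- runif(1, 0.1, 3)
    eps <- 1e-3
    v <- mm_rate(e, s, kcat, km)
    expect_gte(mm_rate(e + eps, s, kcat, km), v)
    expect_gte(mm_rate(e, s + eps, kcat, km), v)
    expect_gte(mm_rate(e, s, kcat + eps, km), v)
  }
})

test_that("competitive inhibition reduces to the plain rate and bounds it", {
  # no inhibitor: identical
  expect_equal(inhibited_mm_rate(2, 1.5, p = 0, kcat = 1.2, km = 0.7,
                                 kr = 3),
               mm_rate(2, 1.5, kcat = 1.2, km = 0.7))
  expect_equal(inhibited_mm_rate(1, 1, p = 1, kcat = 1, km = 1, kr = 1),
               1 / 3)
  # vanishing inhibition strength
  expect_equal(inhibited_mm_rate(1, 1, p = 1, kcat = 1, km = 1, kr = 1e12),
               mm_rate(1, 1, 1, 1), tolerance = 1e-9)
  expect_error(inhibited_mm_rate(1, 1, 1, 1, 1, kr = 0), "positive")
  expect_error(inhibited_mm_rate(1, 1, 1, 1, 1, kr = Inf), "finite")

  # randomized property: inhibited rate never exceeds the plain rate and
  # is monotone in p (decreasing) and kr (increasing)
  set.seed(12)
  for (i in 1:100) {
    e <- runif(1, 0, 3); s <- runif(1, 0, 3); p <- runif(1, 0, 3)
    kcat <- runif(1, 0.1, 2); km <- runif(1, 0.1, 2); kr <- runif(1, 0.1, 5)
    vi <- inhibited_mm_rate(e, s, p, kcat, km, kr)
    expect_lte(vi, mm_rate(e, s, kcat, km) + 1e-12)
    expect_lte(inhibited_mm_rate(e, s, p + 0.5, kcat, km, kr), vi + 1e-12)
    expect_gte(inhibited_mm_rate(e, s, p, kcat, km, kr + 0.5), vi - 1e-12)
  }
})

test_that("two independent inhibitors add in the denominator", {
  v <- inhibited_mm_rate(1, 1, p = c(1, 2), kcat = 1, km = 1, kr = c(1, 2))
  expect_equal(v, 1 / (1 + 1 * (1 + 1 + 1)))
})

test_that("mass balances vanish at a consistent steady state", {
  topo <- build_topology("linear", "none")
  set.seed(4)
  smp <- sample_parameters(topo)
  inter <- topology_intermediates(topo)
  lv <- c(S = 1, stats::setNames(rep(0.6, 4), inter), P = 1)
  e <- steady_state_enzymes(topo, smp$params, c(P = 0.5), lv)
  d <- rhs(topo, smp$params, e, c(v_growth = 0.5), lv, drain = "demand")
  expect_lt(max(abs(d)), 1e-10)
  # first-order drain: dilution = flux / p makes the same state steady
  d2 <- rhs(topo, smp$params, e, c(v_growth = 0.5 / 1), lv,
            drain = "dilution")
  expect_lt(max(abs(d2)), 1e-10)
})

test_that("steady-state enzyme inversion matches hand calculations", {
  topo <- toy_topology()
  par <- kinetic_params(c(e1 = 2, e2 = 2), c(e1 = 1, e2 = 1))
  lv <- c(S = 1, X1 = 1, P = 1)
  e <- steady_state_enzymes(topo, par, 1, lv)
  expect_equal(unname(e), c(1, 1))  # invert 2e/2 = 1
  expect_equal(unname(steady_state_enzymes(topo, par, 0, lv)), c(0, 0))
  # inhibited first step: apparent Km tripled at p = kr = 1
  topoI <- build_topology("linear", "initial")
  parI <- kinetic_params(stats::setNames(rep(1, 5), paste0("e", 1:5)),
                         stats::setNames(rep(1, 5), paste0("e", 1:5)),
                         c("P->e1" = 1))
  lvI <- c(S = 1, X1 = 1, X2 = 1, X3 = 1, X4 = 1, P = 1)
  eI <- steady_state_enzymes(topoI, parI, 1, lvI)
  expect_equal(unname(eI["e1"]), 3)
  expect_error(steady_state_enzymes(topo, par, 1, c(S = 0, X1 = 1, P = 1)),
               "positive")
})

test_that("converging steady state splits supply equally across branches", {
  topo <- build_topology("converging", "none")
  enz <- topo$reactions$enzyme
  par <- kinetic_params(stats::setNames(rep(1, 6), enz),
                        stats::setNames(rep(1, 6), enz))
  lv <- c(S1 = 1, S2 = 1, X1 = 0.5, X2 = 0.5, X3 = 0.5, X4 = 0.5, P = 1)
  e <- steady_state_enzymes(topo, par, c(P = 0.4), lv)
  d <- rhs(topo, par, e, c(v_growth = 0.4), lv)
  expect_lt(max(abs(d)), 1e-12)
  # both supply branches carry half the demand
  expect_equal(unname(e["e1"]), unname(e["e3"]))
})

test_that("buffered substrates have zero derivative for any fluxes", {
  topo <- build_topology("converging", "none")
  set.seed(9)
  smp <- sample_parameters(topo)
  mets <- topology_metabolites(topo)
  state <- stats::setNames(runif(length(mets), 0.1, 1), mets)
  e <- stats::setNames(runif(6, 0, 2), topo$reactions$enzyme)
  d <- rhs(topo, smp$params, e, c(v_growth = 0.5), state)
  expect_equal(unname(d[topo$buffered]), c(0, 0))
  expect_error(rhs(topo, smp$params, e, c(v_growth = 0.5), state[-1]),
               "metabolites")
})

test_that("rhs agrees with the finite difference of an integrated path", {
  topo <- build_topology("linear", "initial")
  set.seed(21)
  smp <- sample_parameters(topo)
  mets <- topology_metabolites(topo)
  state <- stats::setNames(runif(length(mets), 0.2, 0.9), mets)
  state["S"] <- 1
  e <- stats::setNames(runif(5, 0.2, 1.5), paste0("e", 1:5))
  dil <- c(v_growth = 0.4)
  h <- 1e-3
  out <- desolve_trajectory(topo, smp$params, e, dil, state, c(0, h, 2 * h))
  # second-order one-sided difference of the integrated trajectory
  fd <- (4 * out[2, -1] - out[3, -1] - 3 * out[1, -1]) / (2 * h)
  expect_equal(unname(fd),
               unname(rhs(topo, smp$params, e, dil, state)),
               tolerance = 1e-6)
})

test_that("dilution profiles evaluate piecewise-constantly", {
  dp <- dilution_profile(c(0, 15, 30), rbind(v_growth = c(0.3, 0.6)))
  expect_equal(as.numeric(dilution_at(dp, c(0, 14.9, 15, 30))),
               c(0.3, 0.3, 0.6, 0.6))
  expect_error(dilution_profile(c(0, 30), rbind(c(0.2, 0.4))), "ncol")
})
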