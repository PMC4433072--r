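test_that("a steady-state-consistent constant program stays put", {
  prob <- make_linear_problem(5, d = c(0.45, 0.45))
  topo <- prob$topology
  inter <- topology_intermediates(topo)
  lv <- c(S = 1, stats::setNames(rep(0.5, 4), inter), P = 1)
  e0 <- steady_state_enzymes(topo, prob$params, c(P = 0.45), lv)
  ctl <- control_param(matrix(rep(e0, each = 9), 9,
                              dimnames = list(NULL, names(e0))), 30)
  sim <- simulate_pathway(prob, ctl)
  expect_lt(max(abs(sim$states[, "P"] - 1)), 1e-6)
  expect_lt(max(abs(sweep(sim$states[, inter], 2, 0.5))), 1e-6)
  expect_equal(sim$max_violation, 0, tolerance = 1e-10)
})

test_that("the dense reporting grid has at least 20 rho points", {
  prob <- make_linear_problem(5)
  ctl <- control_param(matrix(0.5, 9, 5,
                              dimnames = list(NULL, paste0("e", 1:5))), 30)
  sim <- simulate_pathway(prob, ctl)
  expect_gte(length(sim$times), 20 * prob$rho)
})

test_that("halving the integration step leaves the objective unchanged", {
  # the cost/effort components are closed-form in the controls, so they
  # must be integration-step independent to machine precision
  prob <- make_linear_problem(7)
  set.seed(7)
  ctl <- control_param(matrix(runif(45, 0, 2), 9, 5,
                              dimnames = list(NULL, paste0("e", 1:5))), 30)
  s0 <- simulate_pathway(prob, ctl, n_sub = 2L)
  s1 <- simulate_pathway(prob, ctl, n_sub = 4L)
  s2 <- simulate_pathway(prob, ctl, n_sub = 8L)
  expect_equal(s0$objective$J_reg, s2$objective$J_reg, tolerance = 1e-12)
  # trajectories converge as the step shrinks (order drops near the
  # saturating drain when a pool runs empty, so only monotonicity and a
  # coarse bound are asserted)
  d1 <- max(abs(s0$states - s1$states))
  d2 <- max(abs(s1$states - s2$states))
  expect_lt(d2, d1)
  expect_lt(d2, 0.02)
})

test_that("constraint violations are flagged with the right component", {
  prob <- make_linear_problem(5, d = c(0.45, 0.45))
  # an absurdly large first enzyme floods the first intermediate
  nodes <- matrix(rep(c(15, 0.3, 0.3, 0.3, 0.3), each = 9), 9,
                  dimnames = list(NULL, paste0("e", 1:5)))
  sim <- simulate_pathway(prob, control_param(nodes, 30))
  expect_gt(sim$violations[["intermediate_cap"]], 0)
  expect_gt(max(sim$states[, "X1"]), prob$bounds$x_max)
})

test_that("metabolite trajectories stay non-negative under extreme inputs", {
  prob <- make_linear_problem(8, d = c(0.8, 0.8))
  # starving program: no enzymes at all, prescribed demand keeps draining
  nodes <- matrix(0, 9, 5, dimnames = list(NULL, paste0("e", 1:5)))
  sim <- simulate_pathway(prob, control_param(nodes, 30))
  expect_true(all(sim$states >= 0))
  # the product pool empties toward zero but never crosses it
  expect_lt(min(sim$states[, "P"]), prob$bounds$p_lo)
})

test_that("adjoint gradients match central finite differences", {
  for (seed in c(13, 14)) {
    prob <- make_linear_problem(seed,
                                inhibition = if (seed %% 2) "initial"
                                             else "none")
    spec <- pathreg:::.ocp_spec(prob, n_dense = 40, n_sub = 1L)
    set.seed(seed)
    n <- spec$n_enz * (1 + spec$rho)
    x <- c(runif(spec$n_enz, 0.2, 2), runif(n - spec$n_enz, -0.2, 0.2))
    g <- pathreg:::ocp_penalized_agrad_cpp(x, spec, 1e4)
    g_fd <- vapply(seq_len(n), function(i) {
      h <- 1e-6
      xp <- x; xp[i] <- x[i] + h
      xm <- x; xm[i] <- x[i] - h
      (pathreg:::ocp_penalized_cpp(xp, spec, 1e4) -
         pathreg:::ocp_penalized_cpp(xm, spec, 1e4)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - g_fd)) / max(1, max(abs(g_fd))), 1e-6)
  }
})
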