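test_that("constant demand requires no regulation", {
  prob <- make_linear_problem(3, d = c(0.5, 0.5))
  sol <- solve_ocp(prob, seed = 1, budget = 5e3, maxit = 150)
  expect_true(sol$feasible)
  expect_lte(sol$J_reg, 1e-4)
  # enzyme programs stay flat
  expect_lt(max(abs(sweep(sol$control$nodes, 2,
                          sol$control$nodes[1, ]))), 1e-3)
})

test_that("solutions are deterministic given the seed", {
  prob <- make_linear_problem(6)
  s1 <- solve_ocp(prob, seed = 42, budget = 5e3, maxit = 100)
  s2 <- solve_ocp(prob, seed = 42, budget = 5e3, maxit = 100)
  expect_identical(s1$decision, s2$decision)
  expect_identical(s1$J, s2$J)
})

test_that("doubling the budget never worsens the objective", {
  for (seed in c(2, 6)) {
    prob <- make_linear_problem(seed)
    J <- vapply(c(5e3, 1e4, 2e4), function(b) {
      solve_ocp(prob, seed = 9, budget = b, maxit = 80)$J
    }, numeric(1))
    expect_true(all(diff(J) <= 1e-9))
  }
})

test_that("the objective decomposition holds for returned solutions", {
  prob <- make_linear_problem(6, sigma = 0.7)
  sol <- solve_ocp(prob, seed = 3, budget = 5e3, maxit = 100)
  expect_equal(sol$J, 0.7 * sol$J_cost + sol$J_reg,
               tolerance = 1e-9)
  expect_equal(unname(sol$cost), unname(sol$control$nodes[1, ] * 30),
               tolerance = 1e-12)
  expect_true(all(sol$reg >= 0))
})

test_that("finite rate bounds are satisfied by construction", {
  prob <- make_linear_problem(4, m = 0.05)
  sol <- solve_ocp(prob, seed = 2, budget = 5e3, maxit = 100)
  chk <- check_rate_constraint(sol$control, 0.05)
  expect_true(chk$ok)
})

test_that("feasible solutions respect the path constraints on re-check", {
  prob <- make_linear_problem(10)
  sol <- solve_ocp(prob, seed = 4, budget = 1e4, maxit = 200)
  if (sol$feasible) {
    sim <- simulate_pathway(prob, sol$control, sol$x0)
    expect_lte(sim$max_violation, 1e-4)
    p <- sim$states[, "P"]
    expect_true(all(p >= prob$bounds$p_lo - 1e-4))
    expect_true(all(p <= prob$bounds$p_hi + 1e-4))
  } else {
    succeed("sampled instance infeasible; acceptance covered elsewhere")
  }
})

test_that("the solver matches a brute-force grid oracle on tiny problems", {
  # two-step chain, two control intervals: the full decision box is
  # searchable exhaustively; the oracle is an independent grid search
  # plus a derivative-free polish from the best grid point
  hits <- 0L
  n_inst <- 5L
  for (inst in seq_len(n_inst)) {
    topo <- toy_topology()
    set.seed(100 + inst)
    smp <- sample_parameters(topo)
    dil <- dilution_profile(c(0, 15, 30), rbind(v_growth = runif(2, 0.3,
                                                                 0.6)))
    prob <- new_ocp(topo, smp$params, dil, sigma = 0.1, rho = 2L,
                    e_max = 10, steady_start = FALSE)
    spec <- pathreg:::.ocp_spec(prob, n_sub = 2L)
    # grid over (u0_1, u0_2, s11, s12, s21, s22)
    lv <- c(S = 1, X1 = 0.5, P = 1)
    e_ref <- steady_state_enzymes(topo, smp$params,
                                  c(P = max(dil$values)), lv)
    u_grid <- seq(0.05, 2, length.out = 8)
    s_grid <- seq(-0.1, 0.1, length.out = 7)
    G <- as.matrix(expand.grid(u_grid * e_ref[1], u_grid * e_ref[2],
                               s_grid, s_grid, s_grid, s_grid))
    G <- G[, c(1, 2, 3, 5, 4, 6)]  # enzyme-major slope layout
    vals <- pathreg:::ocp_penalized_batch_cpp(G, spec, 1e6)
    best <- which.min(vals)
    cap <- prob$bounds$e_max / 15
    polish <- stats::optim(G[best, ], function(x)
      pathreg:::ocp_penalized_cpp(x, spec, 1e6),
      method = "L-BFGS-B",
      lower = c(0, 0, rep(-cap, 4)), upper = c(10, 10, rep(cap, 4)),
      control = list(maxit = 2000))
    oracle <- polish$value
    sol <- solve_ocp(prob, seed = inst, budget = 5e3, maxit = 200)
    solved <- pathreg:::ocp_penalized_cpp(sol$decision, spec, 1e6)
    if (solved <= oracle * 1.01 + 1e-8) hits <- hits + 1L
  }
  expect_gte(hits, n_inst - 1L)
})
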