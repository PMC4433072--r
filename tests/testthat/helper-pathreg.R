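## shared fixtures and independent oracles for the test suite

## a minimal two-step chain S -> X1 -> P used for brute-force oracle tests;
## built directly (not via build_topology) so the solver is exercised on a
## wiring it was not tuned for
toy_topology <- function() {
  topo <- structure(list(
    name = "toy2", kind = "toy2", inhibition = "none",
    reactions = data.frame(enzyme = c("e1", "e2"),
                           substrate = c("S", "X1"),
                           product = c("X1", "P"),
                           stringsAsFactors = FALSE),
    buffered = "S",
    drains = c(P = "v_growth"),
    inhibitions = data.frame(inhibitor = character(),
                             enzyme = character(),
                             stringsAsFactors = FALSE)),
    class = "pathway_topology")
  validate_topology(topo)
}

## a small linear problem with sampled kinetics, reproducible per seed
make_linear_problem <- function(seed, inhibition = "none", sigma = 0.1,
                                m = Inf, kr = 1, d = NULL, ...) {
  topo <- build_topology("linear", inhibition)
  set.seed(seed)
  smp <- sample_parameters(topo, kr = kr)
  if (!is.null(d)) smp$dilution_values[] <- d
  dil <- dilution_profile(c(0, 15, 30), smp$dilution_values)
  new_ocp(topo, smp$params, dil, sigma = sigma, m = m, ...)
}

## exact two-sided rank-sum p-value by enumeration of all labelings
## (independent oracle for the wilcox.test-backed wrapper)
enum_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  k <- length(x)
  obs <- sum(rank(pooled)[seq_len(k)])
  combs <- utils::combn(n, k)
  stats <- apply(combs, 2L, function(idx) sum(rank(pooled)[idx]))
  mu <- k * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

## deSolve-based trajectory oracle for the mass-balance right-hand side
desolve_trajectory <- function(topology, params, enzymes, dilution, state,
                               times, drain = "demand") {
  f <- function(t, y, parms) {
    names(y) <- names(state)
    list(unname(rhs(topology, params, enzymes, dilution, y, drain = drain)))
  }
  deSolve::lsoda(y = unname(state), times = times, func = f, parms = NULL,
                 rtol = 1e-10, atol = 1e-12)
}

## tiny annotation table builders for the genomics tests
genes_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), strand = r[[4]],
               operon_id = if (length(r) >= 5) r[[5]] else NA,
               stringsAsFactors = FALSE)
  }))
}

## cache for the expensive ensemble computations shared by the acceptance
## tests (computed once per test run)
.acc_cache <- new.env(parent = emptyenv())

acc_get <- function(key, compute) {
  if (!exists(key, envir = .acc_cache)) {
    assign(key, compute(), envir = .acc_cache)
  }
  get(key, envir = .acc_cache)
}

## shared ensemble runs for the acceptance criteria (master seed fixed)
acc_seed <- 101L

acc_linear_none <- function() acc_get("lin_none", function() {
  run_scenario(scenario_config("acc_lin_none", kind = "linear",
                               inhibition = "none", sigma = 0.1,
                               n_runs = 20L, seed = acc_seed))
})

acc_linear_initial <- function() acc_get("lin_init", function() {
  run_scenario(scenario_config("acc_lin_init", kind = "linear",
                               inhibition = "initial", sigma = 0.1, kr = 1,
                               n_runs = 20L, seed = acc_seed))
})

acc_div_none <- function() acc_get("div_none", function() {
  run_scenario(scenario_config("acc_div_none", kind = "diverging_reduced",
                               inhibition = "none", sigma = 0.1,
                               n_runs = 20L, seed = acc_seed))
})

acc_div_nested <- function() acc_get("div_nested", function() {
  run_scenario(scenario_config("acc_div_nested", kind = "diverging_reduced",
                               inhibition = "nested", sigma = 0.1, kr = 1,
                               n_runs = 20L, seed = acc_seed))
})
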