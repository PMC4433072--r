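#' Solve an enzyme-program optimal control problem
#'
#' Multistart global solution of the control-vector-parametrized problem:
#' a small set of structured starts (demand-tracking and constant
#' steady-state programs derived from [steady_state_enzymes()]) plus
#' Latin-hypercube random starts, each refined by box-constrained
#' L-BFGS-B on a smooth quadratic-penalty formulation of the path
#' constraints with an increasing penalty weight, followed by one
#' scatter-style recombination round (convex combinations of the two best
#' candidates, re-refined).  The decision vector holds each enzyme's
#' initial level, its per-interval slopes (boxed at `m`, so the rate
#' constraint holds by construction) and the free initial intermediate
#' levels.
#'
#' The returned candidate is the feasible one (worst path-constraint
#' violation at most `1e-4` on the dense grid) with lowest objective `J`;
#' if no candidate is feasible the best-violation candidate is returned
#' with `feasible = FALSE`.  Results are deterministic given
#' `(problem, n_starts, seed, budget)`.
#'
#' @param problem an [new_ocp()] problem.
#' @param seed integer seed for the multistart sampling.
#' @param budget approximate number of objective evaluations to spend
#'   (gradients are counted as `n_dim` evaluations); controls the number
#'   of starts, which grows prefix-stably so that a larger budget can
#'   never return a worse objective for the same seed.
#' @param n_starts optional fixed number of local starts (overrides the
#'   budget-derived count).
#' @param maxit L-BFGS-B iteration cap per penalty stage.
#' @param feas_tol feasibility tolerance on the worst scaled constraint
#'   violation.
#' @return an object of class `ocp_solution`; see Details.
#' @export
solve_ocp <- function(problem, seed = 1L, budget = 2e4, n_starts = NULL,
                      maxit = 600L, feas_tol = 1e-4) {
  if (budget < 1e3) stop("budget must be at least 1e3 evaluations",
                         call. = FALSE)
  spec <- .ocp_spec(problem, n_sub = 2L)
  n_enz <- spec$n_enz
  rho <- spec$rho
  n_free <- length(spec$free_idx)
  n_dim <- n_enz * (1L + rho) + n_free
  dt <- problem$t_f / rho
  slope_cap <- min(problem$m, problem$bounds$e_max / dt)

  lower <- c(rep(0, n_enz), rep(-slope_cap, n_enz * rho), rep(0, n_free))
  upper <- c(rep(problem$bounds$e_max, n_enz),
             rep(slope_cap, n_enz * rho),
             rep(problem$bounds$x_max, n_free))

  ## coarse companion problem for the mesh-refinement strategy: a 2-interval
  ## control mesh (node at the demand switch) is optimized first, then
  ## lifted to the full mesh and polished
  rho_c <- if (rho > 2L && rho %% 2L == 0L) 2L else rho
  prob_c <- problem
  prob_c$rho <- rho_c
  n_dim_c <- n_enz * (1L + rho_c) + n_free
  lower_c <- c(rep(0, n_enz), rep(-slope_cap, n_enz * rho_c),
               rep(0, n_free))
  upper_c <- c(rep(problem$bounds$e_max, n_enz),
               rep(slope_cap, n_enz * rho_c),
               rep(problem$bounds$x_max, n_free))

  ## one L-BFGS-B iteration costs about one objective evaluation plus one
  ## adjoint gradient (~3 evaluation-equivalents)
  evals_per_start <- round(1.75 * maxit * 4 + maxit * 4)
  if (is.null(n_starts)) {
    n_starts <- max(3L, min(8L, floor(budget / evals_per_start)))
  }

  ## optimize against a slightly shrunk band/cap so that penalty residuals
  ## and the (second-order) integration error of the coarser optimization
  ## grids land inside the true constraints
  margin <- max(3 * feas_tol, 1e-3)
  shrink <- function(sp) {
    sp$p_lo <- sp$p_lo + margin
    sp$p_hi <- sp$p_hi - margin
    sp$x_max <- sp$x_max - margin
    sp
  }
  ## the final stage runs at the same resolution as the acceptance check,
  ## so its feasibility margin only needs to cover the penalty residual
  spec_c1 <- shrink(.ocp_spec(prob_c, n_dense = 10L * rho, n_sub = 1L))
  spec_c2 <- shrink(.ocp_spec(prob_c, n_dense = 20L * rho, n_sub = 1L))
  spec_f <- shrink(.ocp_spec(problem, n_dense = 20L * rho, n_sub = 2L))

  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- .ocp_starts(prob_c, spec_c1, n_starts, slope_cap)

  lift <- function(par_c) {
    if (rho_c == rho) return(par_c)
    dec <- .ocp_controls(prob_c, par_c)
    mesh_f <- seq(0, problem$t_f, length.out = rho + 1L)
    ctl_f <- control_param(control_values(dec$control, mesh_f),
                           problem$t_f)
    .ocp_decision(problem, ctl_f, dec$x0)
  }

  run_stage <- function(par, sp, w, iters, lo, up) {
    stats::optim(par,
                 fn = function(x) ocp_penalized_cpp(x, sp, w),
                 gr = function(x) ocp_penalized_agrad_cpp(x, sp, w),
                 method = "L-BFGS-B", lower = lo, upper = up,
                 control = list(maxit = iters))$par
  }

  local_solve <- function(par_c) {
    par_c <- run_stage(par_c, spec_c1, 1e4, maxit, lower_c, upper_c)
    par_c <- run_stage(par_c, spec_c2, 1e6, round(0.75 * maxit), lower_c,
                       upper_c)
    par <- run_stage(lift(par_c), spec_f, 1e6, maxit, lower, upper)
    ## short high-weight polish drives residual violations below tolerance
    par <- run_stage(par, spec_f, 1e8, round(0.3 * maxit), lower, upper)
    list(par = par, value = ocp_penalized_cpp(par, spec_f, 1e8))
  }

  cands <- vector("list", 0L)
  for (k in seq_len(n_starts)) {
    cands[[length(cands) + 1L]] <- local_solve(starts[[k]])
  }

  ## scatter-style recombination over the fixed start prefix (keeps the
  ## candidate set monotone in the number of starts)
  prefix <- cands[seq_len(min(3L, length(cands)))]
  ord <- order(vapply(prefix, `[[`, numeric(1), "value"))
  if (length(ord) >= 2L) {
    a <- prefix[[ord[1L]]]$par
    b <- prefix[[ord[2L]]]$par
    combo_vals <- vapply(c(0.25, 0.5, 0.75), function(l) {
      ocp_penalized_cpp(l * a + (1 - l) * b, spec_f, 1e6)
    }, numeric(1))
    l_best <- c(0.25, 0.5, 0.75)[which.min(combo_vals)]
    par_r <- run_stage(l_best * a + (1 - l_best) * b, spec_f, 1e6, maxit,
                       lower, upper)
    par_r <- run_stage(par_r, spec_f, 1e8, round(0.3 * maxit), lower, upper)
    cands[[length(cands) + 1L]] <- list(
      par = par_r, value = ocp_penalized_cpp(par_r, spec_f, 1e8))
  }

  ## final acceptance: exact evaluation against the true bounds
  evals <- lapply(cands, function(cd) ocp_eval_cpp(cd$par, spec))
  viol <- vapply(evals, `[[`, numeric(1), "max_violation")
  Js <- vapply(evals, `[[`, numeric(1), "J")
  feas <- viol <= feas_tol
  best <- if (any(feas)) which(feas)[which.min(Js[feas])] else
    which.min(viol)

  par <- cands[[best]]$par
  dec <- .ocp_controls(problem, par)
  sim <- simulate_pathway(problem, dec$control, dec$x0, n_sub = 2L)
  res <- evals[[best]]

  structure(list(
    problem = problem,
    decision = par,
    control = dec$control,
    x0 = dec$x0,
    trajectories = list(times = sim$times, states = sim$states,
                        enzymes = sim$enzymes),
    J = res$J, J_cost = res$J_cost, J_reg = res$J_reg,
    cost = stats::setNames(res$cost, spec$enzymes),
    reg = stats::setNames(res$reg, spec$enzymes),
    max_violation = viol[best],
    feasible = unname(feas[best]),
    diagnostics = list(seed = seed, budget = budget, n_starts = n_starts,
                       maxit = maxit,
                       evals_est = n_starts * evals_per_start,
                       candidate_J = Js, candidate_violation = viol,
                       best_candidate = best)),
    class = "ocp_solution")
}

#' @export
print.ocp_solution <- function(x, ...) {
  cat("<ocp_solution>", x$problem$topology$name, "\n")
  cat(sprintf("  J = %.5g (sigma*J_cost = %.5g, J_reg = %.5g)\n",
              x$J, x$problem$sigma * x$J_cost, x$J_reg))
  cat(sprintf("  feasible: %s (max violation %.3g)\n", x$feasible,
              x$max_violation))
  cat("  reg_i: ", paste(sprintf("%s=%.3g", names(x$reg), x$reg),
                         collapse = ", "), "\n")
  invisible(x)
}

## structured + Latin-hypercube start points
.ocp_starts <- function(problem, spec, n_starts, slope_cap) {
  topo <- problem$topology
  inter <- topology_intermediates(topo)
  drained <- names(topo$drains)
  rho <- spec$rho
  dt <- problem$t_f / rho
  enz <- spec$enzymes
  n_enz <- length(enz)

  x_lv <- .ocp_x0(problem)
  s0 <- problem$s0
  if (length(s0) == 1L) s0 <- stats::setNames(rep(s0, length(topo$buffered)),
                                              topo$buffered)
  p0 <- problem$p0
  if (length(p0) == 1L) p0 <- stats::setNames(rep(p0, length(drained)),
                                              drained)
  levels <- c(s0, x_lv, p0)

  dil <- problem$dilution
  n_seg <- ncol(dil$values)
  ## steady-state enzyme vector per demand segment, at a given product level
  seg_enz_at <- function(p_target) {
    lv <- levels
    lv[drained] <- p_target
    out <- sapply(seq_len(n_seg), function(s) {
      nu <- dil$values[unname(topo$drains), s]
      tf <- stats::setNames(
        if (identical(problem$drain, "dilution")) nu * p_target else nu,
        drained)
      pmin(steady_state_enzymes(topo, problem$params, tf, lv),
           problem$bounds$e_max)
    })
    matrix(out, nrow = n_enz, dimnames = list(enz, NULL))
  }
  seg_enz <- seg_enz_at(p0[drained])

  mesh <- seq(0, problem$t_f, length.out = rho + 1L)
  seg_of_node <- findInterval(mesh, dil$breakpoints, rightmost.closed = TRUE,
                              all.inside = TRUE)

  clip_nodes <- function(nodes) {
    ## convert to u0 + clipped slopes, rebuild nodes
    slopes <- apply(nodes, 2L, diff) / dt
    slopes <- pmin(pmax(slopes, -slope_cap), slope_cap)
    u0 <- nodes[1L, ]
    cum <- apply(matrix(slopes, nrow = rho) * dt, 2L, cumsum)
    if (rho == 1L) cum <- matrix(cum, nrow = 1L)
    rbind(u0, cum + matrix(u0, nrow = rho, ncol = ncol(nodes), byrow = TRUE))
  }

  mk_decision <- function(nodes, x0) {
    nodes <- clip_nodes(nodes)
    ctl <- control_param(matrix(nodes, nrow = rho + 1L,
                                dimnames = list(NULL, enz)),
                         problem$t_f)
    .ocp_decision(problem, ctl, x0)
  }

  x0_trk <- x_lv

  starts <- list()
  nodes_trk <- t(seg_enz[, seg_of_node, drop = FALSE])
  ## 1: unregulated program: hold the initial steady state (the pathway's
  ## pools and any feedback loop absorb the demand change passively)
  starts[[1L]] <- mk_decision(matrix(nodes_trk[1L, ], nrow = rho + 1L,
                                     ncol = n_enz, byrow = TRUE), x0_trk)
  ## 2: demand-tracking program sized at p(0)
  starts[[2L]] <- mk_decision(nodes_trk, x0_trk)
  ## 3: near-constant program at the worst (largest) per-enzyme demand
  e_hi <- apply(seg_enz, 1L, max)
  nodes_hi <- matrix(e_hi, nrow = rho + 1L, ncol = n_enz, byrow = TRUE)
  nodes_hi[1L, ] <- nodes_trk[1L, ]
  starts[[3L]] <- mk_decision(nodes_hi, x0_trk)
  ## remaining: Latin-hypercube slope programs around the tracking scale
  ## (initial levels stay at the steady-state-consistent sizing; when the
  ## problem allows m to bind, random slopes explore anticipatory ramps)
  if (n_starts > 3L) {
    e_ref <- pmax(pmin(apply(seg_enz, 1L, max), problem$bounds$e_max), 0.1)
    n_lhs <- n_starts - 3L
    free <- isTRUE(problem$free_x0)
    n_dim <- n_enz * rho + if (free) length(inter) else 0L
    H <- lhs::randomLHS(n_lhs, n_dim)
    for (k in seq_len(n_lhs)) {
      s_box <- pmin(slope_cap, 8 * e_ref / problem$t_f)
      sl <- (matrix(H[k, seq_len(n_enz * rho)], nrow = rho) - 0.5) *
        2 * matrix(s_box, nrow = rho, ncol = n_enz, byrow = TRUE)
      dec <- c(nodes_trk[1L, ], as.numeric(sl))
      if (free) {
        dec <- c(dec, 0.05 + 0.9 *
                   H[k, n_enz * rho + seq_along(inter)] *
                   problem$bounds$x_max)
      }
      starts[[3L + k]] <- dec
    }
  }
  starts
}
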