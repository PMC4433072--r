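#' Simulate a pathway under a given enzyme program
#'
#' Integrates the metabolite mass balances with enzyme levels given by a
#' piecewise-linear control parametrization and reports the trajectories
#' together with the worst violation of each path constraint over a dense
#' time grid (at least `20 * rho` points).
#'
#' @param problem an [new_ocp()] problem.
#' @param control a [control_param()] whose columns cover the topology's
#'   enzymes.
#' @param x0 named vector of initial intermediate concentrations;
#'   defaults to the problem's fixed levels (`x_max / 2` unless
#'   overridden).
#' @param n_sub integration substeps per dense grid interval (the
#'   integrator is a second-order positivity-preserving Patankar
#'   Runge-Kutta scheme with fixed step `t_f / (n_dense * n_sub)`).
#' @return list with `times`, `states` (metabolite matrix, named columns),
#'   `enzymes` (control matrix on the same grid), `objective` (the
#'   [evaluate_objective()]-style components, computed in closed form),
#'   `violations` (named worst violations: `product_band`,
#'   `intermediate_cap`, `negativity`, `enzyme_bounds`) and
#'   `max_violation`.
#' @export
simulate_pathway <- function(problem, control, x0 = NULL, n_sub = 2L) {
  inter <- topology_intermediates(problem$topology)
  if (is.null(x0)) x0 <- .ocp_x0(problem)
  spec <- .ocp_spec(problem, n_sub = n_sub)
  if (!isTRUE(problem$free_x0)) {
    ## fixed-x0 problems integrate from the supplied levels
    mets <- spec$metabolites
    x_fixed <- stats::setNames(spec$x_fixed, mets)
    x_fixed[names(x0)] <- x0
    spec$x_fixed <- unname(x_fixed)
  }
  x <- .ocp_decision(problem, control, x0)
  res <- ocp_eval_cpp(x, spec, want_traj = TRUE)
  states <- res$states
  colnames(states) <- spec$metabolites
  enzymes <- res$enzymes
  colnames(enzymes) <- spec$enzymes
  drained <- names(problem$topology$drains)

  pmat <- states[, drained, drop = FALSE]
  xmat <- states[, inter, drop = FALSE]
  ss_resid <- 0
  if (isTRUE(problem$steady_start)) {
    dil0 <- stats::setNames(
      dilution_at(problem$dilution, 0)[unname(problem$topology$drains), 1],
      unname(problem$topology$drains))
    d0 <- rhs(problem$topology, problem$params,
              stats::setNames(enzymes[1L, ], spec$enzymes), dil0,
              stats::setNames(states[1L, ], spec$metabolites),
              drain = problem$drain)
    ss_resid <- max(abs(d0))
  }
  viol <- c(
    product_band = if (length(drained)) max(0, problem$bounds$p_lo - pmat,
                                            pmat - problem$bounds$p_hi)
                   else 0,
    intermediate_cap = if (length(inter)) max(0, xmat - problem$bounds$x_max)
                       else 0,
    negativity = max(0, -states),
    enzyme_bounds = max(0, -control$nodes,
                        control$nodes - problem$bounds$e_max),
    steady_start = ss_resid)
  obj <- list(J = res$J, J_cost = res$J_cost, J_reg = res$J_reg,
              cost = stats::setNames(res$cost, spec$enzymes),
              reg = stats::setNames(res$reg, spec$enzymes))
  list(times = res$times, states = states, enzymes = enzymes,
       objective = obj, violations = viol, max_violation = max(viol))
}
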