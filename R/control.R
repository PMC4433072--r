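#' Piecewise-linear control parametrization
#'
#' Represents the enzyme time-courses \eqn{e_i(t)} as piecewise-linear
#' interpolants on a uniform mesh of `rho` intervals over `[0, t_f]`
#' (control vector parametrization).  `e_i(0)` equals the first node value.
#' With piecewise-linear interpolation the bound on the rate of change of
#' enzyme concentrations, `|de_i/dt| <= m`, is exactly equivalent to a
#' bound on the inter-node slopes.
#'
#' @param nodes numeric matrix `(rho+1) x n_enzymes` of node values
#'   (columns named by enzyme id), all `>= 0`.
#' @param t_f horizon (time units).
#' @return object of class `control_param` with fields `mesh` (node
#'   times), `nodes`, `t_f`, `rho`.
#' @export
control_param <- function(nodes, t_f) {
  nodes <- as.matrix(nodes)
  stopifnot(t_f > 0, nrow(nodes) >= 2L)
  rho <- nrow(nodes) - 1L
  structure(list(mesh = seq(0, t_f, length.out = rho + 1L),
                 nodes = nodes, t_f = t_f, rho = rho),
            class = "control_param")
}

#' Evaluate controls at arbitrary times
#' @param control a `control_param`.
#' @param times numeric vector of times in `[0, t_f]`.
#' @return matrix `length(times) x n_enzymes` of enzyme concentrations.
#' @export
control_values <- function(control, times) {
  stopifnot(all(times >= 0), all(times <= control$t_f + 1e-12))
  out <- apply(control$nodes, 2L, function(col) {
    stats::approx(control$mesh, col, xout = pmin(times, control$t_f))$y
  })
  matrix(out, nrow = length(times), ncol = ncol(control$nodes),
         dimnames = list(NULL, colnames(control$nodes)))
}

#' Inter-node slopes of a control parametrization
#' @inheritParams control_values
#' @return matrix `rho x n_enzymes` of slopes (concentration/time).
#' @export
control_slopes <- function(control) {
  dt <- diff(control$mesh)
  apply(control$nodes, 2L, diff) / dt
}

#' Check the enzyme rate-of-change constraint
#'
#' Tests whether a piecewise-linear control satisfies
#' `|de_i/dt| <= m` everywhere, which for this parametrization reduces to
#' the inter-node slopes (up to a 1e-12 tolerance for boundary cases).
#'
#' @inheritParams control_values
#' @param m maximum enzyme concentration change per unit time (> 0, may be
#'   `Inf`).
#' @return list with `ok` (logical) and `worst_slope` (largest absolute
#'   slope over all enzymes and intervals).
#' @export
check_rate_constraint <- function(control, m) {
  stopifnot(m > 0)
  worst <- max(abs(control_slopes(control)))
  list(ok = worst <= m + 1e-12, worst_slope = worst)
}

#' Protein cost and regulatory effort of enzyme trajectories
#'
#' Computes the two components of the objective from dense enzyme
#' trajectories: the protein cost of each enzyme,
#' `cost_i = e_i(0) * t_f`, and its regulatory effort,
#' `reg_i = integral over [0, t_f] of (e_i(t) - e_i(0))^2 dt`, combined as
#' `J = sigma * sum(cost_i) + sum(reg_i)`.
#'
#' Integration uses composite Simpson quadrature on the supplied grid,
#' which is exact for the piecewise-quadratic integrand arising from
#' piecewise-linear controls (grid aligned with the control mesh).
#'
#' @param times increasing time grid starting at 0 and covering `[0, t_f]`.
#' @param enzymes matrix `length(times) x n_enzymes` of enzyme
#'   concentrations (columns named by enzyme id).
#' @param sigma protein-cost weight (dimensionless).
#' @param t_f horizon; `times` must reach it.
#' @return list with `J`, `J_cost`, `J_reg`, `cost` and `reg` (named
#'   per-enzyme vectors).  The identity `J = sigma * J_cost + J_reg` holds
#'   exactly.
#' @examples
#' tt <- seq(0, 30, length.out = 121)
#' evaluate_objective(tt, matrix(1, 121, 5), sigma = 1, t_f = 30)$J  # 150
#' @export
evaluate_objective <- function(times, enzymes, sigma, t_f) {
  enzymes <- as.matrix(enzymes)
  if (max(times) < t_f - 1e-9) {
    stop("trajectory must cover [0, t_f]", call. = FALSE)
  }
  stopifnot(length(times) == nrow(enzymes), length(times) >= 3L,
            all(diff(times) > 0), times[1] == 0)
  e0 <- enzymes[1L, ]
  cost <- e0 * t_f
  dev2 <- sweep(enzymes, 2L, e0)^2
  reg <- apply(dev2, 2L, .simpson, x = times)
  names(reg) <- names(cost) <- colnames(enzymes)
  J_cost <- sum(cost)
  J_reg <- sum(reg)
  list(J = sigma * J_cost + J_reg, J_cost = J_cost, J_reg = J_reg,
       cost = cost, reg = reg)
}

## composite Simpson on a (possibly non-uniform) grid; pairs of intervals,
## trapezoid fallback for a trailing odd interval
.simpson <- function(y, x) {
  n <- length(x)
  total <- 0
  i <- 1L
  while (i + 2L <= n) {
    h1 <- x[i + 1L] - x[i]
    h2 <- x[i + 2L] - x[i + 1L]
    ## Simpson weights for unequal spacing
    h <- h1 + h2
    total <- total + h / 6 * ((2 - h2 / h1) * y[i] +
                              h^2 / (h1 * h2) * y[i + 1L] +
                              (2 - h1 / h2) * y[i + 2L])
    i <- i + 2L
  }
  if (i < n) total <- total + (x[n] - x[n - 1L]) * (y[n] + y[n - 1L]) / 2
  total
}
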