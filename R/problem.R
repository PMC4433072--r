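#' Enzyme-program optimal control problems
#'
#' Bundles everything that defines one instance of the dynamic
#' optimization: pathway topology and kinetics, the dilution (demand)
#' profile of the product(s), the protein-cost weight `sigma`, the horizon
#' `t_f`, the bound `m` on enzyme concentration changes, the number of
#' control intervals `rho`, and the state bounds.
#'
#' The objective minimized is
#' `J = sigma * sum_i e_i(0) * t_f + sum_i int_0^{t_f} (e_i(t)-e_i(0))^2 dt`,
#' subject to the pathway mass balances, a band `[p_lo, p_hi]` on each
#' drained product, a cap `x_max` on every free intermediate, enzyme
#' bounds `[0, e_max]`, and (when `m` is finite) `|de_i/dt| <= m`.
#'
#' By default the drain is a prescribed demand flux: the product pool is
#' consumed at rate `nu(t)` irrespective of its concentration (the outflow
#' saturates as the pool empties), so a change in demand always forces the
#' pathway flux to follow.  The alternative `drain = "dilution"` uses
#' first-order dilution `nu(t) * p(t)`.  By default the initial state must
#' be a steady state of the first demand segment (`steady_start = TRUE`),
#' so the regulatory effort measures the response to the demand change
#' rather than start-up transients.
#'
#' Default bounds: product band `[0.3, 2]` around `p(0) = 1` (the product
#' pool acts as a buffer whose excursions the feedback-inhibition loop can
#' exploit), `x_max = 1` on intermediates, `e_max = 20`.  Initial
#' intermediate levels are free decision variables in `[0, x_max]`;
#' `p(0)` is fixed.  See the package vignette for how these choices shape
#' the study.
#'
#' @param topology a [build_topology()] result.
#' @param params a [kinetic_params()] set covering the topology.
#' @param dilution a [dilution_profile()] whose rows are named by the
#'   topology's drain ids.
#' @param sigma protein-cost weight; `0.1` and `10` are the study's "low"
#'   and "high" settings.
#' @param t_f horizon (default 30 time units).
#' @param m bound on `|de_i/dt|` (conc/time); `Inf` disables the
#'   protein-biosynthesis rate limitation.
#' @param rho number of uniform control intervals.
#' @param p_lo,p_hi product concentration band.
#' @param x_max cap on free intermediate concentrations.
#' @param e_max cap on enzyme concentrations.
#' @param p0 fixed initial product concentration(s).
#' @param s0 buffered substrate concentration(s).
#' @param drain `"demand"` (prescribed outflow flux) or `"dilution"`
#'   (first-order outflow `nu * p`).
#' @param steady_start require the initial state to be a steady state of
#'   the first demand segment.
#' @param x0 named vector of initial intermediate concentrations; default
#'   `x_max / 2` for every intermediate.
#' @param free_x0 when `TRUE` the initial intermediate levels become free
#'   decision variables in `[0, x_max]` instead of being fixed at `x0`.
#'   Fixed levels are the default: with the protein cost charged on
#'   `e_i(0)` and a steady-state start, free pool levels act as a cost
#'   dial (larger pools buy cheaper enzymes at the price of a little
#'   regulation everywhere), blurring the regulatory patterns under study.
#' @return object of class `ocp`.
#' @export
new_ocp <- function(topology, params, dilution, sigma = 0.1, t_f = 30,
                    m = Inf, rho = 8L, p_lo = 0.3, p_hi = 2,
                    x_max = 1, e_max = 20, p0 = 1, s0 = 1,
                    drain = c("demand", "dilution"), steady_start = TRUE,
                    x0 = NULL, free_x0 = FALSE) {
  drain <- match.arg(drain)
  stopifnot(inherits(topology, "pathway_topology"),
            inherits(params, "kinetic_params"),
            inherits(dilution, "dilution_profile"))
  if (p_lo >= p_hi) stop("p_lo must be < p_hi", call. = FALSE)
  if (x_max <= 0 || e_max <= 0) stop("x_max, e_max must be > 0",
                                     call. = FALSE)
  if (rho < 1L) stop("rho must be >= 1", call. = FALSE)
  drains <- unname(topology$drains)
  if (!all(drains %in% rownames(dilution$values)) &&
      nrow(dilution$values) != length(drains)) {
    stop("dilution profile must provide one row per drain", call. = FALSE)
  }
  if (is.null(rownames(dilution$values))) {
    rownames(dilution$values) <- drains
  }
  needed <- inhibition_edges(topology)
  if (!all(needed %in% names(params$kr))) {
    stop("params$kr must cover the topology's inhibition edges: ",
         paste(setdiff(needed, names(params$kr)), collapse = ", "),
         call. = FALSE)
  }
  structure(list(topology = topology, params = params, dilution = dilution,
                 sigma = sigma, t_f = t_f, m = m, rho = as.integer(rho),
                 bounds = list(p_lo = p_lo, p_hi = p_hi, x_max = x_max,
                               e_max = e_max),
                 p0 = p0, s0 = s0, drain = drain,
                 steady_start = isTRUE(steady_start),
                 x0 = x0, free_x0 = isTRUE(free_x0)),
            class = "ocp")
}

## Compile an ocp into the flat spec list consumed by the C++ evaluator.
## n_dense: number of dense constraint-grid intervals (>= 20 * rho);
## n_sub: integration substeps per dense interval.
.ocp_spec <- function(problem, n_dense = NULL, n_sub = 2L) {
  topo <- problem$topology
  mets <- topology_metabolites(topo)
  inter <- topology_intermediates(topo)
  drained <- names(topo$drains)
  rx <- topo$reactions
  enz <- rx$enzyme
  midx <- stats::setNames(seq_along(mets) - 1L, mets)
  if (is.null(n_dense)) n_dense <- 20L * problem$rho

  inh <- topo$inhibitions
  kr <- numeric(0)
  if (nrow(inh) > 0L) {
    kr <- unname(problem$params$kr[paste0(inh$inhibitor, "->", inh$enzyme)])
  }

  x_fixed <- stats::setNames(numeric(length(mets)), mets)
  s0 <- problem$s0
  if (length(s0) == 1L) s0 <- stats::setNames(rep(s0, length(topo$buffered)),
                                              topo$buffered)
  x_fixed[topo$buffered] <- s0[topo$buffered]
  p0 <- problem$p0
  if (length(p0) == 1L) p0 <- stats::setNames(rep(p0, length(drained)),
                                              drained)
  x_fixed[drained] <- p0[drained]
  x_fixed[inter] <- .ocp_x0(problem)[inter]

  dil_values <- problem$dilution$values[unname(topo$drains), , drop = FALSE]

  list(n_enz = length(enz), n_met = length(mets), rho = problem$rho,
       n_dense = as.integer(n_dense), n_sub = as.integer(n_sub),
       sub = unname(midx[rx$substrate]), prod = unname(midx[rx$product]),
       kcat = unname(problem$params$kcat[enz]),
       km = unname(problem$params$km[enz]),
       inh_met = if (nrow(inh)) unname(midx[inh$inhibitor]) else integer(),
       inh_enz = if (nrow(inh)) match(inh$enzyme, enz) - 1L else integer(),
       inh_kr = kr,
       drain_idx = unname(midx[drained]),
       free_idx = if (isTRUE(problem$free_x0)) unname(midx[inter])
                  else integer(),
       is_buffered = as.integer(mets %in% topo$buffered),
       x_fixed = unname(x_fixed),
       dil_breaks = problem$dilution$breakpoints,
       dil_values = as.numeric(dil_values),
       sigma = problem$sigma, t_f = problem$t_f,
       p_lo = problem$bounds$p_lo, p_hi = problem$bounds$p_hi,
       x_max = problem$bounds$x_max, e_max = problem$bounds$e_max,
       drain_mode = as.integer(identical(problem$drain, "dilution")),
       steady_start = as.integer(isTRUE(problem$steady_start)),
       enzymes = enz, metabolites = mets, intermediates = inter)
}

## fixed/default initial intermediate levels of a problem
.ocp_x0 <- function(problem) {
  inter <- topology_intermediates(problem$topology)
  x0 <- stats::setNames(rep(problem$bounds$x_max / 2, length(inter)), inter)
  if (!is.null(problem$x0)) x0[names(problem$x0)] <- problem$x0
  x0
}

## assemble a decision vector from a control_param and (when free)
## initial intermediate levels
.ocp_decision <- function(problem, control, x0 = NULL) {
  spec_enz <- problem$topology$reactions$enzyme
  nodes <- control$nodes[, spec_enz, drop = FALSE]
  slopes <- control_slopes(control)[, spec_enz, drop = FALSE]
  dec <- c(nodes[1L, ], as.numeric(slopes))
  if (isTRUE(problem$free_x0)) {
    inter <- topology_intermediates(problem$topology)
    if (is.null(x0)) x0 <- .ocp_x0(problem)
    stopifnot(all(inter %in% names(x0)))
    dec <- c(dec, unname(x0[inter]))
  }
  dec
}

## inverse: control_param + x0 from a decision vector
.ocp_controls <- function(problem, x) {
  enz <- problem$topology$reactions$enzyme
  n_enz <- length(enz)
  rho <- problem$rho
  dt <- problem$t_f / rho
  u0 <- x[seq_len(n_enz)]
  slopes <- matrix(x[n_enz + seq_len(n_enz * rho)], nrow = rho,
                   ncol = n_enz, dimnames = list(NULL, enz))
  cum <- apply(slopes * dt, 2L, cumsum)
  if (rho == 1L) cum <- matrix(cum, nrow = 1L)
  nodes <- rbind(u0, cum + matrix(u0, nrow = rho, ncol = n_enz, byrow = TRUE))
  dimnames(nodes) <- list(NULL, enz)
  x0 <- .ocp_x0(problem)
  if (isTRUE(problem$free_x0)) {
    inter <- topology_intermediates(problem$topology)
    x0 <- stats::setNames(x[n_enz * (1L + rho) + seq_along(inter)], inter)
  }
  list(control = control_param(nodes, problem$t_f), x0 = x0)
}
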