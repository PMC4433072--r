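#' Sample randomized kinetic parameters and dilution values
#'
#' Draws the kinetic constants and demand values used by the
#' randomized-parameter ensembles: `kcat` and `km` i.i.d. uniform on
#' `[1e-3, 2]` (a degenerate-zero guard on the nominal `[0, 2]` sampling
#' interval) and the per-segment dilution values i.i.d. uniform on
#' `[0.2, 0.8]`.  Inhibitory constants are not sampled: they are fixed by
#' the scenario (`kr`, unit by default).  Uses the current RNG state, so
#' results are reproducible per seed.
#'
#' @param topology a `pathway_topology`.
#' @param kr inhibitory constant applied to every inhibition edge of the
#'   topology (ignored when there are none).
#' @param n_segments number of demand segments.
#' @param kinetic_interval sampling interval for `kcat` and `km`.
#' @param dilution_interval sampling interval for dilution values.
#' @return list with `params` (a [kinetic_params()]) and `dilution_values`
#'   (matrix `n_drains x n_segments`, rows named by drain id).
#' @export
sample_parameters <- function(topology, kr = 1, n_segments = 2L,
                              kinetic_interval = c(1e-3, 2),
                              dilution_interval = c(0.2, 0.8)) {
  enz <- topology$reactions$enzyme
  n <- length(enz)
  kcat <- stats::setNames(runif(n, kinetic_interval[1], kinetic_interval[2]),
                          enz)
  km <- stats::setNames(runif(n, kinetic_interval[1], kinetic_interval[2]),
                        enz)
  edges <- inhibition_edges(topology)
  krv <- stats::setNames(rep(kr, length(edges)), edges)
  drains <- unname(topology$drains)
  dil <- matrix(runif(length(drains) * n_segments, dilution_interval[1],
                      dilution_interval[2]),
                nrow = length(drains), dimnames = list(drains, NULL))
  list(params = kinetic_params(kcat, km, krv), dilution_values = dil)
}

#' Scenario configurations
#'
#' Declarative description of one randomized-ensemble experiment:
#' topology x inhibition layout x cost weight x rate limit x inhibition
#' strength x number of runs, with a master seed and solver budget.
#'
#' @param id scenario label.
#' @param kind,inhibition topology arguments for [build_topology()].
#' @param sigma protein-cost weight (0.1 = low, 10 = high).
#' @param m enzyme rate-of-change bound (`Inf` = unconstrained).
#' @param kr inhibitory constant for all inhibition edges.
#' @param n_runs number of randomized optimization runs.
#' @param seed master seed; run seeds are derived from it.
#' @param budget solver evaluation budget per run.
#' @param t_f,rho horizon and control intervals.
#' @param kinetic_interval,dilution_interval sampling intervals.
#' @param ... further arguments stored and passed to [new_ocp()]
#'   (e.g. `p_lo`, `p_hi`, `x_max`, `e_max`).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(id, kind = "linear", inhibition = "none",
                            sigma = 0.1, m = Inf, kr = 1, n_runs = 20L,
                            seed = 1L, budget = 2e4, t_f = 30, rho = 8L,
                            kinetic_interval = c(1e-3, 2),
                            dilution_interval = c(0.2, 0.8), ...) {
  stopifnot(n_runs >= 1L, kr > 0,
            kinetic_interval[1] > 0, diff(kinetic_interval) > 0,
            diff(dilution_interval) > 0)
  structure(list(id = id, kind = kind, inhibition = inhibition,
                 sigma = sigma, m = m, kr = kr, n_runs = as.integer(n_runs),
                 seed = as.integer(seed), budget = budget, t_f = t_f,
                 rho = as.integer(rho),
                 kinetic_interval = kinetic_interval,
                 dilution_interval = dilution_interval,
                 ocp_args = list(...)),
            class = "scenario_config")
}

## deterministic per-run seeds from the master seed
.run_seeds <- function(master, n) {
  set.seed(master)
  sample.int(2^30, n)
}

#' Run a randomized-parameter scenario
#'
#' Performs `n_runs` independent optimizations with parameters and demand
#' values sampled per run (run seeds derived deterministically from the
#' master seed, so paired scenarios sharing a master seed see identical
#' samples).  Infeasible runs are flagged rather than resampled, keeping
#' the paired structure intact; a warning is raised when more than half of
#' the runs are infeasible.
#'
#' @param config a [scenario_config()].
#' @return a data.frame with one row per run: run id, seed, feasibility
#'   flag, `J`, `J_cost`, `J_reg`, per-enzyme `reg_*`, `cost_*` and `e0_*`
#'   columns, sampled dilution values `dil_*`, and `max_violation`.
#'   The scenario config is attached as attribute `"config"`.
#' @export
run_scenario <- function(config) {
  topo <- build_topology(config$kind, config$inhibition)
  enz <- topo$reactions$enzyme
  seeds <- .run_seeds(config$seed, config$n_runs)
  rows <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    set.seed(seeds[r])
    smp <- sample_parameters(topo, kr = config$kr,
                             kinetic_interval = config$kinetic_interval,
                             dilution_interval = config$dilution_interval)
    n_seg <- ncol(smp$dilution_values)
    dil <- dilution_profile(seq(0, config$t_f, length.out = n_seg + 1L),
                            smp$dilution_values)
    prob <- do.call(new_ocp, c(list(topology = topo, params = smp$params,
                                    dilution = dil, sigma = config$sigma,
                                    t_f = config$t_f, m = config$m,
                                    rho = config$rho),
                               config$ocp_args))
    sol <- solve_ocp(prob, seed = seeds[r], budget = config$budget)
    row <- data.frame(run = r, seed = seeds[r], feasible = sol$feasible,
                      J = sol$J, J_cost = sol$J_cost, J_reg = sol$J_reg,
                      max_violation = sol$max_violation)
    for (e in enz) {
      row[[paste0("reg_", e)]] <- unname(sol$reg[e])
      row[[paste0("cost_", e)]] <- unname(sol$cost[e])
      row[[paste0("e0_", e)]] <- unname(sol$control$nodes[1L, e])
    }
    dv <- smp$dilution_values
    for (d in rownames(dv)) {
      for (s in seq_len(ncol(dv))) {
        row[[paste0("dil_", d, "_", s)]] <- dv[d, s]
      }
    }
    rows[[r]] <- row
  }
  out <- do.call(rbind, rows)
  n_inf <- sum(!out$feasible)
  if (n_inf > config$n_runs / 2) {
    warning(sprintf("scenario '%s': %d of %d runs infeasible", config$id,
                    n_inf, config$n_runs), call. = FALSE)
  }
  attr(out, "config") <- config
  out
}

#' Per-enzyme medians of regulatory effort over feasible runs
#' @param records a [run_scenario()] table.
#' @param what column prefix, `"reg"`, `"cost"` or `"e0"`.
#' @return named numeric vector (one entry per enzyme).
#' @export
ensemble_medians <- function(records, what = "reg") {
  ok <- records$feasible
  cols <- grep(paste0("^", what, "_e"), names(records), value = TRUE)
  med <- vapply(cols, function(cl) median(records[[cl]][ok]), numeric(1))
  names(med) <- sub(paste0("^", what, "_"), "", cols)
  med
}

#' Two-sample Wilcoxon rank-sum comparison
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test (delegating to
#' [stats::wilcox.test()]): exact for small untied samples
#' (`n_x + n_y <= 12`), normal approximation with tie correction
#' otherwise.  Paired comparisons use the signed-rank form.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param paired logical; use the paired signed-rank test.
#' @return object of class `pathreg_comparison`: group labels, per-group
#'   medians, rank statistic, p-value and group sizes.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided",
                              paired = FALSE) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both samples; p = 1",
            call. = FALSE)
    res <- list(statistic = NA_real_, p.value = 1)
  } else {
    exact <- !paired && (length(x) + length(y) <= 12L) &&
      !anyDuplicated(c(x, y))
    res <- suppressWarnings(
      wilcox.test(x, y, alternative = alternative, paired = paired,
                  exact = exact, correct = TRUE))
  }
  structure(list(groups = c(deparse(substitute(x)), deparse(substitute(y))),
                 medians = c(median(x), median(y)),
                 statistic = unname(res$statistic),
                 p.value = min(1, res$p.value),
                 n = c(length(x), length(y)),
                 alternative = alternative, paired = paired),
            class = "pathreg_comparison")
}

#' @export
print.pathreg_comparison <- function(x, ...) {
  cat(sprintf("<comparison> medians %.4g vs %.4g (n = %d, %d), p = %.4g%s\n",
              x$medians[1], x$medians[2], x$n[1], x$n[2], x$p.value,
              if (isTRUE(x$paired)) " [paired]" else ""))
  invisible(x)
}

#' Count transcriptional control points
#'
#' An enzyme counts as a transcriptional control point when its median
#' regulatory effort exceeds a fraction `tau` of the summed median
#' regulatory efforts, operationalizing the "regulated enzyme" calls of
#' the ensemble figures.
#'
#' @param med_reg named vector of per-enzyme median regulatory efforts.
#' @param tau share threshold in (0, 1); default 0.05.
#' @return integer count (0 for an all-zero vector).
#' @export
count_control_points <- function(med_reg, tau = 0.05) {
  stopifnot(tau > 0, tau < 1)
  total <- sum(med_reg)
  if (total <= 0) return(0L)
  sum(med_reg > tau * total)
}

#' Scan the feedback-inhibition strength
#'
#' Runs one ensemble per value of the inhibitory constant `kr` (paired
#' design: all ensembles share the master seed, hence identical sampled
#' kinetics and demands), returning per-`kr` medians of the initial first
#' enzyme concentration, the per-enzyme regulatory efforts and the
#' objective.
#'
#' @param config base [scenario_config()]; its `inhibition` should name an
#'   inhibited layout (default use is `"initial"`).
#' @param kr_grid positive inhibition constants (log-spaced recommended;
#'   zero is excluded since the inhibited rate law is undefined there).
#' @param include_uninhibited also run the matching no-inhibition
#'   scenario with the same seeds, returned as `uninhibited`.
#' @return list with `kr` (grid), `medians` (data.frame: kr, e0_e1, J,
#'   J_reg, reg_* columns), `records` (list of run tables) and optionally
#'   `uninhibited`.
#' @export
kr_scan <- function(config, kr_grid = 10^seq(-2, 2, length.out = 6),
                    include_uninhibited = TRUE) {
  if (length(kr_grid) == 0L) stop("kr grid must be non-empty", call. = FALSE)
  if (any(kr_grid <= 0)) stop("kr grid must be positive", call. = FALSE)
  records <- lapply(kr_grid, function(kr) {
    cfg <- config
    cfg$kr <- kr
    cfg$id <- paste0(config$id, "_kr", signif(kr, 3))
    run_scenario(cfg)
  })
  med_rows <- lapply(seq_along(kr_grid), function(i) {
    rec <- records[[i]]
    ok <- rec$feasible
    data.frame(kr = kr_grid[i],
               e0_e1 = median(rec$e0_e1[ok]),
               J = median(rec$J[ok]), J_reg = median(rec$J_reg[ok]),
               t(ensemble_medians(rec, "reg")))
  })
  out <- list(kr = kr_grid, medians = do.call(rbind, med_rows),
              records = records)
  if (include_uninhibited) {
    cfg <- config
    cfg$inhibition <- "none"
    cfg$id <- paste0(config$id, "_none")
    out$uninhibited <- run_scenario(cfg)
  }
  out
}

#' Scan the protein biosynthetic rate limit
#'
#' Paired ensembles across values of the enzyme rate-of-change bound `m`
#' (default grid `{0.06, 0.10, 0.15}`; the two extreme values anchor the
#' slow/fast comparisons), sharing sampled parameters through the master
#' seed.
#'
#' @param config base [scenario_config()].
#' @param m_grid positive values of the rate bound.
#' @return list with `m` (grid), `medians` (data.frame of per-position
#'   median regulatory efforts by m) and `records` (list of run tables).
#' @export
m_scan <- function(config, m_grid = c(0.06, 0.10, 0.15)) {
  stopifnot(all(m_grid > 0))
  records <- lapply(m_grid, function(m) {
    cfg <- config
    cfg$m <- m
    cfg$id <- paste0(config$id, "_m", m)
    run_scenario(cfg)
  })
  med_rows <- lapply(seq_along(m_grid), function(i) {
    data.frame(m = m_grid[i], t(ensemble_medians(records[[i]], "reg")))
  })
  list(m = m_grid, medians = do.call(rbind, med_rows), records = records)
}

#' Read a scenario configuration from a YAML file
#'
#' Convenience reader for declarative scenario files: top-level keys match
#' the arguments of [scenario_config()] (requires the `yaml` package).
#'
#' @param path YAML file path.
#' @return a [scenario_config()].
#' @export
scenario_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("scenario_from_yaml requires the yaml package", call. = FALSE)
  }
  obj <- yaml::read_yaml(path)
  if (is.null(obj$id)) obj$id <- tools::file_path_sans_ext(basename(path))
  do.call(scenario_config, obj)
}
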