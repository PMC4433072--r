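#' Irreversible Michaelis-Menten rate
#'
#' Flux of an irreversible Michaelis-Menten reaction,
#' `v = kcat * e * s / (s + km)`.
#'
#' @param e enzyme concentration (>= 0).
#' @param s substrate concentration (>= 0).
#' @param kcat turnover number (> 0, 1/time).
#' @param km half-saturation constant (> 0, concentration).
#' @return flux (concentration/time), non-negative, non-decreasing in each
#'   of `e`, `s` and `kcat`.
#' @examples
#' mm_rate(1, 1, kcat = 2, km = 1)  # 1
#' @export
mm_rate <- function(e, s, kcat, km) {
  if (any(e < 0) || any(s < 0)) {
    stop("enzyme and substrate concentrations must be non-negative",
         call. = FALSE)
  }
  if (any(kcat <= 0) || any(km <= 0)) {
    stop("kcat and km must be strictly positive", call. = FALSE)
  }
  kcat * e * s / (s + km)
}

#' Product-inhibited Michaelis-Menten rate
#'
#' Competitive inhibition of an enzyme by a downstream product `p`: the
#' apparent half-saturation constant is inflated by `(1 + p/kr)`, giving
#' `v = kcat * e * s / (s + km * (1 + p/kr))`.  Smaller `kr` means stronger
#' inhibition; as `kr -> Inf` the plain Michaelis-Menten rate is recovered.
#' `p` and `kr` may be vectors (several independent competitive inhibitors
#' acting on the same enzyme); their contributions add in the denominator.
#'
#' @inheritParams mm_rate
#' @param p inhibitor (product) concentration(s) (>= 0).
#' @param kr inhibitory constant(s) (> 0, finite).
#' @return flux, always `<= mm_rate(e, s, kcat, km)`, non-increasing in `p`
#'   and non-decreasing in `kr`.
#' @examples
#' inhibited_mm_rate(1, 1, p = 1, kcat = 1, km = 1, kr = 1)  # 1/3
#' @export
inhibited_mm_rate <- function(e, s, p, kcat, km, kr) {
  if (any(e < 0) || any(s < 0) || any(p < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (any(kcat <= 0) || any(km <= 0)) {
    stop("kcat and km must be strictly positive", call. = FALSE)
  }
  if (any(kr <= 0) || any(!is.finite(kr))) {
    stop("kr must be strictly positive and finite", call. = FALSE)
  }
  kcat * e * s / (s + km * (1 + sum(p / kr)))
}

#' Piecewise-constant dilution profiles
#'
#' Describes the time course of the drain (dilution) rates `v_growth(t)`
#' (or `v_g1(t)`, `v_g2(t)`): piecewise constant on segments delimited by
#' `breakpoints`, one row of `values` per drain.
#'
#' @param breakpoints increasing vector of segment boundaries, starting at
#'   0 and ending at the horizon `t_f`.
#' @param values numeric matrix (`n_drains` x `n_segments`) of dilution
#'   rates (1/time), or a vector for a single drain; rows named by drain id.
#' @return object of class `dilution_profile`.
#' @examples
#' dilution_profile(c(0, 15, 30), rbind(v_growth = c(0.3, 0.6)))
#' @export
dilution_profile <- function(breakpoints, values) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  stopifnot(is.numeric(breakpoints), length(breakpoints) >= 2L,
            all(diff(breakpoints) > 0),
            ncol(values) == length(breakpoints) - 1L)
  if (any(values < 0)) stop("dilution rates must be >= 0", call. = FALSE)
  structure(list(breakpoints = breakpoints, values = values),
            class = "dilution_profile")
}

#' Evaluate a dilution profile
#' @param profile a `dilution_profile`.
#' @param t time point(s).
#' @return matrix `n_drains` x `length(t)` of dilution rates.
#' @export
dilution_at <- function(profile, t) {
  seg <- findInterval(t, profile$breakpoints, rightmost.closed = TRUE,
                      all.inside = TRUE)
  profile$values[, seg, drop = FALSE]
}

## per-reaction flux vector at one state; enzymes named by enzyme id,
## state named by metabolite id, dil named by drain id
.reaction_fluxes <- function(topology, params, enzyme_levels, state) {
  rx <- topology$reactions
  inh <- topology$inhibitions
  v <- numeric(nrow(rx))
  for (j in seq_len(nrow(rx))) {
    ej <- rx$enzyme[j]
    s <- state[[rx$substrate[j]]]
    edges <- inh[inh$enzyme == ej, , drop = FALSE]
    if (nrow(edges) == 0L) {
      v[j] <- mm_rate(enzyme_levels[[ej]], s, params$kcat[[ej]],
                      params$km[[ej]])
    } else {
      keys <- paste0(edges$inhibitor, "->", ej)
      v[j] <- inhibited_mm_rate(enzyme_levels[[ej]], s,
                                p = unname(state[edges$inhibitor]),
                                kcat = params$kcat[[ej]],
                                km = params$km[[ej]],
                                kr = unname(params$kr[keys]))
    }
  }
  names(v) <- rx$enzyme
  v
}

#' Metabolite mass-balance right-hand side
#'
#' Time derivative of the metabolite vector for given enzyme levels and
#' per-drain demand rates.  Buffered metabolites have derivative zero;
#' intermediates balance inflow minus outflow; each drained product `P`
#' obeys `dP/dt = producing flux - nu` under the prescribed-demand drain
#' (default) or `dP/dt = producing flux - nu * P` under first-order
#' dilution.
#'
#' @param topology a `pathway_topology`.
#' @param params a `kinetic_params`.
#' @param enzyme_levels named numeric vector of enzyme concentrations.
#' @param dilution named numeric vector of demand/dilution rates, one per
#'   drain id.
#' @param state named numeric vector of metabolite concentrations (order
#'   and names must match `topology_metabolites(topology)`).
#' @param drain `"demand"` (outflow `nu`) or `"dilution"` (outflow
#'   `nu * P`).
#' @return named numeric vector of derivatives, same order as `state`.
#' @export
rhs <- function(topology, params, enzyme_levels, dilution, state,
                drain = c("demand", "dilution")) {
  drain <- match.arg(drain)
  mets <- topology_metabolites(topology)
  if (length(state) != length(mets) || !all(names(state) %in% mets)) {
    stop("state must contain exactly the topology's metabolites",
         call. = FALSE)
  }
  state <- state[mets]
  if (!all(topology$reactions$enzyme %in% names(enzyme_levels))) {
    stop("enzyme_levels must cover all enzymes", call. = FALSE)
  }
  if (any(state < 0) || any(enzyme_levels < 0)) {
    stop("state and enzyme levels must be non-negative", call. = FALSE)
  }
  v <- .reaction_fluxes(topology, params, enzyme_levels, state)
  d <- stats::setNames(numeric(length(mets)), mets)
  rx <- topology$reactions
  for (j in seq_len(nrow(rx))) {
    d[rx$substrate[j]] <- d[rx$substrate[j]] - v[j]
    d[rx$product[j]] <- d[rx$product[j]] + v[j]
  }
  for (p in names(topology$drains)) {
    drain_id <- topology$drains[[p]]
    d[p] <- d[p] - if (drain == "dilution")
      dilution[[drain_id]] * state[[p]] else dilution[[drain_id]]
  }
  d[topology$buffered] <- 0
  d
}

## steady-state flux through each reaction given per-drain target fluxes;
## converging supply branches split the demand equally (declared convention)
.steady_fluxes <- function(topology, target_flux) {
  rx <- topology$reactions
  drains <- topology$drains
  if (length(target_flux) == 1L && is.null(names(target_flux))) {
    target_flux <- stats::setNames(rep(target_flux, length(drains)),
                                   names(drains))
  }
  stopifnot(all(names(drains) %in% names(target_flux)))
  flux <- stats::setNames(rep(NA_real_, nrow(rx)), rx$enzyme)
  met_demand <- stats::setNames(rep(NA_real_,
                                    length(topology_metabolites(topology))),
                                topology_metabolites(topology))
  met_demand[names(drains)] <- target_flux[names(drains)]
  while (anyNA(flux)) {
    progressed <- FALSE
    ## assign producers of any metabolite with known demand
    for (m in names(met_demand)[!is.na(met_demand)]) {
      producers <- which(rx$product == m & is.na(flux))
      if (length(producers) > 0L) {
        n_prod <- sum(rx$product == m)
        flux[producers] <- met_demand[[m]] / n_prod
        progressed <- TRUE
      }
    }
    ## a metabolite's demand is known once all its consumers are assigned
    for (m in names(met_demand)[is.na(met_demand)]) {
      consumers <- which(rx$substrate == m)
      if (length(consumers) > 0L && !anyNA(flux[consumers])) {
        met_demand[m] <- sum(flux[consumers])
        progressed <- TRUE
      }
    }
    if (!progressed) stop("cannot resolve steady-state fluxes",
                          call. = FALSE)
  }
  flux
}

#' Steady-state enzyme levels for a target flux
#'
#' Analytically inverts the (possibly inhibited) Michaelis-Menten rate law
#' to find the enzyme concentrations that carry a prescribed steady-state
#' flux at given metabolite concentrations.  For converging supply
#' branches the demand at the merge point is split equally between the
#' branches.  With `dilution = target_flux / product_conc` the returned
#' enzyme vector makes [rhs()] vanish.
#'
#' @inheritParams rhs
#' @param target_flux scalar (applied to every drain) or named vector of
#'   steady-state drain fluxes.
#' @param metabolite_levels named numeric vector of metabolite
#'   concentrations; every reaction substrate must be strictly positive.
#' @return named numeric vector of enzyme concentrations.
#' @export
steady_state_enzymes <- function(topology, params, target_flux,
                                 metabolite_levels) {
  rx <- topology$reactions
  subs <- rx$substrate
  if (any(metabolite_levels[subs] <= 0)) {
    stop("all reaction substrates must have strictly positive levels",
         call. = FALSE)
  }
  flux <- .steady_fluxes(topology, target_flux)
  inh <- topology$inhibitions
  e <- stats::setNames(numeric(nrow(rx)), rx$enzyme)
  for (j in seq_len(nrow(rx))) {
    ej <- rx$enzyme[j]
    s <- metabolite_levels[[subs[j]]]
    km_eff <- params$km[[ej]]
    edges <- inh[inh$enzyme == ej, , drop = FALSE]
    if (nrow(edges) > 0L) {
      keys <- paste0(edges$inhibitor, "->", ej)
      km_eff <- km_eff * (1 + sum(metabolite_levels[edges$inhibitor] /
                                    params$kr[keys]))
    }
    e[ej] <- flux[ej] * (s + km_eff) / (params$kcat[[ej]] * s)
  }
  e
}
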