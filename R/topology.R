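#' Pathway topologies
#'
#' A `pathway_topology` describes the wiring of a small metabolic network:
#' an ordered set of irreversible enzymatic reactions, the buffered
#' (boundary) substrates held at constant concentration, the drained
#' products (subject to first-order dilution), and any competitive
#' feedback-inhibition edges from drained products to enzymes.
#'
#' Four network variants are supported, matching the configurations of the
#' underlying study:
#' \describe{
#'   \item{`linear`}{S -> X1 -> X2 -> X3 -> X4 -> P via e1..e5; P drained by
#'     `v_growth`.}
#'   \item{`converging`}{two buffered substrates S1, S2 feed a common
#'     intermediate: S1 -> X1 -> X3 (e1, e2), S2 -> X2 -> X3 (e3, e4),
#'     X3 -> X4 -> P (e5, e6).}
#'   \item{`diverging_full`}{S -> X1 -> X2 (e1, e2), branch X2 -> X3 (e3)
#'     and X2 -> X4 (e4), then X3 -> X5 -> P1 (e5, e7) and
#'     X4 -> X6 -> P2 (e6, e8); P1, P2 drained by `v_g1`, `v_g2`.}
#'   \item{`diverging_reduced`}{as `diverging_full` with e7, e8 removed so
#'     that e5, e6 produce P1, P2 directly.}
#' }
#'
#' Inhibition layouts: `"none"`; `"initial"` adds edges from every drained
#' product to e1 (for multi-product networks both products act as
#' independent competitive inhibitors of e1); `"branch"` adds P1 -> e3 and
#' P2 -> e4 (diverging networks only); `"nested"` combines both.
#'
#' @param kind one of `"linear"`, `"converging"`, `"diverging_full"`,
#'   `"diverging_reduced"`.
#' @param inhibition one of `"none"`, `"initial"`, `"branch"`, `"nested"`.
#'   `"branch"` and `"nested"` are only defined for the diverging networks.
#' @return an object of class `pathway_topology` with fields `name`,
#'   `reactions` (data.frame: enzyme, substrate, product), `buffered`,
#'   `drains` (named character: product -> drain id), `inhibitions`
#'   (data.frame: inhibitor, enzyme).
#' @examples
#' topo <- build_topology("linear", "initial")
#' topo$reactions
#' @export
build_topology <- function(kind = c("linear", "converging", "diverging_full",
                                    "diverging_reduced"),
                           inhibition = c("none", "initial", "branch",
                                          "nested")) {
  kind <- match.arg(kind)
  inhibition <- match.arg(inhibition)

  reactions <- switch(kind,
    linear = data.frame(
      enzyme    = paste0("e", 1:5),
      substrate = c("S", "X1", "X2", "X3", "X4"),
      product   = c("X1", "X2", "X3", "X4", "P"),
      stringsAsFactors = FALSE),
    converging = data.frame(
      enzyme    = paste0("e", 1:6),
      substrate = c("S1", "X1", "S2", "X2", "X3", "X4"),
      product   = c("X1", "X3", "X2", "X3", "X4", "P"),
      stringsAsFactors = FALSE),
    diverging_full = data.frame(
      enzyme    = paste0("e", 1:8),
      substrate = c("S", "X1", "X2", "X2", "X3", "X4", "X5", "X6"),
      product   = c("X1", "X2", "X3", "X4", "X5", "X6", "P1", "P2"),
      stringsAsFactors = FALSE),
    diverging_reduced = data.frame(
      enzyme    = paste0("e", 1:6),
      substrate = c("S", "X1", "X2", "X2", "X3", "X4"),
      product   = c("X1", "X2", "X3", "X4", "P1", "P2"),
      stringsAsFactors = FALSE))

  buffered <- switch(kind,
    linear = "S", converging = c("S1", "S2"),
    diverging_full = "S", diverging_reduced = "S")

  drains <- switch(kind,
    linear = c(P = "v_growth"),
    converging = c(P = "v_growth"),
    diverging_full = c(P1 = "v_g1", P2 = "v_g2"),
    diverging_reduced = c(P1 = "v_g1", P2 = "v_g2"))

  diverging <- kind %in% c("diverging_full", "diverging_reduced")
  if (inhibition %in% c("branch", "nested") && !diverging) {
    stop("inhibition layout '", inhibition,
         "' is only defined for diverging topologies", call. = FALSE)
  }

  inh <- data.frame(inhibitor = character(), enzyme = character(),
                    stringsAsFactors = FALSE)
  if (inhibition %in% c("initial", "nested")) {
    inh <- rbind(inh, data.frame(inhibitor = names(drains),
                                 enzyme = "e1", stringsAsFactors = FALSE))
  }
  if (inhibition %in% c("branch", "nested")) {
    inh <- rbind(inh, data.frame(inhibitor = c("P1", "P2"),
                                 enzyme = c("e3", "e4"),
                                 stringsAsFactors = FALSE))
  }

  topo <- structure(list(
    name = paste0(kind, if (inhibition != "none") paste0("+", inhibition)),
    kind = kind,
    inhibition = inhibition,
    reactions = reactions,
    buffered = buffered,
    drains = drains,
    inhibitions = inh), class = "pathway_topology")
  validate_topology(topo)
  topo
}

#' Metabolites of a topology
#'
#' All metabolite ids in a canonical order: buffered substrates, free
#' intermediates, drained products.
#' @param topology a `pathway_topology`.
#' @return character vector of metabolite ids.
#' @export
topology_metabolites <- function(topology) {
  mets <- unique(c(topology$reactions$substrate, topology$reactions$product))
  drained <- names(topology$drains)
  inter <- setdiff(mets, c(topology$buffered, drained))
  c(topology$buffered, inter, drained)
}

#' Free intermediates of a topology
#' @inheritParams topology_metabolites
#' @return character vector of intermediate metabolite ids.
#' @export
topology_intermediates <- function(topology) {
  setdiff(topology_metabolites(topology),
          c(topology$buffered, names(topology$drains)))
}

#' Validate a pathway topology
#'
#' Checks the structural invariants: unique enzyme ids, acyclic reaction
#' graph, each drained product produced by exactly one reaction, inhibitors
#' are drained products, and (for the linear layout) exactly five reactions
#' and four intermediates.
#'
#' @inheritParams topology_metabolites
#' @return the topology, invisibly; signals an error on violation.
#' @export
validate_topology <- function(topology) {
  stopifnot(inherits(topology, "pathway_topology"))
  rx <- topology$reactions
  if (anyDuplicated(rx$enzyme)) {
    stop("duplicate enzyme ids in topology", call. = FALSE)
  }
  ## acyclicity via topological elimination
  mets <- topology_metabolites(topology)
  edges <- rx[, c("substrate", "product")]
  remaining <- edges
  nodes <- mets
  repeat {
    has_in <- nodes %in% remaining$product
    src <- nodes[!has_in]
    if (length(src) == 0L) break
    remaining <- remaining[!(remaining$substrate %in% src), , drop = FALSE]
    nodes <- setdiff(nodes, src)
    if (nrow(remaining) == 0L && length(nodes) == 0L) break
  }
  if (nrow(remaining) > 0L) stop("reaction graph is cyclic", call. = FALSE)
  for (p in names(topology$drains)) {
    if (sum(rx$product == p) != 1L) {
      stop("drained product ", p, " must be produced by exactly one reaction",
           call. = FALSE)
    }
  }
  if (nrow(topology$inhibitions) > 0L) {
    bad <- setdiff(topology$inhibitions$inhibitor, names(topology$drains))
    if (length(bad) > 0L) {
      stop("inhibitor metabolites must be drained products: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!all(topology$inhibitions$enzyme %in% rx$enzyme)) {
      stop("inhibition targets unknown enzyme", call. = FALSE)
    }
  }
  if (identical(topology$kind, "linear")) {
    stopifnot(nrow(rx) == 5L, length(topology_intermediates(topology)) == 4L)
  }
  invisible(topology)
}

#' @export
print.pathway_topology <- function(x, ...) {
  cat("<pathway_topology>", x$name, "\n")
  cat("  reactions:  ",
      paste(sprintf("%s: %s->%s", x$reactions$enzyme, x$reactions$substrate,
                    x$reactions$product), collapse = ", "), "\n")
  cat("  buffered:   ", paste(x$buffered, collapse = ", "), "\n")
  cat("  drains:     ",
      paste(sprintf("%s (%s)", names(x$drains), x$drains), collapse = ", "),
      "\n")
  if (nrow(x$inhibitions) > 0L) {
    cat("  inhibition: ",
        paste(sprintf("%s -| %s", x$inhibitions$inhibitor,
                      x$inhibitions$enzyme), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Kinetic parameter sets
#'
#' Bundles turnover numbers (`kcat`, 1/time), half-saturation constants
#' (`km`, concentration units) per enzyme, and inhibitory constants (`kr`,
#' concentration units) per feedback edge.  `kr` entries are named
#' `"<inhibitor>-><enzyme>"`.
#'
#' @param kcat named numeric vector of turnover numbers, one per enzyme.
#' @param km named numeric vector of half-saturation constants.
#' @param kr named numeric vector of inhibitory constants (may be empty).
#' @return an object of class `kinetic_params`.
#' @export
kinetic_params <- function(kcat, km, kr = numeric()) {
  stopifnot(length(kcat) == length(km),
            identical(sort(names(kcat)), sort(names(km))))
  if (any(kcat <= 0) || any(km <= 0)) {
    stop("kcat and km must be strictly positive", call. = FALSE)
  }
  if (length(kr) > 0L && (any(kr <= 0) || any(!is.finite(kr)))) {
    stop("kr must be strictly positive and finite", call. = FALSE)
  }
  structure(list(kcat = kcat, km = km, kr = kr), class = "kinetic_params")
}

#' Default kr names for a topology's inhibition edges
#' @inheritParams topology_metabolites
#' @return character vector of `"<inhibitor>-><enzyme>"` edge keys.
#' @export
inhibition_edges <- function(topology) {
  inh <- topology$inhibitions
  if (nrow(inh) == 0L) return(character())
  paste0(inh$inhibitor, "->", inh$enzyme)
}

#' Serialize a topology (with optional parameters) to JSON
#'
#' @inheritParams topology_metabolites
#' @param params optional `kinetic_params`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
topology_to_json <- function(topology, params = NULL, path = NULL) {
  obj <- list(
    name = topology$name, kind = topology$kind,
    inhibition = topology$inhibition,
    reactions = topology$reactions,
    buffered = topology$buffered,
    drains = as.list(topology$drains),
    inhibitions = topology$inhibitions)
  if (!is.null(params)) {
    obj$params <- list(kcat = as.list(params$kcat), km = as.list(params$km),
                       kr = as.list(params$kr))
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a topology (and parameters, if present) back from JSON
#'
#' @param path file path or JSON string produced by [topology_to_json()].
#' @return a list with elements `topology` and (possibly `NULL`) `params`.
#' @export
topology_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  topo <- build_topology(obj$kind, obj$inhibition)
  params <- NULL
  if (!is.null(obj$params)) {
    params <- kinetic_params(unlist(obj$params$kcat), unlist(obj$params$km),
                             if (length(obj$params$kr)) unlist(obj$params$kr)
                             else numeric())
  }
  list(topology = topo, params = params)
}
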