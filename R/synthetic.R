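#' Configuration for the synthetic annotation generator
#'
#' Describes how to emulate prokaryotic gene-annotation tables: replicons
#' populated by transcription units (single genes and co-directional
#' operons), intergenic gaps drawn from a log-normal base distribution,
#' metabolic pathways laid out as labelled chains (linear, branched,
#' converging motifs), and planted effects: additive base-pair offsets on
#' the promoter gaps of genes with configured position labels, and a
#' multiplicative shrinkage of the promoter gaps of PTM-flagged genes.
#'
#' Pathway genes are placed as single-gene transcription units so that a
#' planted positional effect maps one-to-one onto the gene's own promoter
#' gap; operon structure (shared promoters) is carried by the background
#' genes.  Promoter gaps that will serve metabolic transcription units are
#' scaled down by `metabolic_scale`, so that generated pathways are
#' predominantly classified as sparsely regulated.
#'
#' @param n_genomes number of genomes to generate.
#' @param genes_per_genome approximate number of background genes.
#' @param operon_probability probability that a background transcription
#'   unit is an operon.
#' @param operon_mean_size mean operon size (>= 2 members when an operon).
#' @param gap_median,gap_sdlog median (bp) and log-sd of the log-normal
#'   base intergenic-gap distribution.
#' @param metabolic_scale multiplicative factor (< 1) applied to promoter
#'   gaps of metabolic transcription units.
#' @param delta named additive effects in bp on promoter gaps by position
#'   label; recognized names: `initial`, `terminal`, `branch`,
#'   `converging`.
#' @param ptm_factor multiplicative factor (0 < f <= 1) applied to the
#'   promoter gap of PTM-flagged genes.
#' @param ptm_rate probability that a pathway gene carries at least one
#'   post-translational modification site.
#' @param n_pathways pathways per genome (cycled over linear, branched and
#'   converging motifs).
#' @param chain_length genes per pathway chain (>= 3).
#' @param fraction_metabolic fraction of background genes flagged
#'   metabolic (without pathway membership).
#' @param gene_length_range uniform range of gene lengths (bp).
#' @param seed master seed.
#' @return object of class `annotation_generator_config`.
#' @export
annotation_config <- function(n_genomes = 20L, genes_per_genome = 60L,
                              operon_probability = 0.3,
                              operon_mean_size = 3,
                              gap_median = 120, gap_sdlog = 0.8,
                              metabolic_scale = 0.4,
                              delta = c(initial = 0, terminal = 0,
                                        branch = 0, converging = 0),
                              ptm_factor = 1, ptm_rate = 0.2,
                              n_pathways = 4L, chain_length = 5L,
                              fraction_metabolic = 0.2,
                              gene_length_range = c(300, 1500),
                              seed = 1L) {
  stopifnot(operon_probability >= 0, operon_probability <= 1,
            chain_length >= 3L, gap_median > 0, gap_sdlog > 0,
            ptm_factor > 0, ptm_factor <= 1,
            ptm_rate >= 0, ptm_rate <= 1)
  structure(as.list(environment()), class = "annotation_generator_config")
}

## position labels for one pathway chain of a given motif
.chain_positions <- function(motif, L) {
  switch(motif,
    linear = c("initial", rep("intermediate", L - 2L), "terminal"),
    branched = c("initial", rep("intermediate", max(0L, L - 4L)),
                 "pre_branch", "branch", "branch"),
    converging = c("initial", rep("pre_converging", 2L), "converging",
                   rep("terminal", max(0L, L - 4L))))
}

#' Generate synthetic prokaryotic annotation tables
#'
#' Produces one gene table per genome in the package's annotation dialect
#' (see [read_annotation_tsv()]), with planted positional and PTM effects
#' as configured.  Fully reproducible: the same config (including seed)
#' yields byte-identical tables.
#'
#' @param config an [annotation_config()].
#' @return named list of annotation data.frames, one per genome.
#' @export
generate_annotation <- function(config) {
  set.seed(config$seed)
  out <- vector("list", config$n_genomes)
  names(out) <- sprintf("genome_%03d", seq_len(config$n_genomes))
  for (g in seq_len(config$n_genomes)) {
    out[[g]] <- .generate_one_genome(config, names(out)[g])
  }
  out
}

.generate_one_genome <- function(cfg, genome_id) {
  motifs <- rep(c("linear", "branched", "converging"),
                length.out = cfg$n_pathways)

  ## assemble the gene pool: pathway genes + background genes
  pw_genes <- do.call(rbind, lapply(seq_len(cfg$n_pathways), function(p) {
    pos <- .chain_positions(motifs[p], cfg$chain_length)
    data.frame(gene = sprintf("%s_pw%d_g%d", genome_id, p, seq_along(pos)),
               pathway = sprintf("%s_pw%d", genome_id, p),
               position = pos, metabolic = TRUE,
               stringsAsFactors = FALSE)
  }))
  n_bg <- cfg$genes_per_genome
  bg_genes <- data.frame(
    gene = sprintf("%s_bg%d", genome_id, seq_len(n_bg)),
    pathway = NA_character_, position = NA_character_,
    metabolic = runif(n_bg) < cfg$fraction_metabolic,
    stringsAsFactors = FALSE)
  pool <- rbind(pw_genes, bg_genes)
  pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
  pool$ptm_count <- ifelse(!is.na(pool$pathway) &
                             runif(nrow(pool)) < cfg$ptm_rate,
                           1L + stats::rpois(nrow(pool), 1), 0L)

  ## group into transcription units: pathway genes are single-gene TUs,
  ## background genes may form co-directional operons
  tus <- list()
  i <- 1L
  op_counter <- 0L
  while (i <= nrow(pool)) {
    if (!is.na(pool$pathway[i])) {
      tus[[length(tus) + 1L]] <- list(rows = i, operon = NA_character_)
      i <- i + 1L
    } else if (runif(1) < cfg$operon_probability) {
      size <- 2L + stats::rpois(1L, max(0, cfg$operon_mean_size - 2))
      rows <- i
      j <- i + 1L
      while (length(rows) < size && j <= nrow(pool) &&
             is.na(pool$pathway[j])) {
        rows <- c(rows, j)
        j <- j + 1L
      }
      op_counter <- op_counter + 1L
      tus[[length(tus) + 1L]] <- list(
        rows = rows,
        operon = if (length(rows) > 1L)
          sprintf("%s_op%d", genome_id, op_counter) else NA_character_)
      i <- j
    } else {
      tus[[length(tus) + 1L]] <- list(rows = i, operon = NA_character_)
      i <- i + 1L
    }
  }
  n_tu <- length(tus)
  tu_strand <- sample(c("+", "-"), n_tu, replace = TRUE)
  tu_metabolic <- vapply(tus, function(tu) any(pool$metabolic[tu$rows]),
                         logical(1))

  ## base gaps between consecutive TUs (gap k sits before TU k); a gap is
  ## scaled down when it is the promoter of a metabolic TU
  meanlog <- log(cfg$gap_median)
  gaps <- stats::rlnorm(n_tu, meanlog, cfg$gap_sdlog)
  for (k in seq_len(n_tu)) {
    serves_this <- tu_strand[k] == "+"
    serves_prev <- k > 1L && tu_strand[k - 1L] == "-"
    met <- (serves_this && tu_metabolic[k]) ||
      (serves_prev && tu_metabolic[k - 1L])
    if (met) gaps[k] <- gaps[k] * cfg$metabolic_scale
  }

  ## planted effects act on the promoter gap of the TU holding the gene:
  ## the preceding gap for "+" TUs, the following gap for "-" TUs
  promoter_gap_idx <- function(k) {
    if (tu_strand[k] == "+") k else if (k < n_tu) k + 1L else NA_integer_
  }
  for (k in seq_len(n_tu)) {
    rows <- tus[[k]]$rows
    lead <- rows[1L]
    if (is.na(pool$pathway[lead])) next
    gi <- promoter_gap_idx(k)
    if (is.na(gi)) next
    lab <- pool$position[lead]
    if (lab %in% names(cfg$delta)) gaps[gi] <- gaps[gi] + cfg$delta[[lab]]
    if (pool$ptm_count[lead] > 0L) gaps[gi] <- gaps[gi] * cfg$ptm_factor
  }
  gaps <- pmax(1, round(gaps))

  ## lay out coordinates left to right
  glen <- round(runif(nrow(pool), cfg$gene_length_range[1],
                      cfg$gene_length_range[2]))
  intra_gap <- function() round(runif(1, 5, 40))
  pos <- 0L
  rec <- vector("list", nrow(pool))
  idx <- 0L
  for (k in seq_len(n_tu)) {
    pos <- pos + gaps[k]
    rows <- tus[[k]]$rows
    ## operon members laid out in transcription order; on "-" strands the
    ## leader carries the largest coordinates, so reverse the layout
    layout_rows <- if (tu_strand[k] == "+") rows else rev(rows)
    for (q in seq_along(layout_rows)) {
      r <- layout_rows[q]
      if (q > 1L) pos <- pos + intra_gap()
      start <- pos + 1L
      end <- start + glen[r] - 1L
      pos <- end
      idx <- idx + 1L
      rec[[idx]] <- data.frame(
        gene_id = pool$gene[r], replicon = paste0(genome_id, "_chr"),
        start = start, end = end, strand = tu_strand[k],
        operon_id = tus[[k]]$operon,
        is_metabolic = pool$metabolic[r],
        pathway_id = pool$pathway[r], position = pool$position[r],
        ptm_count = pool$ptm_count[r], stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, rec)
  ann[order(ann$start), , drop = FALSE]
}

#' Scenario suites for the ensemble experiments
#'
#' Emits the scenario configurations of the study's in-silico experiment
#' grid with its standard settings (horizon 30, kinetics sampled from
#' `[1e-3, 2]`, demand values from `[0.2, 0.8]`, unit inhibitory
#' constants, sigma low/high = 0.1/10, rate-limit grid
#' `{0.06, 0.10, 0.15}`, inhibition-strength grid in `[1e-2, 1e2]`).
#'
#' @param experiment one of `"m_scan"`, `"inhibition_linear"`,
#'   `"kr_scan"`, `"converging"`, `"diverging_full"`,
#'   `"diverging_nested"`.
#' @param n_runs randomized runs per scenario.
#' @param seed master seed shared by the suite (paired designs).
#' @param budget solver budget per run.
#' @return list of [scenario_config()] objects.
#' @export
generate_scenario_suite <- function(experiment = c("m_scan",
                                                   "inhibition_linear",
                                                   "kr_scan", "converging",
                                                   "diverging_full",
                                                   "diverging_nested"),
                                    n_runs = 20L, seed = 1L,
                                    budget = 2e4) {
  experiment <- match.arg(experiment)
  base <- function(id, ...) scenario_config(id, n_runs = n_runs,
                                            seed = seed, budget = budget,
                                            ...)
  switch(experiment,
    m_scan = lapply(c(0.06, 0.10, 0.15), function(m) {
      base(sprintf("m_scan_m%.2f", m), kind = "linear",
           inhibition = "none", sigma = 0.1, m = m)
    }),
    inhibition_linear = {
      grid <- expand.grid(sigma = c(0.1, 10),
                          inhibition = c("none", "initial"),
                          stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i) {
        base(sprintf("inh_linear_sigma%g_%s", grid$sigma[i],
                     grid$inhibition[i]),
             kind = "linear", inhibition = grid$inhibition[i],
             sigma = grid$sigma[i], kr = 1)
      })
    },
    kr_scan = lapply(10^seq(-2, 2, length.out = 6), function(kr) {
      base(sprintf("kr_scan_kr%g", signif(kr, 3)), kind = "linear",
           inhibition = "initial", sigma = 0.1, kr = kr)
    }),
    converging = list(base("converging", kind = "converging",
                           inhibition = "none", sigma = 0.1)),
    diverging_full = list(base("diverging_full", kind = "diverging_full",
                               inhibition = "none", sigma = 0.1)),
    diverging_nested = lapply(c("none", "initial", "branch", "nested"),
                              function(inh) {
      base(sprintf("diverging_reduced_%s", inh), kind = "diverging_reduced",
           inhibition = inh, sigma = 0.1, kr = 1)
    }))
}
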