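#' Promoter lengths from gene coordinates and operon structure
#'
#' Computes the promoter-length proxy for regulatory effort: for each
#' gene, the length of the intergenic region upstream of the first gene of
#' its operon (or upstream of the gene itself when it is not in an
#' operon).  If the preceding gene in the direction of transcription is
#' co-directional, the full intergenic gap is assigned; if it points the
#' opposite way (divergent promoters) the gap is shared equally between
#' the two flanking genes.  Negative gaps (overlapping coding regions) and
#' genes at a replicon boundary yield a missing promoter length.
#'
#' Coordinates are 1-based inclusive; the intergenic gap between
#' consecutive genes is `next_start - prev_end - 1`.  Replicons are
#' treated as linear.
#'
#' @param genes data.frame for a single replicon with columns `gene_id`,
#'   `start`, `end`, `strand` (`"+"`/`"-"`) and optional `operon_id`
#'   (`NA` = not in an operon), sorted by `start`.  Operon members must be
#'   contiguous and co-directional.
#' @return data.frame with columns `gene_id`, `promoter_length` (bp, `NA`
#'   when missing), `shared` (logical: gap split with a divergent
#'   neighbor) and `anchor` (the operon-leader gene the length was
#'   measured at).
#' @examples
#' genes <- data.frame(gene_id = c("A", "B"), start = c(101, 301),
#'                     end = c(200, 400), strand = c("+", "+"),
#'                     operon_id = NA)
#' promoter_lengths(genes)  # promoter(B) = 100
#' @export
promoter_lengths <- function(genes) {
  req <- c("gene_id", "start", "end", "strand")
  stopifnot(all(req %in% names(genes)))
  if (is.unsorted(genes$start)) {
    stop("genes must be sorted by start coordinate", call. = FALSE)
  }
  if (any(genes$start > genes$end)) {
    stop("gene start must be <= end", call. = FALSE)
  }
  n <- nrow(genes)
  if (!("operon_id" %in% names(genes))) genes$operon_id <- NA
  op <- as.character(genes$operon_id)

  ## operon sanity: members contiguous and co-directional
  for (o in unique(op[!is.na(op)])) {
    idx <- which(op == o)
    if (any(diff(idx) != 1L)) {
      stop("operon ", o, " members are not contiguous", call. = FALSE)
    }
    if (length(unique(genes$strand[idx])) != 1L) {
      stop("operon ", o, " members are not co-directional", call. = FALSE)
    }
  }

  ## anchor (operon leader) per gene: first member in transcription
  ## direction -- smallest start on "+", largest end on "-"
  anchor <- seq_len(n)
  for (o in unique(op[!is.na(op)])) {
    idx <- which(op == o)
    anchor[idx] <- if (genes$strand[idx[1L]] == "+") idx[1L] else
      idx[length(idx)]
  }

  ## raw upstream gap of each potential anchor
  raw <- rep(NA_real_, n)
  shared <- rep(NA, n)
  for (i in unique(anchor)) {
    if (genes$strand[i] == "+") {
      j <- i - 1L
      if (j < 1L) next  # replicon boundary
      gap <- genes$start[i] - genes$end[j] - 1
      if (gap < 0) next  # overlap -> missing
      shared_i <- genes$strand[j] == "-"
    } else {
      j <- i + 1L
      if (j > n) next
      gap <- genes$start[j] - genes$end[i] - 1
      if (gap < 0) next
      shared_i <- genes$strand[j] == "+"
    }
    raw[i] <- if (shared_i) gap / 2 else gap
    shared[i] <- shared_i
  }

  data.frame(gene_id = genes$gene_id,
             promoter_length = raw[anchor],
             shared = shared[anchor],
             anchor = genes$gene_id[anchor],
             stringsAsFactors = FALSE)
}

#' Relative promoter lengths
#'
#' Normalizes raw promoter lengths for cross-pathway and cross-organism
#' comparison: within each pathway the pathway's mean promoter length is
#' subtracted, and the result is divided by the mean promoter length of
#' the organism's non-metabolic genes.  Missing lengths are excluded from
#' all means and propagate as missing relative lengths.
#'
#' @param assignments a [promoter_lengths()] table (or any data.frame with
#'   `gene_id` and `promoter_length`).
#' @param memberships data.frame with columns `gene_id` and `pathway_id`
#'   (one row per gene x pathway membership; extra columns such as
#'   `position` are carried through).
#' @param non_metabolic character vector of non-metabolic gene ids used
#'   for the normalization denominator.
#' @return `memberships` with added columns `promoter_length` and
#'   `relative_length`.
#' @export
relative_promoter_lengths <- function(assignments, memberships,
                                      non_metabolic) {
  pl <- stats::setNames(assignments$promoter_length, assignments$gene_id)
  nm <- pl[names(pl) %in% non_metabolic]
  nm <- nm[!is.na(nm)]
  if (length(nm) == 0L) {
    stop("need at least one non-metabolic gene with a present promoter",
         call. = FALSE)
  }
  nm_mean <- mean(nm)
  if (nm_mean == 0) {
    stop("non-metabolic mean promoter length is zero; relative lengths ",
         "undefined", call. = FALSE)
  }
  out <- memberships
  out$promoter_length <- unname(pl[out$gene_id])
  out$relative_length <- NA_real_
  for (pw in unique(out$pathway_id)) {
    idx <- which(out$pathway_id == pw)
    lens <- out$promoter_length[idx]
    mu <- mean(lens, na.rm = TRUE)
    out$relative_length[idx] <- (lens - mu) / nm_mean
  }
  out
}

#' Classify a pathway chain as sparsely or pervasively regulated
#'
#' A linear reaction chain is sparsely regulated when the mean promoter
#' length of its genes is strictly below 60% of the mean promoter length
#' of the organism's non-metabolic genes, and pervasively regulated
#' otherwise (ties at exactly the threshold are pervasive).
#'
#' @param chain_lengths raw promoter lengths (bp) of the genes along the
#'   chain; `NA` entries are dropped.
#' @param non_metabolic_mean mean promoter length of non-metabolic genes.
#' @param threshold fraction of the non-metabolic mean (default 0.60).
#' @return `"sparse"` or `"pervasive"`.
#' @export
classify_pathway <- function(chain_lengths, non_metabolic_mean,
                             threshold = 0.60) {
  lens <- chain_lengths[!is.na(chain_lengths)]
  if (length(lens) < 2L) {
    stop("chain needs at least two genes with present promoters",
         call. = FALSE)
  }
  if (mean(lens) < threshold * non_metabolic_mean) "sparse" else "pervasive"
}

#' Full promoter-based regulatory analysis of one genome annotation
#'
#' Convenience pipeline over one annotation table: promoter lengths per
#' replicon, relative lengths per pathway membership, and sparse/pervasive
#' classification per pathway.
#'
#' @param annotation data.frame in the package's annotation dialect:
#'   columns `gene_id`, `replicon`, `start`, `end`, `strand`, `operon_id`,
#'   `is_metabolic`, `pathway_id`, `position` (label), `ptm_count`;
#'   one row per gene x pathway membership, `pathway_id = NA` for genes in
#'   no pathway.
#' @return list with `promoters` (per-gene table), `relative` (per
#'   membership table with `relative_length`, carrying `position`,
#'   `ptm_count` and the pathway's sparse/pervasive `class`), and
#'   `classification` (per-pathway table).
#' @export
analyze_genome <- function(annotation) {
  gene_tab <- unique(annotation[, c("gene_id", "replicon", "start", "end",
                                    "strand", "operon_id", "is_metabolic",
                                    "ptm_count")])
  proms <- do.call(rbind, lapply(split(gene_tab, gene_tab$replicon),
                                 function(g) {
    promoter_lengths(g[order(g$start), ])
  }))
  rownames(proms) <- NULL
  non_met <- gene_tab$gene_id[!gene_tab$is_metabolic]
  memb <- annotation[!is.na(annotation$pathway_id),
                     c("gene_id", "pathway_id", "position", "ptm_count")]
  rel <- relative_promoter_lengths(proms, memb, non_met)

  pl <- stats::setNames(proms$promoter_length, proms$gene_id)
  nm_mean <- mean(pl[names(pl) %in% non_met], na.rm = TRUE)
  cls <- do.call(rbind, lapply(split(rel, rel$pathway_id), function(d) {
    lens <- d$promoter_length
    ok <- sum(!is.na(lens)) >= 2L
    data.frame(pathway_id = d$pathway_id[1L],
               class = if (ok) classify_pathway(lens, nm_mean) else
                 NA_character_,
               mean_promoter = mean(lens, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(cls) <- NULL
  rel$class <- cls$class[match(rel$pathway_id, cls$pathway_id)]
  list(promoters = proms, relative = rel, classification = cls,
       non_metabolic_mean = nm_mean)
}

#' Positional comparisons of relative promoter lengths
#'
#' Pools relative promoter lengths across genomes and compares two gene
#' groups with a Wilcoxon rank-sum test.  Groupings:
#' \describe{
#'   \item{`initial_vs_terminal`}{first vs last reactions of linear
#'     chains.}
#'   \item{`pre_branch_vs_branch`}{reactions before a pathway branch vs
#'     the branching reactions.}
#'   \item{`pre_converging_vs_converging`}{reactions before a converging
#'     reaction vs the converging reaction.}
#'   \item{`ptm_vs_no_ptm`}{genes with vs without post-translational
#'     modification sites, optionally restricted to one position label via
#'     `position`.}
#' }
#' By default only genes of sparsely regulated pathways enter the
#' comparison, matching the scope of the predictions being tested.
#'
#' @param profiles a data.frame pooling the `relative` tables of
#'   [analyze_genome()] across genomes (columns `relative_length`,
#'   `position`, `ptm_count`, `class`).
#' @param grouping one of the groupings above.
#' @param position optional position label filter for `ptm_vs_no_ptm`.
#' @param sparse_only restrict to sparse-classified pathways.
#' @return a [wilcoxon_rank_sum()] comparison with group labels set to the
#'   two pools.
#' @export
positional_comparison <- function(profiles,
                                  grouping = c("initial_vs_terminal",
                                               "pre_branch_vs_branch",
                                               "pre_converging_vs_converging",
                                               "ptm_vs_no_ptm"),
                                  position = NULL, sparse_only = TRUE) {
  grouping <- match.arg(grouping)
  d <- profiles[!is.na(profiles$relative_length), , drop = FALSE]
  if (sparse_only && "class" %in% names(d)) {
    d <- d[!is.na(d$class) & d$class == "sparse", , drop = FALSE]
  }
  pick <- function(lab) d$relative_length[d$position == lab]
  gr <- switch(grouping,
    initial_vs_terminal = list(a = pick("initial"), b = pick("terminal"),
                               labels = c("initial", "terminal")),
    pre_branch_vs_branch = list(a = pick("pre_branch"), b = pick("branch"),
                                labels = c("pre_branch", "branch")),
    pre_converging_vs_converging = list(a = pick("pre_converging"),
                                        b = pick("converging"),
                                        labels = c("pre_converging",
                                                   "converging")),
    ptm_vs_no_ptm = {
      dd <- if (is.null(position)) d else d[d$position == position, ,
                                            drop = FALSE]
      list(a = dd$relative_length[dd$ptm_count > 0],
           b = dd$relative_length[dd$ptm_count == 0],
           labels = c("ptm", "no_ptm"))
    })
  if (length(gr$a) < 2L || length(gr$b) < 2L) {
    stop("each group needs at least two observations (grouping '",
         grouping, "')", call. = FALSE)
  }
  cmp <- wilcoxon_rank_sum(gr$a, gr$b)
  cmp$groups <- gr$labels
  cmp
}

#' Read an annotation table in the package's TSV dialect
#'
#' Columns: `gene_id`, `replicon`, `start`, `end`, `strand`, `operon_id`,
#' `is_metabolic`, `pathway_id`, `position`, `ptm_count`; header line
#' required, `NA` for missing operon/pathway fields.  Lines starting with
#' `#` are treated as comments (generator provenance headers).
#'
#' @param path TSV file path.
#' @return annotation data.frame as consumed by [analyze_genome()].
#' @export
read_annotation_tsv <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("gene_id", "replicon", "start", "end", "strand", "operon_id",
           "is_metabolic", "pathway_id", "position", "ptm_count")
  missing <- setdiff(req, names(d))
  if (length(missing) > 0L) {
    stop("annotation TSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d$is_metabolic <- as.logical(d$is_metabolic)
  d
}

#' Write an annotation table in the package's TSV dialect
#' @param annotation annotation data.frame.
#' @param path output file path.
#' @param seed optional seed recorded in a comment header.
#' @export
write_annotation_tsv <- function(annotation, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  write.table(annotation, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read gene records from a GFF3 file
#'
#' Convenience reader producing the same records as
#' [read_annotation_tsv()] from a GFF3 file whose gene features carry the
#' attributes `operon_id`, `is_metabolic`, `pathway_id`, `position` and
#' `ptm_count` (requires the `rtracklayer` package).
#'
#' @param path GFF3 file path.
#' @return annotation data.frame.
#' @export
read_annotation_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_annotation_gff3 requires the rtracklayer package",
         call. = FALSE)
  }
  g <- as.data.frame(rtracklayer::readGFF(path))
  g <- g[g$type == "gene", , drop = FALSE]
  get_attr <- function(nm, default) {
    if (nm %in% names(g)) g[[nm]] else rep(default, nrow(g))
  }
  data.frame(gene_id = as.character(g$ID),
             replicon = as.character(g$seqid),
             start = g$start, end = g$end,
             strand = as.character(g$strand),
             operon_id = as.character(get_attr("operon_id", NA)),
             is_metabolic = as.logical(get_attr("is_metabolic", FALSE)),
             pathway_id = as.character(get_attr("pathway_id", NA)),
             position = as.character(get_attr("position", NA)),
             ptm_count = as.integer(get_attr("ptm_count", 0L)),
             stringsAsFactors = FALSE)
}
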