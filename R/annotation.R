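#' Fisher exact overlap of a gene list with a target set
#'
#' Builds the 2x2 table a = |list & target|, b = |list \ target|,
#' c = |target \ list|, d = rest of the universe, reports the sample odds
#' ratio `ad / bc` (`Inf` when `bc = 0` and `ad > 0`; degenerate all-overlap
#' tables give p = 1) and the two-sided Fisher exact p-value. Genes outside
#' the universe are dropped with a warning.
#'
#' @param list character vector of genes (e.g. the significant genes).
#' @param target_set character vector (e.g. a disease gene set).
#' @param universe background gene universe (non-empty).
#' @return list with `overlap`, `odds_ratio`, `p`, and the `table`.
#' @export
fisher_overlap <- function(list, target_set, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  drop_n <- sum(!list %in% universe) + sum(!target_set %in% universe)
  if (drop_n > 0)
    warning(drop_n, " gene(s) outside the universe dropped")
  list <- unique(list[list %in% universe])
  target_set <- unique(target_set[target_set %in% universe])
  a <- length(intersect(list, target_set))
  b <- length(setdiff(list, target_set))
  c <- length(setdiff(target_set, list))
  d <- length(universe) - a - b - c
  tab <- matrix(c(a, b, c, d), 2, 2,
                dimnames = list(in_list = c("yes", "no"),
                                in_target = c("yes", "no")))
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c)
  p <- min(1, stats::fisher.test(tab)$p.value)  # summation can overshoot 1
  list(overlap = a, odds_ratio = or, p = p, table = tab)
}

#' Overlap enrichment of a gene list against a set collection
#'
#' Runs [fisher_overlap()] per set and adjusts across sets with
#' Benjamini-Hochberg. Rows are ordered by q, then descending odds ratio.
#'
#' @param list character vector of genes.
#' @param collection named list of gene sets (>= 1).
#' @param universe background universe; defaults to the tested gene universe
#'   the list was drawn from.
#' @param alpha FDR level (default 0.05).
#' @return data frame `set`, `overlap`, `odds_ratio`, `p`, `q`,
#'   `significant`.
#' @export
enrich_collection <- function(list, collection, universe, alpha = 0.05) {
  if (!length(collection)) stop("empty collection")
  res <- lapply(collection, function(s)
    suppressWarnings(fisher_overlap(list, s, universe)))
  out <- data.frame(
    set = names(collection),
    overlap = vapply(res, `[[`, 0, "overlap"),
    odds_ratio = vapply(res, `[[`, 0, "odds_ratio"),
    p = vapply(res, `[[`, 0, "p"),
    row.names = NULL, stringsAsFactors = FALSE)
  fdr <- bh_fdr(out$p, alpha)
  out$q <- fdr$q
  out$significant <- fdr$rejected
  out[order(out$q, -out$odds_ratio), , drop = FALSE]
}

#' Filter a protein-interaction edge list
#'
#' Keeps edges with confidence score strictly above `min_score` and both
#' endpoints in `restrict_to`; removes self-loops and duplicate undirected
#' pairs.
#'
#' @param edges data frame with columns `gene_a`, `gene_b`, `score`
#'   (scores in [0, 1]).
#' @param min_score strict lower bound on the confidence score (default
#'   0.9; an edge at exactly `min_score` is removed).
#' @param restrict_to genes both endpoints must belong to (default: no
#'   restriction).
#' @return Filtered edge data frame.
#' @export
filter_edges <- function(edges, min_score = 0.9, restrict_to = NULL) {
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(edges)))
  keep <- edges$score > min_score & edges$gene_a != edges$gene_b
  if (!is.null(restrict_to))
    keep <- keep & edges$gene_a %in% restrict_to & edges$gene_b %in% restrict_to
  out <- edges[keep, , drop = FALSE]
  key <- paste(pmin(out$gene_a, out$gene_b), pmax(out$gene_a, out$gene_b))
  out[!duplicated(key), , drop = FALSE]
}

#' Hub genes of an interaction network
#'
#' Degree (number of incident edges) is computed per connected node; the
#' `ceiling(top_frac * n_connected)` highest-degree nodes are the hubs
#' (ties broken by gene identifier, ascending). A 689-node connected
#' network yields 69 hubs at the default 10 percent.
#'
#' @param edges edge data frame (`gene_a`, `gene_b`), e.g. from
#'   [filter_edges()].
#' @param top_frac fraction of connected nodes called hubs (default 0.10).
#' @return data frame `gene_id`, `degree`, ordered by degree descending;
#'   empty for an edgeless input.
#' @export
hub_genes <- function(edges, top_frac = 0.10) {
  if (!nrow(edges))
    return(data.frame(gene_id = character(), degree = integer()))
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  deg <- igraph::degree(g)
  ord <- order(-deg, names(deg))
  n_hub <- ceiling(top_frac * length(deg))
  sel <- ord[seq_len(n_hub)]
  data.frame(gene_id = names(deg)[sel], degree = as.integer(deg[sel]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Behavioral relevance of a gene set via term activation maps
#'
#' For each behavioral term map: activation is sphere-sampled at the tissue
#' sample coordinates, correlated with every gene's expression across
#' samples (Pearson), and summarized as the mean absolute correlation
#' `|r|_mean` (both signs indicate a gene contributes to the term). Terms
#' are ranked by `|r|_mean` descending; those above `threshold` are flagged
#' selected. Constant term extractions are skipped with a warning.
#'
#' @param matrix_sig samples x genes expression matrix of the significant
#'   genes (>= 4 samples, >= 1 gene).
#' @param term_maps named list of [volume_map]s.
#' @param coords n x 3 sample MNI mm coordinates, row-aligned with
#'   `matrix_sig`.
#' @param radius_mm sphere radius (default 3).
#' @param threshold selection cut on `|r|_mean` (default 0.2, strict >).
#' @return data frame `term`, `r_abs_mean`, `n_genes`, `selected`, ordered
#'   by `r_abs_mean` descending.
#' @export
behavioral_relevance <- function(matrix_sig, term_maps, coords, radius_mm = 3,
                                 threshold = 0.2) {
  if (nrow(matrix_sig) < 4L) stop("need >= 4 samples")
  if (ncol(matrix_sig) < 1L) stop("need >= 1 gene")
  rows <- list()
  for (term in names(term_maps)) {
    act <- extract_sphere_values(term_maps[[term]], coords, radius_mm)
    ok <- is.finite(act)
    if (sum(ok) < 4L || stats::sd(act[ok]) == 0) {
      warning("term '", term, "' has a constant or empty extraction; skipped")
      next
    }
    r <- suppressWarnings(stats::cor(matrix_sig[ok, , drop = FALSE], act[ok]))
    rows[[term]] <- data.frame(term = term,
                               r_abs_mean = mean(abs(r), na.rm = TRUE),
                               n_genes = sum(!is.na(r)))
  }
  if (!length(rows))
    return(data.frame(term = character(), r_abs_mean = numeric(),
                      n_genes = integer(), selected = logical()))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$selected <- out$r_abs_mean > threshold
  out[order(-out$r_abs_mean), , drop = FALSE]
}
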