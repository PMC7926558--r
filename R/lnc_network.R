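#' Pairwise lncRNA-mRNA correlation edges
#'
#' Pearson correlation of each signature lncRNA with each hepatic
#' protein-coding gene across population individuals; p from
#' `t = r * sqrt(n-2) / sqrt(1-r^2)` (two-sided). An edge is retained iff
#' `|r| > corr_r` (strict) and `p < corr_p` (strict). Zero-variance genes are
#' skipped with one warning.
#'
#' @param expr an `expr_matrix` (population cohort; any scale).
#' @param lnc_ids,mrna_ids gene id vectors; pairs where the two ids coincide
#'   are excluded.
#' @param cfg a `run_config`.
#' @return data.frame of retained edges: lnc_id, mrna_id, r, p.
#' @export
correlate_lnc_mrna <- function(expr, lnc_ids, mrna_ids, cfg = default_config()) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- expr$values
  n <- ncol(v)
  if (n < 4) stop("need >= 4 samples for correlation p-values")
  lnc_ids <- intersect(lnc_ids, rownames(v))
  mrna_ids <- intersect(mrna_ids, rownames(v))
  sds <- apply(v[unique(c(lnc_ids, mrna_ids)), , drop = FALSE], 1, stats::sd)
  dead <- names(sds)[sds == 0]
  if (length(dead)) {
    warning(sprintf("%d zero-variance gene(s) skipped in correlation", length(dead)))
    lnc_ids <- setdiff(lnc_ids, dead)
    mrna_ids <- setdiff(mrna_ids, dead)
  }
  if (!length(lnc_ids) || !length(mrna_ids)) {
    return(data.frame(lnc_id = character(0), mrna_id = character(0),
                      r = numeric(0), p = numeric(0)))
  }
  R <- stats::cor(t(v[lnc_ids, , drop = FALSE]), t(v[mrna_ids, , drop = FALSE]))
  R <- pmin(pmax(R, -1), 1)
  tstat <- R * sqrt(n - 2) / sqrt(pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * stats::pt(-abs(tstat), n - 2)
  P[abs(R) == 1] <- 0
  idx <- which(abs(R) > cfg$corr_r & P < cfg$corr_p, arr.ind = TRUE)
  out <- data.frame(lnc_id = lnc_ids[idx[, 1]], mrna_id = mrna_ids[idx[, 2]],
                    r = R[idx], p = P[idx], stringsAsFactors = FALSE)
  out <- out[out$lnc_id != out$mrna_id, , drop = FALSE]
  out[order(out$lnc_id, out$mrna_id), , drop = FALSE]
}

#' Connected components and hub degrees of the bipartite network
#'
#' @param edges data.frame from [correlate_lnc_mrna()].
#' @return list: `membership` (data.frame node, type, component),
#'   `n_components`, `degree` (per-lncRNA hub size).
#' @export
network_components <- function(edges) {
  if (!nrow(edges)) {
    return(list(membership = data.frame(node = character(0), type = character(0),
                                        component = integer(0)),
                n_components = 0L,
                degree = data.frame(lnc_id = character(0), degree = integer(0))))
  }
  g <- igraph::graph_from_data_frame(edges[, c("lnc_id", "mrna_id")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  nodes <- names(comp$membership)
  membership <- data.frame(node = nodes,
                           type = ifelse(nodes %in% edges$lnc_id, "lncRNA", "mRNA"),
                           component = unname(comp$membership),
                           stringsAsFactors = FALSE)
  deg <- as.data.frame(table(edges$lnc_id), stringsAsFactors = FALSE)
  names(deg) <- c("lnc_id", "degree")
  list(membership = membership, n_components = comp$no,
       degree = deg[order(-deg$degree, deg$lnc_id), , drop = FALSE])
}

#' Per-lncRNA gene-set over-representation
#'
#' For each lncRNA, the query is the set of protein-coding genes it is
#' connected to; each gene set is tested by the one-sided hypergeometric tail
#' `P(X >= overlap)` against the expressed-coding-gene universe, and p-values
#' are BH-adjusted across sets within the lncRNA. Sets with no member in the
#' universe are skipped with one warning.
#'
#' @param edges data.frame from [correlate_lnc_mrna()].
#' @param gene_sets a [read_gmt()] collection.
#' @param universe character vector of universe gene ids.
#' @return data.frame: lnc_id, set_name, overlap, set_size, query_size,
#'   universe_size, p, padj.
#' @export
enrich_per_lnc <- function(edges, gene_sets, universe) {
  universe <- unique(as.character(universe))
  N <- length(universe)
  sets_u <- lapply(gene_sets, function(s) intersect(s, universe))
  empty <- names(sets_u)[lengths(sets_u) == 0]
  if (length(empty)) {
    warning(sprintf("%d gene set(s) entirely outside the universe skipped",
                    length(empty)))
    sets_u <- sets_u[lengths(sets_u) > 0]
  }
  lncs <- unique(edges$lnc_id)
  out <- lapply(lncs, function(l) {
    query <- intersect(unique(edges$mrna_id[edges$lnc_id == l]), universe)
    nq <- length(query)
    rows <- lapply(names(sets_u), function(nm) {
      K <- length(sets_u[[nm]])
      ov <- length(intersect(query, sets_u[[nm]]))
      p <- stats::phyper(ov - 1, K, N - K, nq, lower.tail = FALSE)
      data.frame(lnc_id = l, set_name = nm, overlap = ov, set_size = K,
                 query_size = nq, universe_size = N, p = p,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$padj <- bh_adjust(res$p)
    res
  })
  do.call(rbind, out)
}

#' Top-k representative pathways for a group of lncRNAs
#'
#' Each pathway's support is the number of lncRNAs in the group for which it
#' is enriched at `p_threshold`; pathways are ranked by support (descending),
#' ties by ascending median p across the group, then by name, and the top `k`
#' are returned.
#'
#' @param records [enrich_per_lnc()] output.
#' @param group character vector of lnc ids defining the group.
#' @param k number of pathways to return (default 5).
#' @param p_threshold enrichment threshold (default 0.05, nominal p).
#' @param use_padj rank on BH-adjusted instead of nominal p.
#' @return data.frame: set_name, support, median_p — at most `k` rows.
#' @export
representative_pathways <- function(records, group, k = 5, p_threshold = 0.05,
                                    use_padj = FALSE) {
  rec <- records[records$lnc_id %in% group, , drop = FALSE]
  if (!nrow(rec)) {
    return(data.frame(set_name = character(0), support = integer(0),
                      median_p = numeric(0)))
  }
  pv <- if (use_padj) rec$padj else rec$p
  sig <- rec[pv < p_threshold, , drop = FALSE]
  if (!nrow(sig)) {
    return(data.frame(set_name = character(0), support = integer(0),
                      median_p = numeric(0)))
  }
  support <- tapply(sig$lnc_id, sig$set_name, function(x) length(unique(x)))
  medp <- tapply(if (use_padj) rec$padj else rec$p, rec$set_name, stats::median)
  out <- data.frame(set_name = names(support),
                    support = as.integer(support),
                    median_p = unname(medp[names(support)]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$support, out$median_p, out$set_name), , drop = FALSE]
  utils::head(out, k)
}
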