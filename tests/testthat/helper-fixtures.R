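# Small in-code fixtures shared across test files.

tiny_gene_table <- function() {
  gene_table(c("g1", "g2", "g3"), c("protein_coding", "lncRNA", "protein_coding"))
}

tiny_counts_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("gene_id\ts1\ts2",
               "g1\t10\t0",
               "g2\t5\t5",
               "g3\t0\t100"), path)
  path
}

# count matrix with explicit values and library sizes
mk_cm <- function(m, lib = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  count_matrix(m, library_size = lib)
}

# expression matrix directly on a chosen scale (bypasses count layer)
mk_expr <- function(m, scale = "cpm") {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  structure(list(values = m, scale = scale), class = "expr_matrix")
}

# stacked DE result rows with given calls for the three contrasts
mk_calls <- function(gene_id, dha, epa, oa) {
  do.call(rbind, Map(function(ct, calls) {
    data.frame(gene_id = gene_id, contrast = paste0(ct, "_vs_vehicle"),
               log2FC = ifelse(calls == "up", 1, ifelse(calls == "down", -1, 0)),
               se = 0.1, p = ifelse(calls == "ns", 0.9, 1e-4),
               padj = ifelse(calls == "ns", 0.9, 1e-3),
               call = calls, stringsAsFactors = FALSE)
  }, list("DHA", "EPA", "OA"), list(dha, epa, oa)))
}

# scaled-down DE quotas for small simulated gene panels (sums to 50)
small_quota <- function(scale = 1) {
  round(scale * c(DHA = 8, EPA = 12, OA = 6, DHA_EPA = 10,
                  DHA_OA = 4, EPA_OA = 5, DHA_EPA_OA = 5))
}

zero_quota <- function() {
  c(DHA = 0, EPA = 0, OA = 0, DHA_EPA = 0, DHA_OA = 0, EPA_OA = 0,
    DHA_EPA_OA = 0)
}

# Brute-force BH step-up (independent of the package and of p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper tail by direct combinatorial enumeration
hyper_oracle <- function(overlap, set_size, query_size, universe_size) {
  ks <- overlap:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# Union-find connected-component count
components_oracle <- function(edges) {
  nodes <- unique(c(edges$lnc_id, edges$mrna_id))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(edges))) {
    a <- find(edges$lnc_id[i]); b <- find(edges$mrna_id[i])
    if (a != b) parent[[a]] <- b
  }
  length(unique(vapply(nodes, find, character(1))))
}
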