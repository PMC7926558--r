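#' Counts per million
#'
#' @param cm a [count_matrix()].
#' @return An `expr_matrix`: list with `values` (genes x samples, CPM scale)
#'   and `scale = "cpm"`.
#' @export
cpm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$library_size <= 0)) {
    stop("zero library size for sample ",
         colnames(cm$counts)[which(cm$library_size <= 0)[1]])
  }
  v <- sweep(cm$counts, 2, cm$library_size, `/`) * 1e6
  structure(list(values = v, scale = "cpm"), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix (%s): %d genes x %d samples\n", x$scale,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Drop samples below an aligned-read floor
#'
#' Outlier samples with too few aligned reads are removed before CPM
#' computation; the retained library sizes are then used as the CPM
#' denominator.
#'
#' @param cm a [count_matrix()].
#' @param min_library_size samples with library size strictly below this are
#'   dropped (0 disables).
#' @return A [count_matrix()] restricted to retained samples.
#' @export
drop_low_depth_samples <- function(cm, min_library_size = 0) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- cm$library_size >= min_library_size
  if (!any(keep)) stop("no sample passes the library-size floor")
  if (all(keep)) return(cm)
  count_matrix(cm$counts[, keep, drop = FALSE])
}

#' Biotype-specific expression filter
#'
#' A gene is retained iff its CPM is at or above the biotype threshold
#' (`cpm_coding` for protein-coding and `other`, `cpm_lnc` for lncRNA) in at
#' least `ceiling(frac_samples * n_samples)` samples. With the defaults this
#' is the published rule: protein-coding below CPM 1 and lncRNA below CPM 0.5
#' in fewer than half of the samples are excluded; exactly half counts as
#' retained.
#'
#' @param expr an `expr_matrix` on the CPM scale.
#' @param genes a [gene_table()] covering the matrix genes.
#' @param cfg a `run_config` (see [default_config()]).
#' @return Character vector of retained gene ids, input order preserved.
#' @export
filter_expressed <- function(expr, genes, cfg = default_config()) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$scale != "cpm") stop("filter_expressed requires a CPM-scale matrix")
  genes <- validate_gene_table(genes)
  v <- expr$values
  thr <- ifelse(genes$biotype[match(rownames(v), genes$gene_id)] == "lncRNA",
                cfg$cpm_lnc, cfg$cpm_coding)
  if (anyNA(thr)) stop("gene(s) missing from the gene table: ",
                       rownames(v)[which(is.na(thr))[1]])
  need <- ceiling(cfg$frac_samples * ncol(v))
  keep <- rowSums(v >= thr) >= need
  rownames(v)[keep]
}

#' Variance-flattening transform for sample overview
#'
#' `log2(CPM + pseudocount)`, a monotone transform that flattens the
#' mean-variance relation of counts enough for PCA visualisation.
#'
#' @param cm a [count_matrix()].
#' @param pseudocount positive offset added before the log (default 1).
#' @return An `expr_matrix` with `scale = "log2cpm"`.
#' @export
vst <- function(cm, pseudocount = 1) {
  if (!is.numeric(pseudocount) || pseudocount <= 0) stop("pseudocount must be > 0")
  x <- cpm(cm)
  structure(list(values = log2(x$values + pseudocount), scale = "log2cpm"),
            class = "expr_matrix")
}

#' PCA sample overview
#'
#' Mean-centred gene-wise principal components of the transformed expression
#' matrix; samples are scored on the top components to visualise treatment
#' clustering.
#'
#' @param expr an `expr_matrix` on the `log2cpm` scale.
#' @param design a [design_table()] covering the samples.
#' @param n_components number of components to return (default 2).
#' @return A list with `scores` (data.frame: sample_id, condition, PC1..PCk)
#'   and `explained_variance` (non-increasing fractions, sum <= 1).
#' @export
pca_overview <- function(expr, design, n_components = 2) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$scale != "log2cpm") stop("pca_overview requires a log2cpm-scale matrix")
  v <- expr$values
  if (ncol(v) < n_components + 1) stop("need at least n_components + 1 samples")
  keep <- apply(v, 1, stats::var) > 0
  if (!any(keep)) stop("constant expression matrix: no variance for PCA")
  pc <- stats::prcomp(t(v[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- data.frame(sample_id = colnames(v),
                       condition = design$condition[match(colnames(v), design$sample_id)],
                       pc$x[, seq_len(k), drop = FALSE],
                       stringsAsFactors = FALSE, row.names = NULL)
  list(scores = scores, explained_variance = ev[seq_len(k)])
}
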