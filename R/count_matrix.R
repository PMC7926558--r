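#' Construct a count matrix
#'
#' Genes x samples matrix of non-negative integer read counts with per-sample
#' library sizes. Library sizes default to column sums and are the denominator
#' of CPM normalisation.
#'
#' @param counts numeric matrix (genes in rows, samples in columns) with
#'   rownames (gene ids) and colnames (sample ids); values must be
#'   non-negative integers.
#' @param library_size optional named numeric vector of per-sample library
#'   sizes; defaults to column sums. Must be positive for every sample.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `library_size`.
#' @export
count_matrix <- function(counts, library_size = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames")
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "double"
  if (is.null(library_size)) {
    library_size <- colSums(counts)
  } else {
    library_size <- library_size[colnames(counts)]
  }
  if (any(!is.finite(library_size) | library_size <= 0)) {
    stop("library_size must be > 0 for every sample; offending sample: ",
         colnames(counts)[which(!is.finite(library_size) | library_size <= 0)[1]])
  }
  structure(list(counts = counts, library_size = library_size),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (median library size %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(stats::median(x$library_size), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a gene-level count matrix from TSV or MatrixMarket files
#'
#' TSV layout: header row of sample ids, first column `gene_id`, integer
#' cells. MTX layout: a MatrixMarket triplet file plus sidecar files listing
#' row (gene) and column (sample) ids, one per line.
#'
#' Genes absent from `gene_table` are dropped with a single warning reporting
#' how many were dropped; gene order of the file is otherwise preserved.
#'
#' @param path path to the TSV (or MTX) file.
#' @param gene_table a [gene_table()] restricting and annotating the genes.
#' @param format `"auto"` (by extension), `"tsv"`, or `"mtx"`.
#' @param genes_file,samples_file sidecar paths for MTX input; default
#'   `<path>.genes` / `<path>.samples`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, gene_table, format = c("auto", "tsv", "mtx"),
                              genes_file = NULL, samples_file = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  }
  gene_table <- validate_gene_table(gene_table)
  if (format == "tsv") {
    if (file.size(path) == 0 || length(readLines(path, n = 1L)) == 0) {
      stop("count matrix file is empty: ", path)
    }
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("count matrix TSV needs a gene_id column plus >=1 sample")
    genes <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) , arr.ind = TRUE)
      stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                   genes[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
    rownames(m) <- genes
  } else {
    if (is.null(genes_file)) genes_file <- paste0(path, ".genes")
    if (is.null(samples_file)) samples_file <- paste0(path, ".samples")
    mm <- as.matrix(Matrix::readMM(path))
    rownames(mm) <- readLines(genes_file)
    colnames(mm) <- readLines(samples_file)
    m <- mm
  }
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  unknown <- setdiff(rownames(m), gene_table$gene_id)
  if (length(unknown)) {
    warning(sprintf("dropping %d gene id(s) absent from the gene table", length(unknown)))
    m <- m[rownames(m) %in% gene_table$gene_id, , drop = FALSE]
  }
  count_matrix(m)
}

#' Write a count matrix as TSV
#'
#' @param cm a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Combine technical replicates
#'
#' Collapses columns of a count matrix that belong to the same biological
#' sample. The default combines by summing, which preserves the count nature
#' of the data; `"mean"` (rounded) is available for pre-averaged workflows.
#'
#' @param cm a [count_matrix()].
#' @param groups character or factor of length `ncol`, naming the biological
#'   sample each column belongs to.
#' @param method `"sum"` (default) or `"mean"`.
#' @return A [count_matrix()] with one column per group, in first-appearance
#'   order.
#' @export
combine_technical_replicates <- function(cm, groups, method = c("sum", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(cm, "count_matrix"), length(groups) == ncol(cm$counts))
  groups <- as.character(groups)
  lev <- unique(groups)
  m <- vapply(lev, function(g) {
    cols <- cm$counts[, groups == g, drop = FALSE]
    if (method == "sum") rowSums(cols) else round(rowMeans(cols))
  }, numeric(nrow(cm$counts)))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(lev))
  rownames(m) <- rownames(cm$counts)
  colnames(m) <- lev
  count_matrix(m)
}
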