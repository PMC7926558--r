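#' Construct a gene annotation table
#'
#' A gene table carries the per-gene annotation that governs biotype-specific
#' thresholds throughout the pipeline: expression filters use a CPM cutoff of 1
#' for protein-coding genes and 0.5 for lncRNA, and differential-expression
#' calling uses |log2FC| > 0.2 (coding) vs > 0.15 (non-coding).
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param biotype character vector, one of `"protein_coding"`, `"lncRNA"`,
#'   `"other"`. Recycled if length 1.
#' @param species character vector, `"human"` or `"mouse"` (default human).
#'   Recycled if length 1.
#' @return A `data.frame` of class `gene_table` with columns `gene_id`,
#'   `biotype`, `species`.
#' @export
gene_table <- function(gene_id, biotype = "protein_coding", species = "human") {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) {
    stop("gene_id values must be unique; duplicated: ",
         paste(utils::head(unique(gene_id[duplicated(gene_id)]), 5), collapse = ", "))
  }
  biotype <- rep_len(as.character(biotype), length(gene_id))
  species <- rep_len(as.character(species), length(gene_id))
  bad <- setdiff(unique(biotype), c("protein_coding", "lncRNA", "other"))
  if (length(bad)) stop("unknown biotype: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(species), c("human", "mouse"))
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  out <- data.frame(gene_id = gene_id, biotype = biotype, species = species,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_table", "data.frame")
  out
}

#' @rdname gene_table
#' @param x object to validate.
#' @export
validate_gene_table <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("gene_id", "biotype") %in% names(x)))
  if (is.null(x$species)) x$species <- "human"
  gene_table(x$gene_id, x$biotype, x$species)
}

#' Construct a treatment design table
#'
#' One row per sample: which fatty-acid treatment (or vehicle) it received,
#' which hepatocyte donor it came from, and its replicate index.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param condition character vector in `{vehicle, DHA, EPA, OA}`.
#' @param donor_id character vector (recycled).
#' @param replicate integer vector (recycled).
#' @return A `data.frame` of class `design_table`.
#' @export
design_table <- function(sample_id, condition, donor_id = "donor1", replicate = 1L) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample_id values must be unique")
  condition <- rep_len(as.character(condition), length(sample_id))
  bad <- setdiff(unique(condition), c("vehicle", "DHA", "EPA", "OA"))
  if (length(bad)) stop("unknown condition: ", paste(bad, collapse = ", "))
  out <- data.frame(sample_id = sample_id, condition = condition,
                    donor_id = rep_len(as.character(donor_id), length(sample_id)),
                    replicate = rep_len(as.integer(replicate), length(sample_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("design_table", "data.frame")
  out
}
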