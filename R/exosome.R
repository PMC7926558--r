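#' Read a simplified alignment table
#'
#' TSV with columns `read_id`, `contig`, `gene_id`, `score`; contigs must
#' carry the `human_` or `mouse_` prefix of the combined reference.
#'
#' @param path path to the TSV.
#' @return data.frame of alignment records.
#' @export
read_alignment_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("read_id", "contig", "gene_id", "score")
  if (!all(need %in% names(tab))) {
    stop("alignment table must have columns: ", paste(need, collapse = ", "))
  }
  .check_contigs(tab$contig)
  tab[, need]
}

.check_contigs <- function(contig) {
  ok <- grepl("^(human|mouse)_", contig)
  if (!all(ok)) stop("contig without a known species prefix: ", contig[!ok][1])
  invisible(TRUE)
}

#' Read alignment records from a SAM file
#'
#' Maps SAM records to alignment-table rows using the combined-reference
#' naming convention: reference names are `human_<gene>` / `mouse_<gene>`, so
#' the gene id is the reference name with the species prefix stripped. Primary
#' and secondary alignments are both kept; the alignment score is the `AS` tag
#' when present, otherwise MAPQ. Requires the Rsamtools package.
#'
#' @param path path to a SAM file.
#' @return data.frame of alignment records (read_id, contig, gene_id, score).
#' @export
read_alignment_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("read_alignment_sam requires the Rsamtools package")
  }
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  prm <- Rsamtools::ScanBamParam(what = c("qname", "rname", "mapq"), tag = "AS")
  x <- Rsamtools::scanBam(bam, param = prm)[[1]]
  keep <- !is.na(x$rname)
  contig <- as.character(x$rname)[keep]
  .check_contigs(contig)
  score <- x$tag$AS[keep]
  if (is.null(score)) score <- rep(NA_real_, sum(keep))
  score <- ifelse(is.na(score), as.numeric(x$mapq)[keep], as.numeric(score))
  data.frame(read_id = x$qname[keep], contig = contig,
             gene_id = sub("^(human|mouse)_", "", contig),
             score = score, stringsAsFactors = FALSE)
}

#' Assign each read a genome of origin
#'
#' A read is human iff all of its best-scoring alignments are on `human_`
#' contigs, mouse analogously; a best score achieved on both genomes makes the
#' read ambiguous (and excluded downstream — only human-specific reads feed
#' the biomarker analysis).
#'
#' @param records alignment data.frame (read_id, contig, gene_id, score).
#' @return list of class `origin_tally`: `read_origin` (data.frame read_id,
#'   origin) and `counts` (named totals human/mouse/ambiguous).
#' @export
assign_origin <- function(records) {
  .check_contigs(records$contig)
  species <- ifelse(startsWith(records$contig, "human_"), "human", "mouse")
  best <- tapply(records$score, records$read_id, max)
  is_best <- records$score == best[records$read_id]
  hum <- tapply(is_best & species == "human", records$read_id, any)
  mou <- tapply(is_best & species == "mouse", records$read_id, any)
  origin <- ifelse(hum & mou, "ambiguous", ifelse(hum, "human", "mouse"))
  read_origin <- data.frame(read_id = names(origin), origin = unname(origin),
                            stringsAsFactors = FALSE)
  counts <- c(human = sum(origin == "human"), mouse = sum(origin == "mouse"),
              ambiguous = sum(origin == "ambiguous"))
  structure(list(read_origin = read_origin, counts = counts),
            class = "origin_tally")
}

#' Per-gene counts of human-specific reads
#'
#' Counts human-assigned reads per human gene, taking each read's
#' best-scoring human alignments; a read hitting several genes contributes
#' `1/n` to each (set `fractional = FALSE` to keep uniquely assigned reads
#' only). Reads on genes absent from the gene table go to an `unassigned`
#' bucket with a warning.
#'
#' @param tally an [assign_origin()] result.
#' @param records the alignment data.frame the tally was computed from.
#' @param gene_table a [gene_table()].
#' @param fractional fractional multi-gene assignment (default TRUE).
#' @return data.frame: gene_id, count (human genes with >= 1 assigned read),
#'   with attribute `unassigned` (total weight on unknown genes).
#' @export
quantify_human_genes <- function(tally, records, gene_table, fractional = TRUE) {
  stopifnot(inherits(tally, "origin_tally"))
  gene_table <- validate_gene_table(gene_table)
  human_reads <- tally$read_origin$read_id[tally$read_origin$origin == "human"]
  rec <- records[records$read_id %in% human_reads &
                   startsWith(records$contig, "human_"), , drop = FALSE]
  if (!nrow(rec)) {
    out <- data.frame(gene_id = character(0), count = numeric(0))
    attr(out, "unassigned") <- 0
    return(out)
  }
  best <- tapply(rec$score, rec$read_id, max)
  rec <- rec[rec$score == best[rec$read_id], , drop = FALSE]
  rec <- unique(rec[, c("read_id", "gene_id")])
  ngenes <- table(rec$read_id)
  if (!fractional) {
    rec <- rec[rec$read_id %in% names(ngenes)[ngenes == 1], , drop = FALSE]
    w <- rep(1, nrow(rec))
  } else {
    w <- 1 / as.numeric(ngenes[rec$read_id])
  }
  known <- rec$gene_id %in% gene_table$gene_id[gene_table$species == "human"]
  unassigned <- sum(w[!known])
  if (unassigned > 0) {
    warning(sprintf("%.2f read(s) on genes absent from the gene table left unassigned",
                    unassigned))
  }
  cnt <- tapply(w[known], rec$gene_id[known], sum)
  out <- data.frame(gene_id = names(cnt), count = as.numeric(cnt),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$count, out$gene_id), , drop = FALSE]
  attr(out, "unassigned") <- unassigned
  out
}

#' Top-fraction detectability filter
#'
#' Ranks genes by read count (descending, ties by ascending gene id) and marks
#' the top `ceiling(frac * n)` as detectable — the accessible-biomarker
#' candidates.
#'
#' @param counts data.frame from [quantify_human_genes()].
#' @param frac fraction in (0, 1); default 0.2.
#' @return Character vector of detectable gene ids.
#' @export
top_fraction <- function(counts, frac = 0.2) {
  if (!is.numeric(frac) || frac <= 0 || frac >= 1) stop("frac must lie in (0,1)")
  if (!nrow(counts)) return(character(0))
  ord <- order(-counts$count, counts$gene_id)
  k <- ceiling(frac * nrow(counts))
  counts$gene_id[ord[seq_len(k)]]
}

#' Intersect exosome-detectable genes with variable signature genes
#'
#' @param detectable character vector from [top_fraction()].
#' @param most_variable_signatures named list of per-class gene id vectors
#'   (e.g. `most_by_class` from [stratified_signature_intersection()]).
#' @return list: `genes` (per-class intersection lists) and `counts`
#'   (data.frame class, n).
#' @export
biomarker_intersection <- function(detectable, most_variable_signatures) {
  genes <- lapply(most_variable_signatures, intersect, y = detectable)
  counts <- data.frame(class = names(genes), n = lengths(genes),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(genes = genes, counts = counts)
}
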