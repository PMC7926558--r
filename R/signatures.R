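#' Assign oleic-acid-subtracted signature classes
#'
#' Partitions the DE universe by its DHA/EPA/OA response pattern:
#' `DHA_only` (DHA-responsive, not EPA, not OA), `EPA_only`, `DHA_and_EPA`
#' (both, not OA), `OA_shared` (responsive to OA and to DHA or EPA — the
#' common unsaturated-fatty-acid effect, set aside from the signatures),
#' and `non_responsive` (everything else, including genes responding to OA
#' alone). Responsiveness means an `up` or `down` call in either direction;
#' OA subtraction excludes a gene on an OA call of any direction. DHA/EPA
#' genes with discordant directions stay in `DHA_and_EPA` but are flagged.
#'
#' @param de stacked DE results (from [run_de()]) containing the three
#'   contrasts `DHA_vs_vehicle`, `EPA_vs_vehicle`, `OA_vs_vehicle` with calls.
#' @param genes a [gene_table()].
#' @return data.frame of class `signature_assignment`: gene_id, biotype,
#'   class, dir_DHA, dir_EPA, dir_OA, discordant.
#' @export
assign_signatures <- function(de, genes) {
  genes <- validate_gene_table(genes)
  need <- c("DHA_vs_vehicle", "EPA_vs_vehicle", "OA_vs_vehicle")
  calls <- lapply(need, function(ct) {
    sub <- de[de$contrast == ct, c("gene_id", "call")]
    stats::setNames(sub$call, sub$gene_id)
  })
  names(calls) <- c("DHA", "EPA", "OA")
  universe <- unique(de$gene_id)
  for (nm in names(calls)) {
    missing <- setdiff(universe, names(calls[[nm]]))
    if (length(missing)) {
      stop("gene '", missing[1], "' lacks the ", nm, " contrast")
    }
  }
  dDHA <- calls$DHA[universe]
  dEPA <- calls$EPA[universe]
  dOA <- calls$OA[universe]
  rDHA <- dDHA != "ns"; rEPA <- dEPA != "ns"; rOA <- dOA != "ns"
  cls <- ifelse(rOA & (rDHA | rEPA), "OA_shared",
         ifelse(!rOA & rDHA & rEPA, "DHA_and_EPA",
         ifelse(!rOA & rDHA, "DHA_only",
         ifelse(!rOA & rEPA, "EPA_only", "non_responsive"))))
  out <- data.frame(gene_id = universe,
                    biotype = genes$biotype[match(universe, genes$gene_id)],
                    class = cls,
                    dir_DHA = unname(dDHA), dir_EPA = unname(dEPA),
                    dir_OA = unname(dOA),
                    discordant = rDHA & rEPA & dDHA != dEPA,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (anyNA(out$biotype)) stop("gene missing from gene table: ",
                               out$gene_id[which(is.na(out$biotype))[1]])
  class(out) <- c("signature_assignment", "data.frame")
  out
}

#' Signature composition summary
#'
#' Counts and fractions per class, biotype, and per-contrast direction — the
#' tabular analogue of the intersection and up/down-composition figures.
#'
#' @param assignments a [assign_signatures()] table.
#' @return list: `by_class` (class x biotype counts with fractions),
#'   `by_direction` (per contrast and biotype: up/down counts among responsive
#'   genes, with fractions).
#' @export
composition_summary <- function(assignments) {
  stopifnot(nrow(assignments) > 0)
  classes <- c("DHA_only", "EPA_only", "DHA_and_EPA", "OA_shared", "non_responsive")
  biotypes <- unique(assignments$biotype)
  by_class <- expand.grid(class = classes, biotype = biotypes,
                          stringsAsFactors = FALSE)
  by_class$count <- mapply(function(cl, bt) {
    sum(assignments$class == cl & assignments$biotype == bt)
  }, by_class$class, by_class$biotype)
  tot <- stats::ave(by_class$count, by_class$biotype, FUN = sum)
  by_class$fraction <- ifelse(tot > 0, by_class$count / tot, 0)

  dirs <- lapply(c("DHA", "EPA", "OA"), function(cond) {
    d <- assignments[[paste0("dir_", cond)]]
    resp <- d != "ns"
    do.call(rbind, lapply(biotypes, function(bt) {
      sel <- resp & assignments$biotype == bt
      n <- sum(sel)
      data.frame(contrast = cond, biotype = bt,
                 up = sum(d[sel] == "up"), down = sum(d[sel] == "down"),
                 frac_up = if (n > 0) sum(d[sel] == "up") / n else 0,
                 frac_down = if (n > 0) sum(d[sel] == "down") / n else 0,
                 stringsAsFactors = FALSE)
    }))
  })
  list(by_class = by_class, by_direction = do.call(rbind, dirs))
}

#' Overlap of signature classes with an external DEG set
#'
#' The cross-reference step: what fraction of each response class is also
#' changed in an external cohort (e.g. disease-progression DEGs).
#'
#' @param assignments a [assign_signatures()] table.
#' @param external_deg character vector of gene ids.
#' @return data.frame: class, n_class, overlap, fraction.
#' @export
overlap_with_external_deg <- function(assignments, external_deg) {
  external_deg <- unique(as.character(external_deg))
  if (!length(external_deg)) warning("external DEG set is empty; all overlaps are zero")
  outside <- setdiff(external_deg, assignments$gene_id)
  if (length(outside) && length(outside) < length(external_deg)) {
    warning(sprintf("%d external gene(s) outside the assignment universe were ignored",
                    length(outside)))
  }
  classes <- unique(assignments$class)
  out <- do.call(rbind, lapply(classes, function(cl) {
    g <- assignments$gene_id[assignments$class == cl]
    ov <- length(intersect(g, external_deg))
    data.frame(class = cl, n_class = length(g), overlap = ov,
               fraction = if (length(g) > 0) ov / length(g) else 0,
               stringsAsFactors = FALSE)
  }))
  out[order(out$class), , drop = FALSE]
}

#' Binary intersection (UpSet-style) membership matrix
#'
#' @param assignments a [assign_signatures()] table.
#' @return data.frame: one row per observed DHA/EPA/OA membership pattern with
#'   binary indicator columns and a count.
#' @export
upset_matrix <- function(assignments) {
  m <- data.frame(DHA = assignments$dir_DHA != "ns",
                  EPA = assignments$dir_EPA != "ns",
                  OA = assignments$dir_OA != "ns")
  key <- paste(m$DHA, m$EPA, m$OA)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(agg$key, " "))
  out <- data.frame(DHA = as.integer(as.logical(parts[, 1])),
                    EPA = as.integer(as.logical(parts[, 2])),
                    OA = as.integer(as.logical(parts[, 3])),
                    count = agg$Freq)
  out[order(-out$count), , drop = FALSE]
}
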