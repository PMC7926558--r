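#' Population expression variability (coefficient of variation)
#'
#' Per-gene CV (sample sd with n-1 denominator, divided by the mean) on the
#' CPM scale across all cohort individuals, restricted to genes passing the
#' cohort expression filter. Genes are stratified into `most_variable` (top
#' `quantile` of CV), `least_variable` (bottom `quantile`), or `middle`;
#' stratum sizes are `floor(quantile * n)` with boundary ties broken by
#' ascending gene id.
#'
#' @param expr an `expr_matrix` on the CPM scale (population cohort).
#' @param genes a [gene_table()].
#' @param cfg a `run_config`.
#' @param cohort label stored in the output (`"general"` or `"disease"`).
#' @param universe optional pre-computed [filter_expressed()] output; computed
#'   from `expr` when NULL.
#' @return data.frame of class `variability_table`: gene_id, cohort, mean_cpm,
#'   cv, stratum.
#' @export
population_cv <- function(expr, genes, cfg = default_config(),
                          cohort = "general", universe = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$scale != "cpm") stop("population_cv requires a CPM-scale matrix")
  if (is.null(universe)) universe <- filter_expressed(expr, genes, cfg)
  v <- expr$values[rownames(expr$values) %in% universe, , drop = FALSE]
  m <- rowMeans(v)
  if (any(m <= 0)) stop("gene with non-positive mean survived the expression filter")
  s <- apply(v, 1, stats::sd)
  cv <- s / m
  ord_hi <- order(-cv, rownames(v))
  ord_lo <- order(cv, rownames(v))
  k <- floor(cfg$quantile * length(cv))
  stratum <- rep("middle", length(cv))
  names(stratum) <- rownames(v)
  stratum[rownames(v)[ord_hi[seq_len(k)]]] <- "most_variable"
  stratum[rownames(v)[ord_lo[seq_len(k)]]] <- "least_variable"
  out <- data.frame(gene_id = rownames(v), cohort = cohort, mean_cpm = m,
                    cv = cv, stratum = unname(stratum[rownames(v)]),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("variability_table", "data.frame")
  out
}

#' Intersect signature classes with cross-cohort CV strata
#'
#' A signature gene counts as most (least) variable overall iff it sits in the
#' most (least) variable stratum in BOTH cohorts (set `require_both = FALSE`
#' for either-cohort membership). Reports per-class counts and the
#' most/least ratio, plus an UpSet-style membership matrix.
#'
#' @param var_general,var_disease [population_cv()] tables for the two cohorts.
#' @param assignments a [assign_signatures()] table.
#' @param require_both require stratum membership in both cohorts (default).
#' @return list: `counts` (class, n_most, n_least, ratio), `upset`
#'   (per signature gene binary stratum memberships), `most_by_class` /
#'   `least_by_class` (named lists of gene ids).
#' @export
stratified_signature_intersection <- function(var_general, var_disease,
                                              assignments, require_both = TRUE) {
  shared <- intersect(var_general$gene_id, var_disease$gene_id)
  if (!length(shared)) stop("cohort variability tables share no genes")
  comb <- if (require_both) `&` else `|`
  sg <- var_general[match(shared, var_general$gene_id), ]
  sd_ <- var_disease[match(shared, var_disease$gene_id), ]
  most <- shared[comb(sg$stratum == "most_variable", sd_$stratum == "most_variable")]
  least <- shared[comb(sg$stratum == "least_variable", sd_$stratum == "least_variable")]
  classes <- c("DHA_only", "EPA_only", "DHA_and_EPA")
  most_by_class <- lapply(classes, function(cl) {
    intersect(assignments$gene_id[assignments$class == cl], most)
  })
  least_by_class <- lapply(classes, function(cl) {
    intersect(assignments$gene_id[assignments$class == cl], least)
  })
  names(most_by_class) <- names(least_by_class) <- classes
  counts <- data.frame(class = classes,
                       n_most = lengths(most_by_class),
                       n_least = lengths(least_by_class),
                       stringsAsFactors = FALSE, row.names = NULL)
  counts$ratio <- ifelse(counts$n_least > 0, counts$n_most / counts$n_least, NA_real_)
  sig <- assignments[assignments$class %in% classes, c("gene_id", "class")]
  upset <- data.frame(sig,
                      most_general = sig$gene_id %in%
                        var_general$gene_id[var_general$stratum == "most_variable"],
                      most_disease = sig$gene_id %in%
                        var_disease$gene_id[var_disease$stratum == "most_variable"],
                      least_general = sig$gene_id %in%
                        var_general$gene_id[var_general$stratum == "least_variable"],
                      least_disease = sig$gene_id %in%
                        var_disease$gene_id[var_disease$stratum == "least_variable"],
                      stringsAsFactors = FALSE, row.names = NULL)
  list(counts = counts, upset = upset,
       most_by_class = most_by_class, least_by_class = least_by_class)
}

#' Donor response variability
#'
#' CV (sd/mean) of treatment/vehicle expression ratios across donors, per
#' gene.
#'
#' @param panel genes x donors matrix of positive ratios (>= 3 donors).
#' @return Named numeric vector of response CVs.
#' @export
response_cv <- function(panel) {
  panel <- as.matrix(panel)
  if (ncol(panel) < 3) stop("response CV needs >= 3 donors")
  bad <- which(!is.finite(panel) | panel <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive ratio at gene '%s', donor '%s'",
                 rownames(panel)[bad[1, 1]], colnames(panel)[bad[1, 2]]))
  }
  apply(panel, 1, stats::sd) / rowMeans(panel)
}

#' Validate population CV against donor response CV
#'
#' Two readouts: a two-sided Welch t-test comparing response CV between the
#' most- and least-variable population strata, and the Pearson correlation
#' between population CV and response CV (p from the t transform with n-2
#' degrees of freedom).
#'
#' @param variability a [population_cv()] table (or any data.frame with
#'   gene_id, cv, stratum).
#' @param resp_cv named numeric vector from [response_cv()].
#' @param var_equal use the equal-variance t-test instead of Welch.
#' @return list: `group_test` (t, p, n_most, n_least, means; NULL with a
#'   warning when a stratum has < 3 genes) and `correlation` (r, p, n).
#' @export
variability_validation <- function(variability, resp_cv, var_equal = FALSE) {
  g <- intersect(variability$gene_id, names(resp_cv))
  if (length(g) < 3) stop("need >= 3 genes with both population and response CV")
  v <- variability[match(g, variability$gene_id), ]
  r <- resp_cv[g]
  most <- r[v$stratum == "most_variable"]
  least <- r[v$stratum == "least_variable"]
  group_test <- NULL
  if (length(most) >= 3 && length(least) >= 3) {
    if (stats::sd(most) == 0 && stats::sd(least) == 0) {
      group_test <- list(t = 0, p = 1, n_most = length(most),
                         n_least = length(least),
                         mean_most = mean(most), mean_least = mean(least))
    } else {
      tt <- stats::t.test(most, least, var.equal = var_equal)
      group_test <- list(t = unname(tt$statistic), p = tt$p.value,
                         n_most = length(most), n_least = length(least),
                         mean_most = mean(most), mean_least = mean(least))
    }
  } else {
    warning("a CV stratum has fewer than 3 genes; group test skipped")
  }
  n <- length(g)
  rr <- stats::cor(v$cv, r)
  tstat <- rr * sqrt(n - 2) / sqrt(1 - rr^2)
  pp <- 2 * stats::pt(-abs(tstat), n - 2)
  list(group_test = group_test,
       correlation = list(r = rr, p = pp, n = n))
}
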