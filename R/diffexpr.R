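#' Method-of-moments NB dispersion per gene
#'
#' Counts are first scaled to the mean library size (depth-adjusted counts),
#' then within each contrast group the moment estimate
#' `(s^2 - mean) / mean^2` of the NB dispersion (variance = mu + phi mu^2) is
#' computed; estimates are averaged across the two groups and floored at
#' `phi_floor`. No information is shared across genes.
#'
#' @param cm a [count_matrix()].
#' @param design a [design_table()].
#' @param conditions length-2 character vector: the two contrast groups
#'   (treatment, reference).
#' @param phi_floor lower bound for the dispersion (default 1e-8).
#' @return Named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(cm, design, conditions, phi_floor = 1e-8) {
  stopifnot(inherits(cm, "count_matrix"), length(conditions) == 2)
  groups <- lapply(conditions, function(cc) {
    design$sample_id[design$condition == cc]
  })
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) {
    stop("each contrast group needs >= 2 replicates; group '",
         conditions[which(sizes < 2)[1]], "' has ", min(sizes))
  }
  lbar <- mean(cm$library_size)
  phis <- vapply(groups, function(ids) {
    k <- sweep(cm$counts[, ids, drop = FALSE], 2,
               lbar / cm$library_size[ids], `*`)
    m <- rowMeans(k)
    v <- apply(k, 1, stats::var)
    ifelse(m > 0, (v - m) / m^2, NA_real_)
  }, numeric(nrow(cm$counts)))
  phi <- rowMeans(phis, na.rm = TRUE)
  phi[is.nan(phi)] <- phi_floor
  phi <- pmax(phi_floor, phi)
  names(phi) <- rownames(cm$counts)
  phi
}

# One-gene NB GLM by iteratively reweighted least squares with fixed
# dispersion; returns coefficient vector, its covariance, and convergence.
.nb_irls <- function(y, X, offset, phi, maxit = 50, tol = 1e-8, bcap = 30) {
  p <- ncol(X)
  b <- c(log(max(mean(y / exp(offset)), 1e-10)), rep(0, p - 1))
  for (it in seq_len(maxit)) {
    eta <- offset + drop(X %*% b)
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + phi * mu)
    z <- eta + (y - mu) / mu - offset
    A <- crossprod(X * w, X)
    bn <- tryCatch(drop(solve(A, crossprod(X * w, z))),
                   error = function(e) b)
    bn <- pmin(pmax(bn, -bcap), bcap)
    if (max(abs(bn - b)) < tol) { b <- bn; break }
    b <- bn
  }
  eta <- offset + drop(X %*% b)
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + phi * mu)
  V <- tryCatch(solve(crossprod(X * w, X)), error = function(e) {
    matrix(NA_real_, p, p)
  })
  list(beta = b, vcov = V)
}

#' Negative-binomial Wald test for one contrast
#'
#' Per-gene NB GLM with log link on non-normalised counts, a log library-size
#' offset, an intercept and a treatment indicator (plus optional categorical
#' covariates). The Wald statistic `beta / se(beta)` is referenced against a
#' t distribution with residual degrees of freedom (`n - p`), which reduces to
#' the normal reference as replication grows and keeps small-sample type-I
#' error at its nominal level under plug-in dispersion.
#'
#' Genes with all-zero counts in both groups get `p = 1`, `log2FC = 0` and are
#' flagged. When exactly one group is all zero, a 0.5 pseudo-count on group
#' totals is used for the `log2FC` point estimate only, never for the test.
#'
#' @param cm a [count_matrix()].
#' @param design a [design_table()].
#' @param contrast length-2 character vector `(treatment, reference)`.
#' @param phi named per-gene dispersion vector (see [estimate_dispersion()]).
#' @param covariates optional character vector of additional `design` columns
#'   treated as factors.
#' @return data.frame: gene_id, contrast, log2FC, se, p, all_zero.
#' @export
nb_wald_test <- function(cm, design, contrast, phi, covariates = NULL) {
  stopifnot(inherits(cm, "count_matrix"), length(contrast) == 2)
  sel <- design$condition %in% contrast
  d <- design[sel, , drop = FALSE]
  y <- cm$counts[, d$sample_id, drop = FALSE]
  lib <- cm$library_size[d$sample_id]
  grp <- as.numeric(d$condition == contrast[1])
  X <- cbind(intercept = 1, treat = grp)
  if (!is.null(covariates)) {
    for (cv in covariates) {
      f <- factor(d[[cv]])
      if (nlevels(f) > 1) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cv, seq_len(ncol(mm)))
        X <- cbind(X, mm)
      }
    }
  }
  off <- log(lib)
  df <- nrow(X) - ncol(X)
  if (df < 1) stop("not enough samples for the model degrees of freedom")
  genes <- rownames(y)
  phi <- phi[genes]
  if (anyNA(phi)) stop("dispersion missing for gene ", genes[which(is.na(phi))[1]])
  n <- length(genes)
  lfc <- se <- p <- rep(NA_real_, n)
  allz <- rep(FALSE, n)
  t_tot <- rowSums(y[, grp == 1, drop = FALSE])
  r_tot <- rowSums(y[, grp == 0, drop = FALSE])
  lt <- sum(lib[grp == 1]); lr <- sum(lib[grp == 0])
  for (i in seq_len(n)) {
    if (t_tot[i] == 0 && r_tot[i] == 0) {
      lfc[i] <- 0; se[i] <- NA_real_; p[i] <- 1; allz[i] <- TRUE
      next
    }
    fit <- .nb_irls(y[i, ], X, off, phi[i])
    beta <- fit$beta[2]
    s <- sqrt(fit$vcov[2, 2])
    se[i] <- s
    p[i] <- if (is.finite(s) && s > 0) 2 * stats::pt(-abs(beta / s), df) else 1
    if (t_tot[i] == 0 || r_tot[i] == 0) {
      lfc[i] <- log2(((t_tot[i] + 0.5) / lt) / ((r_tot[i] + 0.5) / lr))
    } else {
      lfc[i] <- beta / log(2)
    }
  }
  data.frame(gene_id = genes,
             contrast = paste0(contrast[1], "_vs_", contrast[2]),
             log2FC = lfc, se = se, p = p, all_zero = allz,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: on sorted p-values,
#' `padj_(i) = min_(j>=i) (p_(j) * m / j)`, capped at 1 and mapped back to the
#' input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Vector of adjusted p-values, same order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be finite numbers in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differential expression with biotype-specific thresholds
#'
#' `up` iff `log2FC > thr` and `padj < alpha`; `down` iff `log2FC < -thr` and
#' `padj < alpha`; otherwise `ns`. Both inequalities are strict; `thr` is
#' `lfc_coding` (0.2) for protein-coding and `other` genes and `lfc_lnc`
#' (0.15) for lncRNA.
#'
#' @param results data.frame from [nb_wald_test()] with a `padj` column.
#' @param genes a [gene_table()].
#' @param cfg a `run_config`.
#' @return `results` with a `call` column added.
#' @export
call_de <- function(results, genes, cfg = default_config()) {
  if (is.null(results$padj)) stop("results must carry a padj column (run bh_adjust first)")
  genes <- validate_gene_table(genes)
  bt <- genes$biotype[match(results$gene_id, genes$gene_id)]
  if (anyNA(bt)) stop("gene missing from gene table: ",
                      results$gene_id[which(is.na(bt))[1]])
  thr <- ifelse(bt == "lncRNA", cfg$lfc_lnc, cfg$lfc_coding)
  results$call <- ifelse(results$padj < cfg$alpha & results$log2FC > thr, "up",
                  ifelse(results$padj < cfg$alpha & results$log2FC < -thr, "down",
                         "ns"))
  results
}

#' Run the full DE stage for one or more contrasts
#'
#' Dispersion estimation, NB Wald test, BH adjustment within each contrast,
#' and biotype-specific calling, over an optional pre-filtered gene universe.
#'
#' @param cm a [count_matrix()].
#' @param design a [design_table()].
#' @param genes a [gene_table()].
#' @param cfg a `run_config`.
#' @param treatments conditions tested against the reference.
#' @param reference reference condition (default `"vehicle"`).
#' @param universe optional character vector restricting the tested genes
#'   (e.g. the output of [filter_expressed()]).
#' @param covariates passed to [nb_wald_test()].
#' @return data.frame of stacked per-contrast results with `padj` and `call`.
#' @export
run_de <- function(cm, design, genes, cfg = default_config(),
                   treatments = c("DHA", "EPA", "OA"), reference = "vehicle",
                   universe = NULL, covariates = NULL) {
  if (!is.null(universe)) {
    cm <- count_matrix(cm$counts[rownames(cm$counts) %in% universe, , drop = FALSE],
                       library_size = cm$library_size)
  }
  out <- lapply(treatments, function(tr) {
    phi <- estimate_dispersion(cm, design, c(tr, reference))
    res <- nb_wald_test(cm, design, c(tr, reference), phi,
                        covariates = covariates)
    res$padj <- bh_adjust(res$p)
    call_de(res, genes, cfg)
  })
  do.call(rbind, out)
}
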