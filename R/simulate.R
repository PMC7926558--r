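#' Simulation specification for the synthetic cohorts
#'
#' Defines the statistical structure of every synthetic input: the hepatocyte
#' treatment experiment (negative-binomial counts with planted
#' condition-specific fold changes arranged so every DHA/EPA/OA intersection
#' class is populated), the general and disease population cohorts (planted
#' per-gene coefficient of variation spanning `cv_range`), the 10-donor
#' response panel (donor variance coupled to population CV through `kappa`),
#' and the exosomal alignment table (mixed human/mouse reads with a planted
#' top-quintile gene set).
#'
#' @param n_genes number of genes.
#' @param frac_lnc fraction of genes annotated lncRNA.
#' @param n_reps replicates per treatment condition (vehicle/DHA/EPA/OA).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   expected counts (at a library size of 1e6, so numerically CPM).
#' @param disp_a0,disp_a1 NB dispersion trend, phi = a0 + a1/mu
#'   (variance = mu + phi mu^2).
#' @param de_quota named integer vector of planted gene numbers for the seven
#'   response classes `DHA`, `EPA`, `OA`, `DHA_EPA`, `DHA_OA`, `EPA_OA`,
#'   `DHA_EPA_OA` (names list the conditions a gene responds to).
#' @param lfc_mean,lfc_sd,lfc_min planted |log2FC| is `max(lfc_min,
#'   |N(lfc_mean, lfc_sd^2)|)`; signs are drawn per condition from `up_frac`.
#' @param up_frac named vector: probability a planted response is upregulated,
#'   per condition.
#' @param libsize_meanlog,libsize_sdlog log-normal library-size distribution.
#' @param n_general,n_disease population cohort sizes.
#' @param cv_range planted population CV grid range (values are spread evenly
#'   over this range and permuted across genes).
#' @param cv_disease_jitter log-sd of the disease-cohort CV around the general
#'   cohort CV.
#' @param disease_overlap_frac fraction of DHA-responsive genes planted as
#'   shifted in the disease cohort (the cross-reference overlap plant).
#' @param disease_lfc |log2| shift of disease-planted genes.
#' @param n_donors donors in the response panel.
#' @param donor_base_sd baseline log-sd of donor treatment/vehicle ratios.
#' @param kappa coupling coefficient: donor log-variance =
#'   `donor_base_sd^2 + kappa * (population CV)^2`. `kappa > 0` makes
#'   population CV predictive of response CV.
#' @param exo_top_frac planted detectable fraction of human genes in exosomes.
#' @param exo_n_mouse_genes,exo_n_human_reads,exo_n_mouse_reads,exo_n_ambiguous
#'   exosome read mix.
#' @param exo_multi_frac fraction of human reads given a second equal-score
#'   alignment to another human gene (exercises fractional counting).
#' @param rng_seed integer seed; all simulators are pure functions of
#'   (spec, seed).
#' @return A validated list of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 2000, frac_lnc = 0.2, n_reps = 5,
                     baseline_meanlog = 4.5, baseline_sdlog = 1.5,
                     disp_a0 = 0.05, disp_a1 = 2,
                     de_quota = c(DHA = 80, EPA = 120, OA = 60, DHA_EPA = 100,
                                  DHA_OA = 40, EPA_OA = 50, DHA_EPA_OA = 50),
                     lfc_mean = 1, lfc_sd = 0.4, lfc_min = 0.3,
                     up_frac = c(DHA = 0.5, EPA = 0.5, OA = 0.5),
                     libsize_meanlog = log(1e6), libsize_sdlog = 0.15,
                     n_general = 100, n_disease = 100,
                     cv_range = c(0.05, 1.5), cv_disease_jitter = 0.15,
                     disease_overlap_frac = 0.7, disease_lfc = 1,
                     n_donors = 10, donor_base_sd = 0.1, kappa = 0.5,
                     exo_top_frac = 0.2, exo_n_mouse_genes = 50,
                     exo_n_human_reads = 20000, exo_n_mouse_reads = 10000,
                     exo_n_ambiguous = 200, exo_multi_frac = 0,
                     rng_seed = 1L) {
  spec <- as.list(environment())
  for (k in c("frac_lnc", "disease_overlap_frac", "exo_top_frac", "exo_multi_frac")) {
    if (spec[[k]] < 0 || spec[[k]] > 1) stop("sim_spec: ", k, " must lie in [0,1]")
  }
  if (spec$disp_a0 <= 0 || spec$disp_a1 < 0) stop("sim_spec: dispersion coefficients must be positive")
  if (spec$n_reps < 2) stop("sim_spec: n_reps must be >= 2 (differential expression is impossible otherwise)")
  if (spec$n_general < 3 || spec$n_disease < 3) stop("sim_spec: cohort sizes must be >= 3")
  if (spec$n_donors < 1) stop("sim_spec: n_donors must be >= 1")
  if (sum(de_quota) > n_genes) stop("sim_spec: DE quotas exceed n_genes")
  need <- c("DHA", "EPA", "OA", "DHA_EPA", "DHA_OA", "EPA_OA", "DHA_EPA_OA")
  if (!all(need %in% names(de_quota))) stop("sim_spec: de_quota must name all seven response classes")
  spec$rng_seed <- as.integer(rng_seed)
  structure(spec, class = c("sim_spec", "list"))
}

# Evaluate code under a given seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.draw_lfc <- function(n, spec, condition) {
  mag <- pmax(spec$lfc_min, abs(stats::rnorm(n, spec$lfc_mean, spec$lfc_sd)))
  sgn <- ifelse(stats::runif(n) < spec$up_frac[[condition]], 1, -1)
  mag * sgn
}

#' Simulate the hepatocyte treatment experiment
#'
#' Draws NB counts (variance = mu + phi mu^2) for vehicle/DHA/EPA/OA with
#' `n_reps` replicates each. Condition-specific log2 fold changes are planted
#' by explicit quotas so that every one of the seven DHA/EPA/OA response
#' classes is non-empty; vehicle fold change is 0 for every gene.
#'
#' @param spec a [sim_spec()].
#' @param seed integer seed (default `spec$rng_seed`).
#' @return A list with elements `counts` ([count_matrix()]), `design`
#'   ([design_table()]), `genes` ([gene_table()]), and `truth` (per-gene
#'   data.frame: baseline mean, planted log2FC and DE flag per condition,
#'   response class).
#' @export
simulate_hepatocyte_experiment <- function(spec, seed = spec$rng_seed) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(seed, {
    ng <- spec$n_genes
    ids <- sprintf("gene%05d", seq_len(ng))
    n_lnc <- round(spec$frac_lnc * ng)
    biotype <- rep("protein_coding", ng)
    biotype[sample.int(ng, n_lnc)] <- "lncRNA"
    genes <- gene_table(ids, biotype)

    base <- stats::rlnorm(ng, spec$baseline_meanlog, spec$baseline_sdlog)
    phi <- spec$disp_a0 + spec$disp_a1 / base

    # plant response classes by quota
    venn <- rep("none", ng)
    pool <- sample.int(ng)
    off <- 0
    for (cls in names(spec$de_quota)) {
      q <- spec$de_quota[[cls]]
      if (q > 0) venn[pool[(off + 1):(off + q)]] <- cls
      off <- off + q
    }
    responds <- function(cls, cond) vapply(strsplit(cls, "_"), function(p) cond %in% p, logical(1))
    lfc <- matrix(0, ng, 3, dimnames = list(ids, c("DHA", "EPA", "OA")))
    for (cond in c("DHA", "EPA", "OA")) {
      hit <- venn != "none" & responds(venn, cond)
      lfc[hit, cond] <- .draw_lfc(sum(hit), spec, cond)
    }

    conds <- rep(c("vehicle", "DHA", "EPA", "OA"), each = spec$n_reps)
    sample_id <- paste0(conds, "_r", rep(seq_len(spec$n_reps), 4))
    design <- design_table(sample_id, conds, donor_id = "donor1",
                           replicate = rep(seq_len(spec$n_reps), 4))
    lib <- round(stats::rlnorm(length(conds), spec$libsize_meanlog, spec$libsize_sdlog))
    cnt <- matrix(0, ng, length(conds), dimnames = list(ids, sample_id))
    for (j in seq_along(conds)) {
      fc <- if (conds[j] == "vehicle") 1 else 2^lfc[, conds[j]]
      mu <- base * fc * lib[j] / 1e6
      cnt[, j] <- stats::rnbinom(ng, mu = mu, size = 1 / phi)
    }
    truth <- data.frame(gene_id = ids, biotype = biotype, base_mean = base,
                        phi = phi,
                        lfc_DHA = lfc[, "DHA"], lfc_EPA = lfc[, "EPA"],
                        lfc_OA = lfc[, "OA"],
                        de_DHA = lfc[, "DHA"] != 0, de_EPA = lfc[, "EPA"] != 0,
                        de_OA = lfc[, "OA"] != 0,
                        venn_class = venn, stringsAsFactors = FALSE)
    list(counts = count_matrix(cnt), design = design, genes = genes, truth = truth)
  })
}

#' Simulate a population expression cohort
#'
#' Per-gene across-individual variability is planted by drawing each sample's
#' expected expression from a log-normal whose sigma is set so the planted CV
#' spans `spec$cv_range` on an evenly spaced (permuted) grid; counts are then
#' Poisson around the expected value, adding the sequencing-noise floor. The
#' disease cohort shifts a planted subset of gene means, constructed to
#' overlap the DHA-responsive genes at `disease_overlap_frac` when hepatocyte
#' ground truth is supplied.
#'
#' @param spec a [sim_spec()].
#' @param cohort `"general"` or `"disease"`.
#' @param truth optional ground-truth data.frame from
#'   [simulate_hepatocyte_experiment()] (reused gene ids/means) and, for the
#'   disease cohort, from a prior general-cohort call (shared CV plant).
#' @param seed integer seed.
#' @return A list with `counts` ([count_matrix()]), `genes` ([gene_table()]),
#'   and `truth` (input truth augmented with `pop_cv_<cohort>` and, for the
#'   disease cohort, `disease_shifted`).
#' @export
simulate_population_cohort <- function(spec, cohort = c("general", "disease"),
                                       truth = NULL, seed = spec$rng_seed) {
  stopifnot(inherits(spec, "sim_spec"))
  cohort <- match.arg(cohort)
  n_samp <- if (cohort == "general") spec$n_general else spec$n_disease
  if (n_samp < 3) stop("cohort size must be >= 3")
  with_seed(seed + if (cohort == "general") 101L else 202L, {
    if (is.null(truth)) {
      ng <- spec$n_genes
      truth <- data.frame(gene_id = sprintf("gene%05d", seq_len(ng)),
                          biotype = "protein_coding",
                          base_mean = stats::rlnorm(ng, spec$baseline_meanlog,
                                                    spec$baseline_sdlog),
                          stringsAsFactors = FALSE)
    }
    ng <- nrow(truth)
    ids <- truth$gene_id
    cvcol <- paste0("pop_cv_", cohort)
    if (cohort == "general" || is.null(truth$pop_cv_general)) {
      cv <- sample(seq(spec$cv_range[1], spec$cv_range[2], length.out = ng))
    } else {
      cv <- pmin(pmax(truth$pop_cv_general *
                        exp(stats::rnorm(ng, 0, spec$cv_disease_jitter)),
                      spec$cv_range[1]), spec$cv_range[2])
    }
    mean_shift <- rep(1, ng)
    if (cohort == "disease") {
      dha <- if (is.null(truth$de_DHA)) integer(0) else
        which(!is.na(truth$de_DHA) & truth$de_DHA)
      shifted <- logical(ng)
      if (length(dha)) {
        take <- sample(dha, round(spec$disease_overlap_frac * length(dha)))
        extra_pool <- setdiff(seq_len(ng), dha)
        extra <- sample(extra_pool, min(length(extra_pool), length(take)))
        shifted[c(take, extra)] <- TRUE
      } else {
        shifted[sample.int(ng, round(0.1 * ng))] <- TRUE
      }
      mean_shift[shifted] <- 2^(sample(c(-1, 1), sum(shifted), replace = TRUE) *
                                  spec$disease_lfc)
      truth$disease_shifted <- shifted
    }
    sigma <- sqrt(log(1 + cv^2))
    lib <- round(stats::rlnorm(n_samp, spec$libsize_meanlog, spec$libsize_sdlog))
    sid <- sprintf("%s_s%03d", cohort, seq_len(n_samp))
    cnt <- matrix(0, ng, n_samp, dimnames = list(ids, sid))
    m <- truth$base_mean * mean_shift
    for (j in seq_len(n_samp)) {
      lam <- m * exp(stats::rnorm(ng, -sigma^2 / 2, sigma)) * lib[j] / 1e6
      cnt[, j] <- stats::rpois(ng, lam)
    }
    truth[[cvcol]] <- cv
    genes <- gene_table(ids,
                        if (is.null(truth$biotype)) "protein_coding" else truth$biotype)
    list(counts = count_matrix(cnt), genes = genes, truth = truth)
  })
}

#' Simulate the donor response panel
#'
#' For each of `n_donors` donors and each requested gene, a treatment/vehicle
#' expression ratio is drawn log-normally around the planted fold change with
#' donor-level log-variance `donor_base_sd^2 + kappa * pop_cv^2`. With
#' `kappa > 0`, genes of high population CV respond more variably across
#' donors, the structure the roadmap validates.
#'
#' @param spec a [sim_spec()].
#' @param truth ground-truth data.frame carrying `pop_cv_general` and
#'   `lfc_<treatment>` columns.
#' @param gene_ids genes to include (must exist in `truth`).
#' @param treatment `"DHA"` or `"EPA"`.
#' @param seed integer seed.
#' @return A genes x donors matrix of positive ratios (class
#'   `response_panel`, attribute `treatment`).
#' @export
simulate_donor_panel <- function(spec, truth, gene_ids, treatment = c("DHA", "EPA"),
                                 seed = spec$rng_seed) {
  stopifnot(inherits(spec, "sim_spec"))
  treatment <- match.arg(treatment)
  unknown <- setdiff(gene_ids, truth$gene_id)
  if (length(unknown)) stop("unknown gene_id in donor panel: ", unknown[1])
  with_seed(seed + 303L, {
    idx <- match(gene_ids, truth$gene_id)
    cv <- truth$pop_cv_general[idx]
    if (is.null(cv) || anyNA(cv)) stop("truth lacks pop_cv_general for requested genes")
    lfc <- truth[[paste0("lfc_", treatment)]][idx]
    if (is.null(lfc)) lfc <- rep(0, length(idx))
    tau <- sqrt(spec$donor_base_sd^2 + spec$kappa * cv^2)
    m <- matrix(0, length(gene_ids), spec$n_donors,
                dimnames = list(gene_ids, sprintf("donor%02d", seq_len(spec$n_donors))))
    for (d in seq_len(spec$n_donors)) {
      m[, d] <- 2^lfc * exp(stats::rnorm(length(gene_ids), 0, tau))
    }
    structure(m, treatment = treatment, class = c("response_panel", class(m)))
  })
}

#' Simulate exosomal RNA-seq alignments against a combined reference
#'
#' Emits per-read alignment records against contigs prefixed `human_` /
#' `mouse_`. Human-gene abundances are drawn so that a planted subset ranks in
#' the top `exo_top_frac` by read count; ambiguous reads carry equal-score
#' alignments to both genomes and a configurable fraction of human reads hit
#' two human genes with equal score.
#'
#' @param spec a [sim_spec()].
#' @param gene_table a [gene_table()] containing both human- and
#'   mouse-labelled genes.
#' @param top_genes optional character vector of human genes to plant into the
#'   top quantile (defaults to a random subset of size
#'   `ceiling(exo_top_frac * n_human)`).
#' @param seed integer seed.
#' @return A list with `alignments` (data.frame: read_id, contig, gene_id,
#'   score), `read_truth` (data.frame: read_id, origin), and `planted_top`
#'   (character vector).
#' @export
simulate_exosome_reads <- function(spec, gene_table, top_genes = NULL,
                                   seed = spec$rng_seed) {
  stopifnot(inherits(spec, "sim_spec"))
  gene_table <- validate_gene_table(gene_table)
  hg <- gene_table$gene_id[gene_table$species == "human"]
  mg <- gene_table$gene_id[gene_table$species == "mouse"]
  if (!length(hg) || !length(mg)) {
    stop("gene_table must contain both human- and mouse-labelled genes")
  }
  with_seed(seed + 404L, {
    n_top <- ceiling(spec$exo_top_frac * length(hg))
    if (is.null(top_genes)) top_genes <- sample(hg, n_top)
    if (!all(top_genes %in% hg)) stop("top_genes must be human genes of the gene_table")
    w <- stats::runif(length(hg), 0.1, 1)
    names(w) <- hg
    w[top_genes] <- stats::runif(length(top_genes), 20, 40)
    kh <- if (spec$exo_n_human_reads > 0) {
      as.vector(stats::rmultinom(1, spec$exo_n_human_reads, w))
    } else rep(0L, length(hg))
    hu_gene <- rep(hg, kh)
    rec <- list()
    if (length(hu_gene)) {
      rid <- sprintf("hr%07d", seq_along(hu_gene))
      rec$human <- data.frame(read_id = rid, contig = paste0("human_", hu_gene),
                              gene_id = hu_gene, score = 60, stringsAsFactors = FALSE)
      n_multi <- round(spec$exo_multi_frac * length(hu_gene))
      if (n_multi > 0 && length(hg) > 1) {
        pick <- sample(seq_along(hu_gene), n_multi)
        second <- vapply(hu_gene[pick],
                         function(g) sample(setdiff(hg, g), 1), character(1))
        rec$multi <- data.frame(read_id = rid[pick],
                                contig = paste0("human_", second),
                                gene_id = second, score = 60,
                                stringsAsFactors = FALSE)
      }
    }
    if (spec$exo_n_mouse_reads > 0) {
      mo_gene <- sample(mg, spec$exo_n_mouse_reads, replace = TRUE)
      rec$mouse <- data.frame(read_id = sprintf("mr%07d", seq_along(mo_gene)),
                              contig = paste0("mouse_", mo_gene),
                              gene_id = mo_gene, score = 60, stringsAsFactors = FALSE)
    }
    if (spec$exo_n_ambiguous > 0) {
      aid <- sprintf("ar%07d", seq_len(spec$exo_n_ambiguous))
      ah <- sample(hg, spec$exo_n_ambiguous, replace = TRUE)
      am <- sample(mg, spec$exo_n_ambiguous, replace = TRUE)
      rec$amb <- rbind(
        data.frame(read_id = aid, contig = paste0("human_", ah), gene_id = ah,
                   score = 60, stringsAsFactors = FALSE),
        data.frame(read_id = aid, contig = paste0("mouse_", am), gene_id = am,
                   score = 60, stringsAsFactors = FALSE))
    }
    aln <- do.call(rbind, unname(rec))
    rownames(aln) <- NULL
    origin <- c(stats::setNames(rep("human", length(hu_gene)),
                                if (length(hu_gene)) sprintf("hr%07d", seq_along(hu_gene)) else character(0)),
                if (spec$exo_n_mouse_reads > 0)
                  stats::setNames(rep("mouse", spec$exo_n_mouse_reads),
                                  sprintf("mr%07d", seq_len(spec$exo_n_mouse_reads))),
                if (spec$exo_n_ambiguous > 0)
                  stats::setNames(rep("ambiguous", spec$exo_n_ambiguous),
                                  sprintf("ar%07d", seq_len(spec$exo_n_ambiguous))))
    list(alignments = aln,
         read_truth = data.frame(read_id = names(origin), origin = unname(origin),
                                 stringsAsFactors = FALSE),
         planted_top = top_genes)
  })
}
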