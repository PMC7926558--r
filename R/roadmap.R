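#' Run the full biomarker roadmap end to end
#'
#' Composes the whole procedure on synthetic cohorts: hepatocyte treatment
#' counts -> CPM + biotype expression filter -> PCA overview -> NB Wald DE for
#' the three contrasts -> OA-subtracted signature classes -> population CV in
#' general and disease cohorts -> cross-cohort most/least-variable
#' stratification of signature genes -> donor response-variability validation
#' -> exosome read-origin partitioning, top-fraction detectability and the
#' final biomarker intersection. Optionally adds the lncRNA-mRNA network and
#' gene-set enrichment stage when a gene-set collection is supplied.
#'
#' The run is a pure function of `(spec, cfg, seed)`: reruns with the same
#' arguments give identical reports.
#'
#' @param spec a [sim_spec()] describing the synthetic cohorts.
#' @param cfg a `run_config` of analysis thresholds.
#' @param seed integer seed (default `spec$rng_seed`).
#' @param gene_sets optional [read_gmt()] collection enabling the network
#'   enrichment stage.
#' @param out_dir optional directory; when given, every stage table plus the
#'   resolved configuration and a summary are written there.
#' @param panel_size genes drawn per stratum for the donor panel (default 12,
#'   i.e. a 24-gene qPCR-scale panel).
#' @param quiet suppress stage-boundary messages.
#' @return A `roadmap_report` list (see [make_report()]).
#' @export
run_roadmap <- function(spec = sim_spec(), cfg = default_config(),
                        seed = spec$rng_seed, gene_sets = NULL,
                        out_dir = NULL, panel_size = 12, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  cfg <- validate_config(cfg)

  hep <- simulate_hepatocyte_experiment(spec, seed)
  cm <- drop_low_depth_samples(hep$counts, cfg$min_library_size)
  say("hepatocyte: %d genes, %d/%d samples kept", nrow(cm$counts),
      ncol(cm$counts), ncol(hep$counts$counts))

  x <- cpm(cm)
  universe <- filter_expressed(x, hep$genes, cfg)
  say("expression filter: %d -> %d genes", nrow(cm$counts), length(universe))

  lx <- vst(cm, cfg$pseudocount)
  lx$values <- lx$values[universe, , drop = FALSE]
  pca <- pca_overview(lx, hep$design)

  de <- run_de(cm, hep$design, hep$genes, cfg, universe = universe)
  n_de <- vapply(split(de$call != "ns", de$contrast), sum, numeric(1))
  say("DE calls: %s", paste(names(n_de), n_de, sep = "=", collapse = ", "))

  assignments <- assign_signatures(de, hep$genes)
  comp <- composition_summary(assignments)

  popg <- simulate_population_cohort(spec, "general", truth = hep$truth, seed = seed)
  popd <- simulate_population_cohort(spec, "disease", truth = popg$truth, seed = seed)
  truth <- popd$truth

  external <- truth$gene_id[truth$disease_shifted]
  nafld_overlap <- overlap_with_external_deg(assignments,
                                             intersect(external, universe))

  xg <- cpm(popg$counts); xd <- cpm(popd$counts)
  var_g <- population_cv(xg, popg$genes, cfg, cohort = "general")
  var_d <- population_cv(xd, popd$genes, cfg, cohort = "disease")
  say("population CV: %d (general) / %d (disease) expressed genes",
      nrow(var_g), nrow(var_d))

  strat <- stratified_signature_intersection(var_g, var_d, assignments)

  pick <- function(pool, n) utils::head(sort(pool), n)
  panel_most <- pick(unique(unlist(strat$most_by_class)), panel_size)
  panel_least <- pick(unique(unlist(strat$least_by_class)), panel_size)
  validation <- NULL; resp <- NULL
  panel_genes <- c(panel_most, panel_least)
  if (length(panel_most) >= 3 && length(panel_least) >= 3) {
    panel <- simulate_donor_panel(spec, truth, panel_genes, "DHA", seed = seed)
    resp <- response_cv(panel)
    validation <- variability_validation(var_g, resp)
    say("validation: Welch p=%.3g, Pearson r=%.3f (p=%.3g)",
        validation$group_test$p, validation$correlation$r,
        validation$correlation$p)
  } else {
    say("validation skipped: too few most/least-variable signature genes")
  }

  network <- NULL
  if (!is.null(gene_sets)) {
    lnc_sig <- assignments$gene_id[assignments$biotype == "lncRNA" &
                                     assignments$class %in%
                                     c("DHA_only", "EPA_only", "DHA_and_EPA")]
    coding_universe <- var_g$gene_id[var_g$gene_id %in%
                                       hep$genes$gene_id[hep$genes$biotype == "protein_coding"]]
    edges <- correlate_lnc_mrna(xg, lnc_sig, coding_universe, cfg)
    comps <- network_components(edges)
    enr <- if (nrow(edges)) enrich_per_lnc(edges, gene_sets, coding_universe) else NULL
    top5 <- if (!is.null(enr)) representative_pathways(enr, lnc_sig, k = 5) else NULL
    network <- list(edges = edges, components = comps, enrichment = enr,
                    representative = top5)
    say("network: %d edges, %d components", nrow(edges), comps$n_components)
  }

  sig_most <- unique(unlist(strat$most_by_class))
  n_top <- length(sig_most)
  exosome <- NULL
  if (n_top >= 1) {
    background <- setdiff(universe, assignments$gene_id[assignments$class != "non_responsive"])
    n_bg <- min(length(background), 4 * n_top)
    exo_human <- c(sig_most, with_seed(seed + 505L, sample(background, n_bg)))
    exo_gt <- rbind(
      data.frame(gene_id = exo_human, biotype = "protein_coding",
                 species = "human", stringsAsFactors = FALSE),
      data.frame(gene_id = sprintf("mmu%05d", seq_len(spec$exo_n_mouse_genes)),
                 biotype = "protein_coding", species = "mouse",
                 stringsAsFactors = FALSE))
    exo <- simulate_exosome_reads(spec, validate_gene_table(exo_gt),
                                  top_genes = sig_most, seed = seed)
    tally <- assign_origin(exo$alignments)
    gq <- quantify_human_genes(tally, exo$alignments, validate_gene_table(exo_gt))
    detectable <- top_fraction(gq, cfg$exo_top_frac)
    biomarkers <- biomarker_intersection(detectable, strat$most_by_class)
    say("exosome: %s; %d detectable genes; biomarkers %s",
        paste(names(tally$counts), tally$counts, sep = "=", collapse = ", "),
        length(detectable),
        paste(biomarkers$counts$class, biomarkers$counts$n, sep = "=",
              collapse = ", "))
    exosome <- list(tally_counts = tally$counts, gene_counts = gq,
                    detectable = detectable, biomarkers = biomarkers)
  } else {
    say("exosome stage skipped: no most-variable signature genes")
  }

  report <- make_report(cfg = cfg, seed = seed,
                        n_genes = nrow(hep$counts$counts),
                        universe = universe, pca = pca, de = de,
                        assignments = assignments, composition = comp,
                        nafld_overlap = nafld_overlap,
                        var_general = var_g, var_disease = var_d,
                        stratified = strat, response_cv = resp,
                        validation = validation, network = network,
                        exosome = exosome)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Assemble the roadmap report
#'
#' Bundles stage outputs into a single `roadmap_report` whose summary numbers
#' are recomputed from the stage tables themselves, so report arithmetic
#' always reconciles with the stage outputs.
#'
#' @param cfg,seed provenance.
#' @param n_genes,universe,pca,de,assignments,composition,nafld_overlap
#'   stage outputs.
#' @param var_general,var_disease,stratified,response_cv,validation,network,exosome
#'   stage outputs (NULL where a stage was skipped).
#' @return A list of class `roadmap_report`.
#' @export
make_report <- function(cfg, seed, n_genes, universe, pca, de, assignments,
                        composition, nafld_overlap, var_general, var_disease,
                        stratified, response_cv = NULL, validation = NULL,
                        network = NULL, exosome = NULL) {
  class_counts <- table(factor(assignments$class,
                               levels = c("DHA_only", "EPA_only", "DHA_and_EPA",
                                          "OA_shared", "non_responsive")))
  summary <- list(
    seed = seed,
    n_genes_simulated = n_genes,
    n_expressed = length(universe),
    n_de = vapply(split(de$call != "ns", de$contrast), sum, numeric(1)),
    class_counts = as.vector(class_counts),
    class_names = names(class_counts),
    most_least = stratified$counts,
    validation = if (!is.null(validation)) {
      c(welch_t = validation$group_test$t, welch_p = validation$group_test$p,
        pearson_r = validation$correlation$r,
        pearson_p = validation$correlation$p)
    },
    biomarker_counts = if (!is.null(exosome)) exosome$biomarkers$counts
  )
  structure(list(config = cfg, summary = summary, pca = pca, de = de,
                 assignments = assignments, composition = composition,
                 nafld_overlap = nafld_overlap, var_general = var_general,
                 var_disease = var_disease, stratified = stratified,
                 response_cv = response_cv, validation = validation,
                 network = network, exosome = exosome),
            class = "roadmap_report")
}

#' @export
print.roadmap_report <- function(x, ...) {
  s <- x$summary
  cat("roadmap_report\n")
  cat(sprintf("  seed %d: %d genes simulated, %d expressed\n", s$seed,
              s$n_genes_simulated, s$n_expressed))
  cat("  DE calls:", paste(names(s$n_de), s$n_de, sep = "=", collapse = ", "), "\n")
  cat("  classes:", paste(s$class_names, s$class_counts, sep = "=",
                          collapse = ", "), "\n")
  if (!is.null(s$validation)) {
    cat(sprintf("  validation: Welch p=%.3g; Pearson r=%.3f (p=%.3g)\n",
                s$validation[["welch_p"]], s$validation[["pearson_r"]],
                s$validation[["pearson_p"]]))
  }
  if (!is.null(s$biomarker_counts)) {
    cat("  exosome biomarkers:",
        paste(s$biomarker_counts$class, s$biomarker_counts$n, sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a roadmap report to disk
#'
#' Writes each stage table as TSV plus the resolved configuration and a
#' key-value summary; the files are deterministic (no timestamps), so a rerun
#' under the same seed reproduces them byte for byte.
#'
#' @param report a `roadmap_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(report$config, file.path(out_dir, "config.yaml"))
  .write_tsv(report$de, file.path(out_dir, "de_results.tsv"))
  .write_tsv(report$assignments, file.path(out_dir, "signature_assignments.tsv"))
  .write_tsv(report$composition$by_class, file.path(out_dir, "composition_by_class.tsv"))
  .write_tsv(report$composition$by_direction, file.path(out_dir, "composition_by_direction.tsv"))
  .write_tsv(report$nafld_overlap, file.path(out_dir, "external_overlap.tsv"))
  .write_tsv(report$var_general, file.path(out_dir, "variability_general.tsv"))
  .write_tsv(report$var_disease, file.path(out_dir, "variability_disease.tsv"))
  .write_tsv(report$stratified$counts, file.path(out_dir, "stratified_counts.tsv"))
  .write_tsv(report$stratified$upset, file.path(out_dir, "stratified_upset.tsv"))
  .write_tsv(report$pca$scores, file.path(out_dir, "pca_scores.tsv"))
  if (!is.null(report$response_cv)) {
    .write_tsv(data.frame(gene_id = names(report$response_cv),
                          response_cv = unname(report$response_cv)),
               file.path(out_dir, "response_cv.tsv"))
  }
  if (!is.null(report$network)) {
    .write_tsv(report$network$edges, file.path(out_dir, "network_edges.tsv"))
    if (!is.null(report$network$enrichment)) {
      .write_tsv(report$network$enrichment, file.path(out_dir, "enrichment.tsv"))
    }
  }
  if (!is.null(report$exosome)) {
    .write_tsv(report$exosome$gene_counts, file.path(out_dir, "exosome_gene_counts.tsv"))
    writeLines(report$exosome$detectable, file.path(out_dir, "exosome_detectable.txt"))
    .write_tsv(report$exosome$biomarkers$counts, file.path(out_dir, "biomarker_counts.tsv"))
  }
  s <- report$summary
  lines <- c(sprintf("seed\t%d", s$seed),
             sprintf("n_genes_simulated\t%d", s$n_genes_simulated),
             sprintf("n_expressed\t%d", s$n_expressed),
             sprintf("n_de_%s\t%d", names(s$n_de), s$n_de),
             sprintf("class_%s\t%d", s$class_names, s$class_counts),
             sprintf("most_%s\t%d", s$most_least$class, s$most_least$n_most),
             sprintf("least_%s\t%d", s$most_least$class, s$most_least$n_least))
  if (!is.null(s$validation)) {
    lines <- c(lines, sprintf("%s\t%.10g", names(s$validation), s$validation))
  }
  if (!is.null(s$biomarker_counts)) {
    lines <- c(lines, sprintf("biomarkers_%s\t%d", s$biomarker_counts$class,
                              s$biomarker_counts$n))
  }
  writeLines(lines, file.path(out_dir, "summary.tsv"))
  invisible(out_dir)
}
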