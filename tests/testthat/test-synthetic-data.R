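test_that("spec validation rejects impossible designs", {
  expect_error(sim_spec(n_reps = 1), "n_reps")
  expect_error(sim_spec(n_general = 2), "cohort sizes")
  expect_error(sim_spec(frac_lnc = 1.2), "frac_lnc")
  expect_error(sim_spec(n_genes = 100,
                        de_quota = c(DHA = 50, EPA = 50, OA = 50, DHA_EPA = 0,
                                     DHA_OA = 0, EPA_OA = 0, DHA_EPA_OA = 0)),
               "quotas exceed")
})

test_that("null plant gives unit treatment/vehicle mean ratios", {
  spec <- sim_spec(n_genes = 300, n_reps = 10,
                   de_quota = c(DHA = 0, EPA = 0, OA = 0, DHA_EPA = 0,
                                DHA_OA = 0, EPA_OA = 0, DHA_EPA_OA = 0))
  sim <- simulate_hepatocyte_experiment(spec, seed = 5)
  expect_true(all(sim$truth$lfc_DHA == 0))
  x <- cpm(sim$counts)$values
  dha <- rowMeans(x[, sim$design$sample_id[sim$design$condition == "DHA"]])
  veh <- rowMeans(x[, sim$design$sample_id[sim$design$condition == "vehicle"]])
  hi <- sim$truth$base_mean > 100  # ratio is noisy for weakly expressed genes
  expect_equal(median(dha[hi] / veh[hi]), 1, tolerance = 0.1)
})

test_that("a planted strong response reproduces its NB mean", {
  # gene planted at log2FC = +2 under DHA, baseline 100: the empirical DHA
  # mean over many seed replicates must match 400 within sampling error
  spec <- sim_spec(n_genes = 50, n_reps = 5, baseline_meanlog = log(100),
                   baseline_sdlog = 0, lfc_mean = 2, lfc_sd = 0, lfc_min = 2,
                   up_frac = c(DHA = 1, EPA = 1, OA = 1),
                   libsize_sdlog = 0,
                   de_quota = c(DHA = 50, EPA = 0, OA = 0, DHA_EPA = 0,
                                DHA_OA = 0, EPA_OA = 0, DHA_EPA_OA = 0))
  reps <- vapply(1:100, function(s) {
    sim <- simulate_hepatocyte_experiment(spec, seed = s)
    dha <- sim$design$sample_id[sim$design$condition == "DHA"]
    mean(sim$counts$counts[, dha])
  }, numeric(1))
  mu <- 400
  phi <- spec$disp_a0 + spec$disp_a1 / 100
  # SE of the grand mean over 100 replicates x 50 genes x 5 samples
  se <- sqrt((mu + phi * mu^2) / (100 * 50 * 5))
  expect_lt(abs(mean(reps) - mu), 4 * se * sqrt(50 * 5))  # genes share draws within a seed
})

test_that("lncRNA fraction and venn quotas are honoured exactly", {
  spec <- sim_spec()
  sim <- simulate_hepatocyte_experiment(spec, seed = 1)
  expect_equal(sum(sim$genes$biotype == "lncRNA"), 400)
  tab <- table(sim$truth$venn_class)
  for (cls in names(spec$de_quota)) {
    expect_equal(unname(tab[[cls]]), unname(spec$de_quota[[cls]]))
  }
  # vehicle is flat: no lfc column applies to it by construction
  expect_true(all(sim$truth$lfc_DHA[sim$truth$venn_class == "none"] == 0))
})

test_that("simulators are deterministic in (spec, seed)", {
  spec <- sim_spec(n_genes = 200, n_general = 10, de_quota = small_quota())
  a <- simulate_hepatocyte_experiment(spec, seed = 3)
  b <- simulate_hepatocyte_experiment(spec, seed = 3)
  expect_identical(a$counts$counts, b$counts$counts)
  pa <- simulate_population_cohort(spec, "general", seed = 3)
  pb <- simulate_population_cohort(spec, "general", seed = 3)
  expect_identical(pa$counts$counts, pb$counts$counts)
  c1 <- simulate_hepatocyte_experiment(spec, seed = 4)
  expect_false(identical(a$counts$counts, c1$counts$counts))
})

test_that("planted population CV is recovered and sigma->0 hits the Poisson floor", {
  spec <- sim_spec(n_genes = 2000, n_general = 100)
  pop <- simulate_population_cohort(spec, "general", seed = 11)
  est <- population_cv(cpm(pop$counts), pop$genes, default_config())
  truth <- pop$truth[match(est$gene_id, pop$truth$gene_id), ]
  expect_gte(cor(truth$pop_cv_general, est$cv, method = "spearman"), 0.8)

  # degenerate plant: cv range collapsed to its floor leaves only Poisson noise
  spec0 <- sim_spec(n_genes = 50, n_general = 50, cv_range = c(1e-6, 1e-6),
                    baseline_meanlog = log(1000), baseline_sdlog = 0,
                    de_quota = zero_quota())
  pop0 <- simulate_population_cohort(spec0, "general", seed = 2)
  est0 <- population_cv(cpm(pop0$counts), pop0$genes, default_config())
  # Poisson floor at mean 1000 counts is ~ 1/sqrt(1000)
  expect_lt(max(est0$cv), 3 / sqrt(1000))
})

test_that("donor panel couples response variance to population CV via kappa", {
  spec <- sim_spec(n_genes = 200, kappa = 0.5, de_quota = small_quota())
  pop <- simulate_population_cohort(spec, "general", seed = 8)
  truth <- pop$truth
  truth$lfc_DHA <- 0.5
  panel_genes <- truth$gene_id[order(truth$pop_cv_general)][seq(1, 200, by = 8)][1:24]
  panel <- simulate_donor_panel(spec, truth, panel_genes, "DHA", seed = 8)
  expect_equal(dim(panel), c(24, 10))
  rcv <- response_cv(panel)
  ct <- cor.test(truth$pop_cv_general[match(panel_genes, truth$gene_id)], rcv)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("kappa = 0 panels carry no population-CV structure", {
  spec <- sim_spec(n_genes = 200, kappa = 0, de_quota = small_quota())
  pop <- simulate_population_cohort(spec, "general", seed = 8)
  truth <- pop$truth
  truth$lfc_DHA <- 0.5
  panel_genes <- truth$gene_id[order(truth$pop_cv_general)][seq(1, 192, by = 8)]
  pvals <- vapply(1:40, function(s) {
    panel <- simulate_donor_panel(spec, truth, panel_genes, "DHA", seed = s)
    cor.test(truth$pop_cv_general[match(panel_genes, truth$gene_id)],
             response_cv(panel))$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("zero variance components give ratios of exactly 2^lfc", {
  spec <- sim_spec(n_donors = 1, donor_base_sd = 0, kappa = 0)
  truth <- data.frame(gene_id = "g1", pop_cv_general = 0.4, lfc_DHA = 1.5)
  panel <- simulate_donor_panel(spec, truth, "g1", "DHA", seed = 1)
  expect_equal(unname(panel[1, 1]), 2^1.5)
  expect_error(simulate_donor_panel(spec, truth, "nope", "DHA"), "unknown gene_id")
})

test_that("exosome simulation constructs the stated read mix", {
  gt <- gene_table(c(sprintf("hs%03d", 1:50), sprintf("mm%03d", 1:10)),
                   species = rep(c("human", "mouse"), c(50, 10)))
  spec <- sim_spec(exo_n_human_reads = 2000, exo_n_mouse_reads = 500,
                   exo_n_ambiguous = 100)
  exo <- simulate_exosome_reads(spec, gt, seed = 4)
  amb <- exo$read_truth$read_id[exo$read_truth$origin == "ambiguous"]
  expect_length(amb, 100)
  two <- table(exo$alignments$read_id[exo$alignments$read_id %in% amb])
  expect_true(all(two == 2))

  # zero mouse reads: everything downstream is human
  spec0 <- sim_spec(exo_n_human_reads = 500, exo_n_mouse_reads = 0,
                    exo_n_ambiguous = 0)
  exo0 <- simulate_exosome_reads(spec0, gt, seed = 4)
  tal <- assign_origin(exo0$alignments)
  expect_equal(unname(tal$counts["human"]), 500)
  expect_equal(unname(tal$counts["mouse"] + tal$counts["ambiguous"]), 0)

  expect_error(simulate_exosome_reads(spec, gene_table("hs1", species = "human")),
               "both human- and mouse")
})

test_that("planted top-quintile genes are recovered exactly by the filter", {
  gt <- gene_table(c(sprintf("hs%03d", 1:100), "mm001"),
                   species = rep(c("human", "mouse"), c(100, 1)))
  spec <- sim_spec(exo_n_human_reads = 50000, exo_n_mouse_reads = 100,
                   exo_n_ambiguous = 0)
  exo <- simulate_exosome_reads(spec, gt, seed = 9)
  tal <- assign_origin(exo$alignments)
  gq <- quantify_human_genes(tal, exo$alignments, gt)
  expect_setequal(top_fraction(gq, 0.2), exo$planted_top)
})
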