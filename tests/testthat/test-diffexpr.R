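de_design <- function(n) {
  design_table(c(paste0("v", 1:n), paste0("t", 1:n)),
               rep(c("vehicle", "DHA"), each = n))
}

test_that("dispersion estimate floors on Poisson and constant data", {
  set.seed(21)
  n <- 10
  d <- de_design(n)
  m <- matrix(rpois(1000 * 2 * n, 500), 1000, 2 * n,
              dimnames = list(paste0("g", 1:1000), d$sample_id))
  cm <- count_matrix(m, lib = setNames(rep(1e6, 2 * n), d$sample_id))
  phi <- estimate_dispersion(cm, d, c("DHA", "vehicle"))
  # Poisson data: moment estimate centred at zero, so about half floor out
  expect_gte(mean(phi <= 0.001), 0.45)
  expect_lt(median(phi), 0.005)

  const <- count_matrix(matrix(7, 2, 2 * n,
                               dimnames = list(c("a", "b"), d$sample_id)),
                        lib = setNames(rep(1e6, 2 * n), d$sample_id))
  expect_equal(unname(estimate_dispersion(const, d, c("DHA", "vehicle"))),
               rep(1e-8, 2))

  expect_error(estimate_dispersion(cm, d[-(1:(n - 1)), ], c("DHA", "vehicle")),
               ">= 2 replicates")
})

test_that("dispersion estimate recovers a planted value", {
  set.seed(22)
  n <- 10
  d <- de_design(n)
  m <- matrix(rnbinom(1000 * 2 * n, mu = 500, size = 1 / 0.1), 1000, 2 * n,
              dimnames = list(paste0("g", 1:1000), d$sample_id))
  cm <- count_matrix(m, lib = setNames(rep(1e6, 2 * n), d$sample_id))
  phi <- estimate_dispersion(cm, d, c("DHA", "vehicle"))
  expect_gt(median(phi), 0.05)
  expect_lt(median(phi), 0.2)
})

test_that("Wald test recovers a planted fold change without material bias", {
  set.seed(23)
  nsim <- 500; n <- 5
  d <- de_design(n)
  lib <- setNames(rep(1e6, 2 * n), d$sample_id)
  m <- cbind(matrix(rnbinom(nsim * n, mu = 100, size = 1 / 0.01), nsim, n),
             matrix(rnbinom(nsim * n, mu = 400, size = 1 / 0.01), nsim, n))
  rownames(m) <- paste0("g", 1:nsim); colnames(m) <- d$sample_id
  cm <- count_matrix(m, lib = lib)
  phi <- setNames(rep(0.01, nsim), rownames(m))
  # vehicle columns hold mu=100, DHA columns mu=400; contrast DHA vs vehicle
  res2 <- nb_wald_test(cm, d, c("DHA", "vehicle"), phi)
  expect_lt(abs(mean(res2$log2FC) - 2), 0.1)
  expect_gt(mean(res2$p < 0.05), 0.99)
})

test_that("swapping group labels negates log2FC and keeps p", {
  set.seed(24)
  n <- 4
  d <- de_design(n)
  m <- matrix(rnbinom(40 * 2 * n, mu = 200, size = 10), 40, 2 * n,
              dimnames = list(paste0("g", 1:40), d$sample_id))
  cm <- count_matrix(m)
  phi <- estimate_dispersion(cm, d, c("DHA", "vehicle"))
  a <- nb_wald_test(cm, d, c("DHA", "vehicle"), phi)
  b <- nb_wald_test(cm, d, c("vehicle", "DHA"), phi)
  expect_equal(a$log2FC, -b$log2FC, tolerance = 1e-6)
  expect_equal(a$p, b$p, tolerance = 1e-6)
})

test_that("degenerate genes are handled as defined", {
  n <- 3
  d <- de_design(n)
  m <- rbind(allzero = rep(0, 2 * n),
             onegrp = c(0, 0, 0, 20, 30, 25))
  colnames(m) <- d$sample_id
  cm <- count_matrix(m, lib = setNames(rep(1e6, 2 * n), d$sample_id))
  phi <- setNames(c(0.1, 0.1), rownames(m))
  res <- nb_wald_test(cm, d, c("DHA", "vehicle"), phi)
  expect_equal(res$p[res$gene_id == "allzero"], 1)
  expect_equal(res$log2FC[res$gene_id == "allzero"], 0)
  expect_true(res$all_zero[res$gene_id == "allzero"])
  # one group all zero: pseudo-counted point estimate, finite and positive
  lfc1 <- res$log2FC[res$gene_id == "onegrp"]
  expect_true(is.finite(lfc1))
  expect_equal(lfc1, log2((75.5 / 3e6) / (0.5 / 3e6)))
})

test_that("BH adjustment matches the brute-force step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1.0), 1.0)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("calling thresholds are biotype-specific and strict", {
  cfg <- default_config()
  gt <- gene_table(c("cod", "lnc", "cod2", "cod3"),
                   c("protein_coding", "lncRNA", "protein_coding", "protein_coding"))
  res <- data.frame(gene_id = c("cod", "lnc", "cod2", "cod3"),
                    contrast = "DHA_vs_vehicle",
                    log2FC = c(0.2, 0.18, 1.5, -0.25),
                    se = 0.1, p = c(0.001, 0.001, 0.02, 0.001),
                    padj = c(0.01, 0.01, 0.06, 0.01))
  out <- call_de(res, gt, cfg)
  expect_equal(out$call, c("ns",   # exactly at the coding threshold: strict
                           "up",   # 0.18 > 0.15 lncRNA threshold
                           "ns",   # fails alpha
                           "down"))
  expect_error(call_de(res[, setdiff(names(res), "padj")], gt, cfg), "padj")
  res$gene_id[1] <- "ghost"
  expect_error(call_de(res, gt, cfg), "missing from gene table")
})

test_that("null simulation is calibrated and planted effects are recovered", {
  spec <- sim_spec(n_genes = 1000, n_reps = 5,
                   de_quota = c(DHA = 0, EPA = 0, OA = 0, DHA_EPA = 0,
                                DHA_OA = 0, EPA_OA = 0, DHA_EPA_OA = 0))
  sim <- simulate_hepatocyte_experiment(spec, seed = 17)
  de <- run_de(sim$counts, sim$design, sim$genes, treatments = "DHA")
  expect_gt(mean(de$p < 0.05), 0.02)
  expect_lt(mean(de$p < 0.05), 0.08)

  spec2 <- sim_spec(n_genes = 1000, n_reps = 5)
  sim2 <- simulate_hepatocyte_experiment(spec2, seed = 18)
  de2 <- run_de(sim2$counts, sim2$design, sim2$genes, treatments = "DHA")
  tr <- sim2$truth[match(de2$gene_id, sim2$truth$gene_id), ]
  strong <- abs(tr$lfc_DHA) >= 1 & tr$base_mean >= 50
  called <- de2$call != "ns"
  expect_gte(mean(called[strong]), 0.8)
  fdr <- sum(called & !tr$de_DHA) / max(1, sum(called))
  expect_lte(fdr, 0.1)
})
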