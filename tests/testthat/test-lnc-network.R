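lnc_expr <- function(n_samples = 30, seed = 61) {
  set.seed(seed)
  base <- rnorm(n_samples)
  v <- rbind(lnc_pos = base,
             lnc_null = rnorm(n_samples),
             m_pos = base + rnorm(n_samples, sd = 0.2),
             m_neg = -base + rnorm(n_samples, sd = 0.2),
             m_null = rnorm(n_samples),
             m_flat = rep(3, n_samples))
  colnames(v) <- paste0("s", 1:n_samples)
  mk_expr(v, "log2cpm")
}

test_that("correlation edges apply strict |r| and p thresholds", {
  expr <- lnc_expr()
  expect_warning(
    edges <- correlate_lnc_mrna(expr, c("lnc_pos", "lnc_null"),
                                c("m_pos", "m_neg", "m_null", "m_flat")),
    "zero-variance")
  expect_setequal(edges$mrna_id[edges$lnc_id == "lnc_pos"], c("m_pos", "m_neg"))
  expect_false("lnc_null" %in% edges$lnc_id)
  expect_gt(edges$r[edges$mrna_id == "m_pos"], 0.6)
  expect_lt(edges$r[edges$mrna_id == "m_neg"], -0.6)
  expect_true(all(edges$p < 0.05))

  # edges agree with cor.test on the same pairs
  ref <- cor.test(expr$values["lnc_pos", ], expr$values["m_pos", ])
  expect_equal(edges$r[edges$mrna_id == "m_pos"], unname(ref$estimate),
               tolerance = 1e-12)
  expect_equal(edges$p[edges$mrna_id == "m_pos"], ref$p.value, tolerance = 1e-12)
})

test_that("threshold boundaries are strict and self-pairs are excluded", {
  # a perfectly correlated pair has r exactly 1: with corr_r = 1 the strict
  # |r| > corr_r rule must drop it, while the default threshold keeps it
  n <- 10
  set.seed(64)
  x <- rnorm(n)
  v <- rbind(lnc_a = x, m_a = 2 * x + 3)
  colnames(v) <- paste0("s", 1:n)
  cfg1 <- default_config(); cfg1$corr_r <- 1
  expect_equal(nrow(correlate_lnc_mrna(mk_expr(v, "log2cpm"), "lnc_a", "m_a",
                                       cfg1)), 0)
  kept <- correlate_lnc_mrna(mk_expr(v, "log2cpm"), "lnc_a", "m_a")
  expect_equal(nrow(kept), 1)
  expect_equal(kept$p, 0)

  # the same id listed on both sides never yields a self edge
  v2 <- rbind(dual = x, m_b = x + rnorm(n, sd = 0.05))
  colnames(v2) <- paste0("s", 1:n)
  e2 <- correlate_lnc_mrna(mk_expr(v2, "log2cpm"), "dual", c("dual", "m_b"))
  expect_false(any(e2$lnc_id == e2$mrna_id))

  expect_error(correlate_lnc_mrna(mk_expr(v[, 1:3], "log2cpm"), "lnc_a", "m_a"),
               ">= 4 samples")
})

test_that("component counts match a union-find oracle on random graphs", {
  set.seed(62)
  for (i in 1:30) {
    n_l <- sample(2:6, 1); n_m <- sample(2:8, 1)
    pairs <- expand.grid(lnc_id = paste0("L", 1:n_l),
                         mrna_id = paste0("M", 1:n_m),
                         stringsAsFactors = FALSE)
    edges <- pairs[runif(nrow(pairs)) < 0.25, , drop = FALSE]
    if (!nrow(edges)) next
    edges$r <- 0.9; edges$p <- 1e-4
    nc <- network_components(edges)
    expect_equal(nc$n_components, components_oracle(edges))
    expect_equal(sum(nc$degree$degree), nrow(edges))
  }
  empty <- network_components(data.frame(lnc_id = character(0),
                                         mrna_id = character(0),
                                         r = numeric(0), p = numeric(0)))
  expect_equal(empty$n_components, 0L)
})

test_that("hub degrees and membership types are reported correctly", {
  edges <- data.frame(lnc_id = c("L1", "L1", "L1", "L2"),
                      mrna_id = c("M1", "M2", "M3", "M3"),
                      r = 0.8, p = 1e-3, stringsAsFactors = FALSE)
  nc <- network_components(edges)
  expect_equal(nc$n_components, 1L)
  expect_equal(nc$degree$lnc_id[1], "L1")
  expect_equal(nc$degree$degree, c(3L, 1L))
  mem <- nc$membership
  expect_equal(sort(mem$node[mem$type == "lncRNA"]), c("L1", "L2"))
  expect_equal(sort(mem$node[mem$type == "mRNA"]), c("M1", "M2", "M3"))
})

test_that("hypergeometric enrichment matches the combinatorial oracle", {
  universe <- paste0("u", 1:40)
  edges <- data.frame(lnc_id = "L1", mrna_id = paste0("u", 1:8),
                      r = 0.9, p = 1e-4, stringsAsFactors = FALSE)
  sets <- list(hit = paste0("u", c(1:6, 30:33)),   # 6 of 10 in the query
               miss = paste0("u", 35:40),
               outside = paste0("x", 1:3))
  expect_warning(res <- enrich_per_lnc(edges, sets, universe),
                 "outside the universe")
  expect_setequal(res$set_name, c("hit", "miss"))
  hit <- res[res$set_name == "hit", ]
  expect_equal(hit$overlap, 6)
  expect_equal(hit$p, hyper_oracle(6, 10, 8, 40), tolerance = 1e-12)
  miss <- res[res$set_name == "miss", ]
  expect_equal(miss$p, hyper_oracle(0, 6, 8, 40), tolerance = 1e-12)
  expect_equal(miss$p, 1)  # zero overlap: upper tail from 0 is certain
  expect_equal(res$padj, bh_adjust(res$p))

  # randomized agreement across many configurations
  set.seed(63)
  for (i in 1:30) {
    N <- sample(20:60, 1)
    uni <- paste0("g", 1:N)
    q <- sample(uni, sample(3:10, 1))
    s <- sample(uni, sample(3:15, 1))
    e <- data.frame(lnc_id = "L", mrna_id = q, r = 0.9, p = 1e-4,
                    stringsAsFactors = FALSE)
    r1 <- enrich_per_lnc(e, list(S = s), uni)
    expect_equal(r1$p, hyper_oracle(length(intersect(q, s)), length(s),
                                    length(q), N), tolerance = 1e-12)
  }
})

test_that("representative pathways rank by support then median p", {
  rec <- rbind(
    data.frame(lnc_id = "L1", set_name = c("A", "B", "C"),
               p = c(0.001, 0.01, 0.2), stringsAsFactors = FALSE),
    data.frame(lnc_id = "L2", set_name = c("A", "B", "C"),
               p = c(0.002, 0.3, 0.04), stringsAsFactors = FALSE),
    data.frame(lnc_id = "L3", set_name = c("A", "B", "C"),
               p = c(0.5, 0.01, 0.03), stringsAsFactors = FALSE))
  rec$padj <- rec$p
  top <- representative_pathways(rec, c("L1", "L2", "L3"), k = 2)
  # support: A=2, B=2, C=2; tie broken by median p: A (0.002) < B (0.01) < C (0.04)
  expect_equal(top$set_name, c("A", "B"))
  expect_equal(top$support, c(2L, 2L))

  one <- representative_pathways(rec, "L1", k = 5)
  expect_equal(one$set_name[1:2], c("A", "B"))
  none <- representative_pathways(rec, "L_absent")
  expect_equal(nrow(none), 0)
})
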