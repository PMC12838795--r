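test_that("fisher enrichment equals the explicit hypergeometric tail", {
  # N=20, pathway 5, query 5, overlap 4
  uni <- sprintf("g%02d", 1:20)
  pw <- uni[1:5]
  q <- c(uni[1:4], uni[10])
  fe <- fisher_enrichment(q, pw, uni)
  expect_equal(fe$k, 4)
  expect_equal(fe$p, hyper_tail_oracle(4, 5, 5, 20))
  # k = 0 tail is 1; saturation is 1
  expect_equal(fisher_enrichment(uni[10:14], pw, uni)$p, 1)
  expect_equal(fisher_enrichment(uni, uni, uni)$p, 1)
  expect_error(fisher_enrichment(q, pw, character(0)), "universe")
})

test_that("fisher enrichment matches exhaustive query enumeration (N <= 12)", {
  set.seed(99)
  for (rep in 1:5) {
    N <- sample(6:12, 1)
    uni <- sprintf("g%02d", seq_len(N))
    pw <- sample(uni, sample(2:(N - 1), 1))
    nq <- sample(2:(N - 1), 1)
    qs <- combn(N, nq)
    # exhaustive null: fraction of all C(N, nq) query draws with overlap >= k
    for (q_obs in list(sample(uni, nq))) {
      k_obs <- length(intersect(q_obs, pw))
      ks <- apply(qs, 2, function(ix) length(intersect(uni[ix], pw)))
      expect_equal(fisher_enrichment(q_obs, pw, uni)$p,
                   mean(ks >= k_obs), tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment reproduces the textbook step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(5)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-14)
})

test_that("combined score follows -ln(p)*|z| with its edge cases", {
  expect_equal(combined_score(0.01, -2), -log(0.01) * 2)
  expect_equal(combined_score(1, 3), 0)
  expect_equal(combined_score(0.5, 0), 0)
  expect_gt(combined_score(0.001, 1.5), combined_score(0.01, 1.5))
})

test_that("rank-deviation z matches an independently coded resampler", {
  db <- pathway_db(list(P1 = sprintf("g%02d", 1:6),
                        P2 = sprintf("g%02d", 5:12),
                        P3 = sprintf("g%02d", 10:20)),
                   universe = sprintf("g%02d", 1:24))
  query <- sprintf("g%02d", c(1:4, 11, 15))
  B <- 400
  z <- rank_deviation_z(query, db, B = B, seed = 123)
  # second implementation: same RNG stream, naive loops
  k_of <- function(genes) vapply(db$pathways, function(pw)
    length(intersect(genes, pw)), numeric(1))
  p_of <- function(genes) {
    k <- k_of(genes)
    np <- lengths(db$pathways)
    pmin(1, phyper(k - 1, np, length(db$universe) - np, length(genes),
                   lower.tail = FALSE))
  }
  obs_rank <- rank(p_of(query), ties.method = "average")
  set.seed(123)
  rk <- t(replicate(B, rank(p_of(sample(db$universe, length(query))),
                            ties.method = "average")))
  mu <- colMeans(rk); sdev <- apply(rk, 2, sd)
  z_oracle <- ifelse(sdev > 0, (obs_rank - mu) / sdev, 0)
  expect_equal(unname(z), unname(z_oracle), tolerance = 1e-9)
})

test_that("a pathway ranked at its null mean gets z = 0 under degenerate sd", {
  # one pathway: its rank is always 1, so sd = 0 and z must be 0
  db <- pathway_db(list(P1 = c("a", "b")), universe = c("a", "b", "c", "d"))
  z <- rank_deviation_z(c("a", "c"), db, B = 50, seed = 9)
  expect_equal(unname(z), 0)
})

test_that("ora results are reproducible under a fixed seed and B", {
  b <- simulate_cohort(small_cfg(41))
  genes <- sample(b$db$universe, 12)
  r1 <- run_ora(genes, b$db, B = 300, seed = 77)
  r2 <- run_ora(genes, b$db, B = 300, seed = 77)
  expect_identical(r1, r2)
  expect_true(all(r1$p_adj >= r1$p))
  expect_true(all(r1$combined >= 0))
})

test_that("volcano table is antisymmetric and flags group significance", {
  b <- simulate_cohort(small_cfg(42))
  genes <- sample(b$db$universe, 10)
  ora <- run_ora(genes, b$db, B = 200, seed = 3)
  v_same <- volcano_table(ora, ora)
  expect_equal(v_same$delta_combined, rep(0, nrow(v_same)))
  # SR-specific enrichment must sit on the negative axis
  ora_sr <- ora
  ora_sr$combined <- ora$combined + 5
  v <- volcano_table(ora_sr, ora)
  expect_true(all(v$delta_combined == -5))
  # significance labels
  o1 <- ora; o1$p_adj <- rep(0.01, nrow(o1))
  o2 <- ora; o2$p_adj <- rep(0.5, nrow(o2))
  expect_true(all(volcano_table(o1, o1)$significant_in == "both"))
  expect_true(all(volcano_table(o1, o2)$significant_in == "SR"))
  expect_true(all(volcano_table(o2, o1)$significant_in == "OR"))
  expect_true(all(volcano_table(o2, o2)$significant_in == "neither"))
})

test_that("under a global null the Fisher p is calibrated", {
  b <- simulate_cohort(small_cfg(43, n_pathways = 10, n_gene_pool = 120,
                                 genes_per_pathway = 12))
  set.seed(202)
  alpha <- 0.1
  hits <- 0; total <- 0
  for (i in 1:300) {
    q <- sample(b$db$universe, 15)
    inc_p <- vapply(b$db$pathways, function(pw)
      fisher_enrichment(q, pw, b$db$universe)$p, numeric(1))
    hits <- hits + sum(inc_p < alpha)
    total <- total + length(inc_p)
  }
  frac <- hits / total
  # discrete test: rejection rate is below alpha, within binomial slack of it
  expect_lt(frac, alpha + 3 * sqrt(alpha * (1 - alpha) / total))
})

test_that("an SR-only effect pathway lands most negative in the volcano", {
  # a pathway carried almost exclusively by SR individuals: its genes enter
  # the SR gene set but hardly the OR set, so its combined-score difference
  # must sit at the negative (SR-specific) end of the volcano axis
  cfg <- synthetic_config(seed = 44,
                          effects = list(list(pathway = 1,
                                              type = "carrier",
                                              p_sr = 0.9, p_or = 0.02)))
  b <- simulate_cohort(cfg)
  qc <- run_qc(b$cv)
  rd <- build_rare_damaging_set(classify_variants(b$annotations), qc$cv)
  gs <- map_variants_to_group_genes(rd, qc$cv, b$design)
  ora_sr <- run_ora(gs$sr_genes, b$db, B = 500, seed = 5)
  ora_or <- run_ora(gs$or_genes, b$db, B = 500, seed = 6)
  v <- volcano_table(ora_sr, ora_or)
  pw <- b$truth$effect_pathways[1]
  expect_equal(v$pathway[which.min(v$delta_combined)], pw)
  expect_lt(v$delta_combined[v$pathway == pw], 0)
})
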