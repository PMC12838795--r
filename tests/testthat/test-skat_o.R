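skato_fixture <- function(seed = 61, n = 60, m = 4, maf = NULL,
                          beta = NULL) {
  # direct dosage fixture: binary phenotype, HWE genotypes, optional
  # per-variant log-odds effects
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.02, 0.2)
  G <- sapply(maf, function(f) rbinom(n, 2, f))
  eta <- if (is.null(beta)) rep(0, n) else as.numeric(G %*% beta)
  y <- rbinom(n, 1, plogis(eta))
  while (sum(y) < 2 || sum(y) > n - 2) y <- rbinom(n, 1, plogis(eta))
  list(G = G, y = y, maf = pmin(colMeans(G) / 2, 0.5))
}

test_that("null model recovers a symmetric intercept-only fit", {
  y <- rep(c(0, 1), 25)
  nm <- fit_null_model(y)
  expect_equal(unname(nm$coefficients[1]), 0, tolerance = 1e-8)
  expect_equal(nm$mu, rep(0.5, 50))
  expect_error(fit_null_model(rep(1, 10)), "each response group")
})

test_that("null model recovers known coefficients within 3 SE", {
  set.seed(62)
  n <- 500
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  beta <- c(-0.3, 0.8, -0.6)
  y <- rbinom(n, 1, plogis(beta[1] + beta[2] * x1 + beta[3] * x2))
  nm <- fit_null_model(y, cbind(x1 = x1, x2 = x2))
  fit <- glm(y ~ x1 + x2, family = binomial())
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(nm$coefficients - beta) < 3 * se))
  # permuting sample order leaves coefficients unchanged
  perm <- sample(n)
  nm2 <- fit_null_model(y[perm], cbind(x1 = x1, x2 = x2)[perm, ])
  expect_equal(unname(nm$coefficients), unname(nm2$coefficients),
               tolerance = 1e-10)
})

test_that("null model rejects separation and rank deficiency", {
  y <- rep(c(0, 1), each = 20)
  x <- as.numeric(y)  # perfect separation
  expect_error(fit_null_model(y, cbind(x = x)), "separation")
  expect_error(fit_null_model(y, cbind(a = 1:40, b = 2 * (1:40))),
               "rank deficient")
})

test_that("beta-density weights follow the closed form and monotonicity", {
  expect_equal(variant_weights(0.5), 25 * 0.5^24)
  expect_gt(variant_weights(0.01), variant_weights(0.04))
  expect_equal(variant_weights(c(0.1, 0.3), 1, 1), c(1, 1))
  expect_error(variant_weights(0), "MAFs")
  expect_error(variant_weights(0.6), "MAFs")
})

test_that("quadform_pvalue matches chi-square closed forms", {
  expect_equal(quadform_pvalue(3.841459, 1)$p, 0.05, tolerance = 1e-4)
  expect_equal(quadform_pvalue(7.814728, c(1, 1, 1))$p, 0.05,
               tolerance = 1e-4)
  # scaled chi-square with several equal weights
  expect_equal(quadform_pvalue(2 * 9.487729, c(2, 2, 2, 2))$p, 0.05,
               tolerance = 1e-4)
  expect_equal(quadform_pvalue(-1, c(1, 2))$p, 1)
  expect_error(quadform_pvalue(1, c(0, 0)), "zero")
})

test_that("quadform_pvalue agrees with Monte Carlo within 3 SE", {
  set.seed(63)
  R <- 200000
  for (lam in list(c(2.3, 0.9, 0.4, 0.1, 0.05), c(1, 0.02),
                   runif(5, 0.1, 3))) {
    draws <- colSums(lam * matrix(rchisq(length(lam) * R, 1), length(lam)))
    for (q in quantile(draws, c(0.5, 0.9, 0.99))) {
      p_hat <- mean(draws >= q)
      se <- sqrt(p_hat * (1 - p_hat) / R)
      expect_lt(abs(quadform_pvalue(q, lam)$p - p_hat), 3 * se)
    }
  }
})

test_that("a single variant makes every rho equivalent", {
  fx <- skato_fixture(m = 1)
  nm <- fit_null_model(fx$y)
  res <- skato_pathway_test(fx$G, nm, variant_weights(fx$maf))
  expect_equal(res$p_rho, rep(res$p_rho[1], length(res$rho_grid)))
  expect_equal(res$p_opt, res$p_rho[1])
})

test_that("rho = 1 reduces to a directly coded weighted burden score test", {
  fx <- skato_fixture(seed = 64, m = 5)
  nm <- fit_null_model(fx$y)
  w <- variant_weights(fx$maf)
  res <- skato_pathway_test(fx$G, nm, w, rho_grid = 1)
  # independent burden coding: score test of the weighted burden b = Gw
  b <- as.numeric(fx$G %*% w)
  U <- sum(b * nm$resid)
  X <- nm$X; V <- nm$v
  Vb <- sum(b^2 * V) -
    (t(b * V) %*% X) %*% solve(crossprod(X, X * V)) %*% t(t(b * V) %*% X)
  p_burden <- pchisq(U^2 / as.numeric(Vb), df = 1, lower.tail = FALSE)
  expect_equal(res$p_rho[1], p_burden, tolerance = 1e-8)
  expect_equal(res$p_opt, p_burden, tolerance = 1e-8)
})

test_that("Q_rho is linear in rho between the SKAT and burden statistics", {
  fx <- skato_fixture(seed = 65, m = 6)
  nm <- fit_null_model(fx$y)
  w <- variant_weights(fx$maf)
  rho <- c(0, 0.3, 0.7, 1)
  res <- skato_pathway_test(fx$G, nm, w, rho_grid = rho)
  q0 <- res$Q_rho[1]; q1 <- res$Q_rho[4]
  expect_equal(res$Q_rho, (1 - rho) * q0 + rho * q1, tolerance = 1e-10)
})

test_that("p_opt stays inside the min-p / Bonferroni envelope", {
  for (seed in 66:70) {
    fx <- skato_fixture(seed = seed, m = sample(2:8, 1))
    nm <- fit_null_model(fx$y)
    res <- skato_pathway_test(fx$G, nm, variant_weights(fx$maf))
    expect_gte(res$p_opt, min(res$p_rho) - 1e-12)
    expect_lte(res$p_opt,
               min(1, length(res$rho_grid) * min(res$p_rho)) + 1e-12)
  }
})

test_that("p_opt matches a permutation oracle in the score test's asymptotic regime", {
  # intercept-only null: the eigenstructure is permutation-invariant, so
  # min-p exceedance thresholds can be reused across permutations. At this
  # sample size and allele frequency the score statistics are close to
  # normal, isolating the min-p combination machinery under test.
  fx <- skato_fixture(seed = 202, n = 300, m = 4,
                      maf = c(0.3, 0.25, 0.35, 0.2),
                      beta = c(0.25, -0.2, 0.25, 0))
  nm <- fit_null_model(fx$y)
  w <- rep(1, 4)
  rho_grid <- c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)
  res <- skato_pathway_test(fx$G, nm, w, rho_grid)
  # observed thresholds at T = min p_rho, from the same p_rho functions
  Gw <- sweep(fx$G, 2, w, `*`)
  R <- 20000
  set.seed(710)
  perms <- replicate(R, sample(fx$y))
  S <- crossprod(Gw, perms - mean(fx$y))          # m x R scores
  Qs <- sapply(rho_grid, function(r)
    (1 - r) * colSums(S^2) + r * colSums(S)^2)    # R x |grid|
  # per-permutation min-p via per-rho exceedance against observed Q quantiles
  exceed <- rep(FALSE, R)
  for (i in seq_along(rho_grid)) {
    # threshold: null quantile of Q_rho at the observed min-p
    lam_i <- local({
      V <- nm$v; X <- nm$X; VX <- X * V
      P <- diag(V) - VX %*% solve(crossprod(X, VX)) %*% t(VX)
      eP <- eigen((P + t(P)) / 2, symmetric = TRUE)
      pos <- eP$values > max(eP$values) * 1e-10
      Ph <- eP$vectors[, pos] %*% (sqrt(eP$values[pos]) *
                                     t(eP$vectors[, pos]))
      Z1 <- Ph %*% Gw
      M <- rvpathrx:::rho_matrix_sqrt(min(rho_grid[i], 0.999), ncol(Gw))
      rvpathrx:::psd_eigen(M %*% crossprod(Z1) %*% M)
    })
    thr <- rvpathrx:::quadform_quantile(min(res$p_rho), lam_i)
    exceed <- exceed | (Qs[, i] > thr)
  }
  p_perm <- mean(exceed)
  se <- sqrt(p_perm * (1 - p_perm) / R)
  expect_lt(abs(res$p_opt - p_perm), 3 * se)
})

test_that("imputation choice never changes the number of qualifying variants", {
  b <- simulate_cohort(synthetic_config(seed = 72))
  qc <- run_qc(b$cv)
  rd <- build_rare_damaging_set(classify_variants(b$annotations), qc$cv)
  pws <- names(b$db$pathways)[1:4]
  r_mean <- run_skato(pws, b$db, rd, qc$cv, b$design, impute = "mean")
  r_zero <- run_skato(pws, b$db, rd, qc$cv, b$design, impute = "zero")
  expect_equal(r_mean$m[order(r_mean$pathway)],
               r_zero$m[order(r_zero$pathway)])
})

test_that("run_skato applies BH across pathways and flags by FDR", {
  b <- simulate_cohort(synthetic_config(seed = 73))
  qc <- run_qc(b$cv)
  rd <- build_rare_damaging_set(classify_variants(b$annotations), qc$cv)
  one <- run_skato(names(b$db$pathways)[1], b$db, rd, qc$cv, b$design)
  expect_equal(one$q, one$p_opt)
  several <- run_skato(names(b$db$pathways)[1:5], b$db, rd, qc$cv,
                       b$design)
  tested <- !is.na(several$p_opt)
  expect_equal(several$q[tested], bh_adjust(several$p_opt[tested]))
})
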