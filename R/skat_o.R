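# Optimal sequence kernel association test (SKAT-O) for pathway gene-sets,
# written against a covariate-adjusted logistic null model.
#
# For a pathway with dosage matrix G (n x m), weights w and null residuals
# r = y - mu, the per-variant scores are S_j = sum_i G_ij r_i and
#   Q_rho = (1 - rho) * sum_j (w_j S_j)^2 + rho * (sum_j w_j S_j)^2,
# interpolating between the variance-component kernel statistic (rho = 0)
# and the squared weighted burden score (rho = 1). Each Q_rho is a quadratic
# form in the null-model residuals; its null distribution is a weighted sum
# of 1-df chi-squares whose weights are the eigenvalues of the projected,
# variance-weighted kernel. The final p-value is that of the minimum per-rho
# p over the grid, computed by one-dimensional integration over the common
# burden-direction component.

#' Fit the logistic null model
#'
#' Logistic regression of the binary response label on the covariates
#' (iteratively reweighted least squares, convergence tolerance 1e-8, at
#' most 50 iterations). Quasi-separation — any fitted probability within
#' 1e-10 of 0 or 1 — is an error, since score-test variances then collapse.
#'
#' @param y Binary 0/1 vector (1 = suboptimal responder by convention).
#' @param covariates `data.frame` or matrix of numeric covariates (e.g. age
#'   and 0/1 sex); may have zero columns for an intercept-only model.
#' @return A `NullModel` list: `coefficients`, fitted means `mu`, residuals
#'   `resid` (`y - mu`), variance weights `v` (`mu * (1 - mu)`), and the
#'   design matrix `X` (with intercept).
#' @export
fit_null_model <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one sample in each response group")
  if (is.null(covariates) || NCOL(covariates) == 0) {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
    fit <- glm(y ~ 1, family = binomial(),
               control = list(epsilon = 1e-8, maxit = 50))
  } else {
    X0 <- as.matrix(covariates)
    storage.mode(X0) <- "double"
    X <- cbind("(Intercept)" = 1, X0)
    if (qr(X)$rank < ncol(X))
      stop("covariate matrix is rank deficient after adding an intercept")
    fit <- glm(y ~ X0, family = binomial(),
               control = list(epsilon = 1e-8, maxit = 50))
  }
  if (!fit$converged) stop("logistic null model did not converge")
  mu <- fit$fitted.values
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10))
    stop("fitted probabilities at 0/1 (separation); review covariates")
  structure(list(coefficients = coef(fit), mu = as.numeric(mu),
                 resid = as.numeric(y - mu), v = as.numeric(mu * (1 - mu)),
                 X = X, y = y),
            class = "NullModel")
}

#' Beta-density variant weights
#'
#' The conventional rare-variant weighting: `w_j = dbeta(maf_j; a, b)` with
#' defaults `a = 1, b = 25`, strongly up-weighting the rarest variants.
#' `a = b = 1` gives the unweighted test.
#'
#' @param mafs Cohort minor allele frequencies in `(0, 0.5]`.
#' @param beta_a,beta_b Beta density parameters (defaults 1 and 25).
#' @return Numeric weight vector.
#' @export
variant_weights <- function(mafs, beta_a = 1, beta_b = 25) {
  if (any(mafs <= 0) || any(mafs > 0.5))
    stop("MAFs must lie in (0, 0.5]; drop uncarried variants first")
  dbeta(mafs, beta_a, beta_b)
}

# Liu-style moment-matching tail approximation (skewness-matched noncentral
# chi-square) for P[sum lambda_k chi2_1 >= Q]
liu_pvalue <- function(Q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    l <- 1 / s2; a <- sqrt(l); delta <- 0
  }
  tstar <- (Q - c1) / sqrt(2 * c2)
  pchisq(tstar * sqrt(2) * a + (l + delta), df = l, ncp = delta,
         lower.tail = FALSE)
}

# Characteristic-function inversion for P[sum lambda chi^2_1 >= Q] on a
# shared Simpson grid, vectorized over several Q values at a common lambda
# set. Upper limit U from the integrand magnitude bound
#   |f(u)| <= 1 / (u * prod(lambda_k u)^{1/2})
# with an additional integration-by-parts credit of 2/(Q u) from the
# oscillation, so that the neglected tail is below eps; the step resolves
# the fastest phase 0.5*(sum lambda + max Q). Returns NULL when the grid
# required for that accuracy is unreasonably large (caller falls back).
qf_engine <- function(lambda, q_lo, q_hi, eps = 1e-7, max_nodes = 5e5) {
  lmax <- max(lambda)
  l <- lambda / lmax
  m <- length(l)
  log_pl <- 0.5 * sum(log(l))
  qmin <- max(q_lo / lmax, 1e-3)
  qmax <- max(q_hi / lmax, qmin)
  logU1 <- (log(2 / (m * pi * eps)) - log_pl) * 2 / m
  logU2 <- (log(2 / (qmin * pi * eps)) - log_pl) * 2 / (m + 2)
  U <- exp(min(logU1, logU2))
  if (!is.finite(U) || U <= 0) return(NULL)
  du <- min(2 * pi / (25 * (0.5 * sum(l) + 0.5 * qmax)), U / 2000)
  n <- ceiling(U / du)
  if (n > max_nodes) return(NULL)
  n <- n + (n %% 2)                      # even interval count for Simpson
  u <- seq(0, U, length.out = n + 1)[-1]
  phase0 <- numeric(n); lamp <- numeric(n)
  for (s in seq(1L, n, by = 50000L)) {     # chunked to bound memory
    e <- min(s + 49999L, n)
    ou <- outer(l, u[s:e])
    phase0[s:e] <- 0.5 * colSums(atan(ou))
    lamp[s:e] <- 0.25 * colSums(log1p(ou^2))
  }
  wamp <- c(rep(c(4, 2), length.out = n - 1), 1) / (u * exp(lamp))
  h <- U / n
  sum_l <- sum(l)
  function(Qs) {
    vapply(Qs / lmax, function(qi) {
      f0 <- (sum_l - qi) / 2                     # limit of f at u = 0
      val <- (h / 3) * (f0 + sum(wamp * sin(phase0 - 0.5 * qi * u)))
      min(max(0.5 + val / pi, .Machine$double.xmin), 1)
    }, numeric(1))
  }
}

qf_inversion_batch <- function(Qs, lambda, eps = 1e-7, max_nodes = 5e5) {
  eng <- qf_engine(lambda, min(Qs), max(Qs), eps, max_nodes)
  if (is.null(eng)) return(NULL)
  eng(Qs)
}

#' Tail probability of a weighted sum of 1-df chi-squares
#'
#' `P[sum_k lambda_k chi^2_1 >= Q]` by numerical inversion of the
#' characteristic function (the classical approach of the Davies/Imhof
#' family) on an oscillation-resolving Simpson grid, targeting absolute
#' error 1e-6. A single eigenvalue is handled in closed form (scaled
#' chi-square). When the inversion grid would be unreasonably large or the
#' tail probability is below 1e-12, a skewness-matched noncentral
#' chi-square moment approximation is used instead; the method actually
#' used is recorded in the result.
#'
#' @param Q Observed statistic (scalar).
#' @param lambda Non-negative eigenvalues, not all zero.
#' @return List with `p` and `method` (`"inversion"` or `"moment"`).
#' @export
quadform_pvalue <- function(Q, lambda) {
  lambda <- lambda[lambda > max(lambda) * 1e-12]
  if (length(lambda) == 0 || all(lambda == 0))
    stop("all eigenvalues are zero")
  if (Q <= 0) return(list(p = 1, method = "inversion"))
  if (length(lambda) == 1)    # a single weight is exactly a scaled chi-square
    return(list(p = pchisq(Q / lambda, df = 1, lower.tail = FALSE),
                method = "inversion"))
  # deep in the tail the inversion integral oscillates too fast to be worth
  # resolving; the moment approximation is used there outright
  p_liu <- liu_pvalue(Q, lambda)
  if (p_liu < 1e-12) return(list(p = p_liu, method = "moment"))
  p <- qf_inversion_batch(Q, lambda)
  if (is.null(p)) return(list(p = p_liu, method = "moment"))
  list(p = p, method = "inversion")
}

# symmetric square root of R_rho = (1-rho) I + rho 11'
rho_matrix_sqrt <- function(rho, m) {
  a <- sqrt(1 - rho)
  b <- (sqrt(1 - rho + m * rho) - a) / m
  diag(a, m) + matrix(b, m, m)
}

# eigenvalues (>= 0, tiny ones dropped) of a symmetric psd matrix
psd_eigen <- function(A) {
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev[ev > max(ev, 0) * 1e-10 & ev > 0]
}

# moment-matched quantile guess (inverse of the Liu tail approximation)
liu_quantile <- function(t, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    l <- 1 / s2; a <- sqrt(l); delta <- 0
  }
  chi_q <- qchisq(t, df = l, ncp = delta, lower.tail = FALSE)
  max(0, (chi_q - (l + delta)) / (sqrt(2) * a) * sqrt(2 * c2) + c1)
}

# upper-tail quantile of sum lambda chi2_1 at tail probability t; moderate
# tail probabilities are refined from the moment-matched guess by root
# finding on the inversion p-value, deep tails keep the moment quantile
# (the convention of the reference optimal-test implementation)
quadform_quantile <- function(t, lambda) {
  guess <- liu_quantile(t, lambda)
  if (t < 1e-4) return(guess)
  lo <- max(guess / 16, 1e-12)
  hi <- max(guess * 16, 1e-6)
  eng <- qf_engine(lambda, lo, hi)
  if (is.null(eng)) return(guess)
  if (eng(lo) < t || eng(hi) > t) return(guess)  # bracket failed; keep guess
  uniroot(function(q) eng(q) - t, lower = lo, upper = hi,
          tol = 1e-8 * max(1, guess))$root
}

#' SKAT-O test for one pathway
#'
#' Computes `Q_rho` across the rho grid, each per-rho p-value from the null
#' quadratic-form distribution, and the combined minimum-p SKAT-O p-value
#' by integrating over the shared burden-direction chi-square component.
#' When that integration cannot be carried out (degenerate burden
#' direction, or numerical failure) the Bonferroni envelope
#' `min(1, |grid| * min_rho p_rho)` is used and flagged in `method`.
#'
#' @param G Dosage matrix (samples x variants), 0/1/2 with missing values
#'   already imputed.
#' @param null A `NullModel` from [fit_null_model()].
#' @param weights Per-variant weights, e.g. [variant_weights()].
#' @param rho_grid Grid of rho values in `[0, 1]`
#'   (default `c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)`).
#' @return List with `m`, `rho_grid`, `Q_rho`, `p_rho`, `p_opt`, `method`.
#' @export
skato_pathway_test <- function(G, null, weights,
                               rho_grid = c(0, 0.01, 0.04, 0.09, 0.16,
                                            0.25, 0.5, 1)) {
  G <- as.matrix(G)
  m <- ncol(G)
  if (m == 0) stop("no qualifying variants (m = 0)")
  if (anyNA(G)) stop("dosage matrix contains missing values; impute first")
  stopifnot(length(weights) == m, all(rho_grid >= 0), all(rho_grid <= 1))
  Gw <- sweep(G, 2, weights, `*`)
  S <- as.numeric(crossprod(Gw, null$resid))
  Q_rho <- (1 - rho_grid) * sum(S^2) + rho_grid * sum(S)^2

  # projected, variance-weighted kernel: Z1 = P^{1/2} G W with
  # P = V - V X (X' V X)^{-1} X' V, V = diag(mu(1-mu))
  V <- null$v
  X <- null$X
  VX <- X * V
  XtVX_inv <- solve(crossprod(X, VX))
  P <- diag(V) - VX %*% XtVX_inv %*% t(VX)
  eP <- eigen((P + t(P)) / 2, symmetric = TRUE)
  pos <- eP$values > max(eP$values) * 1e-10
  P_half <- eP$vectors[, pos, drop = FALSE] %*%
    (sqrt(eP$values[pos]) * t(eP$vectors[, pos, drop = FALSE]))
  Z1 <- P_half %*% Gw
  Sigma <- crossprod(Z1)
  if (max(abs(Sigma)) == 0) stop("singular null variance for this pathway")

  p_rho <- numeric(length(rho_grid))
  lam_rho <- vector("list", length(rho_grid))
  for (i in seq_along(rho_grid)) {
    M <- rho_matrix_sqrt(rho_grid[i], m)
    lam <- psd_eigen(M %*% Sigma %*% M)
    lam_rho[[i]] <- lam
    p_rho[i] <- quadform_pvalue(Q_rho[i], lam)$p
  }
  p_min <- min(p_rho)
  n_rho <- length(rho_grid)

  if (m == 1 || n_rho == 1) {
    return(list(m = m, rho_grid = rho_grid, Q_rho = Q_rho, p_rho = p_rho,
                p_opt = p_rho[1], method = "degenerate"))
  }

  p_opt <- tryCatch({
    rho_c <- pmin(rho_grid, 0.999)      # keep (1 - rho) positive
    zbar <- rowMeans(Z1)
    zbar_sq <- sum(zbar^2)
    if (zbar_sq < .Machine$double.eps) stop("degenerate burden direction")
    a_vec <- as.numeric(crossprod(Z1, zbar)) / sqrt(zbar_sq)
    Z2 <- Z1 - zbar %*% t(a_vec) / sqrt(zbar_sq)
    lambda <- psd_eigen(crossprod(Z2))
    if (length(lambda) == 0) stop("degenerate kernel remainder")
    tau <- (1 - rho_c) * sum(a_vec^2) + rho_c * m^2 * zbar_sq
    mu_k <- sum(lambda)
    var_zeta <- 4 * as.numeric(t(a_vec) %*% crossprod(Z2) %*% a_vec)
    var_k <- 2 * sum(lambda^2) + var_zeta
    q_T <- vapply(seq_len(n_rho), function(i) {
      M <- rho_matrix_sqrt(rho_c[i], m)
      quadform_quantile(p_min, psd_eigen(M %*% Sigma %*% M))
    }, numeric(1))
    # P(kappa < q): variance-adjusted inversion on the lambda mixture,
    # tabulated once over the effective support of kappa and interpolated
    # (beyond q_cap the cdf is 1 to within 1e-7)
    shrink <- sqrt(2 * sum(lambda^2)) / sqrt(var_k)
    q_cap <- (liu_quantile(1e-7, lambda) - mu_k) / shrink + mu_k
    q_max <- min(max(q_T / (1 - rho_c)), q_cap)
    grid <- seq(0, q_max, length.out = 301L)
    q_st <- (grid - mu_k) * shrink + mu_k
    F_grid <- numeric(length(grid))
    ok <- q_st > 0
    if (any(ok)) {
      tail_p <- qf_inversion_batch(q_st[ok], lambda)
      if (is.null(tail_p))
        tail_p <- vapply(q_st[ok], function(qi) liu_pvalue(qi, lambda),
                         numeric(1))
      F_grid[ok] <- 1 - tail_p
    }
    F_grid <- cummax(pmin(pmax(F_grid, 0), 1))   # enforce a monotone cdf
    F_remainder <- function(q) {
      out <- approx(grid, F_grid, xout = pmin(pmax(q, 0), q_max),
                    rule = 2)$y
      out[q <= 0] <- 0
      out[q >= q_cap] <- 1
      out
    }
    # integrate over t = sqrt(x) so the chi-square(1) density's endpoint
    # singularity disappears: dchisq(x,1) dx -> 2 dnorm(t) dt
    integrand <- function(t) {
      x <- t^2
      delta <- apply(outer(q_T, rep(1, length(x))) -
                       outer(tau, x), 2, function(col)
                         min(col / (1 - rho_c)))
      F_remainder(delta) * 2 * stats::dnorm(t)
    }
    int <- integrate(integrand, 0, sqrt(40), subdivisions = 2000L,
                     rel.tol = 1e-6, stop.on.error = FALSE)
    if (int$message != "OK" &&
        !(grepl("roundoff", int$message) && int$abs.error < 1e-5))
      stop("integration failed")
    1 - int$value
  }, error = function(e) NA_real_)

  if (is.na(p_opt)) {
    p_opt <- min(1, n_rho * p_min)
    method <- "bonferroni"
  } else {
    method <- "integration"
    p_opt <- min(max(p_opt, p_min), n_rho * p_min, 1)
  }
  list(m = m, rho_grid = rho_grid, Q_rho = Q_rho, p_rho = p_rho,
       p_opt = p_opt, method = method)
}

# cohort alt-allele frequency per variant row of cv, from non-missing calls
cohort_af <- function(dosage) {
  af <- rowMeans(dosage, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0
  af
}

#' SKAT-O across pathways with FDR control
#'
#' For each pathway, collects the qualifying variants (rare damaging,
#' carried; a variant in several pathway genes enters once), computes
#' cohort MAFs on non-missing post-QC calls, imputes missing dosages
#' (per-variant mean `2 * MAF` by default, or zero), weights variants with
#' the Beta density, and runs [skato_pathway_test()] against the shared
#' null model. P-values are Benjamini-Hochberg adjusted across tested
#' pathways.
#'
#' @param pathways Character vector of pathway names in `db`.
#' @param db A `PathwayDB`.
#' @param rare_damaging Output of [build_rare_damaging_set()].
#' @param cv QC'd biallelic [cohort_variants()] object.
#' @param design [read_phenotypes()] table; `group == "SR"` is coded 1.
#' @param covariates Character vector of design columns used as covariates
#'   (default `c("age", "sex_code")`).
#' @param rho_grid Rho grid, see [skato_pathway_test()].
#' @param weights_beta Beta parameters for [variant_weights()].
#' @param impute `"mean"` (default) or `"zero"` missing-dosage imputation;
#'   imputation never changes the number of qualifying variants.
#' @param fdr FDR threshold for the `significant` flag (default 0.05).
#' @return `data.frame`: `pathway`, `m`, `p_opt`, `q`, `significant`,
#'   `method`; pathways with no qualifying variant get `NA` p and q.
#' @export
run_skato <- function(pathways, db, rare_damaging, cv, design,
                      covariates = c("age", "sex_code"),
                      rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                      weights_beta = c(1, 25), impute = c("mean", "zero"),
                      fdr = 0.05) {
  impute <- match.arg(impute)
  if (length(pathways) == 0)
    return(data.frame(pathway = character(), m = integer(),
                      p_opt = numeric(), q = numeric(),
                      significant = logical(), p_rho = character(),
                      method = character(), stringsAsFactors = FALSE))
  unknown <- setdiff(pathways, names(db$pathways))
  if (length(unknown) > 0)
    stop("unknown pathway name(s): ", paste(unknown, collapse = ", "))
  ord <- match(cv$samples, design$sample_id)
  if (anyNA(ord)) stop("sample(s) in genotypes but absent from design")
  y <- as.numeric(design$group[ord] == "SR")
  covs <- if (length(covariates) > 0)
    as.matrix(design[ord, covariates, drop = FALSE]) else NULL
  null <- fit_null_model(y, covs)
  dosage <- as_dosage(cv)
  af_all <- cohort_af(dosage)
  rows_out <- lapply(pathways, function(pw) {
    rows <- sort(unique(
      rare_damaging$cv_row[rare_damaging$gene %in% db$pathways[[pw]]]))
    af <- af_all[rows]
    maf <- pmin(af, 1 - af)
    keep <- maf > 0
    rows <- rows[keep]; maf <- maf[keep]
    if (length(rows) == 0)
      return(data.frame(pathway = pw, m = 0L, p_opt = NA_real_,
                        p_rho = NA_character_, method = "no_variants",
                        stringsAsFactors = FALSE))
    G <- t(dosage[rows, , drop = FALSE])
    storage.mode(G) <- "double"
    for (j in seq_len(ncol(G))) {
      nas <- is.na(G[, j])
      if (any(nas))
        G[nas, j] <- if (impute == "mean") 2 * af_all[rows[j]] else 0
    }
    w <- variant_weights(maf, weights_beta[1], weights_beta[2])
    res <- skato_pathway_test(G, null, w, rho_grid)
    data.frame(pathway = pw, m = res$m, p_opt = res$p_opt,
               p_rho = paste(signif(res$p_rho, 10), collapse = ";"),
               method = res$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows_out, list(make.row.names = FALSE)))
  out$q <- NA_real_
  tested <- !is.na(out$p_opt)
  out$q[tested] <- bh_adjust(out$p_opt[tested])
  out$significant <- !is.na(out$q) & out$q < fdr
  out <- out[order(out$p_opt), c("pathway", "m", "p_opt", "q",
                                 "significant", "p_rho", "method")]
  rownames(out) <- NULL
  out
}
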