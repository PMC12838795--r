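# Baseline clinical comparison battery: exact tests for r x 2 contingency
# tables and rank tests for unpaired/paired continuous variables.

# log multivariate-hypergeometric probability of an r x c table given margins
log_table_prob <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
    sum(lgamma(tab + 1))
}

# enumerate all non-negative integer tables with the given margins,
# returning the summed probability of tables with prob <= p_obs * (1+eps)
freeman_halton_p <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  lp_obs <- log_table_prob(tab)
  r <- nrow(tab); cc <- ncol(tab)
  total <- 0
  recurse <- function(row, remaining_cols, acc_rows) {
    if (row == r) {
      final <- rbind_list(acc_rows, remaining_cols)
      if (any(remaining_cols < 0)) return()
      lp <- log_table_prob(final)
      if (lp <= lp_obs + 1e-7) total <<- total + exp(lp)
      return()
    }
    # enumerate compositions of rs[row] over cc columns bounded by
    # remaining column margins
    comp_rec <- function(j, left, cells) {
      if (j == cc) {
        if (left <= remaining_cols[cc]) {
          cells[cc] <- left
          recurse(row + 1, remaining_cols - cells,
                  c(acc_rows, list(cells)))
        }
        return()
      }
      for (v in 0:min(left, remaining_cols[j])) {
        cells[j] <- v
        comp_rec(j + 1, left - v, cells)
      }
    }
    comp_rec(1, rs[row], numeric(cc))
  }
  rbind_list <- function(rows, last) do.call(rbind, c(rows, list(last)))
  recurse(1, cs, list())
  min(1, total)
}

#' Fisher's exact test for an r x c contingency table
#'
#' Freeman-Halton generalization: the p-value sums the probabilities of all
#' tables with the observed margins whose multivariate hypergeometric
#' probability does not exceed the observed table's (up to a 1e-7 relative
#' slack), computed by exhaustive enumeration. A 2 x 2 table reduces
#' exactly to [fisher_2x2()]. Rows with a zero margin do not change the
#' p-value.
#'
#' @param tab Integer matrix of non-negative counts (rows = categories,
#'   columns = groups).
#' @param max_total Enumeration bound on the table total (default 10000).
#' @return The two-sided exact p-value.
#' @export
fisher_exact_rxc <- function(tab, max_total = 10000) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (sum(tab) > max_total)
    stop("table total exceeds the enumeration bound (", max_total,
         "); a Monte-Carlo mode is not implemented")
  if (any(colSums(tab) == 0)) stop("every column needs a positive margin")
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2) return(1)
  freeman_halton_p(tab)
}

#' Mann-Whitney U test
#'
#' U computed from midranks (ties averaged). The p-value is exact (full
#' enumeration) when `n_x + n_y <= 20` and the pooled data are tie-free;
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return List with `U` (for `x`) and two-sided `p`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Wilcoxon signed-rank test for paired data
#'
#' Differences of exactly zero are dropped (the standard Wilcoxon
#' convention); midranks are used on the absolute differences. Exact p for
#' up to 15 non-zero tie-free differences, otherwise a normal approximation
#' with continuity correction. `W` is the smaller of the positive- and
#' negative-rank sums.
#'
#' @param before,after Numeric vectors of equal length.
#' @return List with `W`, two-sided `p`, and `n_nonzero`.
#' @export
wilcoxon_signed_rank <- function(before, after) {
  stopifnot(length(before) == length(after))
  d <- after - before
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero")
    return(list(W = 0, p = 1, n_nonzero = 0L))
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= 15 && !ties
  wt <- suppressWarnings(wilcox.test(d, exact = exact, correct = TRUE))
  v <- unname(wt$statistic)                  # positive-rank sum
  tot <- length(d) * (length(d) + 1) / 2
  list(W = min(v, tot - v), p = wt$p.value, n_nonzero = length(d))
}

#' Compare clinical variables between response groups
#'
#' Convenience battery mirroring a typical baseline table: each categorical
#' variable is cross-tabulated against the group label and tested with
#' [fisher_exact_rxc()]; each continuous variable is summarized by
#' median/IQR per group and tested with [mann_whitney_u()].
#'
#' @param design A [read_phenotypes()] table (or any data.frame with a
#'   `group` column of `SR`/`OR`).
#' @param categorical Character vector of categorical column names.
#' @param continuous Character vector of continuous column names.
#' @return `data.frame`: `variable`, `test`, `summary_sr`, `summary_or`,
#'   `p`.
#' @export
compare_clinical <- function(design, categorical = character(0),
                             continuous = character(0)) {
  stopifnot(all(c(categorical, continuous) %in% names(design)))
  sr <- design$group == "SR"
  rows <- list()
  for (v in categorical) {
    tab <- table(factor(design[[v]]), factor(design$group,
                                             levels = c("SR", "OR")))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, test = "fisher_exact",
      summary_sr = paste(tab[, "SR"], collapse = "/"),
      summary_or = paste(tab[, "OR"], collapse = "/"),
      p = fisher_exact_rxc(unclass(tab)), stringsAsFactors = FALSE)
  }
  iqr_str <- function(x) {
    q <- quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE)
    sprintf("%.3g [%.3g-%.3g]", q[1], q[2], q[3])
  }
  for (v in continuous) {
    xs <- design[[v]][sr]; ys <- design[[v]][!sr]
    mw <- mann_whitney_u(xs[!is.na(xs)], ys[!is.na(ys)])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, test = "mann_whitney",
      summary_sr = iqr_str(xs), summary_or = iqr_str(ys),
      p = mw$p, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
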