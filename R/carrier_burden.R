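# Per-pathway carrier counts by response group and the 2x2 Fisher exact
# comparison with the sample odds ratio.

#' Count pathway carriers by response group
#'
#' An individual is a pathway carrier when they carry (>= 1 alt allele,
#' non-missing) at least one rare damaging variant in at least one pathway
#' gene; each individual counts once regardless of how many qualifying
#' variants they carry. Individuals with entirely missing genotypes across
#' the pathway's variants count as non-carriers.
#'
#' @param pathway_genes Character vector of the pathway's genes.
#' @param rare_damaging Output of [build_rare_damaging_set()].
#' @param cv QC'd biallelic [cohort_variants()] object.
#' @param design [read_phenotypes()] table covering every `cv` sample.
#' @return Named integer vector `(a, b, c, d)`: SR carriers, SR
#'   non-carriers, OR carriers, OR non-carriers.
#' @export
count_pathway_carriers <- function(pathway_genes, rare_damaging, cv, design) {
  group <- design$group[match(cv$samples, design$sample_id)]
  if (anyNA(group))
    stop("sample(s) in genotypes but absent from design")
  rows <- rare_damaging$cv_row[rare_damaging$gene %in% pathway_genes]
  carr <- carrier_status(rows, as_dosage(cv))
  c(a = sum(carr & group == "SR"), b = sum(!carr & group == "SR"),
    c = sum(carr & group == "OR"), d = sum(!carr & group == "OR"))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value follows the point-probability rule: the sum over
#' all tables with the observed margins whose hypergeometric probability
#' does not exceed the observed table's (within a 1e-7 relative slack, the
#' convention of standard exact-test implementations). The reported effect
#' is the unconditional sample odds ratio `(a*d)/(b*c)` — `Inf` when
#' `b*c = 0` with `a*d > 0`, and `NA` when both products vanish — not the
#' conditional MLE.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows = groups, columns =
#'   carrier/non-carrier.
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (a + b == 0 || c + d == 0) stop("both row margins must be positive")
  ad <- as.numeric(a) * d
  bc <- as.numeric(b) * c
  odds_ratio <- if (bc > 0) ad / bc else if (ad > 0) Inf else NA_real_
  m <- a + b          # row 1 margin
  k <- a + c          # column 1 margin
  n <- c + d
  support <- max(0, k - n):min(m, k)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = odds_ratio, p = min(1, p))
}

#' Carrier-burden comparison across pathways
#'
#' For each pathway (typically the ORA-significant ones, optionally all),
#' counts carriers by group and compares the two groups with
#' [fisher_2x2()]. Rows are sorted by p.
#'
#' @param pathways Character vector of pathway names present in `db`.
#' @param db A `PathwayDB`.
#' @param rare_damaging Output of [build_rare_damaging_set()].
#' @param cv QC'd biallelic [cohort_variants()] object.
#' @param design [read_phenotypes()] table.
#' @param alpha Significance level used for the `significant` flag.
#' @return `data.frame`: `pathway`, `carriers_sr`, `noncarriers_sr`,
#'   `carriers_or`, `noncarriers_or`, `pct_sr`, `pct_or`, `odds_ratio`,
#'   `p`, `significant`.
#' @export
run_burden <- function(pathways, db, rare_damaging, cv, design,
                       alpha = 0.05) {
  unknown <- setdiff(pathways, names(db$pathways))
  if (length(unknown) > 0)
    stop("unknown pathway name(s): ", paste(unknown, collapse = ", "))
  if (length(pathways) == 0)
    return(data.frame(pathway = character(), carriers_sr = integer(),
                      noncarriers_sr = integer(), carriers_or = integer(),
                      noncarriers_or = integer(), pct_sr = numeric(),
                      pct_or = numeric(), odds_ratio = numeric(),
                      p = numeric(), significant = logical()))
  rows <- lapply(pathways, function(pw) {
    cts <- count_pathway_carriers(db$pathways[[pw]], rare_damaging, cv,
                                  design)
    ft <- fisher_2x2(cts["a"], cts["b"], cts["c"], cts["d"])
    data.frame(pathway = pw,
               carriers_sr = cts[["a"]], noncarriers_sr = cts[["b"]],
               carriers_or = cts[["c"]], noncarriers_or = cts[["d"]],
               pct_sr = 100 * cts[["a"]] / (cts[["a"]] + cts[["b"]]),
               pct_or = 100 * cts[["c"]] / (cts[["c"]] + cts[["d"]]),
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$p), , drop = FALSE]
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}
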