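# Over-representation analysis per response group: one-sided Fisher
# (hypergeometric tail) enrichment, BH adjustment, a Monte-Carlo
# rank-deviation z-score, the combined enrichment score, and the
# between-group delta table that parameterizes the volcano display.

#' One-sided Fisher enrichment of a gene set in a pathway
#'
#' Over-representation p-value: the upper hypergeometric tail
#' `P[X >= k]` for overlap `k` between the query (intersected with the
#' universe first) and the pathway, drawing `|query|` genes from a universe
#' of size `N` containing `|pathway|` successes.
#'
#' @param query Character vector of query genes.
#' @param pathway Character vector of pathway genes (subset of `universe`).
#' @param universe Character vector, the gene universe.
#' @return List with `k` (overlap), `n_query`, `n_pathway`, `n_universe`
#'   and `p`.
#' @export
fisher_enrichment <- function(query, pathway, universe) {
  if (length(universe) == 0) stop("empty gene universe")
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  pathway <- intersect(unique(pathway), universe)
  k <- length(intersect(query, pathway))
  p <- phyper(k - 1, length(pathway), length(universe) - length(pathway),
              length(query), lower.tail = FALSE)
  list(k = k, n_query = length(query), n_pathway = length(pathway),
       n_universe = length(universe), p = min(1, p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values (monotone in p-rank, capped at 1).
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  p.adjust(p, method = "BH")
}

# incidence matrix universe-genes x pathways for fast overlap counting
pathway_incidence <- function(db) {
  inc <- vapply(db$pathways, function(g) db$universe %in% g,
                logical(length(db$universe)))
  rownames(inc) <- db$universe
  inc
}

# Fisher p for every pathway given overlap counts k (vectorized)
all_pathway_p <- function(k, n_path, n_query, n_universe) {
  pmin(1, phyper(k - 1, n_path, n_universe - n_path, n_query,
                 lower.tail = FALSE))
}

#' Monte-Carlo rank-deviation z-scores
#'
#' For each pathway, compares its observed rank (pathways ordered by Fisher
#' p, average ranks on ties) with the rank distribution under random query
#' sets of the same size drawn uniformly from the universe. `z = (observed
#' rank - null mean rank) / null rank sd`; a degenerate null sd yields
#' `z = 0`. Deterministic given `seed` and `B`.
#'
#' @param query Character vector of query genes (already in the universe).
#' @param db A `PathwayDB`.
#' @param B Number of Monte-Carlo draws (default 2000).
#' @param seed Integer RNG seed.
#' @return Numeric vector of z-scores, one per pathway of `db`.
#' @export
rank_deviation_z <- function(query, db, B = 2000, seed = 1) {
  inc <- pathway_incidence(db)
  n_path <- colSums(inc)
  n_universe <- length(db$universe)
  n_query <- length(intersect(query, db$universe))
  k_obs <- colSums(inc[db$universe %in% query, , drop = FALSE])
  p_obs <- all_pathway_p(k_obs, n_path, n_query, n_universe)
  obs_rank <- rank(p_obs, ties.method = "average")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ranks <- matrix(0, B, ncol(inc))
  for (b in seq_len(B)) {
    draw <- sample.int(n_universe, n_query)
    k_b <- colSums(inc[draw, , drop = FALSE])
    p_b <- all_pathway_p(k_b, n_path, n_query, n_universe)
    ranks[b, ] <- rank(p_b, ties.method = "average")
  }
  mu <- colMeans(ranks)
  sdev <- apply(ranks, 2, sd)
  z <- ifelse(sdev > 0, (obs_rank - mu) / sdev, 0)
  setNames(z, names(db$pathways))
}

#' Combined enrichment score
#'
#' `c = -ln(p) * |z|`: large when the enrichment p-value is small and the
#' pathway's rank deviates strongly from its null expectation. Zero when
#' `p = 1` or `z = 0`.
#'
#' @param p_used P-value entering the score (adjusted or raw, see
#'   [run_ora()]).
#' @param z Rank-deviation z-score.
#' @return Non-negative numeric score.
#' @export
combined_score <- function(p_used, z) {
  stopifnot(all(p_used > 0), all(p_used <= 1))
  -log(p_used) * abs(z)
}

#' Over-representation analysis of one group's gene set
#'
#' Runs [fisher_enrichment()] for every pathway, BH-adjusts across
#' pathways, computes rank-deviation z-scores by Monte Carlo, and scores
#' each pathway with [combined_score()]. By default the adjusted p enters
#' the combined score; set `combined_p = "raw"` for the classic Enrichr
#' convention.
#'
#' @param genes Character vector, the group's gene set.
#' @param db A `PathwayDB`.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param B Monte-Carlo draws for the z-score (default 2000).
#' @param seed Integer RNG seed.
#' @param combined_p `"adjusted"` (default) or `"raw"`.
#' @return `data.frame` with one row per pathway: `pathway`, `k`, `n_query`,
#'   `n_pathway`, `n_universe`, `p`, `p_adj`, `z`, `combined`,
#'   `significant`.
#' @export
run_ora <- function(genes, db, alpha = 0.05, B = 2000, seed = 1,
                    combined_p = c("adjusted", "raw")) {
  combined_p <- match.arg(combined_p)
  inc <- pathway_incidence(db)
  n_path <- colSums(inc)
  query <- intersect(unique(genes), db$universe)
  k <- colSums(inc[db$universe %in% query, , drop = FALSE])
  p <- all_pathway_p(k, n_path, length(query), length(db$universe))
  p_adj <- bh_adjust(p)
  z <- rank_deviation_z(query, db, B = B, seed = seed)
  p_used <- if (combined_p == "adjusted") p_adj else p
  data.frame(pathway = names(db$pathways), k = as.integer(k),
             n_query = length(query), n_pathway = as.integer(n_path),
             n_universe = length(db$universe), p = p, p_adj = p_adj,
             z = as.numeric(z), combined = combined_score(p_used, z),
             significant = p_adj < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Between-group combined-score differences (volcano coordinates)
#'
#' One row per pathway appearing in either group's ORA:
#' `delta_combined = combined_OR - combined_SR` (negative = SR-specific
#' enrichment), `min_p_adj` the smaller adjusted p across groups, and
#' `significant_in` whichever groups pass `p_adj < alpha`. A pathway absent
#' from one group's results contributes a combined score of 0 for that
#' group.
#'
#' @param ora_sr,ora_or Results of [run_ora()] for the SR and OR gene sets.
#' @param alpha Significance level (default 0.05).
#' @return `data.frame` with `pathway`, `delta_combined`, `min_p_adj`,
#'   `significant_in` (`"SR"`, `"OR"`, `"both"`, `"neither"`).
#' @export
volcano_table <- function(ora_sr, ora_or, alpha = 0.05) {
  pathways <- union(ora_sr$pathway, ora_or$pathway)
  get <- function(ora, pw, col, default) {
    i <- match(pw, ora$pathway)
    ifelse(is.na(i), default, ora[[col]][i])
  }
  c_sr <- get(ora_sr, pathways, "combined", 0)
  c_or <- get(ora_or, pathways, "combined", 0)
  p_sr <- get(ora_sr, pathways, "p_adj", 1)
  p_or <- get(ora_or, pathways, "p_adj", 1)
  sig_sr <- p_sr < alpha
  sig_or <- p_or < alpha
  data.frame(pathway = pathways,
             delta_combined = c_or - c_sr,
             min_p_adj = pmin(p_sr, p_or),
             significant_in = ifelse(sig_sr & sig_or, "both",
                                     ifelse(sig_sr, "SR",
                                            ifelse(sig_or, "OR", "neither"))),
             stringsAsFactors = FALSE)
}
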