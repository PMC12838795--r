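# Group-specific gene-sets from carried rare damaging variants, and the
# binary gene x individual carrier matrices behind the heatmap displays.

# per-sample logical carrier status for a set of cv rows (dominance coding:
# >=1 alt allele; missing genotypes never count)
carrier_status <- function(cv_rows, dosage) {
  if (length(cv_rows) == 0) return(rep(FALSE, ncol(dosage)))
  sub <- dosage[cv_rows, , drop = FALSE]
  apply(sub, 2, function(col) any(col >= 1, na.rm = TRUE))
}

#' Map rare damaging variants to group-specific gene sets
#'
#' A gene enters the SR set iff at least one SR individual carries (>= 1 alt
#' allele, non-missing) at least one rare damaging variant in it;
#' symmetrically for OR. A gene carried in both groups appears in both sets.
#'
#' @param rare_damaging Output of [build_rare_damaging_set()].
#' @param cv QC'd biallelic [cohort_variants()] object.
#' @param design [read_phenotypes()] table covering every `cv` sample.
#' @return List with `sr_genes`, `or_genes` (sorted character vectors) and
#'   `carriers`, a per-gene list of list(sr = ids, or = ids).
#' @export
map_variants_to_group_genes <- function(rare_damaging, cv, design) {
  absent <- setdiff(cv$samples, design$sample_id)
  if (length(absent) > 0)
    stop("sample(s) in genotypes but absent from design: ",
         paste(absent, collapse = ", "))
  group <- design$group[match(cv$samples, design$sample_id)]
  dosage <- as_dosage(cv)
  genes <- sort(unique(rare_damaging$gene))
  carriers <- list()
  sr_genes <- character(0); or_genes <- character(0)
  for (g in genes) {
    rows <- rare_damaging$cv_row[rare_damaging$gene == g]
    carr <- carrier_status(rows, dosage)
    sr_ids <- cv$samples[carr & group == "SR"]
    or_ids <- cv$samples[carr & group == "OR"]
    if (length(sr_ids) > 0) sr_genes <- c(sr_genes, g)
    if (length(or_ids) > 0) or_genes <- c(or_genes, g)
    carriers[[g]] <- list(sr = sr_ids, or = or_ids)
  }
  list(sr_genes = sr_genes, or_genes = or_genes, carriers = carriers)
}

#' Binary gene-by-individual carrier matrix for selected pathways
#'
#' Rows are all genes of the requested pathways (pathway order, then gene
#' order within pathway, duplicates across pathways kept once at first
#' appearance); columns are cohort samples. A cell is 1 iff that sample
#' carries at least one rare damaging variant in that gene. Genes with no
#' qualifying variant keep their all-zero row so the matrix shape is
#' reproducible.
#'
#' @param pathways Character vector of pathway names, all present in `db`.
#' @param db A `PathwayDB` from [read_gmt()].
#' @param rare_damaging Output of [build_rare_damaging_set()].
#' @param cv QC'd biallelic [cohort_variants()] object.
#' @return Integer 0/1 matrix with gene rownames and sample colnames, plus a
#'   `pathway` attribute mapping each row to the first pathway that
#'   contributed it.
#' @export
carrier_matrix <- function(pathways, db, rare_damaging, cv) {
  unknown <- setdiff(pathways, names(db$pathways))
  if (length(unknown) > 0)
    stop("unknown pathway name(s): ", paste(unknown, collapse = ", "))
  gene_rows <- character(0); pathway_of <- character(0)
  for (p in pathways) {
    new <- setdiff(db$pathways[[p]], gene_rows)
    gene_rows <- c(gene_rows, new)
    pathway_of <- c(pathway_of, rep(p, length(new)))
  }
  dosage <- as_dosage(cv)
  m <- matrix(0L, length(gene_rows), length(cv$samples),
              dimnames = list(gene_rows, cv$samples))
  for (i in seq_along(gene_rows)) {
    rows <- rare_damaging$cv_row[rare_damaging$gene == gene_rows[i]]
    m[i, ] <- as.integer(carrier_status(rows, dosage))
  }
  attr(m, "pathway") <- setNames(pathway_of, gene_rows)
  m
}
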