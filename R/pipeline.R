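# End-to-end convenience wrapper: files in, per-stage results out.

#' Run the full rare-variant pathway pipeline
#'
#' Reads the four inputs, applies genotype QC, classifies variants, builds
#' the group gene-sets, and runs ORA (both groups plus the between-group
#' delta table), carrier-burden tests and SKAT-O. Burden and SKAT-O are run
#' on the ORA-significant pathways by default, or on all pathways.
#'
#' @param vcf,annotations,gmt,phenotypes Paths to the input files, or the
#'   already-loaded objects ([cohort_variants()], annotation `data.frame`,
#'   `PathwayDB`, design `data.frame`).
#' @param thresholds [qc_thresholds()] for the QC stage.
#' @param test_pathways `"significant"` (union of ORA-significant pathways
#'   across groups, the default) or `"all"`.
#' @param alpha Significance level for ORA and burden (default 0.05).
#' @param fdr FDR threshold for SKAT-O (default 0.05).
#' @param B,seed Monte-Carlo settings for the ORA z-scores.
#' @param out_dir Optional directory to write per-stage result TSVs.
#' @param rarity_rule `"max"` or `"min"`, see [is_rare()].
#' @param combined_p `"adjusted"` or `"raw"`, see [run_ora()].
#' @return List with `qc` (report), `classified`, `rare_damaging`,
#'   `gene_sets`, `ora_sr`, `ora_or`, `volcano`, `burden`, `skato`.
#' @export
run_pipeline <- function(vcf, annotations, gmt, phenotypes,
                         thresholds = qc_thresholds(),
                         test_pathways = c("significant", "all"),
                         alpha = 0.05, fdr = 0.05, B = 2000, seed = 1,
                         out_dir = NULL, rarity_rule = "max",
                         combined_p = "adjusted") {
  test_pathways <- match.arg(test_pathways)
  cv <- if (inherits(vcf, "CohortVariants")) vcf else read_vcf(vcf)
  ann <- if (is.data.frame(annotations)) annotations
         else read_annotations(annotations)
  db <- if (inherits(gmt, "PathwayDB")) gmt else read_gmt(gmt)
  design <- if (is.data.frame(phenotypes)) phenotypes
            else read_phenotypes(phenotypes, samples = cv$samples)

  qc <- run_qc(cv, thresholds)
  classified <- classify_variants(ann, rarity_rule = rarity_rule)
  rare_damaging <- build_rare_damaging_set(classified, qc$cv)
  gene_sets <- map_variants_to_group_genes(rare_damaging, qc$cv, design)

  ora_sr <- run_ora(gene_sets$sr_genes, db, alpha = alpha, B = B,
                    seed = seed, combined_p = combined_p)
  ora_or <- run_ora(gene_sets$or_genes, db, alpha = alpha, B = B,
                    seed = seed + 1L, combined_p = combined_p)
  volcano <- volcano_table(ora_sr, ora_or, alpha = alpha)

  pws <- if (test_pathways == "all") names(db$pathways) else
    union(ora_sr$pathway[ora_sr$significant],
          ora_or$pathway[ora_or$significant])
  burden <- run_burden(pws, db, rare_damaging, qc$cv, design, alpha = alpha)
  skato <- run_skato(pws, db, rare_damaging, qc$cv, design, fdr = fdr)

  res <- list(qc = qc$report, classified = classified,
              rare_damaging = rare_damaging, gene_sets = gene_sets,
              ora_sr = ora_sr, ora_or = ora_or, volcano = volcano,
              burden = burden, skato = skato)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    params <- list(seed = seed, B = B, alpha = alpha, fdr = fdr,
                   rarity_rule = rarity_rule, combined_p = combined_p,
                   sex_coding = "female=0,male=1")
    for (nm in c("ora_sr", "ora_or", "volcano", "burden", "skato"))
      write_results(res[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                    params = params)
    write_results(data.frame(gene = gene_sets$sr_genes),
                  file.path(out_dir, "genes_sr.tsv"))
    write_results(data.frame(gene = gene_sets$or_genes),
                  file.path(out_dir, "genes_or.tsv"))
  }
  res
}
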