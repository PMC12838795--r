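# Genotype- and variant-level quality control producing an analysis-ready
# biallelic variant set. Filter chain (fixed order, recorded in the report):
# mask low-quality genotypes -> split/trim multiallelics -> drop variants by
# missingness.

#' QC thresholds
#'
#' All genotype thresholds are strict `<` comparisons, and the missingness
#' bound is strict `>`: a heterozygote with DP exactly 20, GQ exactly 20 and
#' allelic balance exactly 0.2 is kept, and a variant missing in exactly 5%
#' of samples is kept.
#'
#' @param min_dp Minimum read depth (default 20).
#' @param min_gq Minimum genotype quality (default 20).
#' @param min_het_ab Minimum allelic balance for heterozygous calls,
#'   `alt_reads / (ref_reads + alt_reads)` (default 0.2).
#' @param max_missing_fraction Maximum tolerated fraction of missing
#'   genotypes per variant (default 0.05).
#' @return A `QcThresholds` list.
#' @export
qc_thresholds <- function(min_dp = 20L, min_gq = 20L, min_het_ab = 0.2,
                          max_missing_fraction = 0.05) {
  stopifnot(min_dp >= 0, min_gq >= 0,
            min_het_ab >= 0, min_het_ab <= 0.5,
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  structure(list(min_dp = as.integer(min_dp), min_gq = as.integer(min_gq),
                 min_het_ab = min_het_ab,
                 max_missing_fraction = max_missing_fraction),
            class = "QcThresholds")
}

# allelic balance for biallelic-style het calls: alt / (ref + alt).
# Returns NA when AD is absent or the call involves two distinct alt alleles
# (the AB sub-filter is then skipped for that call).
het_allelic_balance <- function(gt, ad) {
  n <- length(gt)
  ab <- rep(NA_real_, n)
  idx <- which(!is.na(gt) & !is.na(ad))
  for (i in idx) {
    al <- as.integer(strsplit(gt[i], "/", fixed = TRUE)[[1]])
    if (sum(al == 0) != 1) next      # not a ref/alt het
    counts <- suppressWarnings(as.integer(strsplit(ad[i], ",",
                                                   fixed = TRUE)[[1]]))
    alt_allele <- al[al != 0]
    if (length(counts) < alt_allele + 1 || anyNA(counts)) next
    tot <- counts[1] + counts[alt_allele + 1]
    ab[i] <- if (tot == 0) 0 else counts[alt_allele + 1] / tot
  }
  ab
}

#' Mask low-quality genotypes
#'
#' Sets a genotype to missing iff `dp < min_dp`, or `gq < min_gq`, or the
#' call is heterozygous with allelic balance `< min_het_ab`. Each sub-filter
#' only applies where its field is present; a heterozygote whose AD sums to
#' zero reads is treated as AB = 0 and masked. No non-missing genotype value
#' is ever altered, only its missingness.
#'
#' @param cv A [cohort_variants()] object.
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with the masked `CohortVariants` (`cv`) and a `data.frame`
#'   `mask_counts` of genotypes masked per sub-filter.
#' @export
mask_low_quality_genotypes <- function(cv, thresholds = qc_thresholds()) {
  called <- !is.na(cv$gt)
  low_dp <- called & !is.na(cv$dp) & cv$dp < thresholds$min_dp
  low_gq <- called & !is.na(cv$gq) & cv$gq < thresholds$min_gq
  is_het <- called & grepl("^0/[1-9]", cv$gt)
  ab <- matrix(het_allelic_balance(as.vector(ifelse(is_het, cv$gt, NA)),
                                   as.vector(cv$ad)),
               nrow(cv$gt), ncol(cv$gt))
  low_ab <- is_het & !is.na(ab) & ab < thresholds$min_het_ab
  drop <- low_dp | low_gq | low_ab
  cv$gt[drop] <- NA_character_
  list(cv = cv,
       mask_counts = data.frame(filter = c("low_dp", "low_gq", "low_het_ab",
                                           "masked_total"),
                                n_genotypes = c(sum(low_dp), sum(low_gq),
                                                sum(low_ab), sum(drop))))
}

trim_allele_pair <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # shared suffix first, then shared prefix (position advances per prefix base)
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Split multiallelic records and trim shared allele sequence
#'
#' Every ALT allele becomes its own biallelic record. Per-sample genotypes
#' are recoded against that ALT: copies of the target allele count as alt,
#' every other allele (reference or a different alt) counts as ref, and
#' missing stays missing. AD is reduced to the (ref, target-alt) pair.
#' Shared REF/ALT sequence is trimmed suffix-first then prefix (advancing
#' `pos`); trimming is reference-free, so full left-alignment against a
#' FASTA is out of scope.
#'
#' @param cv A [cohort_variants()] object (multiallelic records allowed).
#' @return A biallelic `CohortVariants` with records in input order, alt
#'   alleles of a line kept adjacent.
#' @export
split_and_trim_alleles <- function(cv) {
  n <- n_variants(cv)
  rows <- list()
  gt_rows <- list(); dp_rows <- list(); gq_rows <- list(); ad_rows <- list()
  for (i in seq_len(n)) {
    alts <- strsplit(cv$variants$alt[i], ",", fixed = TRUE)[[1]]
    gt_alleles <- strsplit(ifelse(is.na(cv$gt[i, ]), "NA/NA", cv$gt[i, ]),
                           "/", fixed = TRUE)
    ad_counts <- strsplit(ifelse(is.na(cv$ad[i, ]), "", cv$ad[i, ]),
                          ",", fixed = TRUE)
    for (k in seq_along(alts)) {
      tr <- trim_allele_pair(cv$variants$pos[i], cv$variants$ref[i], alts[k])
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = cv$variants$chrom[i], pos = tr$pos,
                   id = cv$variants$id[i], ref = tr$ref, alt = tr$alt,
                   stringsAsFactors = FALSE)
      new_gt <- vapply(gt_alleles, function(al) {
        if (al[1] == "NA") return(NA_character_)
        n_alt <- sum(al == as.character(k))
        c("0/0", "0/1", "1/1")[n_alt + 1L]
      }, character(1))
      new_ad <- vapply(ad_counts, function(cts) {
        if (length(cts) < k + 1) return(NA_character_)
        paste(cts[1], cts[k + 1], sep = ",")
      }, character(1))
      gt_rows[[length(gt_rows) + 1L]] <- new_gt
      dp_rows[[length(dp_rows) + 1L]] <- cv$dp[i, ]
      gq_rows[[length(gq_rows) + 1L]] <- cv$gq[i, ]
      ad_rows[[length(ad_rows) + 1L]] <- new_ad
    }
  }
  variants <- if (length(rows) > 0) do.call(rbind, rows) else
    cv$variants[0, ]
  bindm <- function(lst, mode) {
    if (length(lst) == 0)
      return(matrix(vector(mode, 0), 0, length(cv$samples)))
    m <- do.call(rbind, lst)
    storage.mode(m) <- mode
    m
  }
  cohort_variants(cv$samples, variants,
                  gt = bindm(gt_rows, "character"),
                  dp = bindm(dp_rows, "integer"),
                  gq = bindm(gq_rows, "integer"),
                  ad = bindm(ad_rows, "character"))
}

#' Drop variants by genotype missingness
#'
#' Removes a variant iff the fraction of missing genotypes exceeds
#' `max_missing_fraction` (strict `>`; with 63 samples, 3 missing = 4.8% is
#' kept and 4 missing = 6.3% is dropped at the default 5% bound).
#'
#' @param cv A [cohort_variants()] object, already masked.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with the filtered `cv` and a `report` data.frame
#'   (`n_input_variants`, `n_after_missingness`).
#' @export
drop_high_missingness_variants <- function(cv, thresholds = qc_thresholds()) {
  if (length(cv$samples) == 0) stop("cohort has zero samples")
  miss_frac <- rowMeans(is.na(cv$gt))
  keep <- miss_frac <= thresholds$max_missing_fraction
  out <- cv
  out$variants <- cv$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  for (f in c("gt", "dp", "gq", "ad"))
    out[[f]] <- cv[[f]][keep, , drop = FALSE]
  list(cv = out,
       report = data.frame(n_input_variants = n_variants(cv),
                           n_after_missingness = sum(keep)))
}

#' Run the full genotype QC chain
#'
#' Masking, biallelic normalization, then missingness filtering, with a
#' per-stage report.
#'
#' @param cv A [cohort_variants()] object straight from [read_vcf()].
#' @param thresholds A [qc_thresholds()] object.
#' @return List with the analysis-ready `cv`, the genotype `mask_counts`,
#'   and the variant-count `report` across stages.
#' @export
run_qc <- function(cv, thresholds = qc_thresholds()) {
  masked <- mask_low_quality_genotypes(cv, thresholds)
  split <- split_and_trim_alleles(masked$cv)
  final <- drop_high_missingness_variants(split, thresholds)
  report <- data.frame(stage = c("input", "masked", "biallelic",
                                 "missingness"),
                       n_variants = c(n_variants(cv), n_variants(masked$cv),
                                      n_variants(split),
                                      n_variants(final$cv)))
  list(cv = final$cv, mask_counts = masked$mask_counts, report = report)
}
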