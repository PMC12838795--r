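# Parameter-controlled synthetic cohort generator. Emits the four pipeline
# inputs (VCF, annotation TSV, GMT, phenotype TSV) plus a ground-truth
# bundle, so every analysis stage can be validated against known answers
# without any external data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the study conditions the pipeline targets: 31
#' suboptimal vs 32 optimal responders, rare-skewed allele frequencies,
#' deleteriousness scores separated for damaging vs benign missense
#' variants, gnomAD columns as noisy copies of the true MAF, and one
#' pathway with a planted group-differential carrier rate of 0.58 vs 0.28
#' (the carrier-burden regime the method is designed to flag, odds ratio
#' near 3.5).
#'
#' @param n_sr,n_or Group sizes (defaults 31 and 32).
#' @param n_gene_pool Size of the gene pool pathways draw from.
#' @param n_pathways,genes_per_pathway Gene-set shape of the emitted GMT
#'   (pathways overlap, as in a real hierarchy).
#' @param variants_per_gene_mean Mean of the (1 + Poisson) per-gene variant
#'   count.
#' @param maf_range True MAFs are log-uniform over this interval; with the
#'   default `[5e-4, 0.2]` roughly three quarters of variants fall under
#'   the 0.05 rarity cutoff.
#' @param class_probs Probabilities of the true functional classes
#'   `damaging_missense`, `benign_missense`, `plof_hc`, `plof_lc`,
#'   `synonymous` (must sum to 1).
#' @param score_shape_damaging,score_shape_benign Beta parameters of the
#'   REVEL/MetaRNN laws for damaging vs benign missense variants (means
#'   above and below 0.5).
#' @param score_missing_rate Per-tool probability that a missense score is
#'   absent.
#' @param gnomad_log_noise_sd Lognormal perturbation of the true MAF used
#'   for each gnomAD column (so "exomes" and "genomes" disagree
#'   realistically around the rarity cutoff).
#' @param gnomad_missing_rate Probability a gnomAD column is absent.
#' @param effects List of planted effects. A carrier effect is
#'   `list(pathway = <index or name>, type = "carrier", p_sr =, p_or =)`:
#'   each group member is made a pathway carrier with exactly that
#'   probability. A mixed-direction effect is `list(pathway =, type =
#'   "mixed", n_variants =, delta =)`: half the chosen qualifying variants
#'   get extra alt alleles in SR carriers, half in OR, producing opposing
#'   effects a carrier count cannot see.
#' @param missing_rate Baseline fraction of genotypes emitted as missing.
#' @param qc_low_dp_rate,qc_low_gq_rate,qc_low_ab_rate Fractions of called
#'   genotypes corrupted so the QC filters have known targets (disjoint
#'   sets; AB corruption hits heterozygotes only).
#' @param age_mean,age_sd Age law (normal, rounded, clamped to 20-80).
#' @param p_male Probability of male sex.
#' @param seed Mandatory integer seed; identical configurations and seeds
#'   give byte-identical emitted bundles.
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_sr = 31, n_or = 32, n_gene_pool = 350,
                             n_pathways = 30, genes_per_pathway = 15,
                             variants_per_gene_mean = 3,
                             maf_range = c(5e-4, 0.2),
                             class_probs = c(damaging_missense = 0.20,
                                             benign_missense = 0.35,
                                             plof_hc = 0.08, plof_lc = 0.05,
                                             synonymous = 0.32),
                             score_shape_damaging = c(8, 3),
                             score_shape_benign = c(2, 6),
                             score_missing_rate = 0.10,
                             gnomad_log_noise_sd = 0.3,
                             gnomad_missing_rate = 0.05,
                             effects = list(list(pathway = 1,
                                                 type = "carrier",
                                                 p_sr = 0.58, p_or = 0.28)),
                             missing_rate = 0.003,
                             qc_low_dp_rate = 0.004, qc_low_gq_rate = 0.003,
                             qc_low_ab_rate = 0.002,
                             age_mean = 57, age_sd = 13, p_male = 0.5,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory for any emitted dataset")
  stopifnot(n_sr >= 2, n_or >= 2, abs(sum(class_probs) - 1) < 1e-8,
            all(class_probs >= 0), maf_range[1] > 0, maf_range[2] <= 0.5)
  cfg <- as.list(environment())
  class(cfg) <- "SyntheticConfig"
  cfg
}

sample_scores <- function(n, damaging, cfg) {
  sh_d <- cfg$score_shape_damaging; sh_b <- cfg$score_shape_benign
  s <- ifelse(damaging, stats::rbeta(n, sh_d[1], sh_d[2]),
              stats::rbeta(n, sh_b[1], sh_b[2]))
  s[runif(n) < cfg$score_missing_rate] <- NA
  s
}

#' Generate a synthetic cohort bundle
#'
#' Draws pathways, genes, variants, annotations, genotypes
#' (Hardy-Weinberg, `Binomial(2, MAF)` per sample, no linkage
#' disequilibrium), plants the configured group-differential effects,
#' applies QC corruption ([inject_qc_corruption()]), and optionally writes
#' the four input files plus truth tables. The returned truth bundle
#' records, per variant, the true class and the rarity/qualifying status
#' implied by the emitted annotation columns and post-corruption
#' genotypes, so tests never reverse-engineer truth from pipeline output.
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Optional directory; when given, `cohort.vcf`,
#'   `annotations.tsv`, `pathways.gmt`, `phenotypes.tsv` and
#'   `truth_*.tsv` are written there.
#' @param corrupt Apply the configured QC corruption (default TRUE).
#' @return List with `cv`, `annotations`, `db`, `design`, `truth`
#'   (`variants`, `planted_carriers`, `corrupted`, `effect_pathways`) and
#'   `files` (paths, when written).
#' @export
simulate_cohort <- function(cfg, out_dir = NULL, corrupt = TRUE) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  bundle <- with_seed(cfg$seed, {
    n <- cfg$n_sr + cfg$n_or
    samples <- sprintf("S%03d", seq_len(n))
    group <- c(rep("SR", cfg$n_sr), rep("OR", cfg$n_or))
    design <- data.frame(
      sample_id = samples, group = group,
      age = pmin(80, pmax(20, round(rnorm(n, cfg$age_mean, cfg$age_sd)))),
      sex = ifelse(runif(n) < cfg$p_male, "male", "female"),
      stringsAsFactors = FALSE)
    design$sex_code <- ifelse(design$sex == "male", 1, 0)
    class(design) <- c("CohortDesign", "data.frame")

    pool <- sprintf("GENE%04d", seq_len(cfg$n_gene_pool))
    pathways <- setNames(
      lapply(seq_len(cfg$n_pathways), function(i)
        sort(sample(pool, cfg$genes_per_pathway))),
      sprintf("PWY%03d", seq_len(cfg$n_pathways)))
    db <- pathway_db(pathways, universe = pool)

    genes <- sort(unique(unlist(pathways)))
    n_per_gene <- 1 + rpois(length(genes), cfg$variants_per_gene_mean)
    gene_of <- rep(genes, n_per_gene)
    n_var <- length(gene_of)
    gene_idx <- match(gene_of, genes)
    pos <- 100000L * gene_idx +
      as.integer(unlist(lapply(n_per_gene, function(k)
        sort(sample.int(99000L, k)))))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_var, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    variants <- data.frame(chrom = "1", pos = pos,
                           id = sprintf("var%05d", seq_len(n_var)),
                           ref = ref, alt = unname(alt),
                           stringsAsFactors = FALSE)

    maf <- exp(runif(n_var, log(cfg$maf_range[1]), log(cfg$maf_range[2])))
    true_class <- sample(names(cfg$class_probs), n_var, replace = TRUE,
                         prob = cfg$class_probs)
    is_mis <- true_class %in% c("damaging_missense", "benign_missense")
    dmg <- true_class == "damaging_missense"
    revel <- rep(NA_real_, n_var); metarnn <- rep(NA_real_, n_var)
    revel[is_mis] <- sample_scores(sum(is_mis), dmg[is_mis], cfg)
    metarnn[is_mis] <- sample_scores(sum(is_mis), dmg[is_mis], cfg)
    plof_terms <- c("stop_gained", "frameshift_variant", "start_lost",
                    "stop_lost", "splice_donor_variant",
                    "splice_acceptor_variant")
    consequence <- rep("synonymous_variant", n_var)
    consequence[is_mis] <- ifelse(runif(sum(is_mis)) < 0.2,
                                  "missense_variant&splice_region_variant",
                                  "missense_variant")
    is_plof <- true_class %in% c("plof_hc", "plof_lc")
    consequence[is_plof] <- sample(plof_terms, sum(is_plof), replace = TRUE)
    loftee <- rep(NA_character_, n_var)
    loftee[true_class == "plof_hc"] <- "HC"
    loftee[true_class == "plof_lc"] <- "LC"
    noisy_af <- function() {
      af <- pmin(0.999, maf * exp(rnorm(n_var, 0, cfg$gnomad_log_noise_sd)))
      af[runif(n_var) < cfg$gnomad_missing_rate] <- NA
      af
    }
    af_ex <- noisy_af(); af_gen <- noisy_af()

    annotations <- data.frame(
      chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
      alt = variants$alt, gene = gene_of,
      transcript = sprintf("TX%s.1", gene_of),
      canonical = 1L, consequence = consequence,
      revel = revel, metarnn = metarnn, loftee = loftee,
      af_gnomad_exomes = af_ex, af_gnomad_genomes = af_gen,
      stringsAsFactors = FALSE)

    dosage <- matrix(rbinom(n_var * n, 2, rep(maf, n)), n_var, n)

    # emitted-column view of the damaging/rare decision, for effect
    # planting and truth bookkeeping
    consensus <- consensus_missense_score(revel, metarnn)
    emitted_class <- ifelse(
      true_class == "plof_hc", "plof",
      ifelse(is_mis & !is.na(consensus) & consensus > 0.5,
             "damaging_missense", "none"))
    emitted_rare <- is_rare(af_ex, af_gen)$is_rare

    effect_pathways <- character(0)
    planted <- list()
    for (eff in cfg$effects) {
      pw <- if (is.numeric(eff$pathway))
        names(pathways)[eff$pathway] else eff$pathway
      effect_pathways <- c(effect_pathways, pw)
      qual <- which(gene_of %in% pathways[[pw]] &
                      emitted_class != "none" & emitted_rare)
      if (length(qual) == 0)
        stop("effect pathway ", pw, " has no qualifying variants; ",
             "increase pathway or variant counts")
      if (eff$type == "carrier") {
        target <- rep(NA, n)
        for (i in seq_len(n)) {
          p <- if (group[i] == "SR") eff$p_sr else eff$p_or
          target[i] <- runif(1) < p
          carrier <- any(dosage[qual, i] >= 1)
          if (target[i] && !carrier) {
            dosage[qual[sample.int(length(qual), 1)], i] <- 1L
          } else if (!target[i] && carrier) {
            dosage[qual, i] <- 0L
          }
        }
        planted[[pw]] <- data.frame(sample_id = samples, pathway = pw,
                                    carrier = target,
                                    stringsAsFactors = FALSE)
      } else if (eff$type == "mixed") {
        k <- min(eff$n_variants, length(qual))
        chosen <- qual[sample.int(length(qual), k)]
        up_sr <- chosen[seq_len(ceiling(k / 2))]
        up_or <- setdiff(chosen, up_sr)
        for (j in up_sr) {
          idx <- which(group == "SR" & runif(n) < eff$delta)
          dosage[j, idx] <- pmin(2L, dosage[j, idx] + 1L)
        }
        for (j in up_or) {
          idx <- which(group == "OR" & runif(n) < eff$delta)
          dosage[j, idx] <- pmin(2L, dosage[j, idx] + 1L)
        }
      } else stop("unknown effect type: ", eff$type)
    }

    # baseline call-level fields consistent with the genotypes
    dp <- matrix(rpois(n_var * n, 60) + 20L, n_var, n)
    gq <- matrix(sample(60:99, n_var * n, replace = TRUE), n_var, n)
    alt_reads <- matrix(0L, n_var, n)
    het <- dosage == 1L; hom <- dosage == 2L
    alt_reads[het] <- rbinom(sum(het), dp[het], 0.5)
    alt_reads[hom] <- dp[hom] - rbinom(sum(hom), dp[hom], 0.01)
    alt_reads[dosage == 0L] <- rbinom(sum(dosage == 0L),
                                      dp[dosage == 0L], 0.01)
    gt <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L], n_var, n)
    gt[matrix(runif(n_var * n) < cfg$missing_rate, n_var, n)] <-
      NA_character_
    ad <- matrix(paste(dp - alt_reads, alt_reads, sep = ","), n_var, n)
    dp_m <- dp; gq_m <- gq; ad_m <- ad
    dp_m[is.na(gt)] <- NA_integer_; gq_m[is.na(gt)] <- NA_integer_
    ad_m[is.na(gt)] <- NA_character_
    cv <- cohort_variants(samples, variants, gt, dp_m, gq_m, ad_m)

    # truth bookkeeping: post-QC carrier counts use the generator's own
    # records (clean genotypes, corruption applied later)
    truth_variants <- data.frame(
      chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
      alt = variants$alt, gene = gene_of, true_class = true_class,
      maf_true = maf, emitted_class = emitted_class,
      emitted_rare = emitted_rare, stringsAsFactors = FALSE)

    list(cv = cv, annotations = annotations, db = db, design = design,
         truth = list(variants = truth_variants,
                      planted_carriers = if (length(planted) > 0)
                        do.call(rbind, c(planted,
                                         list(make.row.names = FALSE)))
                      else NULL,
                      corrupted = NULL,
                      effect_pathways = effect_pathways),
         files = NULL)
  })
  if (corrupt)
    bundle <- with_seed(cfg$seed + 1L, inject_qc_corruption(bundle, cfg))
  bundle$truth$variants$qualifying <- qualifying_truth(bundle, cfg)
  if (!is.null(out_dir)) bundle <- write_bundle(bundle, cfg, out_dir)
  bundle
}

# variant qualifies iff emitted-damaging, emitted-rare, and carried by >= 1
# sample whose call survives masking and the missingness filter
qualifying_truth <- function(bundle, cfg) {
  cv <- bundle$cv
  gt <- cv$gt
  if (!is.null(bundle$truth$corrupted) && nrow(bundle$truth$corrupted) > 0)
    gt[cbind(bundle$truth$corrupted$variant_row,
             bundle$truth$corrupted$sample_col)] <- NA_character_
  keep_var <- rowMeans(is.na(gt)) <= 0.05
  carried <- apply(gt, 1, function(g)
    any(!is.na(g) & g %in% c("0/1", "1/1")))
  bundle$truth$variants$emitted_class != "none" &
    bundle$truth$variants$emitted_rare & carried & keep_var
}

#' Inject QC-filter corruption into a clean bundle
#'
#' Lowers DP, GQ or heterozygote allelic balance on disjoint, recorded
#' subsets of the called genotypes, so the set of calls masked by
#' [mask_low_quality_genotypes()] at default thresholds is known exactly.
#' Rates of zero leave the bundle untouched.
#'
#' @param bundle Output of [simulate_cohort()].
#' @param cfg The same [synthetic_config()].
#' @return The bundle with modified `cv` and a `truth$corrupted` table
#'   (`variant_row`, `sample_col`, `reason`).
#' @export
inject_qc_corruption <- function(bundle, cfg) {
  cv <- bundle$cv
  called <- which(!is.na(cv$gt))
  n_call <- length(called)
  pick <- function(pool, rate) {
    k <- min(round(rate * n_call), length(pool))
    if (k == 0) integer(0) else pool[sample.int(length(pool), k)]
  }
  low_dp <- pick(called, cfg$qc_low_dp_rate)
  rest <- setdiff(called, low_dp)
  low_gq <- pick(rest, cfg$qc_low_gq_rate)
  rest <- setdiff(rest, low_gq)
  het_rest <- rest[cv$gt[rest] == "0/1"]
  low_ab <- pick(het_rest, cfg$qc_low_ab_rate)
  if (length(low_dp) > 0)
    cv$dp[low_dp] <- sample(5:19, length(low_dp), replace = TRUE)
  if (length(low_gq) > 0)
    cv$gq[low_gq] <- sample(0:19, length(low_gq), replace = TRUE)
  if (length(low_ab) > 0) {
    dp_ab <- cv$dp[low_ab]
    alt <- floor(dp_ab * runif(length(low_ab), 0, 0.19))
    cv$ad[low_ab] <- paste(dp_ab - alt, alt, sep = ",")
  }
  idx <- c(low_dp, low_gq, low_ab)
  corrupted <- data.frame(
    variant_row = ((idx - 1) %% nrow(cv$gt)) + 1L,
    sample_col = ((idx - 1) %/% nrow(cv$gt)) + 1L,
    reason = rep(c("low_dp", "low_gq", "low_ab"),
                 c(length(low_dp), length(low_gq), length(low_ab))),
    stringsAsFactors = FALSE)
  bundle$cv <- cv
  bundle$truth$corrupted <- corrupted
  bundle
}

write_bundle <- function(bundle, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(
    vcf = file.path(out_dir, "cohort.vcf"),
    annotations = file.path(out_dir, "annotations.tsv"),
    gmt = file.path(out_dir, "pathways.gmt"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    truth_variants = file.path(out_dir, "truth_variants.tsv"),
    truth_corrupted = file.path(out_dir, "truth_corrupted.tsv"))
  write_vcf(bundle$cv, files$vcf)
  write_results(bundle$annotations, files$annotations)
  write_gmt(bundle$db, files$gmt)
  pheno <- bundle$design[, c("sample_id", "group", "age", "sex")]
  write_results(pheno, files$phenotypes)
  write_results(bundle$truth$variants, files$truth_variants,
                params = list(seed = cfg$seed))
  write_results(bundle$truth$corrupted, files$truth_corrupted)
  if (!is.null(bundle$truth$planted_carriers)) {
    files$truth_carriers <- file.path(out_dir, "truth_carriers.tsv")
    write_results(bundle$truth$planted_carriers, files$truth_carriers)
  }
  bundle$files <- files
  bundle
}
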