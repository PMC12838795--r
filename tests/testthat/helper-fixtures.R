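# Shared fixture builders and independent oracles.

# minimal in-memory cohort: gt is a character matrix ("0/1", NA, ...)
make_cv <- function(gt, dp = NULL, gq = NULL, ad = NULL,
                    pos = NULL, ref = NULL, alt = NULL, chrom = "1") {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  variants <- data.frame(
    chrom = rep(chrom, length.out = n),
    pos = if (is.null(pos)) seq_len(n) * 100L else pos,
    id = sprintf("v%d", seq_len(n)),
    ref = if (is.null(ref)) rep("A", n) else ref,
    alt = if (is.null(alt)) rep("G", n) else alt,
    stringsAsFactors = FALSE)
  cohort_variants(sprintf("S%02d", seq_len(ncol(gt))), variants, gt,
                  dp, gq, ad)
}

make_design <- function(groups, age = NULL, sex = NULL) {
  n <- length(groups)
  d <- data.frame(sample_id = sprintf("S%02d", seq_len(n)), group = groups,
                  age = if (is.null(age)) rep(50, n) else age,
                  sex = if (is.null(sex)) rep("female", n) else sex,
                  stringsAsFactors = FALSE)
  d$sex_code <- ifelse(d$sex == "male", 1, 0)
  d
}

# small null-effect generator config for quick structural tests
small_cfg <- function(seed, n_pathways = 4, genes_per_pathway = 5,
                      n_gene_pool = 40, effects = list(), ...) {
  synthetic_config(seed = seed, n_pathways = n_pathways,
                   genes_per_pathway = genes_per_pathway,
                   n_gene_pool = n_gene_pool, effects = effects, ...)
}

# one annotation row with overridable fields
ann_row <- function(chrom = "1", pos = 100L, ref = "A", alt = "G",
                    gene = "G1", transcript = "T1", canonical = TRUE,
                    consequence = "missense_variant", revel = NA,
                    metarnn = NA, loftee = NA, af_ex = NA, af_gen = NA) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             gene = gene, transcript = transcript, canonical = canonical,
             consequence = consequence, revel = as.numeric(revel),
             metarnn = as.numeric(metarnn),
             loftee = as.character(loftee),
             af_gnomad_exomes = as.numeric(af_ex),
             af_gnomad_genomes = as.numeric(af_gen),
             stringsAsFactors = FALSE)
}

# textbook step-up BH, coded independently of stats::p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# hypergeometric upper tail by explicit summation
hyper_tail_oracle <- function(k, n_path, n_query, N) {
  xs <- k:min(n_path, n_query)
  sum(choose(n_path, xs) * choose(N - n_path, n_query - xs)) /
    choose(N, n_query)
}

expect_cv_equal <- function(a, b) {
  expect_identical(a$samples, b$samples)
  expect_equal(a$variants, b$variants)
  expect_identical(a$gt, b$gt)
  expect_identical(a$dp, b$dp)
  expect_identical(a$gq, b$gq)
  expect_identical(a$ad, b$ad)
}
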