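test_that("annotation picking prefers canonical, then severity, then transcript", {
  sev <- severity_order()
  # canonical missense beats non-canonical stop_gained
  recs <- rbind(ann_row(transcript = "T1", canonical = TRUE,
                        consequence = "missense_variant"),
                ann_row(transcript = "T2", canonical = FALSE,
                        consequence = "stop_gained"))
  expect_identical(pick_annotation(recs, sev)$transcript, "T1")
  # compound term outranks its plain counterpart between two canonicals
  recs <- rbind(ann_row(transcript = "T1",
                        consequence = "missense_variant"),
                ann_row(transcript = "T2",
                        consequence = "missense_variant&splice_region_variant"))
  expect_identical(pick_annotation(recs, sev)$transcript, "T2")
  # severity tie -> lexicographically first transcript
  recs <- rbind(ann_row(transcript = "T9"), ann_row(transcript = "T2"))
  expect_identical(pick_annotation(recs, sev)$transcript, "T2")
  # single record is returned as-is
  one <- ann_row(transcript = "T5")
  expect_identical(pick_annotation(one, sev), one)
})

test_that("reversing the severity order flips two-record picks", {
  recs <- rbind(ann_row(transcript = "T1", consequence = "stop_gained"),
                ann_row(transcript = "T2", consequence = "missense_variant"))
  sev <- severity_order()
  expect_identical(pick_annotation(recs, sev)$transcript, "T1")
  expect_identical(pick_annotation(recs, rev(sev))$transcript, "T2")
})

test_that("consensus score averages available tools and vanishes when both absent", {
  expect_equal(consensus_missense_score(0.7, 0.4), 0.55)
  expect_equal(consensus_missense_score(0.8, NA), 0.8)
  expect_equal(consensus_missense_score(NA, 0.3), 0.3)
  expect_true(is.na(consensus_missense_score(NA, NA)))
})

test_that("damage classes follow the LOFTEE-HC and strict >0.5 rules", {
  cl <- function(...) classify_variants(ann_row(...))$damage_class
  expect_identical(cl(consequence = "stop_gained", loftee = "HC"), "plof")
  expect_identical(cl(consequence = "stop_gained", loftee = "LC"), "none")
  expect_identical(cl(consequence = "stop_gained"), "none")
  expect_identical(cl(consequence = "missense_variant",
                      revel = 0.6, metarnn = 0.4), "none")   # 0.5 exactly
  expect_identical(cl(consequence = "missense_variant",
                      revel = 0.7, metarnn = 0.4), "damaging_missense")
  expect_identical(cl(consequence = "missense_variant&splice_region_variant",
                      revel = 0.9, metarnn = 0.9), "damaging_missense")
  expect_identical(cl(consequence = "synonymous_variant"), "none")
  # essential splice with HC is plof even when scores are high
  expect_identical(cl(consequence = "splice_donor_variant", loftee = "HC",
                      revel = 0.9, metarnn = 0.9), "plof")
})

test_that("rarity uses the max-of-available rule with strict cutoff", {
  r <- function(...) is_rare(...)
  expect_false(r(0.04, 0.06)$is_rare)          # common in one resource
  expect_equal(r(0.04, 0.06)$max_gnomad_af, 0.06)
  expect_true(r(0.04, 0.06, rule = "min")$is_rare)
  expect_true(r(NA, NA)$is_rare)               # novel variant, AF -> 0
  expect_equal(r(NA, NA)$max_gnomad_af, 0)
  expect_false(r(0.05, NA)$is_rare)            # strict '<'
  expect_true(r(0.049999, NA)$is_rare)
})

test_that("classification is a pure function of rows (order invariant)", {
  b <- simulate_cohort(small_cfg(21))
  ann <- b$annotations
  perm <- sample(nrow(ann))
  c1 <- classify_variants(ann)
  c2 <- classify_variants(ann[perm, ])
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, d$gene)
  c2 <- c2[match(key(c1), key(c2)), ]
  rownames(c2) <- NULL
  expect_equal(c1, c2)
})

test_that("the damaging/rare funnel is monotone and matches generator truth", {
  b <- simulate_cohort(synthetic_config(seed = 22, n_pathways = 8,
                                        genes_per_pathway = 8,
                                        n_gene_pool = 80, effects = list()))
  qc <- run_qc(b$cv)
  cl <- classify_variants(b$annotations)
  n_damaging <- sum(cl$damage_class != "none")
  n_rare_damaging <- sum(cl$damage_class != "none" & cl$is_rare)
  expect_lte(n_rare_damaging, n_damaging)
  expect_lte(n_damaging, nrow(cl))
  rd <- build_rare_damaging_set(cl, qc$cv)
  expect_lte(nrow(rd), n_rare_damaging)
  # exact bookkeeping against the generator's truth table
  expect_equal(nrow(rd), sum(b$truth$variants$qualifying))
  tv <- b$truth$variants
  expect_setequal(variant_key(rd$chrom, rd$pos, rd$ref, rd$alt),
                  variant_key(tv$chrom, tv$pos, tv$ref,
                              tv$alt)[tv$qualifying])
})

test_that("uncarried and common variants are excluded from the rare damaging set", {
  ann <- rbind(
    ann_row(pos = 100L, gene = "G1", consequence = "stop_gained",
            loftee = "HC", af_ex = 0.2),                      # common
    ann_row(pos = 200L, gene = "G2", consequence = "stop_gained",
            loftee = "HC", af_ex = 0.001),                    # rare, uncarried
    ann_row(pos = 300L, gene = "G3", consequence = "missense_variant",
            revel = 0.9, metarnn = 0.8, af_ex = 0.001))       # rare, carried
  cv <- make_cv(rbind(c("0/1", "0/1"), c("0/0", NA), c("0/0", "0/1")),
                pos = c(100L, 200L, 300L))
  rd <- build_rare_damaging_set(classify_variants(ann), cv)
  expect_identical(rd$gene, "G3")
})
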