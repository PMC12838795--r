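# Reduce per-transcript annotations to one record per variant-gene pair and
# decide damaging-missense / pLoF / rare status.

plof_consequences <- c("frameshift_variant", "start_lost", "stop_lost",
                       "stop_gained", "splice_donor_variant",
                       "splice_acceptor_variant")

#' Consequence severity order
#'
#' The Ensembl consequence ranking (most to least severe) used to pick among
#' transcript annotations and to reduce compound consequence strings. Shipped
#' as data (a TSV under `extdata`) so it can be replaced without touching
#' code.
#'
#' @param path Optional path to a two-column TSV (`rank`, `consequence`)
#'   overriding the packaged default.
#' @return Character vector of Sequence Ontology terms, most severe first.
#' @export
severity_order <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "consequence_severity_order.tsv",
                        package = "rvpathrx")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$consequence[order(df$rank)]
}

#' Most severe component of a consequence string
#'
#' @param consequence Character vector of '&'-joined SO terms.
#' @param severity Severity order from [severity_order()].
#' @return Character vector of single SO terms.
#' @export
most_severe_consequence <- function(consequence, severity = severity_order()) {
  vapply(strsplit(consequence, "&", fixed = TRUE), function(terms) {
    r <- match(terms, severity)
    r[is.na(r)] <- length(severity) + 1L
    terms[which.min(r)]
  }, character(1))
}

# lexicographic severity key: component ranks sorted ascending, zero-padded,
# shorter keys padded with '999' so that, at equal leading components, a
# record with additional consequence components outranks the plain one
# ("missense_variant&splice_region_variant" beats "missense_variant")
severity_key <- function(consequence, severity) {
  ranks <- lapply(strsplit(consequence, "&", fixed = TRUE), function(terms) {
    r <- match(terms, severity)
    r[is.na(r)] <- length(severity) + 1L
    sort(r)
  })
  width <- max(lengths(ranks))
  vapply(ranks, function(r)
    paste(sprintf("%03d", c(r, rep(999L, width - length(r)))),
          collapse = ""), character(1))
}

#' Pick one annotation record per variant-gene pair
#'
#' Canonical-transcript records are preferred; among those, the record whose
#' most severe consequence component ranks highest wins, with further
#' consequence components breaking ties (a compound consequence outranks its
#' plain counterpart); remaining ties break deterministically by transcript
#' id (lexicographic).
#'
#' @param records `data.frame` of annotation rows sharing one variant key and
#'   gene (see [read_annotations()]).
#' @param severity Severity order from [severity_order()].
#' @return The single selected row.
#' @export
pick_annotation <- function(records, severity = severity_order()) {
  stopifnot(nrow(records) >= 1)
  if (nrow(records) == 1) return(records)
  canon <- records$canonical
  if (any(canon)) records <- records[canon, , drop = FALSE]
  key <- severity_key(records$consequence, severity)
  ord <- order(key, records$transcript)
  records[ord[1], , drop = FALSE]
}

#' Consensus missense deleteriousness score
#'
#' Mean of whichever of the two ensemble scores are present, so that a
#' variant scored by a single tool is still judged; `NA` when both are
#' missing.
#'
#' @param revel,metarnn Numeric vectors in `[0,1]`, `NA` = absent.
#' @return Numeric vector of consensus scores.
#' @export
consensus_missense_score <- function(revel, metarnn) {
  out <- rowMeans(cbind(revel, metarnn), na.rm = TRUE)
  out[is.na(revel) & is.na(metarnn)] <- NA_real_
  out
}

#' Rarity decision from gnomAD allele frequencies
#'
#' A variant is rare when its gnomAD frequency is below 0.05. With two
#' gnomAD resources (exomes and genomes) the default `"max"` rule takes the
#' larger of the available frequencies (a variant common in either resource
#' is not rare); `"min"` implements the permissive reading. Variants absent
#' from both resources are treated as novel (AF 0, hence rare). The cutoff
#' is a strict `<`.
#'
#' @param af_exomes,af_genomes Numeric vectors in `[0,1]`, `NA` = absent.
#' @param threshold Rarity cutoff (default 0.05).
#' @param rule `"max"` (default) or `"min"` aggregation over the available
#'   frequencies.
#' @return List with logical `is_rare` and numeric `max_gnomad_af` (the
#'   aggregated frequency actually compared).
#' @export
is_rare <- function(af_exomes, af_genomes, threshold = 0.05,
                    rule = c("max", "min")) {
  rule <- match.arg(rule)
  m <- cbind(ifelse(is.na(af_exomes), NA, af_exomes),
             ifelse(is.na(af_genomes), NA, af_genomes))
  agg <- apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) 0 else if (rule == "max") max(x) else min(x)
  })
  list(is_rare = agg < threshold, max_gnomad_af = agg)
}

classify_one <- function(ann, severity) {
  picked <- most_severe_consequence(ann$consequence, severity)
  score <- consensus_missense_score(ann$revel, ann$metarnn)
  plof <- !is.na(ann$loftee) & ann$loftee == "HC" &
    picked %in% plof_consequences
  dmg_mis <- picked == "missense_variant" & !is.na(score) & score > 0.5
  damage_class <- ifelse(plof, "plof",
                         ifelse(dmg_mis, "damaging_missense", "none"))
  list(consequence_picked = picked, consensus_score = score,
       damage_class = damage_class)
}

#' Classify annotated variants
#'
#' Reduces the annotation table to one row per variant-gene pair
#' ([pick_annotation()]) and assigns each pair a damage class and a rarity
#' flag. A picked record is `plof` when LOFTEE calls it high-confidence and
#' its most severe consequence is a loss-of-function term (frameshift,
#' start/stop lost, stop gained, essential splice); it is
#' `damaging_missense` when the most severe consequence is
#' `missense_variant` and the consensus score exceeds 0.5 (strict); pLoF
#' takes precedence if both apply. Everything else is `none`.
#'
#' @param ann Annotation `data.frame` from [read_annotations()].
#' @param severity Severity order from [severity_order()].
#' @param rarity_rule `"max"` or `"min"`, see [is_rare()].
#' @param rarity_threshold Rarity cutoff (default 0.05).
#' @return `data.frame` with one row per variant-gene pair: the variant key
#'   columns, `gene`, `consequence_picked`, `consensus_score`,
#'   `damage_class`, `max_gnomad_af`, `is_rare`.
#' @export
classify_variants <- function(ann, severity = severity_order(),
                              rarity_rule = "max", rarity_threshold = 0.05) {
  if (nrow(ann) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      gene = character(), consequence_picked = character(),
                      consensus_score = numeric(), damage_class = character(),
                      max_gnomad_af = numeric(), is_rare = logical()))
  key <- paste(variant_key(ann$chrom, ann$pos, ann$ref, ann$alt), ann$gene,
               sep = "|")
  picked_idx <- vapply(split(seq_len(nrow(ann)), factor(key, unique(key))),
                       function(idx) {
                         sel <- pick_annotation(ann[idx, , drop = FALSE],
                                                severity)
                         idx[match(sel$transcript,
                                   ann$transcript[idx])][1]
                       }, integer(1))
  picked <- ann[picked_idx, , drop = FALSE]
  cls <- classify_one(picked, severity)
  rar <- is_rare(picked$af_gnomad_exomes, picked$af_gnomad_genomes,
                 threshold = rarity_threshold, rule = rarity_rule)
  out <- data.frame(chrom = picked$chrom, pos = picked$pos,
                    ref = picked$ref, alt = picked$alt, gene = picked$gene,
                    consequence_picked = cls$consequence_picked,
                    consensus_score = cls$consensus_score,
                    damage_class = cls$damage_class,
                    max_gnomad_af = rar$max_gnomad_af,
                    is_rare = rar$is_rare,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Restrict classified variants to the carried rare damaging set
#'
#' Keeps variant-gene pairs that are damaging (`damage_class != "none"`),
#' rare, and carried by at least one individual (a non-missing het or
#' hom-alt genotype) in the QC'd cohort. Classified variants absent from the
#' cohort matrix are dropped.
#'
#' @param classified Output of [classify_variants()].
#' @param cv QC'd biallelic [cohort_variants()] object.
#' @return Subset of `classified` rows, with a `cv_row` column giving the
#'   matching row in `cv`.
#' @export
build_rare_damaging_set <- function(classified, cv) {
  if (nrow(classified) == 0) {
    classified$cv_row <- integer(0)
    return(classified)
  }
  keys <- variant_key(classified$chrom, classified$pos, classified$ref,
                      classified$alt)
  cv_row <- match(keys, cv_keys(cv))
  dos <- as_dosage(cv)
  carried <- !is.na(cv_row) &
    vapply(cv_row, function(r) {
      if (is.na(r)) return(FALSE)
      any(dos[r, ] >= 1, na.rm = TRUE)
    }, logical(1))
  keep <- classified$damage_class != "none" & classified$is_rare & carried
  out <- classified[keep, , drop = FALSE]
  out$cv_row <- cv_row[keep]
  rownames(out) <- NULL
  out
}
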