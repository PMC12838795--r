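# Readers/writers for the external formats the pipeline touches:
# VCF (via vcfR), GMT gene sets, TSV phenotype/annotation/result tables.

#' Construct a CohortVariants object
#'
#' Container for per-variant, per-sample genotype calls. Genotypes are stored
#' as normalized unphased allele strings (`"0/1"`; `NA` = missing call), read
#' depth and genotype quality as integer matrices, and allelic depths as raw
#' comma-separated strings so that multiallelic records survive until
#' [split_and_trim_alleles()] is applied.
#'
#' @param samples Character vector of sample ids (column order is preserved
#'   everywhere).
#' @param variants `data.frame` with columns `chrom`, `pos` (1-based integer),
#'   `id`, `ref`, `alt` (`alt` may be a comma-separated multiallelic string
#'   before normalization).
#' @param gt Character matrix (variants x samples) of normalized genotype
#'   strings; `NA` means missing.
#' @param dp,gq Integer matrices (variants x samples); `NA` where the field
#'   was absent.
#' @param ad Character matrix of comma-separated allelic depths (ref first);
#'   `NA` where absent.
#' @return An object of class `CohortVariants`.
#' @export
cohort_variants <- function(samples, variants, gt, dp = NULL, gq = NULL,
                            ad = NULL) {
  n_var <- nrow(variants)
  n_smp <- length(samples)
  blank_int <- function(x) {
    if (is.null(x)) x <- matrix(NA_integer_, n_var, n_smp)
    storage.mode(x) <- "integer"
    x
  }
  if (is.null(ad)) ad <- matrix(NA_character_, n_var, n_smp)
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)))
  if (n_var > 0) {
    if (any(variants$pos < 1)) stop("variant positions must be >= 1")
    if (any(variants$ref == variants$alt)) stop("ref and alt must differ")
  }
  gt <- as.matrix(gt)
  if (!all(dim(gt) == c(n_var, n_smp)))
    stop("genotype matrix dimensions must be n_variants x n_samples")
  obj <- list(samples = as.character(samples),
              variants = variants[, c("chrom", "pos", "id", "ref", "alt")],
              gt = gt, dp = blank_int(dp), gq = blank_int(gq),
              ad = as.matrix(ad))
  rownames(obj$variants) <- NULL
  for (f in c("gt", "dp", "gq", "ad")) dimnames(obj[[f]]) <- NULL
  class(obj) <- "CohortVariants"
  obj
}

#' @export
print.CohortVariants <- function(x, ...) {
  cat("CohortVariants:", nrow(x$variants), "variants x",
      length(x$samples), "samples\n")
  invisible(x)
}

n_variants <- function(cv) nrow(cv$variants)

#' Variant identity key
#'
#' The canonical identity of a (normalized, biallelic) variant is the string
#' `chrom:pos:ref:alt`; annotation records and genotype records are joined on
#' this key.
#'
#' @param chrom,pos,ref,alt Vectors of equal length.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

cv_keys <- function(cv) {
  variant_key(cv$variants$chrom, cv$variants$pos,
              cv$variants$ref, cv$variants$alt)
}

# "0|1" -> "0/1" with alleles sorted; any '.' allele -> NA (call is missing)
normalize_gt <- function(g) {
  g <- gsub("|", "/", g, fixed = TRUE)
  parts <- strsplit(g, "/", fixed = TRUE)
  vapply(seq_along(g), function(i) {
    p <- parts[[i]]
    if (is.na(g[i]) || any(p == ".") || length(p) != 2) return(NA_character_)
    p <- sort(as.integer(p))
    paste(p, collapse = "/")
  }, character(1))
}

#' Classify a biallelic genotype string
#'
#' @param gt Character vector of normalized genotype strings (`"0/0"`,
#'   `"0/1"`, `"1/1"`, `NA`).
#' @return Factor-free character vector in
#'   `c("hom_ref", "het", "hom_alt", "missing")`.
#' @export
gt_class <- function(gt) {
  out <- rep("missing", length(gt))
  out[!is.na(gt) & gt == "0/0"] <- "hom_ref"
  out[!is.na(gt) & gt == "0/1"] <- "het"
  out[!is.na(gt) & gt == "1/1"] <- "hom_alt"
  out
}

#' Dosage matrix of a biallelic cohort
#'
#' @param cv A biallelic [cohort_variants()] object.
#' @return Integer matrix (variants x samples) of alt-allele counts 0/1/2,
#'   `NA` for missing calls.
#' @export
as_dosage <- function(cv) {
  if (n_variants(cv) > 0 && any(grepl(",", cv$variants$alt, fixed = TRUE)))
    stop("dosage requires biallelic records; run split_and_trim_alleles()")
  d <- matrix(NA_integer_, n_variants(cv), length(cv$samples))
  d[!is.na(cv$gt) & cv$gt == "0/0"] <- 0L
  d[!is.na(cv$gt) & cv$gt == "0/1"] <- 1L
  d[!is.na(cv$gt) & cv$gt == "1/1"] <- 2L
  d
}

#' Read a cohort VCF
#'
#' Supports the VCF v4.2 subset the pipeline uses: one record per line with
#' FORMAT containing at least `GT`, and optionally `DP`, `GQ` and `AD`.
#' Multiallelic ALT strings are kept intact; [split_and_trim_alleles()]
#' normalizes them downstream. Sample order is preserved.
#'
#' @param path Path to an uncompressed or gzipped VCF.
#' @return A [cohort_variants()] object.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  hdr_idx <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_idx) != 1)
    stop("malformed VCF header: expected exactly one #CHROM line")
  n_cols <- length(strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]])
  if (n_cols < 10) stop("VCF has no sample columns")
  for (i in body_idx) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != n_cols)
      stop(sprintf("ragged VCF record at line %d: %d fields, expected %d",
                   i, nf, n_cols))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = ifelse(is.na(fix$ID), ".", fix$ID),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  grab <- function(el, fun = identity) {
    m <- tryCatch(vcfR::extract.gt(v, element = el),
                  error = function(e) NULL)
    if (is.null(m)) m <- matrix(NA_character_, nrow(variants), length(samples))
    fun(m)
  }
  gt <- grab("GT")
  gt <- matrix(normalize_gt(as.vector(gt)), nrow(variants), length(samples))
  dp <- grab("DP", function(m) {
    m <- suppressWarnings(matrix(as.integer(m), nrow(m), ncol(m))); m
  })
  gq <- grab("GQ", function(m) {
    m <- suppressWarnings(matrix(as.integer(m), nrow(m), ncol(m))); m
  })
  ad <- grab("AD")
  sex_chrom <- grepl("^(chr)?[XY]$", variants$chrom)
  if (any(sex_chrom))
    message(sum(sex_chrom), " X/Y record(s) present; genotypes on sex ",
            "chromosomes are treated autosomally (no hemizygote handling)")
  cohort_variants(samples, variants, gt, dp, gq, ad)
}

#' Write a cohort VCF
#'
#' Emits a minimal VCF v4.2 with `GT:DP:GQ:AD` FORMAT; absent sub-fields are
#' written as `.`. [read_vcf()] on the output reproduces every modeled field.
#'
#' @param cv A [cohort_variants()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cv, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", cv$samples), collapse = "\t"))
  n <- n_variants(cv)
  body <- character(n)
  dot <- function(x) ifelse(is.na(x), ".", as.character(x))
  gt_out <- ifelse(is.na(cv$gt), "./.", cv$gt)
  for (i in seq_len(n)) {
    cells <- paste(gt_out[i, ], dot(cv$dp[i, ]), dot(cv$gq[i, ]),
                   dot(cv$ad[i, ]), sep = ":")
    body[i] <- paste(c(cv$variants$chrom[i], cv$variants$pos[i],
                       cv$variants$id[i], cv$variants$ref[i],
                       cv$variants$alt[i], ".", "PASS", ".",
                       "GT:DP:GQ:AD", cells), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One pathway per line: `name TAB description TAB gene1 TAB gene2 ...`.
#' Duplicate genes within a line are collapsed; the gene universe defaults to
#' the union of all pathway genes.
#'
#' @param path Path to a GMT file.
#' @param universe Optional character vector overriding the default universe.
#' @return A list with elements `pathways` (named list of character vectors)
#'   and `universe` (character vector), of class `PathwayDB`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no pathways in GMT file: ", path)
  pathways <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d fields; need name, description and >=1 gene",
                   i, length(f)))
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0)
      stop(sprintf("GMT line %d (%s) has no genes", i, f[1]))
    pathways[[f[1]]] <- genes
  }
  pathway_db(pathways, universe)
}

#' Construct a PathwayDB
#'
#' @param pathways Named list of character gene vectors.
#' @param universe Optional gene universe; defaults to the union of all
#'   pathway genes. Every pathway gene must belong to the universe.
#' @return A `PathwayDB` object.
#' @export
pathway_db <- function(pathways, universe = NULL) {
  stopifnot(length(pathways) > 0, !is.null(names(pathways)))
  if (is.null(universe)) universe <- sort(unique(unlist(pathways)))
  missing <- setdiff(unlist(pathways), universe)
  if (length(missing) > 0)
    stop("pathway genes outside the universe: ",
         paste(utils::head(missing, 5), collapse = ", "))
  db <- list(pathways = pathways, universe = universe)
  class(db) <- "PathwayDB"
  db
}

#' @export
print.PathwayDB <- function(x, ...) {
  cat("PathwayDB:", length(x$pathways), "pathways,",
      length(x$universe), "genes in universe\n")
  invisible(x)
}

#' Write a PathwayDB as GMT
#'
#' @param db A `PathwayDB`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db$pathways), function(nm) {
    paste(c(nm, "na", db$pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read the phenotype/covariate table
#'
#' TSV with mandatory columns `sample_id`, `group` (`SR`/`OR`), `age`, `sex`
#' (`male`/`female`). Unknown columns are carried through untouched. For
#' modeling, sex is coded 0 = female, 1 = male (see `sex_code` in the result).
#'
#' @param path Path to the TSV.
#' @param samples Optional character vector of VCF sample ids; every
#'   phenotype sample must then be present in it.
#' @return `data.frame` of class `CohortDesign` with a numeric `sex_code`
#'   column appended.
#' @export
read_phenotypes <- function(path, samples = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "group", "age", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("phenotype table missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (!all(df$group %in% c("SR", "OR")))
    stop("group must be 'SR' or 'OR'")
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in phenotype table")
  if (!is.null(samples)) {
    absent <- setdiff(df$sample_id, samples)
    if (length(absent) > 0)
      stop("phenotype sample(s) absent from VCF: ",
           paste(absent, collapse = ", "))
  }
  df$age <- as.numeric(df$age)
  df$sex_code <- ifelse(df$sex == "male", 1, 0)
  class(df) <- c("CohortDesign", "data.frame")
  df
}

#' Read the variant annotation table
#'
#' The contract with the upstream annotator: a TSV holding one row per
#' variant-transcript-gene with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `transcript`, `canonical` (0/1 or TRUE/FALSE), `consequence`
#' ('&'-separated Sequence Ontology terms), `revel`, `metarnn`, `loftee`
#' (`HC`/`LC`/`.`), `af_gnomad_exomes`, `af_gnomad_genomes`. Empty cells and
#' `.` mean "absent". Unknown columns are ignored.
#'
#' @param path Path to the TSV.
#' @return `data.frame` of annotation records.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("", ".", "NA"))
  need <- c("chrom", "pos", "ref", "alt", "gene", "transcript", "canonical",
            "consequence", "revel", "metarnn", "loftee",
            "af_gnomad_exomes", "af_gnomad_genomes")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("annotation table missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  df <- df[, need]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$canonical <- as.logical(as.integer(as.logical(df$canonical)))
  for (col in c("revel", "metarnn", "af_gnomad_exomes", "af_gnomad_genomes")) {
    df[[col]] <- as.numeric(df[[col]])
    bad <- !is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1)
    if (any(bad)) stop("column ", col, " outside [0,1]")
  }
  if (any(is.na(df$consequence)) || any(!nzchar(df$consequence)))
    stop("empty consequence field in annotation table")
  if (any(!is.na(df$loftee) & !df$loftee %in% c("HC", "LC")))
    stop("loftee must be HC, LC or absent")
  df
}

#' Write a results table as TSV
#'
#' Absent values are written as `.` (never the empty string); a `#`-prefixed
#' header comment records run parameters so outputs are self-describing.
#'
#' @param df `data.frame` of results.
#' @param path Output path.
#' @param params Optional named list recorded in the header comment
#'   (e.g. seed, thresholds).
#' @return `path`, invisibly.
#' @export
write_results <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(params) > 0) {
    writeLines(paste0("# ", names(params), "=",
                      vapply(params, function(p)
                        paste(format(p, digits = 17), collapse = ","),
                        character(1))), con)
  }
  out <- df
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.numeric(col)) col <- format(col, digits = 17, trim = TRUE)
    col[is.na(out[[j]])] <- "."
    out[[j]] <- col
  }
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0)
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return `data.frame` with `.` cells restored to `NA` and numeric columns
#'   re-typed.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c(".", "NA"))
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      if (all(is.na(col) == is.na(num))) df[[j]] <- num
    }
  }
  df
}
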