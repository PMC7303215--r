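# Data model and readers/writers for genotype, annotation, clinical and
# summary-statistic tables.

#' Construct a genotype matrix
#'
#' Wraps an integer matrix of alternative-allele counts (0/1/2, `NA` for
#' missing calls; subjects in rows, variants in columns) together with its
#' variant metadata.
#'
#' @param calls Integer matrix with subject row names and variant-id column
#'   names.
#' @param variant_info Tibble with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, aligned with the columns of `calls`.
#' @return A `geno_matrix`.
#' @export
new_geno_matrix <- function(calls, variant_info) {
  stopifnot(is.matrix(calls))
  storage.mode(calls) <- "integer"
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) {
    abort("genotype calls must be 0, 1, 2 or NA")
  }
  if (anyDuplicated(colnames(calls))) abort("variant ids must be unique")
  if (anyDuplicated(rownames(calls))) abort("subject ids must be unique")
  if (!identical(colnames(calls), variant_info$variant_id)) {
    abort("variant_info rows must match genotype columns")
  }
  structure(calls, variant_info = variant_info,
            class = c("geno_matrix", "matrix", "array"))
}

#' Variant metadata of a genotype matrix
#'
#' @param geno A genotype matrix as returned by [read_vcf()].
#' @return A tibble with columns `variant_id`, `chrom`, `pos`, `ref`, `alt`.
#' @export
variant_info <- function(geno) {
  attr(geno, "variant_info")
}

# `[` would drop attributes; keep variant_info in sync on column subsets.
#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = TRUE) {
  vi <- attr(x, "variant_info")
  out <- NextMethod()
  if (is.matrix(out)) {
    vi <- vi[match(colnames(out), vi$variant_id), , drop = FALSE]
    out <- structure(out, variant_info = vi,
                     class = c("geno_matrix", "matrix", "array"))
  }
  out
}

gt_to_dose <- function(gt) {
  # "0/1", "0|1", ".", "./." -> alt-allele count; any "." allele -> NA
  alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
  vapply(alleles, function(a) {
    if (any(a == "." | is.na(a))) return(NA_integer_)
    sum(as.integer(a))
  }, integer(1))
}

#' Read genotypes from a VCF file
#'
#' Reads a VCF (optionally gzipped) and returns a subject-by-variant matrix
#' of alternative-allele counts. Only the GT field is used. Variant keys are
#' `chrom:pos:ref:alt` with 1-based VCF positions. Missing genotypes become
#' `NA` and are excluded from every downstream allele or genotype count.
#'
#' @param path Path to a VCF 4.x file.
#' @param multiallelic `"reject"` (default) errors on multiallelic records;
#'   `"split"` decomposes them into biallelic records, one per alternative
#'   allele.
#' @return A genotype matrix (integer, subjects in rows) carrying a
#'   `variant_info` attribute; see [variant_info()].
#' @export
read_vcf <- function(path, multiallelic = c("reject", "split")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("malformed VCF '", path, "': ",
                                     conditionMessage(e)))
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no variant records")
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_raw)) abort("VCF has no GT field")
  subjects <- colnames(gt_raw)

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1 && multiallelic == "reject") {
      abort(paste0("multiallelic record at ", fix$CHROM[i], ":", fix$POS[i],
                   " (use multiallelic = \"split\")"))
    }
    gt <- gsub("\\|", "/", gt_raw[i, ])
    allele_lists <- strsplit(gt, "/", fixed = FALSE)
    for (k in seq_along(alts)) {
      dose <- vapply(allele_lists, function(a) {
        if (length(a) == 0 || any(a == "." | is.na(a))) return(NA_integer_)
        sum(a == as.character(k))
      }, integer(1))
      rows[[length(rows) + 1]] <- list(
        variant_id = paste(fix$CHROM[i], fix$POS[i], fix$REF[i], alts[k],
                           sep = ":"),
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], dose = dose)
    }
  }
  calls <- vapply(rows, `[[`, integer(length(subjects)), "dose")
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = length(subjects))
  rownames(calls) <- subjects
  colnames(calls) <- vapply(rows, `[[`, character(1), "variant_id")
  vi <- tibble::tibble(
    variant_id = colnames(calls),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    pos = vapply(rows, `[[`, integer(1), "pos"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"))
  new_geno_matrix(calls, vi)
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF 4.2 file with a GT-only FORMAT, the inverse of
#' [read_vcf()] for biallelic data.
#'
#' @param geno Genotype matrix with `variant_info` attribute.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  vi <- variant_info(geno)
  gt_chr <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(nrow(vi)), function(j) {
    g <- geno[, j]
    gt <- ifelse(is.na(g), "./.", gt_chr[as.character(g)])
    paste(c(vi$chrom[j], vi$pos[j], ".", vi$ref[j], vi$alt[j], ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a per-variant annotation table
#'
#' Expects a TSV (optionally gzipped) with header columns `variant_id`,
#' `gene`, `consequence`, `sift`, `cadd`, `ref_panel_af` and optionally
#' `chrom`, `pos`. Unknown consequence strings are mapped to `"other"` with
#' a warning; empty score cells stay `NA` (absent, never zero).
#'
#' @param path Path to the TSV file.
#' @return A tibble, one row per variant.
#' @export
read_annotation_table <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    variant_id = readr::col_character(),
    gene = readr::col_character(),
    consequence = readr::col_character(),
    sift = readr::col_character(),
    cadd = readr::col_character(),
    ref_panel_af = readr::col_character(),
    .default = readr::col_guess()), progress = FALSE)
  if (anyDuplicated(ann$variant_id)) {
    abort(paste0("duplicate variant_id in ", path, ": ",
                 ann$variant_id[duplicated(ann$variant_id)][1]))
  }
  num_col <- function(x, name) {
    x[x %in% c("", "NA", ".")] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      abort(paste0("non-numeric ", name, " at row ", bad[1], ": '",
                   x[bad[1]], "'"))
    }
    out
  }
  ann$sift <- num_col(ann$sift, "sift")
  ann$cadd <- num_col(ann$cadd, "cadd")
  ann$ref_panel_af <- num_col(ann$ref_panel_af, "ref_panel_af")
  if (any(ann$sift < 0 | ann$sift > 1, na.rm = TRUE)) {
    abort("sift scores must lie in [0, 1]")
  }
  if (any(ann$ref_panel_af < 0 | ann$ref_panel_af > 1, na.rm = TRUE)) {
    abort("ref_panel_af must lie in [0, 1]")
  }
  unknown <- !ann$consequence %in% consequence_vocab()
  if (any(unknown)) {
    warn(paste0(sum(unknown), " unknown consequence value(s) mapped to ",
                "'other' (e.g. '", ann$consequence[unknown][1], "')"))
    ann$consequence[unknown] <- "other"
  }
  ann
}

#' Read a per-subject clinical table
#'
#' TSV with a `subject_id` column plus any of: `sex`, `hamd`, `hads_anx`,
#' `bprs_suicide`, `suicide_attempt`, `family_history`, `recurrent`,
#' `age_onset`, `age`, `education_years`, `unemployed`, `diagnosis_mdd`.
#' Binary fields accept TRUE/FALSE or 0/1.
#'
#' @param path Path to the TSV file.
#' @return A tibble, one row per subject.
#' @export
read_clinical_table <- function(path) {
  cl <- readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(), .default = readr::col_guess()),
    progress = FALSE)
  if (anyDuplicated(cl$subject_id)) abort("duplicate subject_id")
  for (col in c("suicide_attempt", "family_history", "recurrent",
                "unemployed", "diagnosis_mdd")) {
    if (col %in% names(cl)) cl[[col]] <- as.logical(cl[[col]])
  }
  if ("bprs_suicide" %in% names(cl) &&
      any(!is.na(cl$bprs_suicide) &
          (cl$bprs_suicide < 1 | cl$bprs_suicide > 7))) {
    abort("bprs_suicide must lie in 1..7")
  }
  if ("age_onset" %in% names(cl) && any(cl$age_onset < 0, na.rm = TRUE)) {
    abort("age_onset must be non-negative")
  }
  cl
}

#' Read a GWAS summary-statistics table
#'
#' TSV with columns `variant_id`, `effect_allele`, `beta`, `p`.
#'
#' @param path Path to the TSV file.
#' @return A tibble, one row per variant.
#' @export
read_summary_stats <- function(path) {
  ss <- readr::read_tsv(path, col_types = readr::cols(
    variant_id = readr::col_character(),
    effect_allele = readr::col_character(),
    beta = readr::col_double(),
    p = readr::col_double()), progress = FALSE)
  if (any(ss$p <= 0 | ss$p > 1, na.rm = TRUE)) {
    abort("summary-statistic p-values must lie in (0, 1]")
  }
  ss
}

#' Assemble a cohort bundle
#'
#' Inner-joins genotypes, sex labels, annotations and (optionally) clinical
#' records on `subject_id` / `variant_id`, reporting how many rows each side
#' loses.
#'
#' @param genotypes Genotype matrix from [read_vcf()] or the simulator.
#' @param sex_labels Tibble with columns `subject_id` and `sex`
#'   (`"female"`/`"male"`).
#' @param annotations Annotation tibble from [read_annotation_table()].
#' @param clinical Optional clinical tibble from [read_clinical_table()].
#' @param cohort Cohort tag, e.g. `"case"`, `"control_a"`.
#' @return A `wes_cohort` object: list with elements `genotypes`, `sex`,
#'   `annotations`, `clinical`, `cohort`.
#' @export
assemble_cohort <- function(genotypes, sex_labels, annotations,
                            clinical = NULL, cohort = "case") {
  if (!all(c("subject_id", "sex") %in% names(sex_labels))) {
    abort("sex_labels needs columns subject_id and sex")
  }
  if (any(is.na(sex_labels$sex))) abort("subject with missing sex label")
  if (!all(sex_labels$sex %in% c("female", "male"))) {
    abort("sex must be 'female' or 'male'")
  }
  subjects <- intersect(rownames(genotypes), sex_labels$subject_id)
  if (length(subjects) == 0) abort("no subjects shared between genotypes and sex labels")
  variants <- intersect(colnames(genotypes), annotations$variant_id)
  if (length(variants) == 0) abort("no variants shared between genotypes and annotations")

  d_geno <- nrow(genotypes) - length(subjects)
  d_sex <- nrow(sex_labels) - length(subjects)
  d_var <- ncol(genotypes) - length(variants)
  d_ann <- nrow(annotations) - length(variants)
  if (d_geno + d_sex + d_var + d_ann > 0) {
    inform(paste0("assemble_cohort: dropped ", d_geno,
                  " genotyped subject(s), ", d_sex, " sex label(s), ",
                  d_var, " genotyped variant(s), ", d_ann,
                  " annotation row(s) outside the intersection"))
  }
  geno <- genotypes[subjects, variants, drop = FALSE]
  sex <- sex_labels[match(subjects, sex_labels$subject_id), c("subject_id", "sex")]
  ann <- annotations[match(variants, annotations$variant_id), , drop = FALSE]
  if (!is.null(clinical)) {
    clinical <- clinical[clinical$subject_id %in% subjects, , drop = FALSE]
  }
  structure(list(genotypes = geno, sex = sex, annotations = ann,
                 clinical = clinical, cohort = cohort),
            class = "wes_cohort")
}

#' @export
print.wes_cohort <- function(x, ...) {
  cat("<wes_cohort '", x$cohort, "'> ", nrow(x$genotypes), " subjects (",
      sum(x$sex$sex == "female"), " female), ", ncol(x$genotypes),
      " variants\n", sep = "")
  invisible(x)
}
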