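# Seeded generator for synthetic study cohorts with the statistical
# structure the analyses assume: Hardy-Weinberg background variants,
# planted sex-differential variants, LD blocks, a planted male excess of
# deleterious protein-truncating variants, and clinical scores shifted in
# homozygous carriers.

#' Simulation configuration
#'
#' Default sizes mirror the study design the package targets: a case cohort
#' of 707 women and 293 men and two control cohorts of 72 (26.4% female)
#' and 207 (50.7% female) subjects. The default planted variant has female
#' and male alternative-allele frequencies 0.085 and 0.034 (a ~2.5x female
#' excess at the scale of the strongest single-variant signal such a screen
#' can detect at these sample sizes); the deleterious-PTV burden excess is a
#' 1.5x male allele-frequency multiplier over 30 protein-truncating
#' variants. Clinical shifts in homozygous carriers default to +2.7 HAMD
#' points and an odds multiplier of 3.2 on moderate-or-worse suicidality
#' (BPRS suicide item >= 4).
#'
#' @param n_case_female,n_case_male Case cohort sizes per sex.
#' @param control_a,control_b Named vectors `c(female=, male=)` giving the
#'   two control cohort compositions.
#' @param n_background Number of background variants (equal sex allele
#'   frequencies, drawn uniformly in `[0.01, 0.3]`).
#' @param planted_sexdiff Data frame with columns `female_af`, `male_af`:
#'   variants planted with sex-specific allele frequencies in cases only.
#' @param planted_in_controls If `TRUE` the sex-differential frequencies are
#'   planted in the control cohorts too (used to exercise the screen's
#'   control-replication filter).
#' @param n_burden_ptv,ptv_base_af,burden_excess Deleterious-PTV burden set:
#'   number of variants, female allele frequency, male multiplier (cases
#'   only; controls stay at the base frequency in both sexes).
#' @param ld_blocks List of blocks, each `list(chrom=, start_pos=,
#'   hap_freqs=)` with `hap_freqs` a named vector over 0/1 allele strings
#'   summing to 1. The defaults include a fully linked pair (D' = 1) and a
#'   five-locus block whose all-alternative haplotype has frequency 0.18, so
#'   roughly `0.18^2 * n` case subjects are homozygous carriers.
#' @param clinical_effect List with `hamd_shift` (additive HAMD points) and
#'   `bprs4_or` (odds multiplier for BPRS suicide >= 4) in subjects
#'   homozygous for any planted sex-differential variant.
#' @param missing_rate Per-call probability of a missing genotype.
#' @param candidate_gene_frac Fraction of genes put in the synthetic
#'   candidate-gene list (stand-in for a curated disease gene set).
#' @param seed RNG seed; every stochastic draw in [simulate_cohort()] flows
#'   from it.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_case_female = 707, n_case_male = 293,
                       control_a = c(female = 19, male = 53),
                       control_b = c(female = 105, male = 102),
                       n_background = 80,
                       planted_sexdiff = data.frame(female_af = 0.085,
                                                    male_af = 0.034),
                       planted_in_controls = FALSE,
                       n_burden_ptv = 30, ptv_base_af = 0.01,
                       burden_excess = 1.5,
                       ld_blocks = list(
                         list(chrom = "19", start_pos = 1100000L,
                              hap_freqs = c("11" = 0.05, "00" = 0.95)),
                         list(chrom = "17", start_pos = 2500000L,
                              hap_freqs = c("11111" = 0.18, "00000" = 0.77,
                                            "10000" = 0.05))),
                       clinical_effect = list(hamd_shift = 2.7,
                                              bprs4_or = 3.2),
                       missing_rate = 0,
                       candidate_gene_frac = 0.5,
                       seed = 1L) {
  cfg <- list(n_case_female = n_case_female, n_case_male = n_case_male,
              control_a = control_a, control_b = control_b,
              n_background = n_background,
              planted_sexdiff = planted_sexdiff,
              planted_in_controls = planted_in_controls,
              n_burden_ptv = n_burden_ptv, ptv_base_af = ptv_base_af,
              burden_excess = burden_excess, ld_blocks = ld_blocks,
              clinical_effect = clinical_effect,
              missing_rate = missing_rate,
              candidate_gene_frac = candidate_gene_frac,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  sizes <- c(cfg$n_case_female, cfg$n_case_male, cfg$control_a, cfg$control_b)
  if (any(sizes <= 0)) abort("cohort sizes must be positive")
  afs <- c(cfg$planted_sexdiff$female_af, cfg$planted_sexdiff$male_af,
           cfg$ptv_base_af, cfg$ptv_base_af * cfg$burden_excess)
  if (any(afs < 0 | afs > 1)) {
    abort("configured allele frequencies (after multipliers) must lie in [0, 1]")
  }
  for (b in cfg$ld_blocks) {
    f <- b$hap_freqs
    if (abs(sum(f) - 1) > 1e-8) abort("haplotype frequencies in a block must sum to 1")
    if (length(unique(nchar(names(f)))) != 1) {
      abort("haplotypes in a block must have equal length")
    }
  }
  invisible(cfg)
}

# Variant panel shared by all cohorts -----------------------------------

build_variant_panel <- function(cfg) {
  vocab_bg <- c(missense = 0.30, synonymous = 0.30, splice_region = 0.08,
                inframe_indel = 0.05, splice_site = 0.05, frameshift = 0.05,
                stop_gain = 0.05, stop_lost = 0.02, stop_retained = 0.02,
                start_lost = 0.03, other = 0.05)
  n_bg <- cfg$n_background
  bg <- tibble::tibble(
    tag = "background",
    chrom = as.character(sample(1:12, n_bg, replace = TRUE)),
    consequence = sample(names(vocab_bg), n_bg, TRUE, prob = vocab_bg),
    sift = ifelse(runif(n_bg) < 0.2, NA_real_, round(runif(n_bg), 3)),
    cadd = ifelse(runif(n_bg) < 0.1, NA_real_,
                  round(ifelse(runif(n_bg) < 0.35, runif(n_bg, 15, 40),
                               runif(n_bg, 0, 15)), 2)),
    ref_panel_af = ifelse(runif(n_bg) < 0.25,
                          ifelse(runif(n_bg) < 0.5, NA_real_,
                                 signif(runif(n_bg, 0, 0.0009), 3)),
                          signif(runif(n_bg, 0.01, 0.4), 3)),
    female_af = runif(n_bg, 0.01, 0.3))
  bg$male_af <- bg$female_af

  # eight crafted variants guaranteeing that no category combination is
  # empty: (rare, common) x (missense, stop_gain) x (deleterious, benign)
  grid <- expand.grid(rare = c(TRUE, FALSE),
                      cons = c("missense", "stop_gain"),
                      del = c(TRUE, FALSE), stringsAsFactors = FALSE)
  cov <- tibble::tibble(
    tag = "coverage",
    chrom = "13",
    consequence = grid$cons,
    sift = ifelse(grid$del, 0.01, 0.5),
    cadd = ifelse(grid$del, 25, 5),
    ref_panel_af = ifelse(grid$rare, 0.0005, 0.05),
    female_af = 0.05, male_af = 0.05)

  pl <- cfg$planted_sexdiff
  planted <- tibble::tibble(
    tag = "planted",
    chrom = "20",
    consequence = "missense",
    sift = 0.02, cadd = 22,
    ref_panel_af = NA_real_,
    female_af = pl$female_af, male_af = pl$male_af)

  n_ptv <- cfg$n_burden_ptv
  ptv <- tibble::tibble(
    tag = "burden_ptv",
    chrom = as.character(sample(14:16, n_ptv, replace = TRUE)),
    consequence = sample(ptv_consequences(), n_ptv, replace = TRUE),
    sift = NA_real_,
    cadd = round(runif(n_ptv, 16, 35), 2),
    ref_panel_af = ifelse(seq_len(n_ptv) %% 2 == 0, 0.0004, 0.02),
    female_af = cfg$ptv_base_af,
    male_af = cfg$ptv_base_af * cfg$burden_excess)

  blocks <- purrr::imap_dfr(cfg$ld_blocks, function(b, i) {
    L <- nchar(names(b$hap_freqs)[1])
    tibble::tibble(
      tag = paste0("block", i), chrom = b$chrom,
      consequence = "missense", sift = 0.3, cadd = 10,
      ref_panel_af = 0.05,
      female_af = NA_real_, male_af = NA_real_)[rep(1, L), ]
  })

  panel <- dplyr::bind_rows(bg, cov, planted, ptv, blocks)
  panel <- panel |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(pos = 1000000L + 50000L * (seq_len(dplyr::n()) - 1L)) |>
    dplyr::ungroup()
  # block loci sit close together so clumping windows see them jointly
  for (i in seq_along(cfg$ld_blocks)) {
    idx <- which(panel$tag == paste0("block", i))
    panel$pos[idx] <- cfg$ld_blocks[[i]]$start_pos + 2000L * (seq_along(idx) - 1L)
  }
  bases <- c("A", "C", "G", "T")
  panel$ref <- sample(bases, nrow(panel), replace = TRUE)
  panel$alt <- vapply(panel$ref, function(r) sample(setdiff(bases, r), 1),
                      character(1))
  panel$variant_id <- paste(panel$chrom, panel$pos, panel$ref, panel$alt,
                            sep = ":")
  # two variants per gene on average
  panel$gene <- paste0("GENE", sprintf("%04d", ceiling(seq_len(nrow(panel)) / 2)))
  panel
}

sim_genotypes <- function(panel, cfg, n_f, n_m, prefix, planted_sexdiff) {
  n <- n_f + n_m
  sexes <- c(rep("female", n_f), rep("male", n_m))
  m <- matrix(0L, n, nrow(panel))
  is_block <- grepl("^block", panel$tag)
  for (j in which(!is_block)) {
    fa <- panel$female_af[j]
    ma <- panel$male_af[j]
    if (!planted_sexdiff) {
      if (panel$tag[j] == "planted") {
        # sex-neutral stand-in at the pooled frequency
        fa <- ma <- (panel$female_af[j] + panel$male_af[j]) / 2
      } else if (panel$tag[j] == "burden_ptv") {
        fa <- ma <- panel$female_af[j]  # base rate, no male excess
      }
    }
    m[, j] <- c(rbinom(n_f, 2, fa), rbinom(n_m, 2, ma))
  }
  for (i in seq_along(cfg$ld_blocks)) {
    b <- cfg$ld_blocks[[i]]
    idx <- which(panel$tag == paste0("block", i))
    haps <- do.call(rbind, lapply(strsplit(names(b$hap_freqs), ""),
                                  as.integer))
    h1 <- sample(nrow(haps), n, replace = TRUE, prob = b$hap_freqs)
    h2 <- sample(nrow(haps), n, replace = TRUE, prob = b$hap_freqs)
    m[, idx] <- haps[h1, , drop = FALSE] + haps[h2, , drop = FALSE]
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(length(m)) < cfg$missing_rate, nrow(m))
    m[miss] <- NA_integer_
  }
  rownames(m) <- sprintf("%s%04d", prefix, seq_len(n))
  colnames(m) <- panel$variant_id
  vi <- panel[, c("variant_id", "chrom", "pos", "ref", "alt")]
  list(geno = new_geno_matrix(m, vi),
       sex = tibble::tibble(subject_id = rownames(m), sex = sexes))
}

sim_clinical <- function(sex_tbl, hom_carrier, cfg) {
  n <- nrow(sex_tbl)
  is_f <- sex_tbl$sex == "female"
  eff <- cfg$clinical_effect
  base_p4 <- 0.33
  logit <- function(p) log(p / (1 - p))
  p4 <- stats::plogis(logit(base_p4) + log(eff$bprs4_or) * hom_carrier)
  high <- runif(n) < p4
  tibble::tibble(
    subject_id = sex_tbl$subject_id,
    hamd = pmax(0L, as.integer(round(rnorm(n, 20.7, 4.2) +
                                       eff$hamd_shift * hom_carrier))),
    hads_anx = pmax(0L, as.integer(round(rnorm(n, 11.8, 4.0)))),
    bprs_suicide = ifelse(high, sample(4:7, n, TRUE), sample(1:3, n, TRUE)),
    suicide_attempt = runif(n) < 0.086,
    family_history = runif(n) < 0.15,
    recurrent = runif(n) < ifelse(is_f, 0.54, 0.44),
    age_onset = pmax(18, round(rnorm(n, 52, 16))),
    age = pmax(18, round(rnorm(n, 57, 14.5))),
    education_years = pmax(0, round(rnorm(n, ifelse(is_f, 8.3, 11.0),
                                          ifelse(is_f, 4.8, 4.3)))),
    unemployed = runif(n) < ifelse(is_f, 0.242, 0.345))
}

#' Simulate a full synthetic study
#'
#' Draws a case cohort and two control cohorts over a shared variant panel:
#' Hardy-Weinberg background variants with equal sex allele frequencies,
#' planted variants with sex-specific frequencies (cases only, unless
#' configured otherwise), LD-block variants drawn as two haplotypes per
#' subject from the block pool, a deleterious-PTV set with a male
#' allele-frequency excess in cases, and case clinical scores shifted in
#' subjects homozygous for a planted variant. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `wes_sim` with elements `case`, `controls` (list
#'   of two `wes_cohort`s), and `truth` (planted variant ids and
#'   frequencies, block haplotype pools, candidate gene list, homozygous
#'   carrier ids, effect sizes).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  panel <- build_variant_panel(config)

  case <- sim_genotypes(panel, config, config$n_case_female,
                        config$n_case_male, "CASE", planted_sexdiff = TRUE)
  ca <- sim_genotypes(panel, config, config$control_a[["female"]],
                      config$control_a[["male"]], "CTLA",
                      planted_sexdiff = config$planted_in_controls)
  cb <- sim_genotypes(panel, config, config$control_b[["female"]],
                      config$control_b[["male"]], "CTLB",
                      planted_sexdiff = config$planted_in_controls)

  planted_ids <- panel$variant_id[panel$tag == "planted"]
  hom <- rowSums(case$geno[, planted_ids, drop = FALSE] == 2,
                 na.rm = TRUE) > 0
  clinical <- sim_clinical(case$sex, hom, config)

  ann <- panel[, c("variant_id", "gene", "consequence", "sift", "cadd",
                   "ref_panel_af", "chrom", "pos")]
  genes <- unique(ann$gene)
  cand <- sort(sample(genes, ceiling(length(genes) * config$candidate_gene_frac)))

  truth <- list(
    planted = panel[panel$tag == "planted",
                    c("variant_id", "female_af", "male_af")],
    burden_ptv = panel[panel$tag == "burden_ptv",
                       c("variant_id", "female_af", "male_af")],
    blocks = purrr::imap(config$ld_blocks, function(b, i) {
      list(loci = panel$variant_id[panel$tag == paste0("block", i)],
           hap_freqs = b$hap_freqs)
    }),
    candidate_genes = cand,
    hom_carriers = case$sex$subject_id[hom],
    clinical_effect = config$clinical_effect,
    burden_excess = config$burden_excess,
    seed = config$seed)

  structure(list(
    case = assemble_cohort(case$geno, case$sex, ann, clinical, "case"),
    controls = list(
      control_a = assemble_cohort(ca$geno, ca$sex, ann, NULL, "control_a"),
      control_b = assemble_cohort(cb$geno, cb$sex, ann, NULL, "control_b")),
    truth = truth), class = "wes_sim")
}

#' Simulate GWAS summary statistics
#'
#' Draws per-variant effect sizes and p-values as a stand-in for external
#' association weights: `beta ~ Normal(0, beta_sd)` and `p ~ Uniform(0, 1)`,
#' with the alternative allele recorded as the effect allele. Variants named
#' in `planted` get the given beta and p instead, which plants a sex
#' difference in downstream risk scores when those variants have
#' sex-differential frequencies.
#'
#' @param geno Genotype matrix whose variants the table should cover.
#' @param beta_sd Standard deviation of the null effect-size draw.
#' @param planted Optional tibble with columns `variant_id`, `beta`, `p`.
#' @param seed RNG seed.
#' @return Tibble with columns `variant_id`, `effect_allele`, `beta`, `p`.
#' @export
simulate_summary_stats <- function(geno, beta_sd = 0.05, planted = NULL,
                                   seed = 1L) {
  set.seed(seed)
  vi <- variant_info(geno)
  ss <- tibble::tibble(
    variant_id = vi$variant_id,
    effect_allele = vi$alt,
    beta = rnorm(nrow(vi), 0, beta_sd),
    p = runif(nrow(vi)))
  if (!is.null(planted)) {
    idx <- match(planted$variant_id, ss$variant_id)
    if (anyNA(idx)) abort("planted summary-stat variant not in genotypes")
    ss$beta[idx] <- planted$beta
    ss$p[idx] <- planted$p
  }
  ss
}

#' Write a simulated study to disk
#'
#' Emits the fixture files the package readers consume: one VCF per cohort,
#' an annotation TSV, a clinical TSV and (optionally) a summary-statistics
#' TSV.
#'
#' @param sim A `wes_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param summary_stats Optional summary-statistics tibble to write.
#' @return Named list of file paths, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir, summary_stats = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    case_vcf = file.path(dir, "case.vcf"),
    control_a_vcf = file.path(dir, "control_a.vcf"),
    control_b_vcf = file.path(dir, "control_b.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    sex = file.path(dir, "sex_labels.tsv"))
  write_vcf(sim$case$genotypes, paths$case_vcf)
  write_vcf(sim$controls$control_a$genotypes, paths$control_a_vcf)
  write_vcf(sim$controls$control_b$genotypes, paths$control_b_vcf)
  readr::write_tsv(sim$case$annotations, paths$annotations)
  readr::write_tsv(sim$case$clinical, paths$clinical)
  sex_all <- dplyr::bind_rows(
    dplyr::mutate(sim$case$sex, cohort = "case"),
    dplyr::mutate(sim$controls$control_a$sex, cohort = "control_a"),
    dplyr::mutate(sim$controls$control_b$sex, cohort = "control_b"))
  readr::write_tsv(sex_all, paths$sex)
  if (!is.null(summary_stats)) {
    paths$summary_stats <- file.path(dir, "summary_stats.tsv")
    readr::write_tsv(summary_stats, paths$summary_stats)
  }
  invisible(paths)
}
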