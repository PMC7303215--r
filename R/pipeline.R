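# Orchestration: run every analysis stage over one configuration with
# seeded reproducibility and structured file outputs.

#' Pipeline configuration
#'
#' Collects every tunable threshold in one validated list. When `inputs` is
#' `NULL` the pipeline simulates its cohorts from `sim` (a [sim_config()]);
#' otherwise `inputs` must name files: `case_vcf`, `control_vcfs` (vector),
#' `sex_labels`, `annotations`, `clinical`, and optionally
#' `summary_stats`.
#'
#' @param seed Master seed for every stochastic stage.
#' @param rare_af,sift_max,cadd_min Variant classification thresholds.
#' @param control_alpha Control non-replication cutoff of the screen.
#' @param perm_t Permutation rounds.
#' @param bonferroni_alpha Family-wise alpha for the severity endpoints.
#' @param prs Named list: `r2_max`, `window_kb`, `maf_min`.
#' @param hom_posterior Homozygous-carrier posterior threshold.
#' @param sim A [sim_config()] used when no input files are given.
#' @param inputs Optional named list of input paths.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, rare_af = 0.001, sift_max = 0.05,
                            cadd_min = 15, control_alpha = 0.05,
                            perm_t = 10000, bonferroni_alpha = 0.05,
                            prs = list(r2_max = 0.1, window_kb = 250,
                                       maf_min = 0.01),
                            hom_posterior = 0.9,
                            sim = NULL, inputs = NULL) {
  if (perm_t < 1) abort("perm_t must be at least 1")
  if (rare_af <= 0 || sift_max <= 0 || cadd_min <= 0) {
    abort("classification thresholds must be positive")
  }
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(seed = as.integer(seed), rare_af = rare_af,
                 sift_max = sift_max, cadd_min = cadd_min,
                 control_alpha = control_alpha, perm_t = perm_t,
                 bonferroni_alpha = bonferroni_alpha, prs = prs,
                 hom_posterior = hom_posterior, sim = sim,
                 inputs = inputs), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- if (!is.null(raw$sim)) do.call(sim_config, raw$sim) else NULL
  raw$sim <- NULL
  args <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  do.call(pipeline_config, c(args, list(sim = sim)))
}

load_inputs <- function(inputs) {
  geno <- read_vcf(inputs$case_vcf)
  sex <- read_clinical_table(inputs$sex_labels)
  ann <- read_annotation_table(inputs$annotations)
  clinical <- if (!is.null(inputs$clinical)) {
    read_clinical_table(inputs$clinical)
  } else NULL
  case <- assemble_cohort(geno, sex[sex$cohort %in% c(NA, "case"), ],
                          ann, clinical, "case")
  controls <- purrr::imap(inputs$control_vcfs, function(p, i) {
    tag <- if (is.character(i)) i else paste0("control_", i)
    g <- read_vcf(p)
    assemble_cohort(g, sex[is.na(sex$cohort) | sex$cohort == tag, ],
                    ann, NULL, tag)
  })
  ss <- if (!is.null(inputs$summary_stats)) {
    read_summary_stats(inputs$summary_stats)
  } else NULL
  list(case = case, controls = controls, summary_stats = ss, truth = NULL)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load), classify, screen, burden + permutation,
#' haplotypes (on the screen hits, falling back to the first configured LD
#' block when fewer than two hits emerge), risk scoring, and the clinical
#' reports. Every stage logs its row counts via `message()`; with
#' `out_dir` set, each result is written under fixed file names together
#' with the effective configuration and its hash.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `wes_pipeline` holding every stage result.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stage <- function(name, ...) message("[", name, "] ", ...)

  if (is.null(config$inputs)) {
    stage("simulate", "seed ", config$sim$seed)
    sim <- simulate_cohort(config$sim)
    case <- sim$case
    controls <- sim$controls
    truth <- sim$truth
    summary_stats <- simulate_summary_stats(
      case$genotypes, seed = config$seed + 1L,
      planted = tibble::tibble(variant_id = truth$burden_ptv$variant_id,
                               beta = 0.25, p = 1e-6))
    gene_list <- truth$candidate_genes
  } else {
    stage("load", "reading input files")
    loaded <- load_inputs(config$inputs)
    case <- loaded$case; controls <- loaded$controls
    summary_stats <- loaded$summary_stats
    truth <- NULL
    gene_list <- config$inputs$gene_list
  }
  stage("assemble", nrow(case$genotypes), " cases, ",
        sum(vapply(controls, function(x) nrow(x$genotypes), numeric(1))),
        " controls, ", ncol(case$genotypes), " variants")

  categories <- classify_variants(case$annotations, rare_af = config$rare_af,
                                  sift_max = config$sift_max,
                                  cadd_min = config$cadd_min)
  stage("classify", sum(categories$is_functional), " functional, ",
        sum(categories$is_ptv), " PTV")

  screen <- run_screen(case, controls, control_alpha = config$control_alpha)
  stage("screen", nrow(screen$case_results), " variants tested, ",
        length(screen$hits), " hit(s), threshold ",
        signif(screen$threshold, 3))

  burden <- compute_burden(case, categories, gene_list = gene_list)
  sex_case <- case$sex
  rel <- relative_burden_summary(burden, sex_case)
  perm <- list()
  for (lev in c("variant", "gene")) {
    b <- burden[burden$combo == "ptv_deleterious" &
                  burden$scope == "all" & burden$level == lev, ]
    b <- b[match(sex_case$subject_id, b$subject_id), ]
    perm[[lev]] <- permutation_test(b$count, sex_case$sex, t = config$perm_t,
                                    seed = config$seed)
  }
  stage("burden", "deleterious-PTV permutation p: variant ",
        signif(perm$variant$p_perm, 3), ", gene ",
        signif(perm$gene$p_perm, 3), " (t = ", perm$variant$t, ")")

  hap_loci <- if (length(screen$hits) >= 2 && length(screen$hits) <= 8) {
    screen$hits
  } else if (!is.null(truth)) {
    truth$blocks[[length(truth$blocks)]]$loci
  } else NULL
  hap <- NULL; hap_ld <- NULL; hom <- NULL
  if (!is.null(hap_loci)) {
    hap <- em_haplotype_freqs(case$genotypes, hap_loci, seed = config$seed)
    hap_ld <- pairwise_ld(case$genotypes, hap_loci[1:2])
    target <- strrep("1", length(hap_loci))
    hom <- homozygous_carriers(hap, target,
                               threshold = config$hom_posterior)
    stage("haplotype", length(hap_loci), " loci, ",
          sum(hom$homozygous), " homozygous carrier(s)")
  }

  prs_scores <- NULL; prs_compare <- NULL; clumped <- NULL
  if (!is.null(summary_stats)) {
    clumped <- ld_clump(summary_stats, case$genotypes,
                        r2_max = config$prs$r2_max,
                        window_kb = config$prs$window_kb,
                        maf_min = config$prs$maf_min)
    prs_scores <- compute_prs(case$genotypes, clumped)
    prs_compare <- compare_prs_by_sex(prs_scores, sex_case)
    stage("prs", nrow(clumped), " index variants")
  }

  table1 <- NULL; severity <- NULL
  if (!is.null(case$clinical)) {
    table1 <- table1_report(case$clinical, sex_case)
    hit_carriers <- if (length(screen$hits)) {
      hits_geno <- case$genotypes[, screen$hits, drop = FALSE]
      rownames(case$genotypes)[
        rowSums(hits_geno == 2, na.rm = TRUE) > 0]
    } else character(0)
    severity <- carrier_severity_comparison(case$clinical, hit_carriers,
                                            sex_case,
                                            alpha = config$bonferroni_alpha)
    stage("clinical", length(hit_carriers), " homozygous carrier(s), ",
          length(covariate_shortlist(table1)), " shortlist covariate(s)")
  }

  result <- structure(list(
    config = config, config_hash = rlang::hash(unclass(config)),
    screen = screen, categories = categories, burden = burden,
    relative_burden = rel, permutation = perm, haplotype = hap,
    haplotype_ld = hap_ld, hom_carriers = hom, clumped = clumped,
    prs = prs_scores, prs_compare = prs_compare, table1 = table1,
    severity = severity, truth = truth), class = "wes_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(result$config)
  cfg$sim <- unclass(cfg$sim)
  yaml::write_yaml(c(list(config_hash = result$config_hash), cfg),
                   file.path(out_dir, "config_echo.yaml"))
  readr::write_tsv(tidy(result$screen), file.path(out_dir, "screen.tsv"))
  jsonlite::write_json(
    list(threshold = result$screen$threshold,
         per_control_minima = as.list(result$screen$per_control_minima),
         hits = result$screen$hits,
         config_hash = result$config_hash,
         seed = result$config$seed),
    file.path(out_dir, "screen_summary.json"), auto_unbox = TRUE,
    digits = NA)
  readr::write_tsv(burden_wide(result$burden),
                   file.path(out_dir, "burden_matrix.tsv"))
  readr::write_tsv(result$relative_burden,
                   file.path(out_dir, "relative_burden.tsv"))
  jsonlite::write_json(
    purrr::map(result$permutation, function(p) as.list(glance(p))),
    file.path(out_dir, "permutation.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(result$haplotype)) {
    readr::write_tsv(tidy(result$haplotype),
                     file.path(out_dir, "haplotype_freqs.tsv"))
    readr::write_tsv(result$haplotype$diplotypes,
                     file.path(out_dir, "diplotypes.tsv"))
  }
  if (!is.null(result$prs)) {
    readr::write_tsv(result$prs, file.path(out_dir, "prs_scores.tsv"))
    readr::write_tsv(result$prs_compare,
                     file.path(out_dir, "prs_compare.tsv"))
    readr::write_tsv(result$clumped, file.path(out_dir, "clump_report.tsv"))
  }
  if (!is.null(result$table1)) {
    readr::write_tsv(result$table1, file.path(out_dir, "clinical_table1.tsv"))
    readr::write_tsv(result$severity,
                     file.path(out_dir, "carrier_severity.tsv"))
  }
  invisible(out_dir)
}

#' @export
print.wes_pipeline <- function(x, ...) {
  cat("<wes_pipeline> hash ", substr(x$config_hash, 1, 8), "; ",
      length(x$screen$hits), " screen hit(s); deleterious-PTV permutation ",
      "p = ", signif(x$permutation$variant$p_perm, 3), " (variant), ",
      signif(x$permutation$gene$p_perm, 3), " (gene)\n", sep = "")
  invisible(x)
}
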