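# LD clumping of GWAS summary statistics against cohort genotypes and
# multi-threshold polygenic risk scoring with a sex comparison.

#' Default p-value thresholds for risk scoring
#' @return The eight standard thresholds.
#' @export
prs_thresholds <- function() c(1e-4, 0.001, 0.01, 0.05, 0.1, 0.2, 0.5, 1)

#' Greedy LD clumping
#'
#' Restricts to common variants (MAF > `maf_min` in the reference
#' genotypes), sorts by ascending association p-value, and greedily accepts
#' each variant unless a previously accepted variant on the same chromosome
#' within `window_kb` has squared dosage correlation above `r2_max` with
#' it. Summary-statistic variants absent from the genotypes are dropped
#' with a warning.
#'
#' @param stats Summary-statistics tibble (`variant_id`, `effect_allele`,
#'   `beta`, `p`).
#' @param geno Reference genotype matrix used for MAF and r-squared.
#' @param r2_max Maximum allowed r-squared between kept variants in a
#'   window.
#' @param window_kb Window half-width in kilobases.
#' @param maf_min Minor-allele-frequency floor.
#' @return Tibble of index variants (summary stats plus `chrom`, `pos`,
#'   `maf`), in acceptance order.
#' @export
ld_clump <- function(stats, geno, r2_max = 0.1, window_kb = 250,
                     maf_min = 0.01) {
  vi <- variant_info(geno)
  missing_ids <- setdiff(stats$variant_id, vi$variant_id)
  if (length(missing_ids)) {
    warn(paste0(length(missing_ids),
                " summary-stat variant(s) absent from genotypes, dropped"))
  }
  dat <- dplyr::inner_join(stats, vi, by = "variant_id")
  dose <- geno[, dat$variant_id, drop = FALSE]
  af <- colMeans(dose, na.rm = TRUE) / 2
  dat$maf <- pmin(af, 1 - af)
  dat <- dat[dat$maf > maf_min, , drop = FALSE]
  dat <- dat[order(dat$p), , drop = FALSE]
  if (nrow(dat) == 0) return(dat)
  keep <- logical(nrow(dat))
  for (i in seq_len(nrow(dat))) {
    near <- which(keep &
                    dat$chrom == dat$chrom[i] &
                    abs(dat$pos - dat$pos[i]) <= window_kb * 1000)
    ok <- TRUE
    for (j in near) {
      r <- suppressWarnings(cor(geno[, dat$variant_id[i]],
                                geno[, dat$variant_id[j]],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_max) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  dat[keep, , drop = FALSE]
}

#' Polygenic risk scores at multiple p-value thresholds
#'
#' For each threshold `tau`, the score of a subject is the sum of
#' `beta * alternative-allele dosage` over index variants with association
#' `p < tau`. Effect alleles are reconciled with the VCF alleles: when the
#' effect allele is the reference allele the beta sign is flipped; variants
#' whose effect allele matches neither allele, and strand-ambiguous (A/T,
#' C/G) variants, are dropped with a warning. A missing dosage contributes
#' the variant's mean dosage, keeping scores comparable across subjects.
#'
#' @param geno Genotype matrix of the scored cohort.
#' @param index Clumped index-variant tibble from [ld_clump()] (or any
#'   tibble with `variant_id`, `effect_allele`, `beta`, `p`).
#' @param thresholds P-value thresholds (default [prs_thresholds()]).
#' @param drop_ambiguous Drop strand-ambiguous variants.
#' @return Long tibble of class `wes_prs`: `subject_id`, `threshold`,
#'   `score`; attribute `"variants"` lists the variants used per threshold.
#' @export
compute_prs <- function(geno, index, thresholds = prs_thresholds(),
                        drop_ambiguous = TRUE) {
  vi <- variant_info(geno)
  dat <- dplyr::inner_join(
    index[, c("variant_id", "effect_allele", "beta", "p")],
    vi[, c("variant_id", "ref", "alt")], by = "variant_id")
  flip <- function(a) unname(c(A = "T", T = "A", C = "G", G = "C")[a])
  fa <- flip(dat$alt)
  ambiguous <- !is.na(fa) & dat$ref == fa
  if (drop_ambiguous && any(ambiguous)) {
    warn(paste0(sum(ambiguous), " strand-ambiguous variant(s) dropped"))
    dat <- dat[!ambiguous, , drop = FALSE]
  }
  match_alt <- dat$effect_allele == dat$alt
  match_ref <- dat$effect_allele == dat$ref
  bad <- !match_alt & !match_ref
  if (any(bad)) {
    warn(paste0(sum(bad), " variant(s) with unresolvable effect allele dropped"))
    dat <- dat[!bad, , drop = FALSE]
    match_alt <- match_alt[!bad]
  }
  dat$beta_alt <- ifelse(match_alt, dat$beta, -dat$beta)

  dose <- geno[, dat$variant_id, drop = FALSE]
  dose <- apply(dose, 2, function(d) {
    d[is.na(d)] <- mean(d, na.rm = TRUE)
    d
  })
  if (is.null(dim(dose))) dose <- matrix(dose, nrow = nrow(geno))
  used <- list()
  out <- purrr::map_dfr(thresholds, function(tau) {
    sel <- dat$p < tau
    used[[as.character(tau)]] <<- dat$variant_id[sel]
    score <- if (any(sel)) {
      as.numeric(dose[, sel, drop = FALSE] %*% dat$beta_alt[sel])
    } else rep(0, nrow(geno))
    tibble::tibble(subject_id = rownames(geno), threshold = tau,
                   score = score)
  })
  structure(out, variants = used, class = c("wes_prs", class(out)))
}

#' Compare risk scores between the sexes
#'
#' Wilcoxon rank-sum test of male versus female scores at each threshold,
#' with the enriched direction.
#'
#' @param prs `wes_prs` tibble from [compute_prs()].
#' @param sex_labels Tibble with `subject_id`, `sex`.
#' @return Tibble with `threshold`, `n_variants`, `w`, `p`, `direction`.
#' @export
compare_prs_by_sex <- function(prs, sex_labels) {
  dat <- dplyr::inner_join(prs, sex_labels, by = "subject_id")
  if (length(unique(dat$sex)) < 2) abort("both sexes must be present")
  used <- attr(prs, "variants")
  dat |>
    dplyr::group_by(.data$threshold) |>
    dplyr::group_modify(function(d, key) {
      m <- d$score[d$sex == "male"]
      f <- d$score[d$sex == "female"]
      wt <- wilcoxon_rank_sum(m, f)
      tibble::tibble(
        n_variants = length(used[[as.character(key$threshold)]] %||%
                              character(0)),
        w = wt$w, p = wt$p,
        direction = dplyr::case_when(
          median(m) > median(f) ~ "male",
          median(m) < median(f) ~ "female",
          mean(m) > mean(f) ~ "male",
          mean(m) < mean(f) ~ "female",
          TRUE ~ "none"))
    }) |>
    dplyr::ungroup()
}
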