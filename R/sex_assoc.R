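# Qualitative screen: per-variant female-vs-male association battery
# (Fisher allele/dominant/recessive, Cochran-Armitage trend), empirical
# threshold from control cohorts, hit filtering, and covariate-adjusted
# association (CMH, logistic regression).

#' Per-variant genotype counts by sex
#'
#' Tallies reference-homozygote, heterozygote and alternative-homozygote
#' subjects per sex for each variant. Missing genotypes are excluded, so the
#' per-variant denominator may be smaller than the cohort.
#'
#' @param cohort A `wes_cohort`.
#' @param variants Optional variant ids to restrict to.
#' @return Tibble with columns `variant_id`, `ref_f`, `het_f`, `hom_f`,
#'   `ref_m`, `het_m`, `hom_m`.
#' @export
genotype_sex_counts <- function(cohort, variants = NULL) {
  geno <- cohort$genotypes
  if (!is.null(variants)) geno <- geno[, variants, drop = FALSE]
  f <- cohort$sex$sex == "female"
  count_g <- function(rows, g) {
    colSums(geno[rows, , drop = FALSE] == g, na.rm = TRUE)
  }
  tibble::tibble(
    variant_id = colnames(geno),
    ref_f = count_g(f, 0L), het_f = count_g(f, 1L), hom_f = count_g(f, 2L),
    ref_m = count_g(!f, 0L), het_m = count_g(!f, 1L), hom_m = count_g(!f, 2L))
}

#' 2x2 tables from genotype counts
#'
#' Build the three 2x2 contrasts of the screen from `(ref, het, hom)` counts
#' per sex. Rows are female/male; the first column is the "exposed" count:
#' alternative alleles (`allele_table`, denominators are 2x the non-missing
#' subjects), carriers of at least one alternative allele
#' (`dominant_table`), or alternative homozygotes (`recessive_table`).
#'
#' @param ref_f,het_f,hom_f,ref_m,het_m,hom_m Genotype counts per sex.
#' @return An integer 2x2 matrix with dimnames.
#' @export
allele_table <- function(ref_f, het_f, hom_f, ref_m, het_m, hom_m) {
  counts_2x2(alt_f = het_f + 2L * hom_f, ref_a_f = 2L * ref_f + het_f,
             alt_m = het_m + 2L * hom_m, ref_a_m = 2L * ref_m + het_m)
}

#' @rdname allele_table
#' @export
dominant_table <- function(ref_f, het_f, hom_f, ref_m, het_m, hom_m) {
  counts_2x2(het_f + hom_f, ref_f, het_m + hom_m, ref_m)
}

#' @rdname allele_table
#' @export
recessive_table <- function(ref_f, het_f, hom_f, ref_m, het_m, hom_m) {
  counts_2x2(hom_f, ref_f + het_f, hom_m, ref_m + het_m)
}

counts_2x2 <- function(alt_f, ref_a_f, alt_m, ref_a_m) {
  x <- c(alt_f, ref_a_f, alt_m, ref_a_m)
  if (any(x < 0)) abort("negative counts in 2x2 table")
  matrix(as.integer(x), nrow = 2, byrow = TRUE,
         dimnames = list(sex = c("female", "male"),
                         status = c("exposed", "unexposed")))
}

#' Fisher exact association on a 2x2 table
#'
#' Two-sided exact p-value by the probability-mass method (summing, over
#' all tables with the observed margins, the hypergeometric probabilities
#' not exceeding that of the observed table). The reported odds ratio is
#' the sample odds ratio `ad/bc`, `Inf` when `bc = 0` with `ad > 0` and 1
#' when both products are zero; the confidence interval is the exact
#' conditional interval. A table with an empty row or column is flagged and
#' returns p = 1 by convention.
#'
#' @param tab 2x2 matrix, e.g. from [allele_table()].
#' @param conf_level Confidence level for the exact CI.
#' @return Tibble with columns `p`, `or`, `ci_lo`, `ci_hi`,
#'   `or_infinite`, `degenerate`.
#' @export
fisher_assoc <- function(tab, conf_level = 0.95) {
  stopifnot(all(dim(tab) == c(2, 2)))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  or <- if (a * d == 0 && b * c_ == 0) 1
        else if (b * c_ == 0) Inf
        else (a * d) / (b * c_)
  if (degenerate) {
    return(tibble::tibble(p = 1, or = or, ci_lo = NA_real_, ci_hi = NA_real_,
                          or_infinite = is.infinite(or), degenerate = TRUE))
  }
  ft <- fisher.test(tab, conf.level = conf_level)
  tibble::tibble(p = ft$p.value, or = or,
                 ci_lo = ft$conf.int[1], ci_hi = ft$conf.int[2],
                 or_infinite = is.infinite(or), degenerate = FALSE)
}

#' Cochran-Armitage trend test
#'
#' Tests for a linear trend in the female proportion across the three
#' genotype classes with additive scores (0, 1, 2 by default). The variance
#' is the binomial form `p1 (1 - p1) (sum s^2 n_j - (sum s n_j)^2 / N)`;
#' `finite_pop = TRUE` multiplies it by `N / (N - 1)` (the hypergeometric
#' convention). A monomorphic table (zero score variance) is flagged and
#' returns p = 1.
#'
#' @param counts 2x3 matrix: rows female/male, columns ref/het/hom.
#' @param scores Numeric genotype scores.
#' @param finite_pop Use the finite-population variance correction.
#' @return Tibble with columns `z`, `p`, `degenerate`.
#' @export
cochran_armitage <- function(counts, scores = c(0, 1, 2),
                             finite_pop = FALSE) {
  stopifnot(nrow(counts) == 2, ncol(counts) == length(scores))
  n_j <- colSums(counts)
  N <- sum(n_j)
  r1 <- sum(counts[1, ])
  p1 <- r1 / N
  s_var <- sum(scores^2 * n_j) - sum(scores * n_j)^2 / N
  if (s_var <= 0 || p1 %in% c(0, 1)) {
    return(tibble::tibble(z = 0, p = 1, degenerate = TRUE))
  }
  t_stat <- sum(scores * (counts[1, ] - n_j * p1))
  v <- p1 * (1 - p1) * s_var
  if (finite_pop) v <- v * N / (N - 1)
  z <- t_stat / sqrt(v)
  tibble::tibble(z = z, p = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Female-vs-male association battery
#'
#' Runs, for each variant, the allele-frequency Fisher test, the dominant
#' and recessive genotype-frequency Fisher tests, and the Cochran-Armitage
#' trend test, comparing women against men within a cohort.
#'
#' @param cohort A `wes_cohort`.
#' @param variants Optional variant ids to restrict to.
#' @inheritParams cochran_armitage
#' @return Tibble with the genotype counts plus `allele_p`, `allele_or`,
#'   `allele_ci_lo`, `allele_ci_hi`, `dominant_p`, `dominant_or`,
#'   `recessive_p`, `recessive_or`, `catt_p` and a `group` tag.
#' @export
sex_assoc_battery <- function(cohort, variants = NULL, finite_pop = FALSE) {
  counts <- genotype_sex_counts(cohort, variants)
  res <- purrr::pmap_dfr(counts, function(variant_id, ref_f, het_f, hom_f,
                                          ref_m, het_m, hom_m) {
    al <- fisher_assoc(allele_table(ref_f, het_f, hom_f, ref_m, het_m, hom_m))
    dom <- fisher_assoc(dominant_table(ref_f, het_f, hom_f, ref_m, het_m, hom_m))
    rec <- fisher_assoc(recessive_table(ref_f, het_f, hom_f, ref_m, het_m, hom_m))
    ca <- cochran_armitage(matrix(c(ref_f, het_f, hom_f, ref_m, het_m, hom_m),
                                  nrow = 2, byrow = TRUE),
                           finite_pop = finite_pop)
    tibble::tibble(allele_p = al$p, allele_or = al$or,
                   allele_ci_lo = al$ci_lo, allele_ci_hi = al$ci_hi,
                   dominant_p = dom$p, dominant_or = dom$or,
                   recessive_p = rec$p, recessive_or = rec$or,
                   catt_p = ca$p)
  })
  dplyr::bind_cols(counts, res) |>
    dplyr::mutate(group = cohort$cohort, .before = 1)
}

#' Empirical significance threshold from control cohorts
#'
#' Under the assumption that allele frequencies do not genuinely differ
#' between the sexes in controls, the smallest female-vs-male allele-test
#' p-value observed across all screened variants in the control data bounds
#' the noise level; it is used as the screen's significance threshold.
#'
#' @param control_results One battery tibble, or a list of battery tibbles
#'   (one per control cohort), as returned by [sex_assoc_battery()].
#' @param scope `"overall"` (default) returns the minimum across all
#'   cohorts; `"per_cohort"` returns one threshold per cohort.
#' @return The threshold p-value (or named vector for `"per_cohort"`), with
#'   attribute `per_cohort` giving each cohort's minimum.
#' @export
empirical_threshold <- function(control_results,
                                scope = c("overall", "per_cohort")) {
  scope <- match.arg(scope)
  if (is.data.frame(control_results)) control_results <- list(control_results)
  if (length(control_results) == 0 ||
      all(vapply(control_results, nrow, integer(1)) == 0)) {
    abort("no control results to derive a threshold from")
  }
  minima <- vapply(control_results,
                   function(r) min(r$allele_p, na.rm = TRUE), numeric(1))
  names(minima) <- vapply(control_results, function(r) r$group[1], character(1))
  out <- if (scope == "overall") min(minima) else minima
  structure(out, per_cohort = minima)
}

#' Run the qualitative single-variant screen
#'
#' Tests all functional variants (missense, stop gain, stop lost, start
#' lost) for a female-vs-male allele-frequency difference in the case
#' cohort, derives the empirical threshold from the same test run in each
#' control cohort, and reports as hits the variants whose case p-value
#' falls below the threshold while no control cohort shows a difference at
#' `control_alpha`. The full battery (dominant, recessive, trend) is
#' reported for every tested variant.
#'
#' @param case A `wes_cohort` of cases.
#' @param controls List of control `wes_cohort`s.
#' @param control_alpha Control non-replication cutoff: a hit must have
#'   allele-test p >= this in every control cohort.
#' @param threshold Optional fixed threshold; by default derived from the
#'   controls via [empirical_threshold()].
#' @param consequences Consequence classes screened (the qualitative
#'   functional set by default).
#' @return A `wes_screen` object; see [tidy.wes_screen()] and
#'   [glance.wes_screen()].
#' @export
run_screen <- function(case, controls, control_alpha = 0.05,
                       threshold = NULL,
                       consequences = screen_consequences()) {
  if (!is.list(controls) || is.data.frame(controls)) {
    abort("controls must be a list of wes_cohort objects")
  }
  variants <- case$annotations$variant_id[
    case$annotations$consequence %in% consequences]
  if (length(variants) == 0) abort("no functional variants to screen")
  case_res <- sex_assoc_battery(case, variants)
  ctl_res <- purrr::map(controls, function(ctl) {
    shared <- intersect(variants, colnames(ctl$genotypes))
    sex_assoc_battery(ctl, shared)
  })
  if (is.null(threshold)) threshold <- empirical_threshold(ctl_res)
  ctl_p <- purrr::map(ctl_res, ~ setNames(.x$allele_p, .x$variant_id))
  replicated_null <- vapply(case_res$variant_id, function(v) {
    all(vapply(ctl_p, function(p) is.na(p[v]) || p[v] >= control_alpha,
               logical(1)))
  }, logical(1))
  hits <- case_res$variant_id[case_res$allele_p < as.numeric(threshold) &
                                replicated_null]
  structure(list(
    threshold = as.numeric(threshold),
    per_control_minima = attr(threshold, "per_cohort") %||%
      vapply(ctl_res, function(r) min(r$allele_p, na.rm = TRUE), numeric(1)),
    control_alpha = control_alpha,
    case_results = case_res,
    control_results = ctl_res,
    hits = hits), class = "wes_screen")
}

#' @export
print.wes_screen <- function(x, ...) {
  cat("<wes_screen> ", nrow(x$case_results), " variants tested; threshold ",
      signif(x$threshold, 3), "; ", length(x$hits), " hit(s)\n", sep = "")
  invisible(x)
}

#' Tidy a screen result
#'
#' @param x A `wes_screen` from [run_screen()].
#' @param ... Unused.
#' @return The per-variant case battery with a logical `hit` column.
#' @export
tidy.wes_screen <- function(x, ...) {
  dplyr::mutate(x$case_results, hit = .data$variant_id %in% x$hits)
}

#' @rdname tidy.wes_screen
#' @return For `glance`: a one-row tibble with the threshold, the number of
#'   variants tested and the number of hits.
#' @export
glance.wes_screen <- function(x, ...) {
  tibble::tibble(threshold = x$threshold,
                 n_tested = nrow(x$case_results),
                 n_hits = length(x$hits),
                 control_alpha = x$control_alpha)
}

#' Cochran-Mantel-Haenszel test across strata
#'
#' Common-odds-ratio test over a set of 2x2 tables (one per stratum of an
#' adjustment covariate), without continuity correction, plus the
#' Mantel-Haenszel common odds ratio.
#'
#' @param tables A 2x2xK array, or a list of 2x2 matrices.
#' @return Tibble with columns `statistic`, `p`, `common_or`.
#' @export
cmh_test <- function(tables) {
  if (is.list(tables)) {
    tables <- array(unlist(tables), dim = c(2, 2, length(tables)))
  }
  stopifnot(length(dim(tables)) == 3, all(dim(tables)[1:2] == 2))
  ok <- apply(tables, 3, function(t) all(rowSums(t) > 0) && sum(t) > 1)
  if (!any(ok)) abort("all strata are degenerate")
  kept <- tables[, , ok, drop = FALSE]
  if (sum(ok) == 1) {
    # mantelhaen.test requires >= 2 strata; the single-stratum statistic
    # is the conditional (hypergeometric-variance) chi-square
    t1 <- kept[, , 1]
    n <- sum(t1)
    e <- sum(t1[1, ]) * sum(t1[, 1]) / n
    v <- prod(rowSums(t1)) * prod(colSums(t1)) / (n^2 * (n - 1))
    stat <- (t1[1, 1] - e)^2 / v
    return(tibble::tibble(statistic = stat,
                          p = pchisq(stat, 1, lower.tail = FALSE),
                          common_or = (t1[1, 1] * t1[2, 2]) /
                            (t1[1, 2] * t1[2, 1])))
  }
  mh <- mantelhaen.test(kept, correct = FALSE)
  tibble::tibble(statistic = unname(mh$statistic), p = mh$p.value,
                 common_or = unname(mh$estimate))
}

#' Covariate-adjusted logistic association
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()], deviance tolerance 1e-8, at most 50
#' iterations) of a binary outcome on sex plus adjustment covariates, with
#' Wald tests per term. Complete or quasi-complete separation is detected
#' (fitted probabilities numerically at 0/1 alongside inflated standard
#' errors) and flagged rather than silently reported.
#'
#' @param data Data frame holding all model variables.
#' @param formula Model formula, e.g. `carrier ~ sex + age`.
#' @return List with `coefficients` (tibble: term, beta, se, p),
#'   `converged`, and `separation`.
#' @export
logistic_adjusted <- function(data, formula) {
  fit <- suppressWarnings(
    glm(formula, data = data, family = binomial(),
        control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  co <- summary(fit)$coefficients
  mu <- fit$fitted.values
  separation <- any(mu > 1 - 1e-8 | mu < 1e-8) && any(co[, 2] > 10)
  list(coefficients = tibble::tibble(term = rownames(co),
                                     beta = unname(co[, 1]),
                                     se = unname(co[, 2]),
                                     p = unname(co[, 4])),
       converged = fit$converged, separation = separation)
}

#' Stratify a 2x2 sex-by-carrier contrast by a covariate
#'
#' Helper for covariate adjustment by stratification: bins a covariate
#' (quartiles for numeric, levels otherwise) and builds one
#' female/male-by-carrier table per stratum for [cmh_test()].
#'
#' @param carrier Logical carrier status per subject.
#' @param sex Character vector `"female"`/`"male"` per subject.
#' @param covariate Covariate to stratify on.
#' @param n_bins Number of quantile bins for numeric covariates.
#' @return 2x2xK array of counts.
#' @export
stratified_tables <- function(carrier, sex, covariate, n_bins = 4) {
  strata <- if (is.numeric(covariate)) {
    cut(covariate, breaks = unique(stats::quantile(covariate,
        probs = seq(0, 1, length.out = n_bins + 1), na.rm = TRUE)),
        include.lowest = TRUE)
  } else factor(covariate)
  keep <- !is.na(strata) & !is.na(carrier)
  tab <- table(factor(sex[keep], c("female", "male")),
               factor(carrier[keep], c(TRUE, FALSE)), strata[keep])
  array(tab, dim = dim(tab))
}
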