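# Quantitative analysis: per-subject genetic burden across the eight
# annotation-category combinations at variant and gene level, sex
# comparison by rank-sum test, and a sex-label permutation null.

#' Per-subject genetic burden
#'
#' Counts, for every subject and every category combination, the number of
#' carried variants (>= 1 alternative allele; missing genotypes count as
#' non-carrier) and the number of distinct genes containing at least one
#' carried variant. Burdens are computed over all genes with a variant
#' (scope `"all"`) and, when `gene_list` is given, additionally over that
#' candidate gene list (scope `"candidate"`).
#'
#' @param cohort A `wes_cohort`.
#' @param categories Output of [classify_variants()] covering the cohort's
#'   variants.
#' @param gene_list Optional character vector of candidate gene symbols.
#'   Genes absent from the cohort are ignored with a warning.
#' @param dosage If `TRUE`, the variant-level count sums alternative-allele
#'   dosages instead of counting carried variants once.
#' @return Long tibble with columns `subject_id`, `scope`, `level`
#'   (`"variant"`/`"gene"`), `combo`, `count`.
#' @export
compute_burden <- function(cohort, categories, gene_list = NULL,
                           dosage = FALSE) {
  geno <- cohort$genotypes
  ann <- cohort$annotations
  cat_idx <- match(colnames(geno), categories$variant_id)
  if (anyNA(cat_idx)) abort("categories must cover every cohort variant")
  categories <- categories[cat_idx, , drop = FALSE]
  carrier <- !is.na(geno) & geno > 0
  weight <- if (dosage) ifelse(is.na(geno), 0, geno) else carrier * 1

  scopes <- list(all = ann$gene)
  if (!is.null(gene_list)) {
    unknown <- setdiff(gene_list, ann$gene)
    if (length(unknown)) {
      warn(paste0(length(unknown),
                  " candidate gene(s) absent from the cohort, ignored"))
    }
    scopes$candidate <- ann$gene[ann$gene %in% gene_list]
  }

  out <- purrr::imap_dfr(scopes, function(scope_genes, scope_name) {
    in_scope <- ann$gene %in% scope_genes
    purrr::map_dfr(combo_names(), function(combo) {
      members <- which(categories[[combo]] & in_scope)
      vc <- rowSums(weight[, members, drop = FALSE])
      gc <- if (length(members)) {
        m <- carrier[, members, drop = FALSE] * 1
        per_gene <- rowsum(t(m), ann$gene[members])
        rowSums(t(per_gene) > 0)
      } else rep(0, nrow(geno))
      tibble::tibble(
        subject_id = rep(rownames(geno), 2),
        scope = scope_name,
        level = rep(c("variant", "gene"), each = nrow(geno)),
        combo = combo,
        count = unname(c(vc, gc)))
    })
  })
  out
}

#' Burden matrix in wide form
#'
#' @param burden Long burden tibble from [compute_burden()].
#' @return Tibble with one row per subject and one column per
#'   scope/level/combo cell.
#' @export
burden_wide <- function(burden) {
  burden |>
    tidyr::pivot_wider(names_from = c("scope", "level", "combo"),
                       values_from = "count")
}

# rank-sum machinery ----------------------------------------------------

rank_sum_u <- function(ranks, idx, n1) {
  sum(ranks[idx]) - n1 * (n1 + 1) / 2
}

#' Wilcoxon rank-sum test
#'
#' Mann-Whitney form: the statistic `w` is the rank sum of the first group
#' minus `n1 (n1 + 1) / 2`, with mid-ranks for ties. For combined sample
#' sizes up to `exact_max`, the p-value comes from exhaustive enumeration
#' of all group assignments (valid under ties); otherwise from the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric samples (e.g. male and female burdens).
#' @param alternative `"two_sided"` (default) or `"greater"` (first group
#'   stochastically larger).
#' @param exact_max Largest `n1 + n2` for which the exact enumeration runs.
#' @return Tibble with columns `w`, `p`, `method`, `degenerate`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two_sided", "greater"),
                              exact_max = 12) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- rank_sum_u(ranks, seq_len(n1), n1)
  mu <- n1 * n2 / 2
  eps <- sqrt(.Machine$double.eps)

  if (length(unique(pooled)) == 1) {
    return(tibble::tibble(w = w_obs, p = 1, method = "degenerate",
                          degenerate = TRUE))
  }
  if (n <= exact_max) {
    sel <- combn(n, n1)
    ws <- apply(sel, 2, function(idx) rank_sum_u(ranks, idx, n1))
    p <- if (alternative == "greater") {
      mean(ws >= w_obs - eps)
    } else {
      mean(abs(ws - mu) >= abs(w_obs - mu) - eps)
    }
    return(tibble::tibble(w = w_obs, p = p, method = "exact",
                          degenerate = FALSE))
  }
  ties <- table(pooled)
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v <= 0) {
    return(tibble::tibble(w = w_obs, p = 1, method = "degenerate",
                          degenerate = TRUE))
  }
  z_num <- w_obs - mu
  cc <- sign(z_num) * 0.5
  p <- if (alternative == "greater") {
    pnorm((z_num - 0.5) / sqrt(v), lower.tail = FALSE)
  } else {
    min(1, 2 * pnorm(-abs(z_num - cc) / sqrt(v)))
  }
  tibble::tibble(w = w_obs, p = p, method = "normal", degenerate = FALSE)
}

#' Sex-label permutation test of male burden excess
#'
#' Permutes the sex labels uniformly at random while preserving the
#' observed group sizes, recomputes the male-vs-female rank-sum statistic
#' `W` each round, and reports `p = C/T` where `C` counts permuted
#' statistics at least as large as the observed one (the male-excess
#' direction; `"two_sided"` counts deviations from the null mean in either
#' direction). When the label multiset admits at most `exhaustive_max`
#' distinct male/female splits, all splits are enumerated instead and `T`
#' becomes that number. `p = 0` can only arise under enumeration; a sampled
#' zero count is reported as `p = 0` annotated `"< 1/T"` via the
#' `note` field of [glance.wes_perm()].
#'
#' @param burdens Numeric burden per subject.
#' @param sex Character vector `"female"`/`"male"`, aligned with `burdens`.
#' @param t Number of permutation rounds.
#' @param seed RNG seed for the label shuffles.
#' @param alternative `"greater"` (male excess, default) or `"two_sided"`.
#' @param exhaustive_max Enumeration cutoff on the number of distinct splits.
#' @return A `wes_perm` object with fields `observed_w`, `permuted_ws`,
#'   `c`, `t`, `p_perm`, `seed`, `exhaustive`.
#' @export
permutation_test <- function(burdens, sex, t = 10000, seed = 1L,
                             alternative = c("greater", "two_sided"),
                             exhaustive_max = 20000) {
  alternative <- match.arg(alternative)
  if (t < 1) abort("t must be at least 1")
  if (length(burdens) != length(sex)) abort("burdens and sex must align")
  is_m <- sex == "male"
  n1 <- sum(is_m); n2 <- sum(!is_m); n <- n1 + n2
  if (n1 == 0 || n2 == 0) abort("both sexes must be present")
  ranks <- rank(burdens)
  offset <- n1 * (n1 + 1) / 2
  w_obs <- sum(ranks[is_m]) - offset
  mu <- n1 * n2 / 2
  eps <- sqrt(.Machine$double.eps)

  exhaustive <- choose(n, n1) <= exhaustive_max
  if (exhaustive) {
    sel <- combn(n, n1)
    ws <- colSums(matrix(ranks[sel], nrow = n1)) - offset
  } else {
    set.seed(seed)
    ws <- vapply(seq_len(t), function(i) {
      sum(ranks[sample.int(n, n1)]) - offset
    }, numeric(1))
  }
  c_cnt <- if (alternative == "greater") {
    sum(ws >= w_obs - eps)
  } else {
    sum(abs(ws - mu) >= abs(w_obs - mu) - eps)
  }
  t_eff <- length(ws)
  structure(list(observed_w = w_obs, permuted_ws = ws, c = c_cnt,
                 t = t_eff, p_perm = c_cnt / t_eff, seed = seed,
                 alternative = alternative, exhaustive = exhaustive),
            class = "wes_perm")
}

#' @export
print.wes_perm <- function(x, ...) {
  cat("<wes_perm> observed W = ", x$observed_w, "; C/T = ", x$c, "/", x$t,
      " = ", signif(x$p_perm, 3),
      if (x$exhaustive) " (exhaustive)" else "", "\n", sep = "")
  invisible(x)
}

#' Tidy / summarize a permutation result
#'
#' @param x A `wes_perm` from [permutation_test()].
#' @param ... Unused.
#' @return `tidy`: one row per permutation round (`round`, `w`).
#'   `glance`: one-row tibble with `observed_w`, `c`, `t`, `p_perm`,
#'   `seed`, `exhaustive` and a `note` (`"< 1/T"` when a sampled count is
#'   zero).
#' @export
tidy.wes_perm <- function(x, ...) {
  tibble::tibble(round = seq_along(x$permuted_ws), w = x$permuted_ws)
}

#' @rdname tidy.wes_perm
#' @export
glance.wes_perm <- function(x, ...) {
  tibble::tibble(observed_w = x$observed_w, c = x$c, t = x$t,
                 p_perm = x$p_perm, seed = x$seed,
                 exhaustive = x$exhaustive,
                 note = if (x$c == 0 && !x$exhaustive) "< 1/T" else NA_character_)
}

#' Relative burden summary across the 32 cells
#'
#' For every combination x scope x level cell, computes the relative burden
#' (mean male burden over mean female burden), the two-sided rank-sum
#' p-value, and which sex is enriched. A zero female mean gives an infinite
#' ratio, flagged.
#'
#' @param burden Long burden tibble from [compute_burden()].
#' @param sex_labels Tibble with `subject_id`, `sex`.
#' @return A tibble of class `wes_burden_summary`, one row per cell, with
#'   columns `scope`, `level`, `combo`, `mean_male`, `mean_female`,
#'   `relative_burden`, `p`, `enriched_sex`, `infinite_ratio`.
#' @export
relative_burden_summary <- function(burden, sex_labels) {
  dat <- dplyr::inner_join(burden, sex_labels, by = "subject_id")
  out <- dat |>
    dplyr::group_by(.data$scope, .data$level, .data$combo) |>
    dplyr::group_modify(function(d, key) {
      m <- d$count[d$sex == "male"]
      f <- d$count[d$sex == "female"]
      mm <- mean(m); mf <- mean(f)
      rel <- if (mf == 0 && mm == 0) NA_real_
             else if (mf == 0) Inf else mm / mf
      wt <- wilcoxon_rank_sum(m, f)
      tibble::tibble(mean_male = mm, mean_female = mf,
                     relative_burden = rel, p = wt$p,
                     enriched_sex = dplyr::case_when(
                       is.na(rel) | rel == 1 ~ "none",
                       rel > 1 ~ "male", TRUE ~ "female"),
                     infinite_ratio = is.infinite(rel))
    }) |>
    dplyr::ungroup()
  class(out) <- c("wes_burden_summary", class(out))
  out
}
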