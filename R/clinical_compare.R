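# Demographic/clinical sex comparisons, carrier vs non-carrier severity
# comparisons, and the Bonferroni regime for the seven severity endpoints.

#' Yates-corrected chi-squared test on a 2x2 table
#'
#' `chi2 = n (|ad - bc| - n/2)^2 / ((a+b)(c+d)(a+c)(b+d))` with the
#' corrected difference floored at zero; df = 1. A table with an empty row
#' or column is flagged and returns chi2 = 0, p = 1.
#'
#' @param tab 2x2 matrix of counts.
#' @return Tibble with `chi2`, `p`, `degenerate`.
#' @export
yates_chi2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble::tibble(chi2 = 0, p = 1, degenerate = TRUE))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
  tibble::tibble(chi2 = unname(ct$statistic), p = ct$p.value,
                 degenerate = FALSE)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom, from raw
#' vectors (`welch_t`) or group summaries (`welch_t_summary`), the latter
#' so printed mean/SD/n rows of a cohort table can be re-tested directly.
#'
#' @param x,y Numeric samples (n >= 2 each).
#' @return Tibble with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("each group needs n >= 2")
  welch_t_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' @rdname welch_t
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  if (v1 + v2 == 0) abort("zero variance in both groups")
  t_stat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

#' 2x2 group test with sparse-table fallback
#'
#' Yates chi-squared when all expected counts are at least 5, otherwise
#' Fisher's exact test. An empty margin is flagged degenerate with p = 1.
#'
#' @param tab 2x2 matrix of counts.
#' @return Tibble with `test`, `statistic`, `p`, `degenerate`.
#' @export
binary_group_test <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble::tibble(test = "chi2", statistic = 0, p = 1,
                          degenerate = TRUE))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- fisher.test(tab)
    tibble::tibble(test = "fisher", statistic = NA_real_, p = ft$p.value,
                   degenerate = FALSE)
  } else {
    yc <- yates_chi2(tab)
    tibble::tibble(test = "chi2", statistic = yc$chi2, p = yc$p,
                   degenerate = FALSE)
  }
}

severity_endpoints <- function() {
  tibble::tribble(
    ~variable, ~type,
    "hamd", "continuous",
    "hads_anx", "continuous",
    "bprs_suicide_ge4", "binary",
    "suicide_attempt", "binary",
    "family_history", "binary",
    "recurrent", "binary",
    "age_onset", "continuous")
}

#' Carrier vs non-carrier clinical severity comparison
#'
#' Compares the seven severity endpoints (HAMD, HADS-anxiety and age of
#' onset by Wilcoxon rank-sum; BPRS suicide item >= 4, suicide attempt,
#' family history and recurrence by Yates chi-squared, falling back to
#' Fisher's exact test when any expected cell is below 5) between subjects
#' homozygous for an associated variant or haplotype ("carriers" here) and
#' everyone else. Run for all subjects and within each sex. The Bonferroni
#' threshold 0.05/7 is applied per population. Populations with an empty
#' carrier group produce rows marked not computable.
#'
#' @param clinical Clinical tibble (needs `subject_id`, `hamd`, `hads_anx`,
#'   `bprs_suicide`, `suicide_attempt`, `family_history`, `recurrent`,
#'   `age_onset`).
#' @param carrier_ids Subject ids of homozygous carriers.
#' @param sex_labels Optional tibble `subject_id`, `sex`; when given, the
#'   comparison is additionally run within each sex.
#' @param alpha Family-wise error rate before Bonferroni division.
#' @return Tibble with one row per population x endpoint: `population`,
#'   `variable`, `test`, `statistic`, `p`, `alpha`, `significant`,
#'   `computable`, plus carrier/non-carrier summaries.
#' @export
carrier_severity_comparison <- function(clinical, carrier_ids,
                                        sex_labels = NULL, alpha = 0.05) {
  dat <- clinical |>
    dplyr::mutate(carrier = .data$subject_id %in% carrier_ids,
                  bprs_suicide_ge4 = .data$bprs_suicide >= 4)
  pops <- list(all = dat)
  if (!is.null(sex_labels)) {
    dat2 <- dplyr::inner_join(dat, sex_labels, by = "subject_id")
    pops$female <- dat2[dat2$sex == "female", ]
    pops$male <- dat2[dat2$sex == "male", ]
  }
  n_endpoints <- nrow(severity_endpoints())
  bonf <- alpha / n_endpoints
  purrr::imap_dfr(pops, function(d, pop) {
    purrr::pmap_dfr(severity_endpoints(), function(variable, type) {
      car <- d[[variable]][d$carrier]
      non <- d[[variable]][!d$carrier]
      base <- tibble::tibble(population = pop, variable = variable,
                             n_carrier = sum(d$carrier),
                             n_noncarrier = sum(!d$carrier))
      if (sum(d$carrier) == 0 || sum(!d$carrier) == 0) {
        return(dplyr::mutate(base, test = NA_character_,
                             statistic = NA_real_, p = NA_real_,
                             carrier_summary = NA_character_,
                             noncarrier_summary = NA_character_,
                             alpha = bonf, significant = NA,
                             computable = FALSE))
      }
      if (type == "continuous") {
        wt <- wilcoxon_rank_sum(car, non)
        res <- tibble::tibble(test = "wilcoxon", statistic = wt$w, p = wt$p)
        cs <- sprintf("%.1f (%.1f)", mean(car, na.rm = TRUE),
                      sd(car, na.rm = TRUE))
        ns <- sprintf("%.1f (%.1f)", mean(non, na.rm = TRUE),
                      sd(non, na.rm = TRUE))
      } else {
        tab <- matrix(c(sum(car, na.rm = TRUE), sum(!car, na.rm = TRUE),
                        sum(non, na.rm = TRUE), sum(!non, na.rm = TRUE)),
                      nrow = 2, byrow = TRUE)
        bt <- binary_group_test(tab)
        res <- tibble::tibble(test = bt$test, statistic = bt$statistic,
                              p = bt$p)
        cs <- sprintf("%d (%.1f%%)", sum(car, na.rm = TRUE),
                      100 * mean(car, na.rm = TRUE))
        ns <- sprintf("%d (%.1f%%)", sum(non, na.rm = TRUE),
                      100 * mean(non, na.rm = TRUE))
      }
      dplyr::bind_cols(base, res) |>
        dplyr::mutate(carrier_summary = cs, noncarrier_summary = ns,
                      alpha = bonf, significant = .data$p < bonf,
                      computable = TRUE)
    })
  })
}

#' Sex comparison of demographic and clinical characteristics
#'
#' Compares every available cohort-description variable between women and
#' men: numeric variables by Welch t-test, binary variables by Yates
#' chi-squared (Fisher fallback under sparse expected counts). Returns the
#' comparison rows and, as an attribute, the shortlist of variables with
#' p below `shortlist_alpha` (the broader cut-off feeding covariate
#' adjustment of the single-variant results).
#'
#' @param clinical Clinical tibble.
#' @param sex_labels Tibble `subject_id`, `sex`.
#' @param shortlist_alpha Shortlist cut-off (default 0.1).
#' @return Tibble of class `wes_table1`, one row per variable, with
#'   attribute `"shortlist"`; see [covariate_shortlist()].
#' @export
table1_report <- function(clinical, sex_labels, shortlist_alpha = 0.1) {
  dat <- dplyr::inner_join(clinical, sex_labels, by = "subject_id")
  dat$bprs_suicide_ge4 <- if ("bprs_suicide" %in% names(dat)) {
    dat$bprs_suicide >= 4
  } else NULL
  skip <- c("subject_id", "sex", "bprs_suicide")
  vars <- setdiff(names(dat), skip)
  f <- dat$sex == "female"
  rows <- purrr::map_dfr(vars, function(v) {
    x <- dat[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      return(tibble::tibble(variable = v, test = NA_character_,
                            statistic = NA_real_, p = NA_real_,
                            female_summary = NA_character_,
                            male_summary = NA_character_,
                            degenerate = TRUE))
    }
    if (is.logical(x)) {
      tab <- matrix(c(sum(x[f], na.rm = TRUE), sum(!x[f], na.rm = TRUE),
                      sum(x[!f], na.rm = TRUE), sum(!x[!f], na.rm = TRUE)),
                    nrow = 2, byrow = TRUE)
      bt <- binary_group_test(tab)
      tibble::tibble(variable = v, test = bt$test,
                     statistic = bt$statistic, p = bt$p,
                     female_summary = sprintf("%d (%.1f%%)", tab[1, 1],
                                              100 * tab[1, 1] / sum(tab[1, ])),
                     male_summary = sprintf("%d (%.1f%%)", tab[2, 1],
                                            100 * tab[2, 1] / sum(tab[2, ])),
                     degenerate = FALSE)
    } else {
      wt <- welch_t(x[f], x[!f])
      tibble::tibble(variable = v, test = "welch_t", statistic = wt$t,
                     p = wt$p,
                     female_summary = sprintf("%.1f (%.1f)",
                                              mean(x[f], na.rm = TRUE),
                                              sd(x[f], na.rm = TRUE)),
                     male_summary = sprintf("%.1f (%.1f)",
                                            mean(x[!f], na.rm = TRUE),
                                            sd(x[!f], na.rm = TRUE)),
                     degenerate = FALSE)
    }
  })
  shortlist <- rows$variable[!is.na(rows$p) & rows$p < shortlist_alpha]
  structure(rows, shortlist = shortlist,
            class = c("wes_table1", class(rows)))
}

#' Covariate shortlist of a sex-comparison report
#'
#' @param report A `wes_table1` from [table1_report()].
#' @return Character vector of variables with a sex difference below the
#'   shortlist cut-off.
#' @export
covariate_shortlist <- function(report) {
  attr(report, "shortlist")
}
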