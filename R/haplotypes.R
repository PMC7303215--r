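# EM estimation of multilocus haplotype frequencies from unphased
# genotypes (assuming Hardy-Weinberg diplotype formation), pairwise LD
# statistics, and homozygous-haplotype carrier classification.

hap_string <- function(bits) paste(bits, collapse = "")

# All unordered haplotype pairs compatible with a genotype vector over
# {0,1,2}: hom loci are fixed, the first het locus is pinned to break the
# pair symmetry, remaining het loci enumerate 2^(h-1) configurations.
compatible_pairs <- function(g) {
  L <- length(g)
  het <- which(g == 1L)
  base <- as.integer(g / 2L)  # 0 -> 0, 2 -> 1 at hom loci
  if (length(het) == 0) {
    return(list(list(h1 = hap_string(base), h2 = hap_string(base))))
  }
  free <- het[-1]
  combos <- if (length(free)) {
    as.matrix(expand.grid(rep(list(0:1), length(free))))
  } else matrix(integer(0), nrow = 1, ncol = 0)
  lapply(seq_len(nrow(combos)), function(r) {
    h1 <- base; h2 <- base
    h1[het[1]] <- 0L; h2[het[1]] <- 1L
    if (length(free)) {
      h1[free] <- as.integer(combos[r, ])
      h2[free] <- 1L - as.integer(combos[r, ])
    }
    list(h1 = hap_string(h1), h2 = hap_string(h2))
  })
}

#' EM haplotype frequency estimation
#'
#' Estimates multilocus haplotype frequencies from unphased genotypes at up
#' to 8 loci. The E-step distributes each ambiguous genotype over its
#' compatible diplotypes in proportion to current frequency products
#' (Hardy-Weinberg assumption); the M-step re-estimates frequencies from
#' the expected haplotype counts. Iteration stops when the log-likelihood
#' improves by less than `tol`. Multiple seeded restarts (uniform start
#' plus jittered starts) guard against local maxima; the best-likelihood
#' solution is kept. Subjects with a missing call at any locus are excluded
#' and reported.
#'
#' @param geno Genotype matrix.
#' @param loci Character vector of variant ids (length <= 8).
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param n_restarts Number of jittered restarts in addition to the uniform
#'   start.
#' @param seed Seed for the restart jitter.
#' @return A `hap_model`: list with `loci`, `freqs` (named by 0/1 allele
#'   strings, alternative allele = 1), `loglik`, `trace`, `converged`,
#'   `diplotypes` (per-subject most probable diplotype with its posterior),
#'   `n_excluded`.
#' @export
em_haplotype_freqs <- function(geno, loci, tol = 1e-8, max_iter = 500,
                               n_restarts = 5, seed = 1L) {
  if (length(loci) > 8) abort("at most 8 loci are supported")
  g <- geno[, loci, drop = FALSE]
  ok <- stats::complete.cases(g)
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    inform(paste0(n_excluded, " subject(s) with missing calls excluded ",
                  "from haplotype estimation"))
  }
  g <- g[ok, , drop = FALSE]
  if (nrow(g) == 0) abort("no subjects with complete genotypes at the loci")

  pat_key <- apply(g, 1, paste, collapse = ",")
  pat_tab <- table(pat_key)
  pats <- lapply(strsplit(names(pat_tab), ","), as.integer)
  counts <- as.numeric(pat_tab)
  pairs <- lapply(pats, compatible_pairs)
  haps <- sort(unique(unlist(lapply(pairs, function(pp) {
    unlist(lapply(pp, function(p) c(p$h1, p$h2)))
  }))))
  H <- length(haps)
  # per-pattern index matrices into the haplotype table
  pair_idx <- lapply(pairs, function(pp) {
    cbind(i = match(vapply(pp, `[[`, character(1), "h1"), haps),
          j = match(vapply(pp, `[[`, character(1), "h2"), haps))
  })
  n_sub <- sum(counts)

  run_em <- function(f0) {
    f <- f0 / sum(f0)
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      new_counts <- numeric(H)
      ll <- 0
      for (k in seq_along(pats)) {
        idx <- pair_idx[[k]]
        pp <- f[idx[, "i"]] * f[idx[, "j"]] *
          ifelse(idx[, "i"] == idx[, "j"], 1, 2)
        s <- sum(pp)
        w <- pp / s
        ll <- ll + counts[k] * log(s)
        add <- counts[k] * w
        for (r in seq_len(nrow(idx))) {
          new_counts[idx[r, "i"]] <- new_counts[idx[r, "i"]] + add[r]
          new_counts[idx[r, "j"]] <- new_counts[idx[r, "j"]] + add[r]
        }
      }
      trace <- c(trace, ll)
      if (ll < ll_old - 1e-9) abort("EM log-likelihood decreased")
      if (is.finite(ll_old) && ll - ll_old < tol) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      f <- new_counts / (2 * n_sub)
    }
    list(f = f, loglik = trace[length(trace)], trace = trace,
         converged = converged)
  }

  set.seed(seed)
  starts <- c(list(rep(1, H)),
              lapply(seq_len(n_restarts), function(i) runif(H, 0.5, 1.5)))
  fits <- lapply(starts, run_em)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  f <- setNames(best$f, haps)

  # per-subject posteriors at the final frequencies
  dip <- purrr::map_dfr(seq_along(pats), function(k) {
    idx <- pair_idx[[k]]
    pp <- f[idx[, "i"]] * f[idx[, "j"]] *
      ifelse(idx[, "i"] == idx[, "j"], 1, 2)
    w <- pp / sum(pp)
    b <- which.max(w)
    tibble::tibble(pattern = names(pat_tab)[k],
                   hap1 = haps[idx[b, "i"]], hap2 = haps[idx[b, "j"]],
                   posterior = unname(w[b]))
  })
  diplotypes <- tibble::tibble(subject_id = rownames(g), pattern = pat_key) |>
    dplyr::left_join(dip, by = "pattern") |>
    dplyr::select(-"pattern")

  structure(list(loci = loci, freqs = f, loglik = best$loglik,
                 trace = best$trace, converged = best$converged,
                 diplotypes = diplotypes, n_excluded = n_excluded,
                 pattern_counts = pat_tab, pair_idx = pair_idx,
                 haps = haps, subject_pattern = pat_key),
            class = "hap_model")
}

#' @export
print.hap_model <- function(x, ...) {
  cat("<hap_model> ", length(x$loci), " loci, ",
      sum(x$freqs > 1e-6), " haplotype(s) with non-trivial frequency; ",
      "loglik ", signif(x$loglik, 8),
      if (!x$converged) " (NOT converged)" else "", "\n", sep = "")
  invisible(x)
}

#' Tidy / summarize a haplotype model
#'
#' @param x A `hap_model` from [em_haplotype_freqs()].
#' @param ... Unused.
#' @return `tidy`: tibble of haplotype frequencies. `glance`: one-row
#'   tibble with `loglik`, `n_iter`, `converged`, `n_haplotypes`,
#'   `n_excluded`.
#' @export
tidy.hap_model <- function(x, ...) {
  tibble::tibble(haplotype = names(x$freqs), freq = unname(x$freqs))
}

#' @rdname tidy.hap_model
#' @export
glance.hap_model <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_iter = length(x$trace),
                 converged = x$converged, n_haplotypes = length(x$freqs),
                 n_excluded = x$n_excluded)
}

ld_from_freqs <- function(freqs) {
  need <- c("00", "01", "10", "11")
  f <- setNames(numeric(4), need)
  f[names(freqs)] <- freqs
  p_a <- f[["10"]] + f[["11"]]
  p_b <- f[["01"]] + f[["11"]]
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    return(tibble::tibble(d = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                          p_a = p_a, p_b = p_b, degenerate = TRUE))
  }
  d <- f[["11"]] - p_a * p_b
  d_max <- if (d >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
           else min(p_a * p_b, (1 - p_a) * (1 - p_b))
  tibble::tibble(d = d,
                 d_prime = if (d_max == 0) NA_real_ else abs(d) / d_max,
                 r2 = d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b)),
                 p_a = p_a, p_b = p_b, degenerate = FALSE)
}

#' Pairwise linkage disequilibrium
#'
#' D, D' and r-squared for a pair of loci. Given a genotype matrix, the
#' four two-locus haplotype frequencies are first estimated by EM (phase
#' unknown); alternatively a named frequency vector over `"00"`, `"01"`,
#' `"10"`, `"11"` (alternative allele = 1) can be supplied directly. A
#' monomorphic locus yields flagged `NA`s.
#'
#' @param x Genotype matrix, or a named haplotype frequency vector.
#' @param loci Two variant ids (required when `x` is a genotype matrix).
#' @return Tibble with columns `d`, `d_prime`, `r2`, `p_a`, `p_b`,
#'   `degenerate`.
#' @export
pairwise_ld <- function(x, loci = NULL) {
  if (is.numeric(x) && !is.matrix(x)) {
    return(ld_from_freqs(x))
  }
  if (length(loci) != 2) abort("exactly two loci are required")
  model <- em_haplotype_freqs(x, loci)
  ld_from_freqs(model$freqs)
}

#' Classify subjects homozygous for a target haplotype
#'
#' A subject is called a homozygous carrier when the posterior probability
#' of the (target, target) diplotype, under the fitted haplotype model,
#' exceeds `threshold`. Subjects homozygous at every locus for the target
#' alleles have posterior 1 regardless of the threshold; subjects
#' heterozygous at any locus have posterior 0.
#'
#' @param model A `hap_model`.
#' @param target Haplotype string over 0/1, e.g. `"11111"`.
#' @param threshold Posterior probability cutoff.
#' @return Tibble with `subject_id`, `posterior_hom`, `homozygous`.
#' @export
homozygous_carriers <- function(model, target, threshold = 0.9) {
  if (!target %in% model$haps && !grepl("^[01]+$", target)) {
    abort("target must be a 0/1 haplotype string over the model's loci")
  }
  f <- model$freqs
  t_idx <- match(target, model$haps)
  post_by_pattern <- vapply(seq_along(model$pair_idx), function(k) {
    idx <- model$pair_idx[[k]]
    pp <- f[idx[, "i"]] * f[idx[, "j"]] *
      ifelse(idx[, "i"] == idx[, "j"], 1, 2)
    if (is.na(t_idx)) return(0)
    hit <- idx[, "i"] == t_idx & idx[, "j"] == t_idx
    if (!any(hit)) 0 else sum(pp[hit]) / sum(pp)
  }, numeric(1))
  names(post_by_pattern) <- names(model$pattern_counts)
  post <- unname(post_by_pattern[model$subject_pattern])
  tibble::tibble(subject_id = model$diplotypes$subject_id,
                 posterior_hom = post,
                 homozygous = post > threshold)
}
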