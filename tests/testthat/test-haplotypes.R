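test_that("EM with no phase ambiguity reduces to direct counting", {
  # genotypes where no subject is doubly heterozygous: phase is certain
  g <- rbind(c(0L, 0L), c(2L, 2L), c(2L, 0L), c(0L, 2L), c(1L, 0L),
             c(0L, 0L), c(2L, 2L), c(0L, 1L))
  rownames(g) <- paste0("s", 1:8)
  colnames(g) <- c("a", "b")
  m <- em_haplotype_freqs(g, c("a", "b"))
  # count chromosomes directly: each subject contributes 2 haplotypes
  direct <- c("00" = 0, "01" = 0, "10" = 0, "11" = 0)
  haps <- list(c("00", "00"), c("11", "11"), c("10", "10"), c("01", "01"),
               c("00", "10"), c("00", "00"), c("11", "11"), c("00", "01"))
  for (h in unlist(haps)) direct[h] <- direct[h] + 1
  direct <- direct / 16
  for (h in names(m$freqs)) {
    expect_equal(unname(m$freqs[h]), unname(direct[h]), tolerance = 1e-6)
  }
  expect_true(m$converged)
})

test_that("EM recovers cis phase and matches a grid-search oracle", {
  # simulate 400 subjects from known 2-locus haplotype frequencies
  set.seed(52)
  hf <- c("11" = 0.3, "00" = 0.6, "10" = 0.1)
  draws <- sample(names(hf), 800, replace = TRUE, prob = hf)
  h <- do.call(rbind, strsplit(draws, ""))
  storage.mode(h) <- "integer"
  g <- h[seq(1, 800, 2), ] + h[seq(2, 800, 2), ]
  rownames(g) <- paste0("s", 1:400)
  colnames(g) <- c("a", "b")
  m <- em_haplotype_freqs(g, c("a", "b"))
  expect_gt(m$freqs[["11"]], 0.25)   # cis configuration recovered
  expect_lt(m$freqs[["01"]], 0.05)

  # independent oracle: with p01 ~ 0 the likelihood is effectively a
  # 2-parameter surface; grid-search the simplex and check the EM solution
  # attains at least the best grid log-likelihood
  loglik_at <- function(f) {
    f <- f / sum(f)
    names(f) <- c("00", "01", "10", "11")
    ll <- 0
    for (i in seq_len(nrow(g))) {
      pp <- vapply(sexdiffwes:::compatible_pairs(g[i, ]), function(p) {
        f[p$h1] * f[p$h2] * if (p$h1 == p$h2) 1 else 2
      }, numeric(1))
      ll <- ll + log(sum(pp))
    }
    ll
  }
  grid <- expand.grid(p00 = seq(0.5, 0.7, 0.02),
                      p10 = seq(0.02, 0.18, 0.02),
                      p11 = seq(0.2, 0.4, 0.02))
  grid <- grid[rowSums(grid) < 1, ]
  best_grid <- max(apply(grid, 1, function(r) {
    loglik_at(c(r[["p00"]], 1 - sum(r), r[["p10"]], r[["p11"]]))
  }))
  expect_gte(m$loglik + 1e-6, best_grid)
  # and the EM loglik equals the independent evaluation at its own freqs
  f_em <- setNames(numeric(4), c("00", "01", "10", "11"))
  f_em[names(m$freqs)] <- m$freqs
  expect_equal(m$loglik, loglik_at(f_em), tolerance = 1e-6)
})

test_that("EM recovers the 5-locus generator truth within 3 SE", {
  cfg <- sim_config(n_case_female = 707, n_case_male = 293,
                    n_background = 5, seed = 61)
  sim <- simulate_cohort(cfg)
  block <- sim$truth$blocks[[length(sim$truth$blocks)]]
  expect_equal(length(block$loci), 5)
  m <- em_haplotype_freqs(sim$case$genotypes, block$loci)
  n_chr <- 2 * nrow(sim$case$genotypes)
  for (h in names(block$hap_freqs)) {
    p <- block$hap_freqs[[h]]
    se <- sqrt(p * (1 - p) / n_chr)
    est <- if (h %in% names(m$freqs)) m$freqs[[h]] else 0
    expect_lt(abs(est - p), 3 * se + 1e-9)
  }
})

test_that("EM log-likelihood trace is monotone and frequencies a simplex", {
  sim <- small_sim(seed = 63, nf = 50, nm = 30, n_background = 5)
  block <- sim$truth$blocks[[length(sim$truth$blocks)]]
  m <- em_haplotype_freqs(sim$case$genotypes, block$loci)
  expect_true(all(diff(m$trace) >= -1e-9))
  expect_equal(sum(m$freqs), 1, tolerance = 1e-9)
  expect_true(all(m$freqs >= 0))
  expect_true(m$converged)
  g <- glance(m)
  expect_equal(g$n_iter, length(m$trace))
  expect_error(em_haplotype_freqs(sim$case$genotypes,
                                  colnames(sim$case$genotypes)[1:9]),
               "at most 8")
})

test_that("missing calls are excluded and reported", {
  sim <- small_sim(seed = 64, nf = 30, nm = 20, n_background = 5)
  block <- sim$truth$blocks[[1]]
  g <- sim$case$genotypes
  g[1:3, block$loci[1]] <- NA_integer_
  expect_message(m <- em_haplotype_freqs(g, block$loci), "3 subject")
  expect_equal(m$n_excluded, 3)
  expect_equal(nrow(m$diplotypes), nrow(g) - 3)
})

test_that("LD statistics match the hand-computed haplotype table", {
  # chromosome counts (00, 01, 10, 11) = (30, 10, 10, 50):
  # pA = pB = 0.6, f11 = 0.5, D = 0.5 - 0.36 = 0.14,
  # Dmax = min(0.6*0.4, 0.4*0.6) = 0.24 so D' = 0.5833..., r2 = 0.3403
  f <- c("00" = 0.3, "01" = 0.1, "10" = 0.1, "11" = 0.5)
  ld <- pairwise_ld(f)
  expect_equal(ld$d, 0.14, tolerance = 1e-12)
  expect_equal(ld$d_prime, 0.14 / 0.24, tolerance = 1e-12)
  expect_equal(ld$r2, 0.14^2 / (0.6 * 0.4 * 0.6 * 0.4), tolerance = 1e-12)

  # full association gives D' = r2 = 1; independence gives 0
  perfect <- c("00" = 0.7, "11" = 0.3)
  ldp <- pairwise_ld(perfect)
  expect_equal(ldp$d_prime, 1)
  expect_equal(ldp$r2, 1)
  indep <- c("00" = 0.42, "01" = 0.28, "10" = 0.18, "11" = 0.12)
  ldi <- pairwise_ld(indep)
  expect_equal(ldi$d, 0, tolerance = 1e-12)
  expect_equal(ldi$r2, 0, tolerance = 1e-12)

  mono <- c("00" = 0.4, "01" = 0.6)
  expect_true(pairwise_ld(mono)$degenerate)
})

test_that("LD for independently simulated loci is near zero", {
  set.seed(71)
  g <- cbind(a = rbinom(800, 2, 0.3), b = rbinom(800, 2, 0.4))
  rownames(g) <- paste0("s", 1:800)
  ld <- pairwise_ld(g, c("a", "b"))
  expect_lt(ld$r2, 0.02)
})

test_that("homozygous carrier calls have the right certain and HWE limits", {
  sim <- simulate_cohort(sim_config(n_case_female = 400, n_case_male = 200,
                                    n_background = 5, seed = 73))
  block <- sim$truth$blocks[[length(sim$truth$blocks)]]
  target <- strrep("1", length(block$loci))
  m <- em_haplotype_freqs(sim$case$genotypes, block$loci)
  hc <- homozygous_carriers(m, target)
  g <- sim$case$genotypes[, block$loci]
  all2 <- rownames(g)[rowSums(g == 2) == ncol(g)]
  any_het_or_ref <- rownames(g)[apply(g, 1, function(r) any(r < 2))]
  # all-hom-alt subjects are certain carriers; anything else is not
  expect_true(all(hc$posterior_hom[hc$subject_id %in% all2] > 0.999))
  expect_true(all(!hc$homozygous[hc$subject_id %in% any_het_or_ref]))
  # observed carrier count near the HWE expectation p^2 * n
  p <- block$hap_freqs[[target]]
  n <- nrow(g)
  expect_lt(abs(sum(hc$homozygous) - p^2 * n),
            4 * sqrt(n * p^2 * (1 - p^2)) + 1)
  expect_error(homozygous_carriers(m, "banana"), "0/1 haplotype")
})
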