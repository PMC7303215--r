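test_that("burden counts two planted PTVs in one gene correctly", {
  geno <- matrix(c(1L, 1L,   # s1 carries both variants of gene G1
                   1L, 0L,   # s2 carries one
                   0L, 0L),  # s3 carries none
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("s1", "s2", "s3"), c("v1", "v2")))
  ann <- tibble::tibble(variant_id = c("v1", "v2"), gene = "G1",
                        consequence = "stop_gain", sift = 0.01, cadd = 30,
                        ref_panel_af = 1e-4)
  cohort <- list(genotypes = geno,
                 sex = tibble::tibble(subject_id = rownames(geno),
                                      sex = c("female", "male", "male")),
                 annotations = ann, clinical = NULL, cohort = "case")
  class(cohort) <- "wes_cohort"
  cats <- classify_variants(ann)
  b <- compute_burden(cohort, cats)
  get <- function(lv, s) b$count[b$level == lv & b$subject_id == s &
                                   b$combo == "rare_ptv_deleterious"]
  expect_equal(get("variant", "s1"), 2)
  expect_equal(get("variant", "s2"), 1)
  expect_equal(get("variant", "s3"), 0)
  expect_equal(get("gene", "s1"), 1)   # both variants sit in one gene
  expect_equal(get("gene", "s2"), 1)
  expect_equal(get("gene", "s3"), 0)
})

test_that("vectorized burden equals a per-subject brute-force recount", {
  sim <- small_sim(seed = 23, nf = 25, nm = 15, n_background = 20)
  cohort <- sim$case
  cats <- classify_variants(cohort$annotations)
  genes <- sim$truth$candidate_genes
  b <- compute_burden(cohort, cats, gene_list = genes)
  for (combo in c("functional", "rare_ptv_deleterious", "ptv")) {
    for (lv in c("variant", "gene")) {
      oracle_all <- burden_oracle(cohort$genotypes, cohort$annotations,
                                  cats, unique(cohort$annotations$gene),
                                  combo, lv)
      got <- b[b$scope == "all" & b$level == lv & b$combo == combo, ]
      expect_equal(got$count[match(names(oracle_all), got$subject_id)],
                   unname(oracle_all))
      oracle_cand <- burden_oracle(cohort$genotypes, cohort$annotations,
                                   cats, genes, combo, lv)
      gotc <- b[b$scope == "candidate" & b$level == lv & b$combo == combo, ]
      expect_equal(gotc$count[match(names(oracle_cand), gotc$subject_id)],
                   unname(oracle_cand))
    }
  }
})

test_that("burden respects set-inclusion conservation invariants", {
  sim <- small_sim(seed = 29, nf = 20, nm = 20, n_background = 15)
  cats <- classify_variants(sim$case$annotations)
  b <- burden_wide(compute_burden(sim$case, cats,
                                  gene_list = sim$truth$candidate_genes))
  # rarer / more restrictive categories can never exceed their supersets
  expect_true(all(b$all_variant_rare_functional <= b$all_variant_functional))
  expect_true(all(b$all_variant_ptv <= b$all_variant_functional))
  expect_true(all(b$all_variant_rare_ptv_deleterious <=
                    b$all_variant_rare_ptv))
  # candidate scope is a subset of all genes
  expect_true(all(b$candidate_variant_functional <=
                    b$all_variant_functional))
  # gene-level counts can never exceed variant-level counts
  expect_true(all(b$all_gene_ptv <= b$all_variant_ptv))
})

test_that("rank-sum test reproduces frozen exact oracles", {
  # x = (1,2) vs y = (3,4): U = 0, exact two-sided p = 2/6 = 1/3
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$w, 0)
  expect_equal(r$p, 1 / 3)
  expect_equal(r$method, "exact")
  # all-equal input is degenerate with p = 1
  d <- wilcoxon_rank_sum(c(2, 2, 2), c(2, 2))
  expect_true(d$degenerate)
  expect_equal(d$p, 1)
})

test_that("rank-sum agrees with stats::wilcox.test where both are valid", {
  set.seed(41)
  # untied data, exact regime
  for (i in 1:20) {
    x <- sample(1:100, 5); y <- sample(101:200, 6)
    x <- x + runif(5); y <- y - runif(6) * 150
    ours <- wilcoxon_rank_sum(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$w, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
  # large tied data, normal regime: compare against wilcox.test's
  # tie-corrected normal approximation with continuity correction
  for (i in 1:10) {
    x <- rpois(40, 2); y <- rpois(35, 2.5)
    ours <- wilcoxon_rank_sum(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(ours$w, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
  }
  # one-sided greater
  x <- rpois(30, 3); y <- rpois(30, 2)
  ours <- wilcoxon_rank_sum(x, y, alternative = "greater")
  ref <- suppressWarnings(wilcox.test(x, y, alternative = "greater",
                                      exact = FALSE, correct = TRUE))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
})

test_that("permutation test reproduces the frozen exhaustive oracle", {
  # male burdens (10, 9) vs female (1, 2): of the C(4,2)=6 splits exactly
  # one has rank-sum >= observed, so p = 1/6
  burdens <- c(10, 9, 1, 2)
  sex <- c("male", "male", "female", "female")
  r <- permutation_test(burdens, sex, t = 100, seed = 1)
  expect_true(r$exhaustive)
  expect_equal(r$t, 6)
  expect_equal(r$p_perm, 1 / 6)
  # flat burdens: every permutation ties the observed statistic, p = 1
  flat <- permutation_test(rep(3, 6), rep(c("male", "female"), 3), t = 50)
  expect_equal(flat$p_perm, 1)
})

test_that("sampled permutation p converges to the exhaustive value", {
  set.seed(6)
  burdens <- c(rpois(6, 3), rpois(6, 1.5))
  sex <- rep(c("male", "female"), each = 6)
  exact <- permutation_test(burdens, sex, t = 10)
  expect_true(exact$exhaustive)
  sampled <- permutation_test(burdens, sex, t = 20000, seed = 3,
                              exhaustive_max = 1)
  expect_false(sampled$exhaustive)
  se <- sqrt(exact$p_perm * (1 - exact$p_perm) / 20000)
  expect_lt(abs(sampled$p_perm - exact$p_perm), 4 * se + 1e-12)
  # determinism and seed sensitivity of the sampled path
  again <- permutation_test(burdens, sex, t = 20000, seed = 3,
                            exhaustive_max = 1)
  expect_identical(sampled$permuted_ws, again$permuted_ws)
})

test_that("glance annotates sampled zero counts as below resolution", {
  b <- c(rep(100, 5), rep(0, 5))
  sex <- rep(c("male", "female"), each = 5)
  r <- permutation_test(b, sex, t = 50, seed = 2, exhaustive_max = 1)
  g <- glance(r)
  if (r$c == 0) expect_equal(g$note, "< 1/T") else expect_true(is.na(g$note))
  expect_equal(g$p_perm, r$c / r$t)
})

test_that("the relative-burden grid covers all 32 cells", {
  sim <- small_sim(seed = 37, nf = 30, nm = 20, n_background = 15)
  cats <- classify_variants(sim$case$annotations)
  b <- compute_burden(sim$case, cats, gene_list = sim$truth$candidate_genes)
  s <- relative_burden_summary(b, sim$case$sex)
  expect_equal(nrow(s), 32)
  expect_equal(sort(unique(s$combo)), sort(combo_names()))
  expect_equal(sort(unique(s$scope)), c("all", "candidate"))
  expect_equal(sort(unique(s$level)), c("gene", "variant"))
  expect_true(all(s$p >= 0 & s$p <= 1))
  # the ratio label agrees with the means
  nz <- !is.na(s$relative_burden) & is.finite(s$relative_burden) &
    s$relative_burden != 1
  expect_equal(s$enriched_sex[nz],
               ifelse(s$relative_burden[nz] > 1, "male", "female"))
})
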