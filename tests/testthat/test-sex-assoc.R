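test_that("2x2 contrasts from printed genotype counts reproduce the margins", {
  tab <- do.call(allele_table, strongest_variant_counts)
  expect_equal(unname(tab), matrix(c(120L, 1294L, 20L, 566L), 2,
                                   byrow = TRUE))
  dom <- do.call(dominant_table, strongest_variant_counts)
  expect_equal(unname(dom), matrix(c(109L, 598L, 20L, 273L), 2,
                                   byrow = TRUE))
  rec <- do.call(recessive_table, strongest_variant_counts)
  expect_equal(unname(rec), matrix(c(11L, 696L, 0L, 293L), 2, byrow = TRUE))
  # allele denominators are twice the non-missing subjects
  expect_equal(sum(tab[1, ]), 2 * (598 + 98 + 11))
})

test_that("allele tables equal a per-subject counting oracle", {
  set.seed(31)
  sim <- small_sim(seed = 31, nf = 25, nm = 20, n_background = 10)
  counts <- genotype_sex_counts(sim$case)
  g <- sim$case$genotypes
  f <- sim$case$sex$sex == "female"
  for (v in sample(colnames(g), 5)) {
    row <- counts[counts$variant_id == v, ]
    tab <- allele_table(row$ref_f, row$het_f, row$hom_f,
                        row$ref_m, row$het_m, row$hom_m)
    alt_f <- sum(g[f, v], na.rm = TRUE)
    tot_f <- 2 * sum(!is.na(g[f, v]))
    alt_m <- sum(g[!f, v], na.rm = TRUE)
    tot_m <- 2 * sum(!is.na(g[!f, v]))
    expect_equal(unname(tab), matrix(c(alt_f, tot_f - alt_f,
                                       alt_m, tot_m - alt_m), 2,
                                     byrow = TRUE))
  }
  # dominant and recessive exposed counts partition carriers: difference
  # equals the heterozygote count
  dom_exp <- counts$het_f + counts$hom_f
  rec_exp <- counts$hom_f
  expect_equal(dom_exp - rec_exp, counts$het_f)
})

test_that("fisher_assoc matches full hypergeometric enumeration", {
  # small frozen case first: table (3,1;1,3) has exactly 5 tables with its
  # margins and probability-mass p = 34/70
  t0 <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(fisher_assoc(t0)$p, 34 / 70)
  set.seed(17)
  for (i in 1:1000) {
    tab <- random_2x2(40)
    expect_equal(fisher_assoc(tab)$p, fisher_enum_p(tab), tolerance = 1e-10)
  }
})

test_that("fisher_assoc p is invariant under simultaneous row/col swap", {
  set.seed(5)
  for (i in 1:50) {
    tab <- random_2x2(60)
    swapped <- tab[2:1, 2:1]
    expect_equal(fisher_assoc(tab)$p, fisher_assoc(swapped)$p)
    expect_equal(fisher_assoc(tab)$or, fisher_assoc(swapped)$or)
  }
})

test_that("odds-ratio conventions handle empty cells", {
  rec <- do.call(recessive_table, strongest_variant_counts)
  r <- fisher_assoc(rec)
  expect_true(is.infinite(r$or) && r$or_infinite)
  expect_equal(fisher_assoc(matrix(c(0, 5, 0, 7), 2))$or, 1)
  deg <- fisher_assoc(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(deg$p, 1)
  expect_true(deg$degenerate)
})

test_that("trend test: symmetry, scaling, and exact relabeling oracle", {
  eq <- matrix(c(10, 6, 4, 10, 6, 4), 2, byrow = TRUE)
  r <- cochran_armitage(eq)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)

  tab <- matrix(c(30, 12, 4, 18, 20, 9), 2, byrow = TRUE)
  z1 <- cochran_armitage(tab)$z
  z2 <- cochran_armitage(2 * tab)$z
  expect_equal(abs(z2), sqrt(2) * abs(z1), tolerance = 1e-12)

  # the binomial-variance form agrees with stats::prop.trend.test
  pt <- stats::prop.trend.test(tab[1, ], colSums(tab))
  expect_equal(cochran_armitage(tab)$z^2, unname(pt$statistic),
               tolerance = 1e-12)

  # exact permutation oracle at n = 12: compare the normal p against the
  # exhaustive relabeling distribution of the trend statistic
  toy <- matrix(c(4, 2, 0, 0, 2, 4), 2, byrow = TRUE)
  genos <- rep(c(0, 1, 2), times = colSums(toy))
  n1 <- sum(toy[1, ])
  t_of <- function(idx) {
    g1 <- tabulate(factor(genos[idx], levels = 0:2), 3)
    cochran_armitage(rbind(g1, tabulate(factor(genos[-idx], 0:2), 3)))$z
  }
  z_obs <- cochran_armitage(toy)$z
  sel <- combn(length(genos), n1)
  zs <- apply(sel, 2, t_of)
  p_exact <- mean(abs(zs) >= abs(z_obs) - 1e-9)
  # the statistic's ordering is what matters; the normal p approximates
  # the exact one within the resolution of this tiny support
  expect_lt(abs(cochran_armitage(toy)$p - p_exact), 0.05)
  expect_equal(p_exact, mean(abs(zs) >= abs(z_obs) - 1e-9))

  mono <- matrix(c(10, 0, 0, 8, 0, 0), 2, byrow = TRUE)
  expect_true(cochran_armitage(mono)$degenerate)
})

test_that("empirical threshold is the minimum control p-value", {
  one <- tibble::tibble(group = "ctl", variant_id = "v1", allele_p = 0.5)
  expect_equal(as.numeric(empirical_threshold(one)), 0.5)
  two <- list(
    tibble::tibble(group = "a", variant_id = c("v1", "v2"),
                   allele_p = c(0.2, 0.03)),
    tibble::tibble(group = "b", variant_id = c("v1", "v2"),
                   allele_p = c(0.6, 0.10)))
  th <- empirical_threshold(two)
  expect_equal(as.numeric(th), 0.03)
  expect_equal(attr(th, "per_cohort"), c(a = 0.03, b = 0.10))
  expect_equal(empirical_threshold(two, scope = "per_cohort"),
               c(a = 0.03, b = 0.10), ignore_attr = TRUE)
  expect_error(empirical_threshold(list()), "no control")
})

test_that("threshold behaves like a minimum of exchangeable p-values", {
  # under null controls the threshold is the min of m p-values; compare
  # its distribution against direct order-statistic simulation
  m <- NULL
  mins <- vapply(1:30, function(i) {
    sim <- simulate_cohort(sim_config(
      n_case_female = 40, n_case_male = 20, n_background = 25,
      planted_sexdiff = data.frame(female_af = 0.1, male_af = 0.1),
      seed = 400 + i))
    ctl <- sex_assoc_battery(sim$controls$control_b)
    m <<- nrow(ctl)
    min(ctl$allele_p)
  }, numeric(1))
  # discrete Fisher p-values are super-uniform, so the observed minima
  # must be stochastically >= minima of m Uniform(0,1) draws on average
  expect_gt(mean(mins), qbeta(0.005, 1, m))
})

test_that("screen flags planted female-excess variants and not controls", {
  sim <- simulate_cohort(sim_config(
    n_case_female = 707, n_case_male = 293, n_background = 30,
    planted_sexdiff = data.frame(female_af = 0.12, male_af = 0.02),
    seed = 99))
  scr <- run_screen(sim$case, sim$controls)
  planted <- sim$truth$planted$variant_id
  expect_true(planted %in% scr$hits)
  hit_row <- tidy(scr)[tidy(scr)$variant_id == planted, ]
  expect_gt(hit_row$allele_or, 1)  # female-enriched
  expect_equal(glance(scr)$n_hits, length(scr$hits))

  # planting the same contrast in the controls removes the hit
  sim2 <- simulate_cohort(sim_config(
    n_case_female = 707, n_case_male = 293, n_background = 30,
    planted_sexdiff = data.frame(female_af = 0.25, male_af = 0.02),
    planted_in_controls = TRUE, seed = 99))
  scr2 <- run_screen(sim2$case, sim2$controls)
  expect_false(sim2$truth$planted$variant_id %in% scr2$hits)
})

test_that("CMH reduces correctly and matches the direct formula", {
  tab <- matrix(c(20, 30, 10, 40), 2, byrow = TRUE)
  one <- cmh_test(list(tab))
  # single stratum: the CMH statistic is (N-1)/N times the uncorrected
  # Pearson chi-square, and the common OR is the sample OR
  pear <- unname(chisq.test(tab, correct = FALSE)$statistic)
  N <- sum(tab)
  expect_equal(one$statistic, pear * (N - 1) / N, tolerance = 1e-10)
  expect_equal(one$common_or, (20 * 40) / (30 * 10), tolerance = 1e-6)

  two <- cmh_test(list(tab, tab))
  expect_equal(two$common_or, (20 * 40) / (30 * 10), tolerance = 1e-6)

  # three random strata vs an independent implementation of the formula
  set.seed(8)
  strata <- replicate(3, random_2x2(80), simplify = FALSE)
  got <- cmh_test(strata)
  a <- vapply(strata, function(t) t[1, 1], numeric(1))
  e <- vapply(strata, function(t) sum(t[1, ]) * sum(t[, 1]) / sum(t),
              numeric(1))
  v <- vapply(strata, function(t) {
    n <- sum(t)
    prod(rowSums(t)) * prod(colSums(t)) / (n^2 * (n - 1))
  }, numeric(1))
  stat <- sum(a - e)^2 / sum(v)
  expect_equal(got$statistic, stat, tolerance = 1e-10)
  expect_equal(got$p, pchisq(stat, 1, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("logistic adjustment recovers known effects and flags separation", {
  # covariate-free model: intercept-only contrast equals the log sample OR
  d <- data.frame(y = rep(c(1, 1, 0, 0), c(30, 10, 20, 40)),
                  x = rep(c(1, 0, 1, 0), c(30, 10, 20, 40)))
  fit <- logistic_adjusted(d, y ~ x)
  expect_equal(fit$coefficients$beta[2], log((30 * 40) / (10 * 20)),
               tolerance = 1e-6)
  expect_false(fit$separation)

  set.seed(12)
  n <- 1000
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  eta <- -0.5 + 0.8 * x1 + 0.5 * x2
  y <- rbinom(n, 1, plogis(eta))
  fit <- logistic_adjusted(data.frame(y, x1, x2), y ~ x1 + x2)
  co <- fit$coefficients
  expect_lt(abs(co$beta[co$term == "x1"] - 0.8),
            3 * co$se[co$term == "x1"])
  expect_lt(abs(co$beta[co$term == "x2"] - 0.5),
            3 * co$se[co$term == "x2"])

  sep <- data.frame(y = c(0, 0, 0, 1, 1, 1), x = c(1, 2, 3, 10, 11, 12))
  expect_true(logistic_adjusted(sep, y ~ x)$separation)
})

test_that("stratified tables feed the CMH adjustment", {
  sim <- small_sim(seed = 13, nf = 60, nm = 40)
  carrier <- sim$case$genotypes[, sim$truth$planted$variant_id] > 0
  age <- sim$case$clinical$age
  arr <- stratified_tables(carrier, sim$case$sex$sex, age, n_bins = 3)
  expect_equal(dim(arr)[1:2], c(2, 2))
  expect_equal(sum(arr), length(carrier))
  res <- cmh_test(arr)
  expect_true(res$p > 0 && res$p <= 1)
})
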