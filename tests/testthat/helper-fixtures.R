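# Shared fixtures and independent oracles, built in code at test time.

# small simulated study reused across tests
small_sim <- function(seed = 7, nf = 120, nm = 60, n_background = 40) {
  simulate_cohort(sim_config(n_case_female = nf, n_case_male = nm,
                             n_background = n_background, seed = seed))
}

# independent Fisher oracle: full hypergeometric enumeration with the
# probability-mass two-sided rule
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # column 1 total
  ks <- max(0, k - n):min(k, m)
  probs <- dhyper(ks, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_2x2 <- function(max_total = 40) {
  repeat {
    tot <- sample(4:max_total, 1)
    x <- as.vector(stats::rmultinom(1, tot, runif(4, 0.05, 1)))
    tab <- matrix(x, 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

# brute-force per-subject burden recount (independent of compute_burden's
# vectorized path)
burden_oracle <- function(geno, ann, categories, gene_scope_genes, combo,
                          level) {
  members <- categories$variant_id[categories[[combo]]]
  members <- members[ann$gene[match(members, ann$variant_id)] %in%
                       gene_scope_genes]
  vapply(rownames(geno), function(s) {
    carried <- character(0)
    for (v in members) {
      g <- geno[s, v]
      if (!is.na(g) && g > 0) carried <- c(carried, v)
    }
    if (level == "variant") {
      length(carried)
    } else {
      length(unique(ann$gene[match(carried, ann$variant_id)]))
    }
  }, numeric(1))
}

# genotype counts for the strongest variant of the study's Table-style
# printed rows: female (ref, het, hom) = (598, 98, 11), male (273, 20, 0)
strongest_variant_counts <- list(ref_f = 598L, het_f = 98L, hom_f = 11L,
                     ref_m = 273L, het_m = 20L, hom_m = 0L)
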