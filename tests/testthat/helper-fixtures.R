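# Small in-code fixtures shared across test files.

# Complete (no-missing) multi-group founder matrix.
make_founders <- function(n_per = 100L, n_groups = 2L, n_snps = 300L,
                          fst = 0.1, seed = 1L, missing_rate = 0) {
  labels <- c("African", "American", "East Asian", "European",
              "South Asian", "West Asian")[seq_len(n_groups)]
  simulate_founders(founder_config(
    group_sizes = stats::setNames(rep(n_per, n_groups), labels),
    n_snps = n_snps, fst = fst, maf_range = c(0.1, 0.5),
    missing_rate = missing_rate, seed = seed))
}

# Random valid geno_matrix (possibly with missing values).
make_random_gm <- function(n = 20L, p = 50L, missing_rate = 0.05, seed = 99L) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * p, replace = TRUE), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("snp%03d", seq_len(p))))
  if (missing_rate > 0) g[runif(n * p) < missing_rate] <- NA_integer_
  geno_matrix(g, ancestry = sample(c("African", "European"), n, replace = TRUE))
}

# Independent exact-HWE oracle: direct log-factorial enumeration over all
# heterozygote counts compatible with the allele counts (no recurrence).
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0) return(1.0)
  ks <- seq(n_rare %% 2, n_rare, by = 2)
  logw <- ks * log(2) - lfactorial((n_rare - ks) / 2) - lfactorial(ks) -
    lfactorial(n - ks - (n_rare - ks) / 2)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  w_obs <- w[ks == n_het]
  min(1, sum(w[w <= w_obs * (1 + 1e-10)]))
}

# A complete one-group matrix with PCA model and geometry, for synthesis
# tests.
make_synth_setup <- function(n = 300L, n_snps = 300L, seed = 3L) {
  gm <- make_founders(n_per = n, n_groups = 1L, n_snps = n_snps, seed = seed)
  model <- fit_pca(gm, 20L)
  geom <- group_geometry(model, gm)[[1L]]
  list(gm = gm, model = model, geom = geom)
}

# Balanced binary phenotype vector of length n.
make_balanced_phenotype <- function(n, seed = 1L) {
  set.seed(seed)
  y <- sample(rep(0:1, length.out = n))
  phenotype_set(stats::setNames(y, sprintf("s%06d", seq_len(n))),
                case_fraction = 0.5)
}
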