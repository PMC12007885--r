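test_that("flip probabilities follow the randomized-response formulas", {
  p <- ldp_params(6)
  expect_equal(p$q_extreme, 2 / (exp(6) + 2))
  expect_equal(p$q_het, 1 / (exp(6) + 2))
  expect_equal(p$q_extreme, 2 * p$q_het)
  # per-state transition rows sum to 1 exactly
  expect_equal((1 - p$q_extreme) + p$q_extreme, 1)
  expect_equal((1 - 2 * p$q_het) + 2 * p$q_het, 1)
  expect_error(ldp_params(0), "positive")
  expect_error(ldp_params(6, d = 4), "d = 3")
})

test_that("empirical transition frequencies match the formulas at eps 1 and 6", {
  n <- 1e6L
  for (eps in c(1, 6)) {
    prm <- ldp_params(eps)
    set.seed(100 + eps)

    out0 <- perturb_genotypes(rep(0L, n), prm)
    f01 <- mean(out0 == 1L)
    se <- sqrt(prm$q_extreme * (1 - prm$q_extreme) / n)
    expect_lt(abs(f01 - prm$q_extreme), 3 * se)
    expect_equal(sum(out0 == 2L), 0L)  # 0 -> 2 never happens

    out2 <- perturb_genotypes(rep(2L, n), prm)
    expect_lt(abs(mean(out2 == 1L) - prm$q_extreme), 3 * se)
    expect_equal(sum(out2 == 0L), 0L)  # 2 -> 0 never happens

    out1 <- perturb_genotypes(rep(1L, n), prm)
    se1 <- sqrt(prm$q_het * (1 - prm$q_het) / n)
    expect_lt(abs(mean(out1 == 0L) - prm$q_het), 3 * se1)
    expect_lt(abs(mean(out1 == 2L) - prm$q_het), 3 * se1)
  }
})

test_that("very large epsilon leaves genotypes untouched", {
  prm <- ldp_params(50)
  g <- rep(0:2, length.out = 3e5L)
  expect_identical(perturb_genotypes(g, prm), g)
})

test_that("perturbation rejects missing or invalid genotypes", {
  prm <- ldp_params(6)
  expect_error(perturb_genotypes(c(0L, NA, 1L), prm), "missing")
  expect_error(perturb_genotypes(c(0L, 3L), prm), "\\{0, 1, 2\\}")
})

test_that("expected modified fraction matches the state-frequency formula", {
  prm <- ldp_params(3)
  set.seed(41)
  g <- sample(0:2, 4e5L, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  out <- perturb_genotypes(g, prm)
  pi_ <- tabulate(g + 1L, 3L) / length(g)
  expected <- pi_[1] * prm$q_extreme + pi_[2] * 2 * prm$q_het +
    pi_[3] * prm$q_extreme
  observed <- mean(out != g)
  expect_lt(abs(observed - expected),
            3 * sqrt(expected * (1 - expected) / length(g)))
})

test_that("group synthesis reaches the target with correct labels and no clones", {
  setup <- make_synth_setup(n = 5L, n_snps = 200L, seed = 23L)
  cfg <- synthesis_config(per_group_target = 10L, seed = 2L)
  out <- synthesize_group(setup$gm, setup$model, setup$geom, cfg, ldp_params(6))
  expect_equal(nrow(genotypes_of(out)), 10L)
  expect_true(all(ancestry_of(out) == unique(ancestry_of(setup$gm))))

  cfg0 <- synthesis_config(per_group_target = 0L)
  out0 <- synthesize_group(setup$gm, setup$model, setup$geom, cfg0, ldp_params(6))
  expect_equal(nrow(genotypes_of(out0)), 0L)
})

test_that("no accepted synthetic sample can equal any original under the strict filter", {
  setup <- make_synth_setup(n = 20L, n_snps = 100L, seed = 24L)
  cfg <- synthesis_config(per_group_target = 50L, seed = 3L,
                          identity_filter = "all")
  out <- synthesize_group(setup$gm, setup$model, setup$geom, cfg, ldp_params(4))
  keys_orig <- apply(genotypes_of(setup$gm), 1L, paste, collapse = ",")
  keys_syn <- apply(genotypes_of(out), 1L, paste, collapse = ",")
  expect_false(any(keys_syn %in% keys_orig))
})

test_that("synthetic allele frequencies track the originals closely at eps 6", {
  setup <- make_synth_setup(n = 300L, n_snps = 100L, seed = 25L)
  cfg <- synthesis_config(per_group_target = 5000L, seed = 4L)
  out <- synthesize_group(setup$gm, setup$model, setup$geom, cfg, ldp_params(6))
  maf_orig <- apply(genotypes_of(setup$gm), 2L, compute_maf)
  maf_syn <- apply(genotypes_of(out), 2L, compute_maf)
  expect_lt(max(abs(maf_orig - maf_syn)), 0.02)
})

test_that("an unreachable acceptance target reports the acceptance rate", {
  setup <- make_synth_setup(n = 20L, n_snps = 100L, seed = 26L)
  tight <- setup$geom
  tight$radius <- 0  # nothing can be consistent
  cfg <- synthesis_config(per_group_target = 5L, max_attempts = 2L, seed = 5L)
  expect_error(
    synthesize_group(setup$gm, setup$model, tight, cfg, ldp_params(6)),
    "acceptance rate")
})

test_that("random sample IDs are unique, ascending and reproducible", {
  cfg <- synthesis_config(id_range = c(100L, 999L), seed = 11L)
  ids <- assign_sample_ids(20L, cfg)
  expect_length(ids, 20L)
  expect_false(is.unsorted(ids, strictly = TRUE))
  expect_true(all(ids >= 100L & ids <= 999L))
  expect_identical(assign_sample_ids(20L, cfg), ids)

  full <- assign_sample_ids(10L, synthesis_config(id_range = c(1L, 10L), seed = 1L))
  expect_identical(full, 1:10)  # pigeonhole: the whole range, in order
  expect_error(assign_sample_ids(11L, synthesis_config(id_range = c(1L, 10L))),
               "exhausted")
})
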