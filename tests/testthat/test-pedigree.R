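test_that("Mendelian transmission matches the per-genotype distributions", {
  n <- 1e5L
  set.seed(60)
  off01 <- mendelian_offspring(rep(0L, n), rep(1L, n))
  f <- tabulate(off01 + 1L, 3L) / n
  se <- 3 * sqrt(0.25 / n)
  expect_lt(abs(f[1] - 0.5), se)
  expect_lt(abs(f[2] - 0.5), se)
  expect_equal(f[3], 0)

  off11 <- mendelian_offspring(rep(1L, n), rep(1L, n))
  f11 <- tabulate(off11 + 1L, 3L) / n
  expect_lt(abs(f11[1] - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  expect_lt(abs(f11[2] - 0.50), 3 * sqrt(0.25 / n))
  expect_lt(abs(f11[3] - 0.25), 3 * sqrt(0.25 * 0.75 / n))

  expect_true(all(mendelian_offspring(rep(0L, 1000L), rep(0L, 1000L)) == 0L))
  expect_true(all(mendelian_offspring(rep(2L, 1000L), rep(2L, 1000L)) == 2L))
  expect_true(all(mendelian_offspring(rep(0L, 1000L), rep(2L, 1000L)) == 1L))
})

test_that("offspring are always Mendel-consistent over random parents", {
  set.seed(61)
  n <- 1e5L
  pa <- sample(0:2, n, replace = TRUE)
  pb <- sample(0:2, n, replace = TRUE)
  off <- mendelian_offspring(pa, pb)
  # each parent transmits at least one alt allele iff homozygous alternate,
  # and cannot transmit one iff homozygous reference
  expect_true(all(off >= (pa == 2L) + (pb == 2L)))
  expect_true(all(off <= (pa > 0L) + (pb > 0L)))
  expect_error(mendelian_offspring(c(0L, NA), c(1L, 1L)), "missing")
  expect_error(mendelian_offspring(0L, c(1L, 1L)), "length")
})

test_that("KING coefficient reproduces hand-counted examples", {
  # n11 = 1, n02 = n20 = 0, n1* = 3, n*1 = 1 -> (2 - 0 - 1 + 3) / 12 = 1/3
  expect_equal(king_coefficient(c(1, 1, 0, 2, 1), c(1, 0, 0, 2, 2)), 1 / 3)
  set.seed(62)
  for (i in 1:10) {
    x <- sample(0:2, 50, replace = TRUE)
    if (!any(x == 1L)) x[1L] <- 1L
    expect_equal(king_coefficient(x, x), 0.5)  # self-kinship
  }
  expect_error(king_coefficient(c(0, 2, 0), c(1, 1, 0)), "no heterozygous")
})

test_that("parent-offspring pairs score near the first-degree expectation", {
  gm <- make_founders(n_per = 200L, n_groups = 1L, n_snps = 2000L, seed = 63L)
  g <- genotypes_of(gm)
  set.seed(64)
  kings <- replicate(100, {
    pair <- sample(nrow(g), 2L)
    child <- mendelian_offspring(g[pair[1L], ], g[pair[2L], ])
    king_coefficient(child, g[pair[1L], ])
  })
  expect_gt(mean(kings), 0.20)
  expect_lt(mean(kings), 0.30)
})

test_that("the default schedule yields 350 relatives with the declared degrees", {
  gm <- make_founders(n_per = 450L, n_groups = 1L, n_snps = 200L, seed = 65L)
  sched <- generation_schedule(seed = 66L)
  out <- simulate_generations(gm, sched)
  expect_equal(nrow(genotypes_of(out$relatives)), 350L)
  expect_setequal(unique(out$kinship$degree),
                  c("first-degree", "second-degree", "third-degree"))
  # all recorded IDs resolve to founders or relatives
  known <- c(sample_ids(gm), sample_ids(out$relatives))
  expect_true(all(out$kinship$sample_id %in% sample_ids(out$relatives)))
  expect_true(all(out$kinship$related_sample_id %in% known))
})

test_that("KING decreases with relationship degree and unrelated pairs sit lowest", {
  gm <- make_founders(n_per = 450L, n_groups = 1L, n_snps = 400L, seed = 67L)
  out <- simulate_generations(gm, generation_schedule(seed = 68L))
  means <- tapply(out$kinship$king, out$kinship$degree, mean)
  expect_gt(means[["first-degree"]], means[["second-degree"]])
  expect_gt(means[["second-degree"]], means[["third-degree"]])

  g <- genotypes_of(gm)
  set.seed(69)
  unrelated <- replicate(100, {
    pair <- sample(nrow(g), 2L)
    king_coefficient(g[pair[1L], ], g[pair[2L], ])
  })
  expect_gt(means[["third-degree"]], mean(unrelated))
})

test_that("a toy two-generation schedule produces the exact pedigree trace", {
  gm <- make_founders(n_per = 4L, n_groups = 1L, n_snps = 100L, seed = 70L)
  sched <- generation_schedule(n_founders_selected = 4L,
                               descendants = c(2L, 1L), seed = 71L)
  out <- simulate_generations(gm, sched)
  expect_equal(nrow(genotypes_of(out$relatives)), 3L)
  per_desc <- table(out$kinship$sample_id)
  # the generation-2 child has 2 first-degree + 4 second-degree ancestors
  expect_setequal(as.integer(per_desc), c(2L, 2L, 6L))
  gen2 <- names(per_desc)[per_desc == 6L]
  gen2_deg <- table(out$kinship$degree[out$kinship$sample_id == gen2])
  expect_equal(as.integer(gen2_deg[c("first-degree", "second-degree")]),
               c(2L, 4L))
})

test_that("empty and infeasible schedules are handled", {
  gm <- make_founders(n_per = 10L, n_groups = 1L, n_snps = 50L, seed = 72L)
  empty <- simulate_generations(gm, generation_schedule(
    n_founders_selected = 4L, descendants = integer(0)))
  expect_equal(nrow(genotypes_of(empty$relatives)), 0L)
  expect_equal(nrow(empty$kinship), 0L)

  expect_error(generation_schedule(n_founders_selected = 4L,
                                   descendants = c(3L)),
               "infeasible")
  expect_error(simulate_generations(gm, generation_schedule(
    n_founders_selected = 20L, descendants = c(10L))),
    "founders")
})
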