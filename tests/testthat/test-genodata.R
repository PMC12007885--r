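test_that("sample SNP CSV parsing handles the documented layout", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,ancestry,snp1,snp2",
               "s1,African,0,1",
               "s2,European,2,NA",
               "s3,African,1,0"), path)
  gm <- read_sample_snp_csv(path)
  expect_s3_class(gm, "geno_matrix")
  expect_equal(dim(gm), c(3L, 2L))
  expect_equal(sample_ids(gm), c("s1", "s2", "s3"))
  expect_equal(unname(ancestry_of(gm)), c("African", "European", "African"))
  expect_identical(genotypes_of(gm)["s2", "snp2"], NA_integer_)
})

test_that("invalid genotype cells and duplicate IDs are hard errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,ancestry,snp1,snp2",
               "s1,African,0,3",
               "s2,European,2,1"), path)
  expect_error(read_sample_snp_csv(path), "invalid genotype '3'.*snp2")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,ancestry,snp1",
               "s1,African,0",
               "s1,European,2"), path2)
  expect_error(read_sample_snp_csv(path2), "duplicate sample IDs")
})

test_that("write-then-read round-trip is the identity on a random matrix", {
  gm <- make_random_gm(20L, 50L, missing_rate = 0.05)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_snp_csv(gm, path)
  back <- read_sample_snp_csv(path)
  expect_identical(genotypes_of(back), genotypes_of(gm))
  expect_identical(ancestry_of(back), ancestry_of(gm))
})

test_that("constructor enforces the container invariants", {
  g <- matrix(0:3, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(geno_matrix(g, ancestry = c("A", "B")), "outside \\{0,1,2,NA\\}")
  g2 <- matrix(0L, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(geno_matrix(g2, ancestry = c("A", "B")), "duplicate sample IDs")
  g3 <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(geno_matrix(g3, ancestry = "A"), "one label per sample")
})

make_toy_bundle <- function(n = 10L, n_wm = 2L, n_snps = 5L, seed = 42L) {
  set.seed(seed)
  gm <- make_random_gm(n, n_snps, missing_rate = 0, seed = seed)
  ph <- phenotype_set(stats::setNames(rep_len(0:1, n), sample_ids(gm)),
                      case_fraction = 0.5)
  wm_g <- matrix(sample(0:2, n * n_wm, replace = TRUE), n, n_wm,
                 dimnames = list(sample_ids(gm), paste0("rs", seq_len(n_wm))))
  wm <- watermark_block(wm_g, p_values = runif(n_wm))
  rel <- geno_matrix(genotypes_of(gm)[1:2, , drop = FALSE],
                     ancestry = ancestry_of(gm)[1:2],
                     sample_ids = c("r1", "r2"))
  kin <- data.frame(sample_id = "r1", related_sample_id = sample_ids(gm)[1],
                    degree = "first-degree", king = 0.25,
                    stringsAsFactors = FALSE)
  dataset_bundle(gm, rel, ph, wm, kin)
}

test_that("five-file bundle export matches the documented layouts", {
  b <- make_toy_bundle()
  dir <- withr::local_tempdir()
  paths <- write_bundle(b, dir)
  expect_length(paths, 5L)
  expect_true(all(file.exists(paths)))

  wm_lines <- readLines(paths[3L])
  expect_length(wm_lines, 1L + 10L + 1L)  # header + samples + p-value row
  expect_match(wm_lines[length(wm_lines)], "^p_value,")
  expect_equal(length(strsplit(wm_lines[1L], ",")[[1L]]), 1L + 2L)

  ph <- read.csv(paths[2L])
  expect_equal(ncol(ph), 2L)
  expect_equal(nrow(ph), 10L)

  kin <- read.csv(paths[4L], colClasses = "character")
  expect_equal(names(kin), c("sample_id", "related_sample_id",
                             "relatedness", "kinship_coefficient"))

  rel_header <- strsplit(readLines(paths[5L], n = 1L), ",")[[1L]]
  expect_equal(rel_header, c("sample_id", snp_ids(b$samples)))
})

test_that("empty kinship exports a header-only file", {
  b <- make_toy_bundle()
  b$kinship <- empty_kinship()
  dir <- withr::local_tempdir()
  paths <- write_bundle(b, dir)
  expect_length(readLines(paths[4L]), 1L)
})

test_that("bundle invariants: SNP-axis match and known kinship IDs", {
  b <- make_toy_bundle()
  bad_rel <- geno_matrix(genotypes_of(b$relatives)[, 1:3, drop = FALSE],
                         ancestry = ancestry_of(b$relatives))
  expect_error(dataset_bundle(b$samples, bad_rel, b$phenotype, b$watermark),
               "SNP axis")
  bad_kin <- data.frame(sample_id = "ghost", related_sample_id = "r1",
                        degree = "first-degree", king = 0.2)
  expect_error(dataset_bundle(b$samples, b$relatives, b$phenotype,
                              b$watermark, bad_kin),
               "unknown sample IDs")
})

test_that("VCF import collapses GT calls to additive counts", {
  skip_if_not_installed("vcfR")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t1/1\t./."), path)
  gm <- read_vcf_genotypes(path)
  g <- genotypes_of(gm)
  expect_equal(unname(g["s1", ]), c(0L, 2L))
  expect_equal(unname(g["s2", "v1"]), 1L)
  expect_true(is.na(g["s2", "v2"]))
})
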