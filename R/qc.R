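#' Quality-control thresholds
#'
#' Defaults mirror common PLINK practice for array data: drop SNPs with
#' minor allele frequency below 1%, SNP or sample missingness above 5%, and
#' exact Hardy-Weinberg test p-values below 1e-6.
#'
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param snp_missing_max maximum per-SNP missing rate (default 0.05).
#' @param hwe_p_min minimum exact HWE p-value (default 1e-6).
#' @param sample_missing_max maximum per-sample missing rate (default 0.05).
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, snp_missing_max = 0.05,
                          hwe_p_min = 1e-6, sample_missing_max = 0.05) {
  vals <- c(maf_min, snp_missing_max, hwe_p_min, sample_missing_max)
  if (any(vals < 0 | vals > 1)) stop("all thresholds must lie in [0, 1]")
  if (maf_min > 0.5) stop("maf_min cannot exceed 0.5")
  structure(list(maf_min = maf_min, snp_missing_max = snp_missing_max,
                 hwe_p_min = hwe_p_min, sample_missing_max = sample_missing_max),
            class = "qc_thresholds")
}

#' Minor allele frequency of one genotype column
#'
#' Alternate-allele count over twice the number of non-missing genotypes,
#' folded to the minor side (always <= 0.5).
#'
#' @param genotype_column integer vector in \{0, 1, 2, NA\}.
#' @return the minor allele frequency.
#' @examples
#' compute_maf(c(0, 1, 2, 2))   # 5 alt alleles / 8 -> folded to 3/8
#' @export
compute_maf <- function(genotype_column) {
  ok <- !is.na(genotype_column)
  if (!any(ok)) stop("all genotypes missing; MAF undefined")
  p <- sum(genotype_column[ok]) / (2 * sum(ok))
  min(p, 1 - p)
}

# Vectorized alternate-allele frequency (unfolded) and MAF per column.
col_alt_freq <- function(g) {
  nn <- colSums(!is.na(g))
  colSums(g, na.rm = TRUE) / (2 * nn)
}

col_maf <- function(g) {
  p <- col_alt_freq(g)
  pmin(p, 1 - p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the total probability of heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (standard formulation, not mid-p), computed with the usual
#' numerically-stable recurrence over heterozygote counts.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (0/1/2 respectively).
#' @return the exact p-value in (0, 1].
#' @examples
#' hwe_test(25, 50, 25)   # perfectly HWE-ish
#' hwe_test(0, 100, 0)    # extreme heterozygote excess, tiny p
#' @export
hwe_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  if (any(counts != round(counts))) stop("genotype counts must be integers")
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be positive")

  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0) return(1.0)  # monomorphic: single configuration

  # heterozygote counts share the parity of the rare-allele count
  het_obs <- n_het
  probs <- numeric(n_rare + 1)  # index k+1 <-> k heterozygotes
  mid <- floor(n_rare * (2 * n - n_rare) / (2 * n))
  if ((mid %% 2) != (n_rare %% 2)) mid <- mid + 1
  probs[mid + 1] <- 1

  # downward recurrence: P(k-2)/P(k) = k(k-1) / (4 (hom_r+1)(hom_c+1))
  hom_r <- (n_rare - mid) / 2       # rare homozygotes at k = mid
  hom_c <- n - mid - hom_r          # common homozygotes
  k <- mid
  while (k >= 2) {
    probs[k - 1] <- probs[k + 1] * k * (k - 1) /
      (4 * (hom_r + 1) * (hom_c + 1))
    k <- k - 2
    hom_r <- hom_r + 1
    hom_c <- hom_c + 1
  }
  # upward recurrence: P(k+2)/P(k) = 4 hom_r hom_c / ((k+2)(k+1))
  hom_r <- (n_rare - mid) / 2
  hom_c <- n - mid - hom_r
  k <- mid
  while (k <= n_rare - 2) {
    probs[k + 3] <- probs[k + 1] * 4 * hom_r * hom_c / ((k + 2) * (k + 1))
    k <- k + 2
    hom_r <- hom_r - 1
    hom_c <- hom_c - 1
  }

  probs <- probs / sum(probs)
  p_obs <- probs[het_obs + 1]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

# HWE p-value per SNP column from a genotype matrix (NAs dropped per SNP).
col_hwe_p <- function(g) {
  vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(1.0)
    hwe_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  }, numeric(1))
}

#' Apply quality-control filters to a genotype matrix
#'
#' Filters in a fixed order: (1) samples with missing rate above
#' `sample_missing_max`; (2) SNPs with missing rate above
#' `snp_missing_max`; (3) SNPs with MAF below `maf_min`; (4) SNPs failing
#' the exact HWE test at `hwe_p_min`.  Remaining missing genotypes are then
#' imputed to the per-SNP modal genotype (ties broken toward the lower
#' value), so downstream stages always receive a complete matrix.
#'
#' @param gm a [geno_matrix()].
#' @param thr a [qc_thresholds()].
#' @return a list with elements `geno` (the filtered, complete
#'   `geno_matrix`) and `report` (a `qc_report` listing removals per stage
#'   and the number of imputed cells).
#' @export
apply_qc <- function(gm, thr = qc_thresholds()) {
  stopifnot(inherits(gm, "geno_matrix"))
  g <- gm$genotypes
  if (nrow(g) == 0L || ncol(g) == 0L) stop("empty genotype matrix")
  dims_before <- dim(g)

  smiss <- rowMeans(is.na(g))
  rm_samples <- rownames(g)[smiss > thr$sample_missing_max]
  g <- g[smiss <= thr$sample_missing_max, , drop = FALSE]
  if (nrow(g) == 0L) stop("no samples left after missingness filter; review thresholds")

  cmiss <- colMeans(is.na(g))
  rm_miss <- colnames(g)[cmiss > thr$snp_missing_max]
  g <- g[, cmiss <= thr$snp_missing_max, drop = FALSE]
  if (ncol(g) == 0L) stop("no SNPs left after missingness filter; review thresholds")

  maf <- col_maf(g)
  rm_maf <- colnames(g)[maf < thr$maf_min]
  g <- g[, maf >= thr$maf_min, drop = FALSE]
  if (ncol(g) == 0L) stop("no SNPs left after MAF filter; review thresholds")

  hwe <- col_hwe_p(g)
  rm_hwe <- colnames(g)[hwe < thr$hwe_p_min]
  g <- g[, hwe >= thr$hwe_p_min, drop = FALSE]
  if (ncol(g) == 0L) stop("no SNPs left after HWE filter; review thresholds")

  n_imputed <- 0L
  if (anyNA(g)) {
    for (j in which(colSums(is.na(g)) > 0L)) {
      x <- g[, j]
      tab <- tabulate(x[!is.na(x)] + 1L, nbins = 3L)
      mode_g <- which.max(tab) - 1L  # which.max takes the first (lower) tie
      n_imputed <- n_imputed + sum(is.na(x))
      g[is.na(x), j] <- mode_g
    }
  }

  out <- geno_matrix(g, ancestry = gm$ancestry[rownames(g)])
  report <- structure(list(removed_samples = rm_samples,
                           removed_snps_missing = rm_miss,
                           removed_snps_maf = rm_maf,
                           removed_snps_hwe = rm_hwe,
                           n_imputed = n_imputed,
                           dims_before = dims_before,
                           dims_after = dim(g),
                           thresholds = thr),
                      class = "qc_report")
  list(geno = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d x %d -> %d x %d\n",
              x$dims_before[1], x$dims_before[2],
              x$dims_after[1], x$dims_after[2]))
  cat(sprintf("  removed samples (missingness): %d\n", length(x$removed_samples)))
  cat(sprintf("  removed SNPs: missingness %d, MAF %d, HWE %d\n",
              length(x$removed_snps_missing), length(x$removed_snps_maf),
              length(x$removed_snps_hwe)))
  cat(sprintf("  imputed genotypes: %d\n", x$n_imputed))
  invisible(x)
}
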