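#' Founder-population configuration
#'
#' Parameters of the Balding-Nichols founder simulator that stands in for a
#' real multi-ancestry cohort.  Each SNP receives an ancestral allele
#' frequency drawn uniformly from `maf_range`; each ancestry group then
#' draws its own frequency from Beta(p(1-F)/F, (1-p)(1-F)/F), whose mean is
#' the ancestral frequency p and whose variance grows with the group's
#' divergence parameter F (an FST analogue).  Genotypes are binomial(2)
#' draws, giving PCA-separable groups without linkage disequilibrium.
#'
#' @param group_sizes named integer vector: ancestry label -> sample count.
#'   Default: six groups of 500 (African, American, East Asian, European,
#'   South Asian, West Asian).
#' @param n_snps number of SNPs to simulate.
#' @param fst divergence parameter per group, strictly inside (0, 1); a
#'   scalar is recycled.  Default 0.1, a typical between-continental-group
#'   value.
#' @param maf_range interval within (0, 0.5] for the ancestral frequency.
#' @param missing_rate independent per-cell missingness fraction in [0, 1).
#' @param seed integer RNG seed.
#' @return an object of class `founder_config`.
#' @export
founder_config <- function(group_sizes = c(African = 500L, American = 500L,
                                           `East Asian` = 500L, European = 500L,
                                           `South Asian` = 500L, `West Asian` = 500L),
                           n_snps = 1000L, fst = 0.1,
                           maf_range = c(0.05, 0.5),
                           missing_rate = 0.01, seed = 1L) {
  if (is.null(names(group_sizes)) || anyDuplicated(names(group_sizes))) {
    stop("group_sizes must be uniquely named by ancestry label")
  }
  if (any(group_sizes < 0)) stop("group sizes must be >= 0")
  if (n_snps < 1) stop("n_snps must be >= 1")
  fst <- rep_len(fst, length(group_sizes))
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie strictly inside (0, 1)")
  if (length(maf_range) != 2L || maf_range[1L] >= maf_range[2L] ||
      maf_range[1L] <= 0 || maf_range[2L] > 0.5) {
    stop("maf_range must be an increasing interval within (0, 0.5]")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  structure(list(group_sizes = group_sizes, n_snps = as.integer(n_snps),
                 fst = stats::setNames(fst, names(group_sizes)),
                 maf_range = maf_range, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "founder_config")
}

#' Simulate a multi-ancestry founder population
#'
#' @param config a [founder_config()].
#' @return a [geno_matrix()] with `sum(group_sizes)` samples; sample IDs are
#'   `F000001`, `F000002`, ... in group order.
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "founder_config"))
  set.seed(config$seed)
  p_anc <- stats::runif(config$n_snps, config$maf_range[1L], config$maf_range[2L])
  labels <- names(config$group_sizes)
  blocks <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    n_g <- config$group_sizes[[k]]
    if (n_g == 0L) {
      blocks[[k]] <- matrix(integer(), 0L, config$n_snps)
      next
    }
    f <- config$fst[[k]]
    p_g <- stats::rbeta(config$n_snps,
                        p_anc * (1 - f) / f,
                        (1 - p_anc) * (1 - f) / f)
    blocks[[k]] <- matrix(stats::rbinom(n_g * config$n_snps, 2L,
                                        rep(p_g, each = n_g)),
                          nrow = n_g, ncol = config$n_snps)
  }
  g <- do.call(rbind, blocks)
  if (config$missing_rate > 0) {
    g[stats::runif(length(g)) < config$missing_rate] <- NA_integer_
  }
  n <- nrow(g)
  dimnames(g) <- list(sprintf("F%06d", seq_len(n)),
                      sprintf("snp%05d", seq_len(config$n_snps)))
  geno_matrix(g, ancestry = rep(labels, times = config$group_sizes))
}
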