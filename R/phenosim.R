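#' Phenotype-simulation parameters
#'
#' @param causal_fraction fraction of SNPs acting as causal variants
#'   (default 0.10).
#' @param effect_sd standard deviation of the zero-mean normal from which
#'   causal logit coefficients are drawn (default 0.5, giving per-SNP odds
#'   ratios mostly between about 1.1 and 3).
#' @param case_fraction target case fraction; labels are balanced exactly
#'   to `round(case_fraction * n)` cases (default 0.5).
#' @param seed optional integer seed.
#' @return an object of class `pheno_params`.
#' @export
pheno_params <- function(causal_fraction = 0.10, effect_sd = 0.5,
                         case_fraction = 0.5, seed = NULL) {
  if (causal_fraction <= 0 || causal_fraction > 1) {
    stop("causal_fraction must lie in (0, 1]")
  }
  if (case_fraction <= 0 || case_fraction >= 1) {
    stop("case_fraction must lie in (0, 1)")
  }
  if (effect_sd < 0) stop("effect_sd must be >= 0")
  structure(list(causal_fraction = causal_fraction, effect_sd = effect_sd,
                 case_fraction = case_fraction, seed = seed),
            class = "pheno_params")
}

#' Select a random causal SNP set
#'
#' Uniform random subset of size `round(fraction * length(snp_ids))`, with a
#' minimum of one SNP.
#'
#' @param snp_ids character vector of SNP IDs.
#' @param fraction fraction in (0, 1].
#' @param seed optional integer seed.
#' @return character vector of selected SNP IDs.
#' @export
select_causal_snps <- function(snp_ids, fraction = 0.10, seed = NULL) {
  if (length(snp_ids) == 0L) stop("snp_ids must be non-empty")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  k <- max(1L, round(fraction * length(snp_ids)))
  snp_ids[sort(sample.int(length(snp_ids), k))]
}

#' Simulate a balanced binary phenotype from causal SNPs
#'
#' Liability model on the logit scale: coefficients for the causal SNPs are
#' drawn from N(0, effect_sd^2); each sample's liability is the genetic
#' score plus standard-logistic observational noise.  Labels are then
#' assigned by thresholding the liability at its `case_fraction` quantile so
#' that exactly `round(case_fraction * n)` samples are cases (the samples
#' with the largest liabilities; ties resolved by sample order).
#'
#' @param gm a complete [geno_matrix()].
#' @param causal character vector of causal SNP IDs (subset of `snp_ids(gm)`).
#' @param params a [pheno_params()].
#' @return a [phenotype_set()].
#' @export
simulate_phenotype <- function(gm, causal, params = pheno_params()) {
  stopifnot(inherits(gm, "geno_matrix"))
  g <- gm$genotypes
  n <- nrow(g)
  if (n < 2L) stop("at least 2 samples required")
  if (anyNA(g)) stop("missing genotypes present; run apply_qc() first")
  if (!all(causal %in% colnames(g))) {
    stop("causal SNPs not present in the matrix: ",
         paste(utils::head(setdiff(causal, colnames(g)), 5L), collapse = ", "))
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  beta <- stats::rnorm(length(causal), 0, params$effect_sd)
  liability <- as.vector(g[, causal, drop = FALSE] %*% beta) +
    stats::rlogis(n)
  n_case <- round(params$case_fraction * n)
  y <- integer(n)
  y[order(liability, decreasing = TRUE)[seq_len(n_case)]] <- 1L
  phenotype_set(stats::setNames(y, rownames(g)),
                causal_snps = causal, coefficients = beta,
                intercept = 0, case_fraction = params$case_fraction)
}
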