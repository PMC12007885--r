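#' Watermark-generation parameters
#'
#' Watermark SNPs are fabricated genotype columns engineered to associate
#' strongly with the simulated phenotype, so that a third party recomputing
#' a GWAS can be checked against known ground truth.  `z0` is the baseline
#' alternate-allele frequency and `eps` the association strength: the
#' target frequency is `z0 + eps` among cases and `z0 - eps` among
#' controls.
#'
#' @param n_watermarks number of watermark SNPs (default 20).
#' @param eps association-strength parameter in allele-frequency units
#'   (default 0.3).
#' @param z0 baseline allele-frequency parameter (default 0.49).
#' @param seed optional integer seed.
#' @return an object of class `watermark_params`.
#' @export
watermark_params <- function(n_watermarks = 20L, eps = 0.3, z0 = 0.49,
                             seed = NULL) {
  if (n_watermarks < 0) stop("n_watermarks must be >= 0")
  if (z0 + eps > 1 || z0 - eps < 0) {
    stop("require 0 <= z0 - eps and z0 + eps <= 1")
  }
  structure(list(n_watermarks = as.integer(n_watermarks), eps = eps, z0 = z0,
                 seed = seed),
            class = "watermark_params")
}

# Largest-remainder apportionment of n into round(n * probs) summing to n;
# remainder ties go to the lower index.
largest_remainder <- function(n, probs) {
  # rounding the quotas kills float noise so exact ties break toward the
  # lower genotype deterministically
  quota <- round(n * probs, 9)
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    rem <- quota - base
    give <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Genotype-count plan for one watermark SNP
#'
#' Target alternate-allele frequency `z0 + eps` among cases and `z0 - eps`
#' among controls; within each arm the genotype counts are the
#' Hardy-Weinberg expectations n p^2 (genotype 2), 2 n p (1-p) (genotype 1)
#' and n (1-p)^2 (genotype 0), rounded by largest remainder so they sum
#' exactly to the arm size.
#'
#' @param n_cases,n_controls arm sizes (> 0).
#' @param params a [watermark_params()].
#' @return list with integer vectors `case` and `control`, each named
#'   `g0`, `g1`, `g2` and summing to its arm size.
#' @examples
#' watermark_counts(100, 100, watermark_params())
#' @export
watermark_counts <- function(n_cases, n_controls, params = watermark_params()) {
  if (n_cases <= 0 || n_controls <= 0) stop("both arms must be non-empty")
  plan_arm <- function(n, p) {
    counts <- largest_remainder(n, c((1 - p)^2, 2 * p * (1 - p), p^2))
    stats::setNames(counts, c("g0", "g1", "g2"))
  }
  list(case = plan_arm(n_cases, params$z0 + params$eps),
       control = plan_arm(n_controls, params$z0 - params$eps))
}

# Step 1 of watermark construction: the column starts as a copy of the
# phenotype vector (cases 1, controls 0); kept separate so the
# initialization contract is visible and testable.
watermark_init <- function(phenotype) {
  as.integer(phenotype)
}

#' Generate one watermark SNP column
#'
#' Four steps: (1) initialize the column as a copy of the phenotype vector;
#' (2) split indices into the case set and the control set; (3) compute the
#' within-arm genotype-count plan with [watermark_counts()]; (4) overwrite
#' each arm with a uniformly random arrangement of genotypes realizing that
#' plan.
#'
#' @param phenotype a [phenotype_set()] or a named 0/1 vector with both
#'   classes present.
#' @param params a [watermark_params()].
#' @return integer genotype vector in \{0, 1, 2\}, named like the phenotype.
#' @export
generate_watermark_snp <- function(phenotype, params = watermark_params()) {
  y <- if (inherits(phenotype, "phenotype_set")) phenotype$phenotype else phenotype
  if (!all(y %in% 0:1)) stop("phenotype must be binary 0/1")
  idx_case <- which(y == 1L)
  idx_ctrl <- which(y == 0L)
  if (length(idx_case) == 0L || length(idx_ctrl) == 0L) {
    stop("phenotype must contain both classes")
  }
  plan <- watermark_counts(length(idx_case), length(idx_ctrl), params)
  col <- watermark_init(y)
  col[idx_case] <- sample(rep(0:2, times = plan$case))
  col[idx_ctrl] <- sample(rep(0:2, times = plan$control))
  names(col) <- names(y)
  col
}

#' Single-SNP logistic association test (likelihood ratio)
#'
#' Fits phenotype ~ genotype (additive coding) by logistic regression and
#' returns the likelihood-ratio p-value against the intercept-only model.
#' A constant genotype column returns 1 by convention.  Near-separation is
#' handled by capping the IRLS iterations; such fits are flagged via the
#' `"capped"` attribute.  p-values that underflow double precision are
#' floored at `.Machine$double.xmin` so the result stays in (0, 1].
#'
#' @param genotype_column numeric/integer vector.
#' @param phenotype a [phenotype_set()] or 0/1 vector of the same length.
#' @return p-value in (0, 1], with logical attribute `capped`.
#' @export
association_test <- function(genotype_column, phenotype) {
  y <- if (inherits(phenotype, "phenotype_set")) phenotype$phenotype else phenotype
  if (length(genotype_column) != length(y)) {
    stop("genotype and phenotype lengths differ")
  }
  if (length(unique(y)) < 2L) stop("phenotype must contain both classes")
  if (length(unique(genotype_column)) < 2L) {
    return(structure(1.0, capped = FALSE))
  }
  capped <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ genotype_column, family = stats::binomial(),
               control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      capped <<- TRUE
      invokeRestart("muffleWarning")
    })
  stat <- fit$null.deviance - fit$deviance
  p <- stats::pchisq(max(stat, 0), df = 1L, lower.tail = FALSE)
  if (p <= 0) p <- .Machine$double.xmin
  structure(p, capped = capped)
}

#' Build the full watermark block
#'
#' Generates `n_watermarks` watermark columns for the given phenotype,
#' assigns each a random SNP ID disjoint from the data SNP IDs, and records
#' the logistic association p-value of every column.
#'
#' @param phenotype a [phenotype_set()] restricted to the samples that will
#'   carry the watermark columns.
#' @param params a [watermark_params()].
#' @param data_snp_ids SNP IDs already used by the genotype matrix (the
#'   watermark IDs are guaranteed disjoint from these).
#' @return a [watermark_block()]; zero watermarks give an empty block.
#' @export
build_watermark_block <- function(phenotype, params = watermark_params(),
                                  data_snp_ids = character()) {
  y <- phenotype$phenotype
  if (!is.null(params$seed)) set.seed(params$seed)
  k <- params$n_watermarks
  if (k == 0L) {
    return(watermark_block(matrix(integer(), length(y), 0L,
                                  dimnames = list(names(y), NULL)),
                           p_values = numeric()))
  }
  ids <- character(0)
  while (length(ids) < k) {
    cand <- sprintf("rs%08d", sample.int(99999999L, k))
    ids <- unique(c(ids, setdiff(cand, data_snp_ids)))
  }
  ids <- ids[seq_len(k)]
  g <- matrix(NA_integer_, length(y), k, dimnames = list(names(y), ids))
  pv <- numeric(k)
  fl <- logical(k)
  for (j in seq_len(k)) {
    g[, j] <- generate_watermark_snp(y, params)
    p <- association_test(g[, j], y)
    pv[j] <- as.numeric(p)
    fl[j] <- isTRUE(attr(p, "capped"))
  }
  watermark_block(g, p_values = pv, flags = fl)
}
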