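#' Principal-component model of a genotype matrix
#'
#' Column-centers the genotype matrix and extracts the leading principal
#' components.  Component signs are fixed deterministically by forcing the
#' largest-magnitude loading of each component to be positive, so results
#' are reproducible across runs and platforms.
#'
#' @param gm a complete (no missing data) [geno_matrix()].
#' @param n_components number of components to keep; clipped to
#'   `min(n_samples - 1, n_snps)`.  Default 200, the usual choice for
#'   fine-grained ancestry structure in large cohorts.
#' @return an object of class `geno_pca`: list with `center` (per-SNP
#'   means), `rotation` (SNPs x K loadings), `sdev` (component standard
#'   deviations), `scores` (samples x K), `n_components`.
#' @export
fit_pca <- function(gm, n_components = 200L) {
  stopifnot(inherits(gm, "geno_matrix"))
  g <- gm$genotypes
  if (anyNA(g)) stop("missing genotypes present; run apply_qc() first")
  if (n_components < 1) stop("n_components must be >= 1")
  k <- min(n_components, nrow(g) - 1L, ncol(g))
  pc <- stats::prcomp(g, center = TRUE, scale. = FALSE, rank. = k)
  rotation <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rotation))) {
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(center = pc$center, rotation = rotation,
                 sdev = pc$sdev[seq_len(k)], scores = scores,
                 n_components = k, total_variance = sum(pc$sdev^2)),
            class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("geno_pca: %d components over %d samples x %d SNPs\n",
              x$n_components, nrow(x$scores), length(x$center)))
  cat(sprintf("variance explained by kept components: %.1f%%\n",
              100 * sum(x$sdev^2) / x$total_variance))
  invisible(x)
}

#' Project genotype rows into a fitted PC space
#'
#' @param model a [fit_pca()] model.
#' @param genotypes integer matrix (samples x SNPs) on the same SNP axis the
#'   model was fitted on.
#' @return a samples x K score matrix.
#' @export
project_scores <- function(model, genotypes) {
  if (ncol(genotypes) != length(model$center)) {
    stop("SNP axis does not match the fitted model")
  }
  sweep(genotypes, 2L, model$center, check.margin = FALSE) %*% model$rotation
}

#' Per-ancestry geometry in PC space
#'
#' For each ancestry group present: the centroid of member scores and the
#' `percentile`-th percentile of member Euclidean distances to that
#' centroid.  This radius operationalizes "deviates from the target
#' ancestry group": a sample is consistent with the group when its distance
#' to the centroid is within (slack times) the radius.
#'
#' @param model a [fit_pca()] model fitted on `gm`'s samples.
#' @param gm the [geno_matrix()] supplying ancestry labels.
#' @param percentile radius percentile in (0, 100] (default 97.5).
#' @return named list of `group_geometry` objects (one per ancestry label),
#'   each with `ancestry`, `centroid`, `radius`, `n_members`, `percentile`.
#' @export
group_geometry <- function(model, gm, percentile = 97.5) {
  stopifnot(inherits(model, "geno_pca"), inherits(gm, "geno_matrix"))
  if (nrow(model$scores) != nrow(gm$genotypes)) {
    stop("model scores do not cover the supplied samples")
  }
  labels <- unique(gm$ancestry)
  out <- lapply(labels, function(lab) {
    idx <- which(gm$ancestry == lab)
    if (length(idx) < 2L) stop("ancestry group '", lab, "' has < 2 members")
    s <- model$scores[idx, , drop = FALSE]
    centroid <- colMeans(s)
    d <- sqrt(rowSums(sweep(s, 2L, centroid)^2))
    structure(list(ancestry = lab, centroid = centroid,
                   radius = stats::quantile(d, percentile / 100, names = FALSE),
                   n_members = length(idx), percentile = percentile),
              class = "group_geometry")
  })
  stats::setNames(out, labels)
}

#' Ancestry-consistency test in PC space
#'
#' @param sample_scores numeric vector (one sample) or matrix (samples x K)
#'   of PC scores.
#' @param geom a `group_geometry` from [group_geometry()].
#' @param slack multiplier on the group radius (default 1).
#' @return logical (vector): distance to the group centroid <= slack * radius.
#' @export
is_ancestry_consistent <- function(sample_scores, geom, slack = 1.0) {
  if (is.null(dim(sample_scores))) {
    sample_scores <- matrix(sample_scores, nrow = 1L)
  }
  if (ncol(sample_scores) != length(geom$centroid)) {
    stop("score dimensionality does not match the group geometry")
  }
  d <- sqrt(rowSums(sweep(sample_scores, 2L, geom$centroid)^2))
  d <= slack * geom$radius
}
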