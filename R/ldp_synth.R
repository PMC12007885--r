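#' Constrained randomized-response parameters
#'
#' Randomized response over the three additive genotype states, constrained
#' so the two homozygous states never flip into each other (a 0 <-> 2
#' transition would fabricate biologically implausible double allele
#' changes).  With d = 3 states and privacy-loss parameter epsilon:
#' a homozygote (0 or 2) flips to the heterozygote with probability
#' `q_extreme = 2 / (exp(epsilon) + d - 1)`; a heterozygote flips to 0 or to
#' 2, each with probability `q_het = 1 / (exp(epsilon) + d - 1)`.  All three
#' states therefore keep the same stay probability
#' `1 - 2 / (exp(epsilon) + d - 1)`.
#'
#' @param epsilon positive privacy-loss parameter (default 6, a low-noise
#'   setting: flip probabilities below 0.5%).
#' @param d number of genotype states; fixed at 3 for additive coding.
#' @return an object of class `ldp_params` with fields `epsilon`, `d`,
#'   `q_extreme`, `q_het`.
#' @examples
#' ldp_params(6)$q_extreme   # 2 / (exp(6) + 2)
#' @export
ldp_params <- function(epsilon = 6, d = 3L) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (d != 3L) stop("only d = 3 genotype states are supported")
  denom <- exp(epsilon) + d - 1
  structure(list(epsilon = epsilon, d = as.integer(d),
                 q_extreme = 2 / denom, q_het = 1 / denom),
            class = "ldp_params")
}

#' @export
print.ldp_params <- function(x, ...) {
  cat(sprintf("ldp_params: epsilon = %g, d = %d, q_extreme = %.4g, q_het = %.4g\n",
              x$epsilon, x$d, x$q_extreme, x$q_het))
  invisible(x)
}

#' Perturb genotypes by constrained randomized response
#'
#' Applies the per-state flip rule of [ldp_params()] independently to every
#' entry.  0 and 2 can only move to 1; 1 can move to 0 or to 2 with equal
#' probability `q_het` each.
#'
#' @param g integer vector or matrix with values in \{0, 1, 2\} (no
#'   missing values).
#' @param params an [ldp_params()] object.
#' @return perturbed genotypes, same shape and dimnames as `g`.
#' @export
perturb_genotypes <- function(g, params) {
  stopifnot(inherits(params, "ldp_params"))
  if (anyNA(g)) stop("missing genotypes cannot be perturbed; impute first")
  if (!all(g %in% 0:2)) stop("genotype values must lie in {0, 1, 2}")
  u <- stats::runif(length(g))
  out <- g
  out[(g == 0L | g == 2L) & u < params$q_extreme] <- 1L
  out[g == 1L & u < params$q_het] <- 0L
  out[g == 1L & u >= params$q_het & u < 2 * params$q_het] <- 2L
  out
}

#' Synthesis configuration
#'
#' @param per_group_target synthetic samples to produce per ancestry group
#'   (default 5000).
#' @param max_attempts cap on generated candidates, as a multiple of the
#'   target (default 50); exceeding it raises an error reporting the
#'   acceptance rate.
#' @param slack multiplier on the ancestry-consistency radius (default 1).
#' @param id_range inclusive integer interval from which random sample IDs
#'   are drawn (default 1,000,000..9,999,999).
#' @param identity_filter `"source"` (reject a candidate identical to its
#'   own source sample; default) or `"all"` (reject if identical to any
#'   original).
#' @param seed optional integer seed applied by [synthesize_group()] and
#'   [assign_sample_ids()] when not `NULL`.
#' @return an object of class `synthesis_config`.
#' @export
synthesis_config <- function(per_group_target = 5000L, max_attempts = 50L,
                             slack = 1.0, id_range = c(1000000L, 9999999L),
                             identity_filter = c("source", "all"),
                             seed = NULL) {
  if (per_group_target < 0) stop("per_group_target must be >= 0")
  if (max_attempts < 1) stop("max_attempts must be >= 1")
  if (length(id_range) != 2L || id_range[1L] > id_range[2L]) {
    stop("id_range must be a non-empty integer interval")
  }
  structure(list(per_group_target = as.integer(per_group_target),
                 max_attempts = as.integer(max_attempts),
                 slack = slack,
                 id_range = as.integer(id_range),
                 identity_filter = match.arg(identity_filter),
                 seed = seed),
            class = "synthesis_config")
}

#' Generate synthetic samples for one ancestry group
#'
#' Repeatedly draws a source sample uniformly (with replacement, so groups
#' smaller than the target still reach it), perturbs its genotype row with
#' the constrained randomized response, and accepts the candidate iff it is
#' (a) not genotype-identical to its source and (b) ancestry-consistent:
#' its PC-space projection lies within the group's radius (times `slack`).
#'
#' @param originals a [geno_matrix()] containing exactly one ancestry group.
#' @param model a [fit_pca()] model on the originals' SNP axis.
#' @param geom the group's [group_geometry()] entry.
#' @param cfg a [synthesis_config()].
#' @param params an [ldp_params()].
#' @return a [geno_matrix()] with `per_group_target` samples labelled with
#'   the group's ancestry; sample IDs are provisional
#'   (`<ancestry>_syn<i>`) until [assign_sample_ids()] replaces them.
#' @export
synthesize_group <- function(originals, model, geom, cfg = synthesis_config(),
                             params = ldp_params()) {
  stopifnot(inherits(originals, "geno_matrix"))
  g <- originals$genotypes
  if (nrow(g) == 0L) stop("originals must be non-empty")
  if (anyNA(g)) stop("originals must be complete; run apply_qc() first")
  lab <- unique(originals$ancestry)
  if (length(lab) != 1L) stop("originals must contain a single ancestry group")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  target <- cfg$per_group_target
  if (target == 0L) {
    return(geno_matrix(matrix(integer(), 0L, ncol(g),
                              dimnames = list(NULL, colnames(g))),
                       ancestry = character(),
                       sample_ids = character()))
  }

  accepted <- matrix(NA_integer_, target, ncol(g))
  n_acc <- 0L
  n_att <- 0L
  max_att <- cfg$max_attempts * target
  while (n_acc < target) {
    batch <- min(max(2L * (target - n_acc), 64L), max_att - n_att)
    if (batch <= 0L) {
      stop(sprintf(paste0("synthesis for group '%s' did not reach %d accepted ",
                          "samples within %d attempts (acceptance rate %.3f); ",
                          "epsilon may be too small or the ancestry radius too tight"),
                   lab, target, max_att, n_acc / max(n_att, 1L)))
    }
    src <- sample.int(nrow(g), batch, replace = TRUE)
    cand <- perturb_genotypes(g[src, , drop = FALSE], params)
    changed <- rowSums(cand != g[src, , drop = FALSE]) > 0L
    if (cfg$identity_filter == "all") {
      key_orig <- apply(g, 1L, paste, collapse = ",")
      key_cand <- apply(cand, 1L, paste, collapse = ",")
      changed <- changed & !(key_cand %in% key_orig)
    }
    scores <- project_scores(model, cand)
    ok <- changed & is_ancestry_consistent(scores, geom, cfg$slack)
    n_att <- n_att + batch
    take <- which(ok)
    if (length(take) > 0L) {
      take <- take[seq_len(min(length(take), target - n_acc))]
      accepted[n_acc + seq_along(take), ] <- cand[take, , drop = FALSE]
      n_acc <- n_acc + length(take)
    }
  }
  dimnames(accepted) <- list(paste0(gsub("\\s+", "_", lab), "_syn",
                                    seq_len(target)),
                             colnames(g))
  geno_matrix(accepted, ancestry = rep(lab, target))
}

#' Draw random ascending sample IDs
#'
#' Draws `n` unique integers uniformly from the configured ID range and
#' returns them sorted ascending (the samples carrying them are expected to
#' be reordered to match).
#'
#' @param n number of IDs.
#' @param cfg a [synthesis_config()] supplying `id_range` (and optionally a
#'   seed).
#' @param exclude integer IDs that must not be reused.
#' @return sorted integer vector of length `n`.
#' @export
assign_sample_ids <- function(n, cfg = synthesis_config(), exclude = integer()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lo <- cfg$id_range[1L]
  hi <- cfg$id_range[2L]
  avail <- hi - lo + 1 - length(exclude)
  if (n > avail) stop("id_range exhausted: ", n, " IDs requested, ",
                      avail, " available")
  ids <- integer(0)
  while (length(ids) < n) {
    draw <- lo - 1L + sample.int(hi - lo + 1L, min(n - length(ids) + 16L,
                                                   hi - lo + 1L))
    ids <- unique(c(ids, setdiff(draw, exclude)))
  }
  sort(ids[seq_len(n)])
}
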