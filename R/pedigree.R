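#' Generation schedule for synthetic relatives
#'
#' Defaults follow a three-generation design per ancestry group: 400
#' founders are drawn from the group, paired into 200 father/mother couples
#' producing 200 first-generation descendants; those are re-paired to
#' produce 100 second-generation descendants, and again for 50
#' third-generation descendants.
#'
#' @param n_founders_selected founders drawn per group (default 400).
#' @param descendants integer vector of per-generation offspring counts
#'   (default `c(200, 100, 50)`); each entry can be at most half the number
#'   of available parents from the previous generation.
#' @param id_range inclusive integer interval for relatives' random sample
#'   IDs.
#' @param seed optional integer seed.
#' @return an object of class `generation_schedule`.
#' @export
generation_schedule <- function(n_founders_selected = 400L,
                                descendants = c(200L, 100L, 50L),
                                id_range = c(1000000L, 9999999L),
                                seed = NULL) {
  if (n_founders_selected < 0) stop("n_founders_selected must be >= 0")
  descendants <- as.integer(descendants)
  if (any(descendants < 1)) stop("descendant counts must be >= 1")
  avail <- n_founders_selected
  for (d in descendants) {
    if (d > avail %/% 2L) {
      stop("infeasible schedule: ", d, " offspring need ", 2L * d,
           " parents but only ", avail, " are available")
    }
    avail <- d
  }
  structure(list(n_founders_selected = as.integer(n_founders_selected),
                 descendants = descendants,
                 id_range = as.integer(id_range), seed = seed),
            class = "generation_schedule")
}

#' Simulate one Mendelian offspring
#'
#' Per SNP, each parent independently transmits one allele: genotype 0
#' always transmits the reference allele, genotype 2 always the alternate,
#' genotype 1 either with probability 1/2.  The offspring genotype is the
#' number of transmitted alternate alleles, so e.g. parents (0, 1) yield 0
#' or 1 with equal probability and parents (1, 1) yield 0/1/2 with
#' probability 1/4, 1/2, 1/4.
#'
#' @param parent_a,parent_b equal-length complete genotype vectors in
#'   \{0, 1, 2\}.
#' @return integer offspring genotype vector.
#' @export
mendelian_offspring <- function(parent_a, parent_b) {
  if (length(parent_a) != length(parent_b)) stop("parent sequences differ in length")
  if (anyNA(parent_a) || anyNA(parent_b)) stop("missing genotypes not allowed")
  if (!all(parent_a %in% 0:2) || !all(parent_b %in% 0:2)) {
    stop("genotype values must lie in {0, 1, 2}")
  }
  p <- length(parent_a)
  stats::rbinom(p, 1L, parent_a / 2) + stats::rbinom(p, 1L, parent_b / 2)
}

#' Simulate multi-generation synthetic relatives for one group
#'
#' Draws `n_founders_selected` founders from the group, splits them
#' uniformly at random into equal father/mother halves and pairs them
#' without replacement; each of the first `descendants[1]` pairs produces
#' one offspring.  Each later generation re-partitions the previous
#' generation's offspring into father/mother halves, pairs them without
#' replacement, and produces the scheduled count.  Because every pair
#' produces exactly one child and no parent is reused within a generation,
#' no siblings or collateral relatives arise; all related pairs are
#' ancestor-descendant pairs, recorded with their meiosis distance
#' (1 = first-degree, 2 = second-degree, 3 = third-degree; deeper links are
#' not emitted).  Each relative receives a fresh random sample ID from the
#' schedule's ID range, and the KING coefficient of every recorded pair is
#' computed from the genotypes.
#'
#' @param group a complete [geno_matrix()] of one ancestry group.
#' @param schedule a [generation_schedule()].
#' @param exclude_ids integer sample IDs that must not be reused for
#'   relatives.
#' @return list with `relatives` (a [geno_matrix()]) and `kinship` (a
#'   data.frame: `sample_id` = descendant, `related_sample_id` = ancestor,
#'   `degree`, `king`).
#' @export
simulate_generations <- function(group, schedule = generation_schedule(),
                                 exclude_ids = integer()) {
  stopifnot(inherits(group, "geno_matrix"),
            inherits(schedule, "generation_schedule"))
  g <- group$genotypes
  if (anyNA(g)) stop("group must be complete; run apply_qc() first")
  lab <- unique(group$ancestry)
  if (length(lab) != 1L) stop("group must contain a single ancestry label")
  if (!is.null(schedule$seed)) set.seed(schedule$seed)

  if (length(schedule$descendants) == 0L) {
    return(list(relatives = geno_matrix(matrix(integer(), 0L, ncol(g),
                                               dimnames = list(NULL, colnames(g))),
                                        ancestry = character(),
                                        sample_ids = character()),
                kinship = empty_kinship()))
  }
  if (nrow(g) < schedule$n_founders_selected) {
    stop("group has ", nrow(g), " samples but the schedule selects ",
         schedule$n_founders_selected, " founders")
  }

  founders <- sample.int(nrow(g), schedule$n_founders_selected)
  founder_ids <- rownames(g)[founders]

  total_desc <- sum(schedule$descendants)
  rel_ids <- as.character(assign_sample_ids(
    total_desc,
    synthesis_config(id_range = schedule$id_range),
    exclude = exclude_ids))
  rel_ids <- sample(rel_ids)  # random assignment order, not sorted by pedigree

  geno <- matrix(NA_integer_, total_desc, ncol(g),
                 dimnames = list(rel_ids, colnames(g)))
  parent_of <- list()  # id -> c(father id, mother id)
  get_geno <- function(id) {
    if (id %in% rownames(g)) g[id, ] else geno[id, ]
  }

  prev_ids <- founder_ids
  row_at <- 0L
  for (d_k in schedule$descendants) {
    perm <- sample(prev_ids)
    half <- length(perm) %/% 2L
    fathers <- perm[seq_len(half)]
    mothers <- perm[half + seq_len(half)]
    gen_ids <- character(d_k)
    for (i in seq_len(d_k)) {
      row_at <- row_at + 1L
      id <- rel_ids[row_at]
      geno[id, ] <- mendelian_offspring(get_geno(fathers[i]), get_geno(mothers[i]))
      parent_of[[id]] <- c(fathers[i], mothers[i])
      gen_ids[i] <- id
    }
    prev_ids <- gen_ids
  }

  # enumerate ancestor-descendant pairs up to 3 meioses
  recs <- vector("list", 0L)
  deg_label <- c("first-degree", "second-degree", "third-degree")
  for (id in names(parent_of)) {
    anc <- parent_of[[id]]
    deg <- 1L
    while (length(anc) > 0L && deg <= 3L) {
      for (a in anc) {
        recs[[length(recs) + 1L]] <- data.frame(
          sample_id = id, related_sample_id = a,
          degree = deg_label[deg],
          king = king_coefficient(geno[id, ], get_geno(a)),
          stringsAsFactors = FALSE)
      }
      anc <- unique(unlist(lapply(anc, function(a) parent_of[[a]])))
      deg <- deg + 1L
    }
  }
  kinship <- if (length(recs) > 0L) do.call(rbind, recs) else empty_kinship()

  list(relatives = geno_matrix(geno, ancestry = rep(lab, total_desc)),
       kinship = kinship)
}

# Pairwise heterozygosity/opposite-homozygote counts feeding the KING
# estimator.
king_counts <- function(geno_i, geno_j) {
  list(n11 = sum(geno_i == 1L & geno_j == 1L),
       n02 = sum(geno_i == 0L & geno_j == 2L),
       n20 = sum(geno_i == 2L & geno_j == 0L),
       n1_star = sum(geno_i == 1L),
       star_1 = sum(geno_j == 1L))
}

#' KING robust kinship coefficient
#'
#' Heterozygosity-based kinship estimator
#' \deqn{\phi(i,j) = \frac{2 n_{11} - 4 (n_{02} + n_{20}) - n_{*1} + n_{1*}}{4\, n_{1*}}}
#' where \eqn{n_{11}} counts SNPs at which both individuals are
#' heterozygous, \eqn{n_{02}}/\eqn{n_{20}} count opposite homozygotes, and
#' \eqn{n_{1*}}, \eqn{n_{*1}} count heterozygous SNPs of `geno_i` and
#' `geno_j` respectively.  Identical sequences score 0.5; parent-offspring
#' pairs about 0.25.  The estimator is asymmetric in i and j (it normalizes
#' by i's heterozygosity), matching the robust within-family form.
#'
#' @param geno_i,geno_j equal-length complete genotype vectors in
#'   \{0, 1, 2\}; `geno_i` must contain at least one heterozygous site.
#' @return the kinship coefficient (numeric scalar).
#' @examples
#' king_coefficient(c(1, 1, 0, 2, 1), c(1, 0, 0, 2, 2))  # 1/3
#' @export
king_coefficient <- function(geno_i, geno_j) {
  if (length(geno_i) != length(geno_j)) stop("sequences differ in length")
  if (anyNA(geno_i) || anyNA(geno_j)) stop("missing genotypes not allowed")
  k <- king_counts(geno_i, geno_j)
  if (k$n1_star == 0L) {
    stop("individual i has no heterozygous sites; coefficient undefined")
  }
  (2 * k$n11 - 4 * (k$n02 + k$n20) - k$star_1 + k$n1_star) / (4 * k$n1_star)
}
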