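#' End-to-end run configuration
#'
#' Bundles every stage's parameter block and a single global seed from
#' which all per-stage random streams are derived deterministically.
#'
#' @param founder a [founder_config()] used when no input matrix is given.
#' @param qc a [qc_thresholds()].
#' @param n_components PCA components to fit (clipped to the data).
#' @param geometry_percentile radius percentile for [group_geometry()].
#' @param ldp an [ldp_params()].
#' @param synthesis a [synthesis_config()].
#' @param pheno a [pheno_params()].
#' @param watermark a [watermark_params()].
#' @param schedule a [generation_schedule()] for synthetic relatives.
#' @param include_originals_in_phenotype simulate the phenotype on the
#'   combined original + synthetic matrix (default TRUE); only synthetic
#'   samples' labels are exported either way.
#' @param keep_originals store the post-QC original matrix in the bundle's
#'   provenance (handy for [validate_bundle()]; off by default to keep large
#'   runs lean).
#' @param seed global integer seed.
#' @param out_dir optional directory; when set, [run_pipeline()] writes the
#'   five-file CSV bundle there.
#' @param verbose emit one progress line per stage (default FALSE).
#' @return an object of class `run_config`.
#' @export
run_config <- function(founder = founder_config(),
                       qc = qc_thresholds(),
                       n_components = 200L,
                       geometry_percentile = 97.5,
                       ldp = ldp_params(),
                       synthesis = synthesis_config(),
                       pheno = pheno_params(),
                       watermark = watermark_params(),
                       schedule = generation_schedule(),
                       include_originals_in_phenotype = TRUE,
                       keep_originals = FALSE,
                       seed = 1L, out_dir = NULL, verbose = FALSE) {
  structure(list(founder = founder, qc = qc,
                 n_components = as.integer(n_components),
                 geometry_percentile = geometry_percentile,
                 ldp = ldp, synthesis = synthesis, pheno = pheno,
                 watermark = watermark, schedule = schedule,
                 include_originals_in_phenotype = include_originals_in_phenotype,
                 keep_originals = keep_originals,
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = verbose),
            class = "run_config")
}

# Deterministic per-stage seed derived from the global seed; stays inside
# 32-bit integer range.
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + as.double(stage) * 16807) %% 2147483647)
}

#' Run the full synthetic-dataset generation pipeline
#'
#' Stages: quality control -> PCA stratification -> per-group synthesis by
#' constrained randomized response -> random ascending sample IDs ->
#' phenotype simulation (on the combined original + synthetic matrix by
#' default) -> watermark SNP generation -> Mendelian synthetic relatives ->
#' KING kinship records.  The result is a [dataset_bundle()]; when
#' `config$out_dir` is set the five-file CSV bundle is written there too.
#'
#' @param config a [run_config()].
#' @param input an optional [geno_matrix()]; when `NULL`, founders are
#'   simulated from `config$founder`.
#' @return a [dataset_bundle()].
#' @export
run_pipeline <- function(config = run_config(), input = NULL) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))

  if (is.null(input)) {
    fc <- config$founder
    fc$seed <- stage_seed(config$seed, 1L)
    input <- simulate_founders(fc)
    say("founders: %d samples x %d SNPs", nrow(input$genotypes),
        ncol(input$genotypes))
  }

  qc_out <- apply_qc(input, config$qc)
  originals <- qc_out$geno
  say("qc: %d x %d -> %d x %d", nrow(input$genotypes), ncol(input$genotypes),
      nrow(originals$genotypes), ncol(originals$genotypes))

  model <- fit_pca(originals, config$n_components)
  geoms <- group_geometry(model, originals, config$geometry_percentile)
  say("pca: %d components; %d ancestry groups", model$n_components,
      length(geoms))

  labels <- sort(names(geoms))
  syn_cfg <- config$synthesis
  syn_cfg$seed <- NULL  # stage streams come from the global seed
  set.seed(stage_seed(config$seed, 2L))
  synth_blocks <- lapply(labels, function(lab) {
    synthesize_group(gm_subset(originals, samples = originals$ancestry == lab),
                     model, geoms[[lab]], syn_cfg, config$ldp)
  })
  synthetic <- Reduce(gm_rbind, synth_blocks)

  set.seed(stage_seed(config$seed, 3L))
  syn_ids <- assign_sample_ids(nrow(synthetic$genotypes), syn_cfg)
  # random IDs are sorted ascending; assign them to a random permutation of
  # the synthetic samples so row order carries no group information
  perm <- sample.int(nrow(synthetic$genotypes))
  g <- synthetic$genotypes[perm, , drop = FALSE]
  rownames(g) <- as.character(syn_ids)
  synthetic <- geno_matrix(g, ancestry = unname(synthetic$ancestry[perm]))
  say("synthesis: %d synthetic samples across %d groups",
      nrow(synthetic$genotypes), length(labels))

  pheno_input <- if (isTRUE(config$include_originals_in_phenotype)) {
    gm_rbind(originals, synthetic)
  } else {
    synthetic
  }
  pp <- config$pheno
  pp$seed <- NULL
  set.seed(stage_seed(config$seed, 4L))
  causal <- select_causal_snps(snp_ids(pheno_input), pp$causal_fraction)
  pheno_all <- simulate_phenotype(pheno_input, causal, pp)
  exported <- phenotype_set(
    pheno_all$phenotype[rownames(synthetic$genotypes)],
    causal_snps = pheno_all$causal_snps,
    coefficients = pheno_all$coefficients,
    intercept = pheno_all$intercept,
    case_fraction = pheno_all$case_fraction)
  say("phenotype: %d causal SNPs; %d cases / %d controls (simulated on %d samples)",
      length(causal), sum(exported$phenotype == 1L),
      sum(exported$phenotype == 0L), length(pheno_all$phenotype))

  wp <- config$watermark
  wp$seed <- NULL
  set.seed(stage_seed(config$seed, 5L))
  wm <- build_watermark_block(exported, wp, data_snp_ids = snp_ids(synthetic))
  say("watermark: %d SNPs, mean p = %.3g", ncol(wm$genotypes),
      mean(wm$p_values))

  sched <- config$schedule
  sched$seed <- NULL
  set.seed(stage_seed(config$seed, 6L))
  used_ids <- suppressWarnings(as.integer(rownames(synthetic$genotypes)))
  used_ids <- used_ids[!is.na(used_ids)]
  rel_blocks <- vector("list", length(labels))
  kin_blocks <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    grp <- gm_subset(synthetic, samples = synthetic$ancestry == labels[k])
    sim <- simulate_generations(grp, sched, exclude_ids = used_ids)
    used_ids <- c(used_ids,
                  suppressWarnings(as.integer(rownames(sim$relatives$genotypes))))
    rel_blocks[[k]] <- sim$relatives
    kin_blocks[[k]] <- sim$kinship
  }
  relatives <- Reduce(gm_rbind, rel_blocks)
  kinship <- do.call(rbind, kin_blocks)
  rownames(kinship) <- NULL
  say("relatives: %d across %d groups; %d kinship pairs",
      nrow(relatives$genotypes), length(labels), nrow(kinship))

  bundle <- dataset_bundle(
    samples = synthetic, relatives = relatives, phenotype = exported,
    watermark = wm, kinship = kinship,
    provenance = list(seed = config$seed, config = config,
                      qc_report = qc_out$report,
                      originals_post_qc = dim(originals$genotypes),
                      originals = if (isTRUE(config$keep_originals)) originals))
  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config$out_dir)
    say("bundle written to %s", config$out_dir)
  }
  bundle
}

#' Validate a generated bundle against its source data
#'
#' Computes the per-SNP MAF gap between the post-QC originals and the
#' synthetic samples, summarizes the watermark association p-values
#' (recomputed from the bundle), and summarizes KING coefficients per
#' declared relationship degree.
#'
#' @param bundle a [dataset_bundle()].
#' @param originals the post-QC [geno_matrix()] the bundle was generated
#'   from (same SNP axis).
#' @return an object of class `validation_report`.
#' @export
validate_bundle <- function(bundle, originals) {
  stopifnot(inherits(bundle, "dataset_bundle"),
            inherits(originals, "geno_matrix"))
  if (!identical(snp_ids(bundle$samples), snp_ids(originals))) {
    stop("SNP axes of bundle and originals differ")
  }
  maf_orig <- col_maf(originals$genotypes)
  maf_syn <- col_maf(bundle$samples$genotypes)
  gap <- abs(maf_orig - maf_syn)

  wm <- bundle$watermark
  wm_p <- if (ncol(wm$genotypes) > 0L) {
    vapply(seq_len(ncol(wm$genotypes)), function(j) {
      as.numeric(association_test(wm$genotypes[, j], bundle$phenotype))
    }, numeric(1))
  } else {
    numeric(0)
  }

  kin <- bundle$kinship
  king_summary <- if (nrow(kin) > 0L) {
    do.call(rbind, lapply(split(kin$king, kin$degree), function(v) {
      data.frame(n = length(v), mean = mean(v), sd = stats::sd(v))
    }))
  } else {
    data.frame(n = integer(), mean = numeric(), sd = numeric())
  }

  structure(list(
    maf = data.frame(snp_id = snp_ids(originals), original = maf_orig,
                     synthetic = maf_syn, gap = gap, row.names = NULL),
    maf_mean_gap = mean(gap), maf_max_gap = max(gap),
    watermark_p = wm_p,
    watermark_summary = if (length(wm_p) > 0L) {
      c(mean = mean(wm_p), sd = stats::sd(wm_p), max = max(wm_p))
    } else {
      c(mean = NA_real_, sd = NA_real_, max = NA_real_)
    },
    king_summary = king_summary,
    counts = c(samples = nrow(bundle$samples$genotypes),
               relatives = nrow(bundle$relatives$genotypes),
               data_snps = ncol(bundle$samples$genotypes),
               watermark_snps = ncol(wm$genotypes),
               kinship_pairs = nrow(kin))),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report\n")
  cat(sprintf("  samples %d + relatives %d; SNPs %d data + %d watermark; %d kinship pairs\n",
              x$counts["samples"], x$counts["relatives"],
              x$counts["data_snps"], x$counts["watermark_snps"],
              x$counts["kinship_pairs"]))
  cat(sprintf("  MAF gap: mean %.4g, max %.4g\n", x$maf_mean_gap, x$maf_max_gap))
  if (length(x$watermark_p) > 0L) {
    cat(sprintf("  watermark p: mean %.3g, sd %.3g, max %.3g\n",
                x$watermark_summary["mean"], x$watermark_summary["sd"],
                x$watermark_summary["max"]))
  }
  if (nrow(x$king_summary) > 0L) {
    cat("  KING by degree:\n")
    for (d in rownames(x$king_summary)) {
      cat(sprintf("    %s: n = %d, mean = %.3f, sd = %.3f\n", d,
                  x$king_summary[d, "n"], x$king_summary[d, "mean"],
                  x$king_summary[d, "sd"]))
    }
  }
  invisible(x)
}
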