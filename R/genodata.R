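#' Ancestry-labelled genotype matrix
#'
#' The central container of the package: a samples x SNPs integer matrix in
#' additive encoding (0 = homozygous dominant/reference, 1 = heterozygous,
#' 2 = homozygous recessive/alternate, `NA` = missing) together with a
#' per-sample ancestry label.  Sample IDs are the matrix rownames, SNP IDs
#' the colnames; both must be unique.
#'
#' @param genotypes integer matrix with values in \{0, 1, 2, NA\}; rownames
#'   are sample IDs, colnames SNP IDs (supplied separately if absent).
#' @param ancestry character vector of ancestry labels, one per sample.
#' @param sample_ids,snp_ids optional explicit IDs overriding the dimnames.
#' @return an object of class `geno_matrix`: a list with elements
#'   `genotypes` (integer matrix with dimnames) and `ancestry` (character,
#'   named by sample ID).
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 1L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("snp1", "snp2")))
#' gm <- geno_matrix(g, ancestry = c("African", "European"))
#' gm
#' @export
geno_matrix <- function(genotypes, ancestry,
                        sample_ids = rownames(genotypes),
                        snp_ids = colnames(genotypes)) {
  if (!is.matrix(genotypes)) {
    stop("'genotypes' must be a matrix")
  }
  if (is.null(sample_ids) || is.null(snp_ids)) {
    stop("sample and SNP IDs are required (dimnames or explicit arguments)")
  }
  storage.mode(genotypes) <- "integer"
  dimnames(genotypes) <- list(as.character(sample_ids), as.character(snp_ids))
  ancestry <- as.character(ancestry)
  if (length(ancestry) != nrow(genotypes)) {
    stop("ancestry must have one label per sample")
  }
  obj <- structure(list(genotypes = genotypes,
                        ancestry = stats::setNames(ancestry, rownames(genotypes))),
                   class = "geno_matrix")
  validate_geno_matrix(obj)
  obj
}

validate_geno_matrix <- function(x) {
  g <- x$genotypes
  sid <- rownames(g)
  if (anyDuplicated(sid)) {
    stop("duplicate sample IDs: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  if (anyDuplicated(colnames(g))) {
    stop("duplicate SNP IDs: ",
         paste(unique(colnames(g)[duplicated(colnames(g))]), collapse = ", "))
  }
  bad <- !is.na(g) & !(g %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("genotype value outside {0,1,2,NA} at sample '%s', SNP '%s'",
                 rownames(g)[idx[1L]], colnames(g)[idx[2L]]))
  }
  if (length(x$ancestry) != nrow(g)) {
    stop("ancestry must have one label per sample")
  }
  if (anyNA(x$ancestry)) {
    stop("missing ancestry label")
  }
  invisible(x)
}

#' @export
print.geno_matrix <- function(x, ...) {
  g <- x$genotypes
  cat(sprintf("geno_matrix: %d samples x %d SNPs\n", nrow(g), ncol(g)))
  tab <- table(x$ancestry)
  cat("ancestry: ",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  nm <- sum(is.na(g))
  cat(sprintf("missing genotypes: %d (%.2f%%)\n", nm, 100 * nm / length(g)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$genotypes)

#' Accessors for geno_matrix components
#' @param x a `geno_matrix`.
#' @return `sample_ids()` and `snp_ids()` return character vectors;
#'   `ancestry_of()` the named ancestry vector; `genotypes_of()` the integer
#'   matrix.
#' @export
sample_ids <- function(x) rownames(x$genotypes)

#' @rdname sample_ids
#' @export
snp_ids <- function(x) colnames(x$genotypes)

#' @rdname sample_ids
#' @export
ancestry_of <- function(x) x$ancestry

#' @rdname sample_ids
#' @export
genotypes_of <- function(x) x$genotypes

#' Subset a geno_matrix by samples and/or SNPs
#'
#' @param x a `geno_matrix`.
#' @param samples,snps index vectors (integer, logical or ID character);
#'   `NULL` keeps the axis unchanged.
#' @return a `geno_matrix`.
#' @export
gm_subset <- function(x, samples = NULL, snps = NULL) {
  g <- x$genotypes
  anc <- x$ancestry
  if (!is.null(samples)) {
    g <- g[samples, , drop = FALSE]
    anc <- anc[rownames(g)]
  }
  if (!is.null(snps)) {
    g <- g[, snps, drop = FALSE]
  }
  geno_matrix(g, ancestry = anc)
}

#' Combine two geno_matrix objects over the sample axis
#' @param x,y `geno_matrix` objects sharing an identical SNP axis.
#' @return a `geno_matrix` with the samples of `x` followed by those of `y`.
#' @export
gm_rbind <- function(x, y) {
  if (!identical(colnames(x$genotypes), colnames(y$genotypes))) {
    stop("SNP axes differ; cannot combine")
  }
  geno_matrix(rbind(x$genotypes, y$genotypes),
              ancestry = c(x$ancestry, y$ancestry))
}

#' Read a Sample SNP Data CSV
#'
#' Layout: column 1 = Sample ID, column 2 = Ancestry, columns 3+ = one SNP
#' per column with additive genotypes.  Header row required; comma
#' separated; missing genotypes are encoded by `missing_token`.
#'
#' @param path path to the CSV file.
#' @param missing_token string standing for a missing genotype
#'   (default `"NA"`).
#' @return a [geno_matrix()].
#' @export
read_sample_snp_csv <- function(path, missing_token = "NA") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = "character", na.strings = NULL,
                          data.table = FALSE)
  if (ncol(dt) < 3L) stop("expected at least 3 columns (ID, ancestry, >=1 SNP)")
  sid <- dt[[1L]]
  if (anyDuplicated(sid)) {
    stop("duplicate sample IDs in ", path, ": ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  anc <- dt[[2L]]
  g <- parse_genotype_columns(dt[, -(1:2), drop = FALSE], sid, missing_token)
  geno_matrix(g, ancestry = anc)
}

#' Read a Synthetic Relatives SNP Data CSV
#'
#' Layout: column 1 = Sample ID, columns 2+ = SNP genotypes.  The relatives
#' file carries no ancestry column; labels can be supplied via `ancestry`
#' (default: the placeholder `"unknown"`).
#'
#' @inheritParams read_sample_snp_csv
#' @param ancestry optional character vector (length 1 or one per row).
#' @return a [geno_matrix()].
#' @export
read_relatives_snp_csv <- function(path, missing_token = "NA",
                                   ancestry = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = "character", na.strings = NULL,
                          data.table = FALSE)
  if (ncol(dt) < 2L) stop("expected at least 2 columns (ID, >=1 SNP)")
  sid <- dt[[1L]]
  if (anyDuplicated(sid)) stop("duplicate sample IDs in ", path)
  g <- parse_genotype_columns(dt[, -1L, drop = FALSE], sid, missing_token)
  geno_matrix(g, ancestry = rep_len(ancestry, nrow(g)))
}

# Strict parse of character genotype columns: cells must be "0", "1", "2"
# or the missing token; anything else is a hard error naming the cell.
parse_genotype_columns <- function(df, sample_id, missing_token) {
  m <- as.matrix(df)
  ok <- m %in% c("0", "1", "2", missing_token)
  if (!all(ok)) {
    idx <- which(!ok)[1L]
    r <- ((idx - 1L) %% nrow(m)) + 1L
    c_ <- ((idx - 1L) %/% nrow(m)) + 1L
    stop(sprintf("invalid genotype '%s' at sample '%s', SNP '%s' (row %d, column %d)",
                 m[r, c_], sample_id[r], colnames(m)[c_], r, c_))
  }
  m[m == missing_token] <- NA_character_
  g <- matrix(as.integer(m), nrow(m), ncol(m),
              dimnames = list(sample_id, colnames(m)))
  g
}

#' Write a geno_matrix as a Sample SNP Data CSV
#'
#' @param gm a [geno_matrix()].
#' @param path output file path.
#' @param missing_token string written for missing genotypes.
#' @return the path, invisibly.
#' @export
write_sample_snp_csv <- function(gm, path, missing_token = "NA") {
  g <- gm$genotypes
  dt <- data.table::data.table(sample_id = rownames(g),
                               ancestry = unname(gm$ancestry))
  dt <- cbind(dt, data.table::as.data.table(g))
  data.table::fwrite(dt, path, na = missing_token, quote = FALSE)
  invisible(path)
}

#' Binary phenotype set
#'
#' Stores the simulated 0/1 phenotype per sample, plus the generating ground
#' truth: the causal SNP IDs, their logit coefficients and the intercept.
#'
#' @param phenotype integer vector of 0/1 labels, named by sample ID.
#' @param causal_snps character vector of causal SNP IDs.
#' @param coefficients numeric vector named by causal SNP ID.
#' @param intercept numeric scalar.
#' @param case_fraction target case fraction used to balance the labels.
#' @return an object of class `phenotype_set`.
#' @export
phenotype_set <- function(phenotype, causal_snps = character(),
                          coefficients = numeric(), intercept = 0,
                          case_fraction = NA_real_) {
  phenotype <- stats::setNames(as.integer(phenotype), names(phenotype))
  if (is.null(names(phenotype))) stop("phenotype must be named by sample ID")
  if (!all(phenotype %in% 0:1)) stop("phenotype values must be 0 or 1")
  if (length(coefficients) != length(causal_snps)) {
    stop("one coefficient per causal SNP required")
  }
  structure(list(phenotype = phenotype,
                 causal_snps = as.character(causal_snps),
                 coefficients = stats::setNames(as.numeric(coefficients),
                                                causal_snps),
                 intercept = intercept,
                 case_fraction = case_fraction),
            class = "phenotype_set")
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat(sprintf("phenotype_set: %d samples (%d cases / %d controls), %d causal SNPs\n",
              length(x$phenotype), sum(x$phenotype == 1L),
              sum(x$phenotype == 0L), length(x$causal_snps)))
  invisible(x)
}

#' Watermark SNP block
#'
#' @param genotypes integer matrix (samples x watermark SNPs) with dimnames.
#' @param p_values numeric vector of association p-values, one per column.
#' @param flags logical vector marking columns whose logistic fit hit the
#'   iteration cap (near-separation); optional.
#' @return an object of class `watermark_block`.
#' @export
watermark_block <- function(genotypes, p_values,
                            flags = rep(FALSE, ncol(genotypes))) {
  storage.mode(genotypes) <- "integer"
  if (length(p_values) != ncol(genotypes)) {
    stop("one p-value per watermark SNP required")
  }
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  structure(list(genotypes = genotypes,
                 snp_ids = colnames(genotypes),
                 p_values = stats::setNames(as.numeric(p_values),
                                            colnames(genotypes)),
                 flags = flags),
            class = "watermark_block")
}

#' @export
print.watermark_block <- function(x, ...) {
  cat(sprintf("watermark_block: %d SNPs x %d samples; mean p = %.3g\n",
              ncol(x$genotypes), nrow(x$genotypes), mean(x$p_values)))
  invisible(x)
}

#' Assemble a complete synthetic dataset bundle
#'
#' Holds everything the five-file CSV export needs: synthetic samples,
#' synthetic relatives (same SNP axis), the phenotype set, the watermark
#' block and the kinship table, plus run provenance.
#'
#' @param samples `geno_matrix` of synthetic (non-relative) samples.
#' @param relatives `geno_matrix` of synthetic relatives; may have 0 rows.
#' @param phenotype a [phenotype_set()] covering at least the samples.
#' @param watermark a [watermark_block()] whose rows match `samples`.
#' @param kinship data.frame with columns `sample_id`, `related_sample_id`,
#'   `degree`, `king`.
#' @param provenance list of run configuration and seed; free-form.
#' @return an object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(samples, relatives, phenotype, watermark,
                           kinship = empty_kinship(), provenance = list()) {
  if (nrow(relatives$genotypes) > 0L &&
      !identical(colnames(samples$genotypes), colnames(relatives$genotypes))) {
    stop("relatives' SNP axis must equal the samples' SNP axis")
  }
  known <- c(rownames(samples$genotypes), rownames(relatives$genotypes))
  if (nrow(kinship) > 0L) {
    refs <- unique(c(kinship$sample_id, kinship$related_sample_id))
    if (!all(refs %in% known)) {
      stop("kinship records reference unknown sample IDs: ",
           paste(utils::head(setdiff(refs, known), 5L), collapse = ", "))
    }
  }
  structure(list(samples = samples, relatives = relatives,
                 phenotype = phenotype, watermark = watermark,
                 kinship = kinship, provenance = provenance),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("dataset_bundle: %d samples + %d relatives, %d data SNPs + %d watermark SNPs\n",
              nrow(x$samples$genotypes), nrow(x$relatives$genotypes),
              ncol(x$samples$genotypes), ncol(x$watermark$genotypes)))
  cat(sprintf("kinship pairs: %d\n", nrow(x$kinship)))
  invisible(x)
}

#' @rdname dataset_bundle
#' @export
empty_kinship <- function() {
  data.frame(sample_id = character(), related_sample_id = character(),
             degree = character(), king = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a dataset bundle as the five-file CSV folder
#'
#' Writes, into `dir`: `sample_snp_data.csv` (Sample ID, Ancestry, SNP
#' columns), `phenotype_condition_data.csv` (Sample ID, Phenotype
#' Condition), `watermark_snp_data.csv` (Sample ID row labels, one column
#' per watermark SNP, and one final row carrying the association p-values),
#' `kinship_relatedness_data.csv` (Sample ID, related Sample ID,
#' Relatedness, Kinship Coefficient) and `synthetic_relatives_snp_data.csv`
#' (Sample ID, SNP columns).
#'
#' @param bundle a [dataset_bundle()].
#' @param dir output directory (created if absent).
#' @param missing_token string written for missing genotypes.
#' @return character vector of the five file paths written.
#' @export
write_bundle <- function(bundle, dir, missing_token = "NA") {
  stopifnot(inherits(bundle, "dataset_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sm <- bundle$samples
  ph <- bundle$phenotype$phenotype
  if (!all(rownames(sm$genotypes) %in% names(ph))) {
    stop("phenotype is missing labels for some samples")
  }

  paths <- file.path(dir, c("sample_snp_data.csv",
                            "phenotype_condition_data.csv",
                            "watermark_snp_data.csv",
                            "kinship_relatedness_data.csv",
                            "synthetic_relatives_snp_data.csv"))

  write_sample_snp_csv(sm, paths[1L], missing_token)

  data.table::fwrite(
    data.table::data.table(sample_id = rownames(sm$genotypes),
                           phenotype = unname(ph[rownames(sm$genotypes)])),
    paths[2L], quote = FALSE)

  wm <- bundle$watermark
  wdt <- data.table::data.table(sample_id = c(rownames(wm$genotypes), "p_value"))
  for (j in seq_along(wm$snp_ids)) {
    wdt[[wm$snp_ids[j]]] <- c(wm$genotypes[, j], wm$p_values[j])
  }
  data.table::fwrite(wdt, paths[3L], quote = FALSE)

  kin <- bundle$kinship
  data.table::fwrite(
    data.table::data.table(sample_id = kin$sample_id,
                           related_sample_id = kin$related_sample_id,
                           relatedness = kin$degree,
                           kinship_coefficient = kin$king),
    paths[4L], quote = FALSE)

  rel <- bundle$relatives$genotypes
  rdt <- data.table::data.table(sample_id = rownames(rel))
  rdt <- cbind(rdt, data.table::as.data.table(rel))
  data.table::fwrite(rdt, paths[5L], na = missing_token, quote = FALSE)

  paths
}

#' Import genotypes from a VCF file (convenience)
#'
#' Collapses diploid GT fields to additive counts of the first ALT allele;
#' any call containing a missing allele becomes `NA`.  Requires the `vcfR`
#' package.
#'
#' @param path path to a VCF (v4.x) file.
#' @param ancestry character vector (length 1 or one per sample).
#' @return a [geno_matrix()] (samples x SNPs).
#' @export
read_vcf_genotypes <- function(path, ancestry = "unknown") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the 'vcfR' package is required for VCF import")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(cell) {
    if (is.na(cell)) return(NA_integer_)
    alleles <- strsplit(cell, "[/|]")[[1L]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  }
  g <- apply(gt, c(1, 2), alt_count)
  g <- t(g)  # vcfR is variants x samples
  if (is.null(colnames(g))) colnames(g) <- paste0("snp", seq_len(ncol(g)))
  geno_matrix(g, ancestry = rep_len(ancestry, nrow(g)))
}
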