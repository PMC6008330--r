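#' Domain containers
#'
#' Lightweight S3 containers used throughout the package. All are validated
#' lists built around plain matrices and data frames so they interoperate
#' directly with base modelling functions.
#'
#' @name methmediate-types
NULL

#' Construct a table of variant records
#'
#' @param id,chrom,pos,effect_allele,other_allele,maf parallel vectors; `maf`
#'   is the effect-allele frequency, constrained to (0, 0.5].
#' @return a `data.frame` with one row per variant.
#' @export
variant_records <- function(id, chrom, pos, effect_allele, other_allele, maf) {
  v <- data.frame(id = as.character(id), chrom = as.character(chrom),
                  pos = as.integer(pos),
                  effect_allele = toupper(effect_allele),
                  other_allele = toupper(other_allele),
                  maf = as.numeric(maf), stringsAsFactors = FALSE)
  if (anyDuplicated(v$id)) stop_spec("duplicate variant ids")
  if (any(v$pos < 1)) stop_spec("variant pos must be >= 1")
  if (any(v$effect_allele == v$other_allele))
    stop_spec("effect and other allele must differ")
  if (any(v$maf <= 0 | v$maf > 0.5)) stop_spec("maf must lie in (0, 0.5]")
  v
}

#' Genotype dosage table
#'
#' @param sample_ids character vector of sample names.
#' @param variants variant data frame (see [variant_records()]).
#' @param dosages numeric matrix, samples x variants, values in \[0, 2\].
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(sample_ids, variants, dosages) {
  dosages <- as.matrix(dosages)
  if (anyDuplicated(sample_ids)) stop_spec("duplicate sample ids")
  if (nrow(dosages) != length(sample_ids) || ncol(dosages) != nrow(variants))
    stop_spec("dosage matrix dimensions do not match id lists")
  if (any(!is.finite(dosages))) stop_spec("dosages must be finite")
  if (any(dosages < 0 | dosages > 2)) stop_spec("dosages must lie in [0, 2]")
  dimnames(dosages) <- list(sample_ids, variants$id)
  structure(list(sample_ids = as.character(sample_ids), variants = variants,
                 dosages = dosages), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table> ", length(x$sample_ids), " samples x ",
      nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}

#' Probe annotation table
#'
#' @param id,chrom,pos,relation_to_island parallel vectors;
#'   `relation_to_island` is one of island/shore/shelf/open_sea.
#' @return a `data.frame` with one row per probe.
#' @export
probe_records <- function(id, chrom, pos,
                          relation_to_island = "open_sea") {
  rel <- match.arg(rep(relation_to_island, length.out = length(id)),
                   c("island", "shore", "shelf", "open_sea"), several.ok = TRUE)
  p <- data.frame(id = as.character(id), chrom = as.character(chrom),
                  pos = as.integer(pos), relation_to_island = rel,
                  stringsAsFactors = FALSE)
  if (any(p$pos < 1)) stop_spec("probe pos must be >= 1")
  p
}

#' Methylation beta-value table
#'
#' Beta values are methylation fractions on \[0, 1\] (the array convention
#' M/(M+U+offset)). `probes` may describe individual CpGs or, after
#' [collapse_regions()], region clusters.
#'
#' @param sample_ids character vector.
#' @param probes probe data frame (see [probe_records()]).
#' @param betas numeric matrix, samples x probes, in \[0, 1\].
#' @return object of class `methylation_table`.
#' @export
methylation_table <- function(sample_ids, probes, betas) {
  betas <- as.matrix(betas)
  if (nrow(betas) != length(sample_ids) || ncol(betas) != nrow(probes))
    stop_spec("beta matrix dimensions do not match id lists")
  if (any(!is.finite(betas)) || any(betas < 0 | betas > 1))
    stop_spec("betas must lie in [0, 1]")
  dimnames(betas) <- list(sample_ids, probes$id)
  structure(list(sample_ids = as.character(sample_ids), probes = probes,
                 betas = betas), class = "methylation_table")
}

#' @export
print.methylation_table <- function(x, ...) {
  cat("<methylation_table> ", length(x$sample_ids), " samples x ",
      nrow(x$probes), " probes\n", sep = "")
  invisible(x)
}

#' Binary phenotype plus covariates
#'
#' @param sample_ids character vector.
#' @param status integer 0 (control) / 1 (case).
#' @param covariates data frame of numeric covariate columns (age, sex,
#'   smoking, batch, cell-count PCs, ancestry PCs, ...). May be `NULL`.
#' @return object of class `phenotype_table`.
#' @export
phenotype_table <- function(sample_ids, status, covariates = NULL) {
  status <- as.integer(status)
  if (!all(status %in% c(0L, 1L))) stop_spec("status must be 0/1")
  if (length(status) != length(sample_ids)) stop_spec("status length mismatch")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(sample_ids))
      stop_spec("covariates row count mismatch")
  }
  structure(list(sample_ids = as.character(sample_ids), status = status,
                 covariates = covariates), class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat("<phenotype_table> ", length(x$sample_ids), " samples (",
      sum(x$status), " cases), ",
      if (is.null(x$covariates)) 0L else ncol(x$covariates),
      " covariates\n", sep = "")
  invisible(x)
}

#' Per-variant summary statistics for one trait
#'
#' @param id,chrom,pos,effect_allele,other_allele,beta,se,p,n,eaf parallel
#'   vectors; `eaf` (effect-allele frequency) is optional.
#' @return object of class `trait_summary_stats` (a data frame).
#' @export
trait_summary_stats <- function(id, chrom, pos, effect_allele, other_allele,
                                beta, se, p, n, eaf = NA_real_) {
  s <- data.frame(id = as.character(id), chrom = as.character(chrom),
                  pos = as.integer(pos),
                  effect_allele = toupper(effect_allele),
                  other_allele = toupper(other_allele),
                  beta = as.numeric(beta), se = as.numeric(se),
                  p = as.numeric(p), n = as.numeric(n),
                  eaf = as.numeric(eaf), stringsAsFactors = FALSE)
  if (anyDuplicated(s$id)) stop_spec("duplicate variant ids")
  if (any(s$se <= 0)) stop_spec("se must be > 0")
  if (any(!is.na(s$eaf) & (s$eaf <= 0 | s$eaf >= 1)))
    stop_spec("eaf must lie in (0, 1)")
  class(s) <- c("trait_summary_stats", "data.frame")
  s
}

#' Signed LD correlation matrix
#'
#' @param ids ordered variant ids.
#' @param r symmetric correlation matrix with unit diagonal; signs refer to
#'   the exposure effect alleles.
#' @return object of class `ld_matrix`.
#' @export
ld_matrix <- function(ids, r) {
  r <- as.matrix(r)
  if (nrow(r) != length(ids) || ncol(r) != length(ids))
    stop_spec("LD matrix dimensions do not match ids")
  if (max(abs(r - t(r))) > 1e-12) stop_spec("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-12) stop_spec("LD diagonal must be 1")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_spec("LD matrix is not positive semi-definite (min eigenvalue ",
              signif(min(ev), 3), ")")
  dimnames(r) <- list(ids, ids)
  structure(list(ids = as.character(ids), r = r), class = "ld_matrix")
}

#' Reference methylation signatures for cell deconvolution
#'
#' @param probe_ids character vector.
#' @param cell_types character vector (>= 2 types).
#' @param reference_betas matrix probes x cell types, in \[0, 1\].
#' @return object of class `cell_reference_panel`.
#' @export
cell_reference_panel <- function(probe_ids, cell_types, reference_betas) {
  reference_betas <- as.matrix(reference_betas)
  if (length(cell_types) < 2) stop_spec("need at least 2 cell types")
  if (nrow(reference_betas) != length(probe_ids) ||
      ncol(reference_betas) != length(cell_types))
    stop_spec("reference matrix dimensions mismatch")
  if (any(reference_betas < 0 | reference_betas > 1))
    stop_spec("reference betas must lie in [0, 1]")
  dimnames(reference_betas) <- list(probe_ids, cell_types)
  structure(list(probe_ids = as.character(probe_ids),
                 cell_types = as.character(cell_types),
                 reference_betas = reference_betas),
            class = "cell_reference_panel")
}
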