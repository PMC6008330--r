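#' Text-format readers and writers
#'
#' Plain-text interchange for every container: minimal VCFv4.2 and TSV
#' dosage matrices for genotypes, probe x sample TSVs plus annotation for
#' methylation, TSVs for phenotypes and GWAS summary statistics, an
#' id-labelled TSV for LD matrices, BED export for probe clusters
#' (converting the package's 1-based inclusive coordinates to BED's
#' 0-based half-open convention) and a JSON sidecar for simulation truth.
#'
#' @name methmediate-io
NULL

tsv_write <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

tsv_read <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a genotype table as minimal VCFv4.2
#'
#' GT is the rounded dosage; DS carries the dosage itself. The effect
#' allele is written as ALT.
#'
#' @param geno a [genotype_table()].
#' @param path output file.
#' @export
write_genotype_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$sample_ids), collapse = "\t")), con)
  gt_of <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(geno$variants))) {
    v <- geno$variants[j, ]
    ds <- geno$dosages[, j]
    cells <- paste0(gt_of[pmin(pmax(round(ds), 0), 2) + 1], ":",
                    format(ds, trim = TRUE))
    writeLines(paste(c(v$chrom, v$pos, v$id, v$other_allele,
                       v$effect_allele, ".", "PASS", ".", "GT:DS", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal VCF with DS fields back into a genotype table
#'
#' Only the subset written by [write_genotype_vcf()] is supported: the DS
#' entry of each FORMAT cell supplies the dosage (GT is used as fallback).
#' Effect-allele frequency is estimated from the dosages.
#'
#' @param path VCF file.
#' @return a [genotype_table()].
#' @export
read_genotype_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  cols <- strsplit(lines[hdr], "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  recs <- strsplit(body, "\t")
  dos <- matrix(0, length(samples), length(recs))
  v <- data.frame(id = character(length(recs)), chrom = "", pos = 0L,
                  effect_allele = "", other_allele = "", maf = 0,
                  stringsAsFactors = FALSE)
  for (j in seq_along(recs)) {
    r <- recs[[j]]
    fmt <- strsplit(r[9], ":")[[1]]
    ds_i <- match("DS", fmt)
    cells <- strsplit(r[-(1:9)], ":")
    dos[, j] <- if (!is.na(ds_i)) {
      as.numeric(vapply(cells, `[[`, "", ds_i))
    } else {
      vapply(cells, function(cc) {
        sum(as.integer(strsplit(cc[1], "[/|]")[[1]]))
      }, 0)
    }
    v$id[j] <- r[3]; v$chrom[j] <- r[1]; v$pos[j] <- as.integer(r[2])
    v$other_allele[j] <- r[4]; v$effect_allele[j] <- r[5]
  }
  freq <- colMeans(dos) / 2
  v$maf <- clamp(freq, 1e-6, 0.5)
  genotype_table(samples, v, dos)
}

#' Write / read a TSV dosage matrix
#'
#' Variants as rows (id, chrom, pos, effect_allele, other_allele, maf, then
#' one column per sample).
#'
#' @param geno a [genotype_table()].
#' @param path file path.
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- cbind(geno$variants, as.data.frame(t(geno$dosages)))
  tsv_write(df, path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- tsv_read(path)
  meta <- c("id", "chrom", "pos", "effect_allele", "other_allele", "maf")
  samples <- setdiff(colnames(df), meta)
  genotype_table(samples, df[meta], t(as.matrix(df[samples])))
}

#' Write / read methylation tables as TSV pairs
#'
#' `path` holds probes x samples beta values (first column `probe_id`);
#' `annotation_path` holds id, chrom, pos, relation_to_island.
#'
#' @param meth a [methylation_table()].
#' @param path,annotation_path file paths.
#' @export
write_methylation_tsv <- function(meth, path, annotation_path) {
  tsv_write(cbind(data.frame(probe_id = meth$probes$id),
                  as.data.frame(t(meth$betas))), path)
  tsv_write(meth$probes, annotation_path)
  invisible(path)
}

#' @rdname write_methylation_tsv
#' @export
read_methylation_tsv <- function(path, annotation_path) {
  vals <- tsv_read(path)
  ann <- tsv_read(annotation_path)
  samples <- setdiff(colnames(vals), "probe_id")
  ann <- ann[match(vals$probe_id, ann$id), ]
  methylation_table(samples,
                    probe_records(ann$id, ann$chrom, ann$pos,
                                  ann$relation_to_island),
                    t(as.matrix(vals[samples])))
}

#' Write / read phenotype tables
#'
#' @param pheno a [phenotype_table()].
#' @param path file path.
#' @export
write_phenotype_tsv <- function(pheno, path) {
  df <- data.frame(sample_id = pheno$sample_ids, status = pheno$status)
  if (!is.null(pheno$covariates)) df <- cbind(df, pheno$covariates)
  tsv_write(df, path)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  df <- tsv_read(path)
  cov_cols <- setdiff(colnames(df), c("sample_id", "status"))
  phenotype_table(df$sample_id, df$status,
                  if (length(cov_cols)) df[cov_cols] else NULL)
}

#' Write / read GWAS summary statistics
#'
#' Columns SNP, CHR, POS, EA, OA, BETA, SE, P, N, EAF.
#'
#' @param stats a [trait_summary_stats()].
#' @param path file path.
#' @export
write_summary_stats_tsv <- function(stats, path) {
  tsv_write(data.frame(SNP = stats$id, CHR = stats$chrom, POS = stats$pos,
                       EA = stats$effect_allele, OA = stats$other_allele,
                       BETA = stats$beta, SE = stats$se, P = stats$p,
                       N = stats$n, EAF = stats$eaf), path)
  invisible(path)
}

#' @rdname write_summary_stats_tsv
#' @export
read_summary_stats_tsv <- function(path) {
  df <- tsv_read(path)
  trait_summary_stats(df$SNP, df$CHR, df$POS, df$EA, df$OA, df$BETA,
                      df$SE, df$P, df$N, df$EAF %||% NA_real_)
}

#' Write / read an LD matrix TSV (ids as header row and first column)
#'
#' @param ld an [ld_matrix()].
#' @param path file path.
#' @export
write_ld_tsv <- function(ld, path) {
  df <- cbind(data.frame(id = ld$ids), as.data.frame(ld$r))
  tsv_write(df, path)
  invisible(path)
}

#' @rdname write_ld_tsv
#' @export
read_ld_tsv <- function(path) {
  df <- tsv_read(path)
  ld_matrix(df$id, as.matrix(df[, -1, drop = FALSE]))
}

#' Export probe clusters as BED
#'
#' BED is 0-based half-open, so `start - 1` / `end` bracket the 1-based
#' inclusive cluster span.
#'
#' @param clusters a `region_cluster_set`.
#' @param path file path.
#' @export
clusters_to_bed <- function(clusters, path) {
  df <- data.frame(
    chrom = vapply(clusters, `[[`, "", "chrom"),
    start = vapply(clusters, function(cl) cl$start, 0) - 1,
    end = vapply(clusters, function(cl) cl$end, 0),
    name = vapply(clusters, `[[`, "", "cluster_id"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' JSON sidecar for a simulation truth object
#'
#' @param truth a [sim_truth()].
#' @param path file path.
#' @export
write_sim_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    scenario = truth$scenario,
    path_effects = as.list(truth$path_effects),
    planted_dmr = truth$planted_dmr,
    driver_variant = truth$driver_variant,
    seed = truth$seed), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
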