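#' Cluster probes into candidate regions
#'
#' Within each chromosome, consecutive probes whose inter-probe gap is at
#' most `max_gap_bp` (and, when `use_island_annotation` is set, that share
#' the same relation to a CpG island) are assigned to the same cluster.
#' Clusters are maximal and every probe belongs to exactly one cluster.
#' Unsorted input is sorted internally; duplicate positions are allowed.
#'
#' @param probes probe data frame (see [probe_records()]).
#' @param max_gap_bp maximum gap between consecutive probes of one cluster
#'   (default 500 bp, the conventional clustering default for this array
#'   platform).
#' @param use_island_annotation split clusters at island-annotation changes.
#' @return a `region_cluster_set`: list of clusters, each with `cluster_id`,
#'   `chrom`, `member_probe_ids`, `start`, `end` (1-based inclusive).
#' @export
cluster_probes <- function(probes, max_gap_bp = 500,
                           use_island_annotation = FALSE) {
  if (max_gap_bp <= 0) stop_spec("max_gap_bp must be > 0")
  ord <- order(probes$chrom, probes$pos)
  p <- probes[ord, , drop = FALSE]
  n <- nrow(p)
  new_cluster <- c(TRUE, (p$chrom[-1] != p$chrom[-n]) |
                     (p$pos[-1] - p$pos[-n] > max_gap_bp))
  if (use_island_annotation && n > 1) {
    new_cluster <- new_cluster |
      c(FALSE, p$relation_to_island[-1] != p$relation_to_island[-n])
  }
  cl <- cumsum(new_cluster)
  clusters <- lapply(split(seq_len(n), cl), function(i) {
    list(cluster_id = sprintf("cl%04d", cl[i[1]]),
         chrom = p$chrom[i[1]],
         member_probe_ids = p$id[i],
         start = min(p$pos[i]), end = max(p$pos[i]))
  })
  names(clusters) <- vapply(clusters, `[[`, "", "cluster_id")
  structure(clusters, class = "region_cluster_set")
}

#' @export
print.region_cluster_set <- function(x, ...) {
  cat("<region_cluster_set> ", length(x), " clusters, ",
      sum(vapply(x, function(cl) length(cl$member_probe_ids), 0L)),
      " probes\n", sep = "")
  invisible(x)
}

#' Per-probe cluster index
#'
#' Maps probe ids onto the integer index of their cluster, in the order the
#' clusters appear in `clusters`.
#'
#' @param clusters a `region_cluster_set`.
#' @param probe_ids probe ids to map.
#' @return integer vector parallel to `probe_ids` (NA when unclustered).
#' @export
probe_cluster_index <- function(clusters, probe_ids) {
  map <- rep(seq_along(clusters),
             vapply(clusters, function(cl) length(cl$member_probe_ids), 0L))
  names(map) <- unlist(lapply(clusters, `[[`, "member_probe_ids"))
  unname(map[probe_ids])
}

#' Collapse probe-level methylation to cluster-level values
#'
#' One output column per cluster: the arithmetic mean of the member probes'
#' beta values per sample (the collapsed-CpG analysis used upstream of DMR
#' and causal testing).
#'
#' @param meth a [methylation_table()].
#' @param clusters a `region_cluster_set` whose members are all in `meth`.
#' @return a cluster-level [methylation_table()] whose probes carry the
#'   cluster ids, chromosome and start position.
#' @export
collapse_regions <- function(meth, clusters) {
  missing <- setdiff(unlist(lapply(clusters, `[[`, "member_probe_ids")),
                     meth$probes$id)
  if (length(missing))
    stop_spec("cluster members missing from methylation table: ",
              paste(missing, collapse = ", "))
  vals <- vapply(clusters, function(cl) {
    rowMeans(meth$betas[, cl$member_probe_ids, drop = FALSE])
  }, numeric(length(meth$sample_ids)))
  vals <- matrix(vals, nrow = length(meth$sample_ids))
  pr <- probe_records(vapply(clusters, `[[`, "", "cluster_id"),
                      vapply(clusters, `[[`, "", "chrom"),
                      vapply(clusters, function(cl) cl$start, 0),
                      "open_sea")
  methylation_table(meth$sample_ids, pr, vals)
}

#' Reference-based cell-fraction estimation
#'
#' Per sample, solves a non-negative least-squares fit of the sample's beta
#' values on the reference signatures (Houseman-style deconvolution). When
#' `normalize` is set the unit-sum constraint is imposed by augmenting the
#' system with a heavily weighted sum row rather than rescaling afterwards,
#' so an absent cell type does not distort the remaining fits.
#'
#' @param meth a [methylation_table()].
#' @param panel a [cell_reference_panel()]; its probes must intersect `meth`
#'   in at least as many probes as there are cell types.
#' @param normalize force fractions to sum to one.
#' @return object of class `cell_fractions`: `sample_ids`, `cell_types`,
#'   `fractions` (samples x types).
#' @export
estimate_cell_fractions <- function(meth, panel, normalize = FALSE) {
  shared <- intersect(panel$probe_ids, meth$probes$id)
  k <- length(panel$cell_types)
  if (length(shared) < k)
    stop_spec("need at least ", k, " shared probes, have ", length(shared))
  A <- panel$reference_betas[shared, , drop = FALSE]
  qa <- qr(A)
  if (qa$rank < k) {
    dep <- panel$cell_types[qa$pivot[(qa$rank + 1):k]]
    stop_spec("reference panel is rank deficient; collinear cell types: ",
              paste(dep, collapse = ", "))
  }
  B <- meth$betas[, shared, drop = FALSE]
  lambda <- 1e4  # weight of the unit-sum constraint row
  Aa <- if (normalize) rbind(A, lambda) else A
  fr <- t(apply(B, 1, function(b) {
    bb <- if (normalize) c(b, lambda) else b
    pracma::lsqnonneg(Aa, bb)$x
  }))
  dimnames(fr) <- list(meth$sample_ids, panel$cell_types)
  structure(list(sample_ids = meth$sample_ids, cell_types = panel$cell_types,
                 fractions = fr), class = "cell_fractions")
}

#' @export
print.cell_fractions <- function(x, ...) {
  cat("<cell_fractions> ", length(x$sample_ids), " samples x ",
      length(x$cell_types), " cell types\n", sep = "")
  invisible(x)
}

#' Principal components of estimated cell fractions
#'
#' Column-centers the fraction matrix and projects it on the top
#' `n_pc` right singular vectors; the returned score columns are orthogonal
#' and ordered by variance explained, ready to be used as covariates.
#'
#' @param fracs a `cell_fractions` object.
#' @param n_pc number of components (must be < number of cell types).
#' @return numeric matrix samples x `n_pc` with columns `CellPC1`, ...;
#'   variance explained in `attr(, "var_explained")` and the centered input's
#'   full SVD reconstruction available through `attr(, "svd")`.
#' @export
cell_fraction_pcs <- function(fracs, n_pc = 2) {
  if (n_pc <= 0) stop_spec("n_pc must be > 0")
  k <- length(fracs$cell_types)
  if (n_pc >= k) stop_spec("n_pc must be < number of cell types")
  X <- scale(fracs$fractions, center = TRUE, scale = FALSE)
  sv <- svd(X)
  scores <- sv$u[, seq_len(n_pc), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pc)], n_pc)
  dimnames(scores) <- list(fracs$sample_ids, paste0("CellPC", seq_len(n_pc)))
  attr(scores, "var_explained") <- sv$d^2 / sum(sv$d^2)
  attr(scores, "svd") <- sv
  scores
}
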