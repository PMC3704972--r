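#' Read a long-format qPCR Ct table
#'
#' @param path TSV with columns `gene`, `condition`, `replicate`, `ct`.
#' @return Data frame with those columns; errors on non-positive Ct values.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct)) || any(df$ct <= 0)) stop("Ct values must be > 0")
  df
}

.mean_ct <- function(ct, gene, condition) {
  rows <- ct$gene == gene & ct$condition == condition
  if (!any(rows)) return(NA_real_)
  mean(ct$ct[rows])
}

#' Relative expression by the delta-delta Ct method
#'
#' Replicate Ct values are averaged (arithmetic mean) per gene and condition.
#' Then `dCt(s) = Ct(target, s) - Ct(reference, s)`,
#' `ddCt = dCt(sample) - dCt(calibrator)`, and the fold change is
#' `2^(-ddCt)` (perfect doubling per PCR cycle; no efficiency correction).
#' The calibrator sample itself yields exactly 1.
#'
#' @param ct Long-format Ct data frame (see [read_ct_table()]).
#' @param target_gene Gene to quantify.
#' @param sample Condition/sample to quantify.
#' @param reference_gene Internal reference (housekeeping) gene.
#' @param calibrator Calibrator condition/sample.
#' @return Fold change (unitless, > 0).
#' @export
ddct_fold_change <- function(ct, target_gene, sample, reference_gene,
                             calibrator) {
  if (sample == calibrator) return(1)
  t_s <- .mean_ct(ct, target_gene, sample)
  r_s <- .mean_ct(ct, reference_gene, sample)
  t_c <- .mean_ct(ct, target_gene, calibrator)
  r_c <- .mean_ct(ct, reference_gene, calibrator)
  if (is.na(r_s) || is.na(r_c))
    stop("missing reference-gene Ct for ", reference_gene,
         " in sample or calibrator")
  if (is.na(t_s) || is.na(t_c))
    stop("missing Ct for target ", target_gene, " in sample or calibrator")
  ddct <- (t_s - r_s) - (t_c - r_c)
  2^(-ddct)
}

#' Fold-change matrix from a Ct table
#'
#' Applies [ddct_fold_change()] to every target gene and condition.
#'
#' @inheritParams ddct_fold_change
#' @return Numeric matrix: target genes x conditions, fold change vs the
#'   calibrator.
#' @export
ddct_table <- function(ct, reference_gene, calibrator) {
  genes <- setdiff(unique(ct$gene), reference_gene)
  conds <- unique(ct$condition)
  m <- matrix(NA_real_, length(genes), length(conds),
              dimnames = list(genes, conds))
  for (g in genes) for (cc in conds)
    m[g, cc] <- ddct_fold_change(ct, g, cc, reference_gene, calibrator)
  m
}

#' Hierarchical clustering of an expression matrix
#'
#' Agglomerative clustering with pairwise Euclidean distances and complete
#' linkage (inter-cluster distance is the maximum pairwise distance), the
#' combination used by the Cluster 3.0 defaults this emulates. Merge heights
#' of complete linkage are non-decreasing; this is asserted on every run.
#'
#' @param mat Numeric matrix (genes x conditions).
#' @param axis `"rows"` to cluster genes, `"columns"` to cluster conditions.
#' @return An [stats::hclust] object (merge list plus heights).
#' @export
hierarchical_cluster <- function(mat, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- if (axis == "columns") t(mat) else mat
  if (nrow(m) < 2) stop("need at least 2 ", axis, " to cluster")
  h <- stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
  stopifnot(!is.unsorted(h$height))
  h
}

#' Cut a dendrogram into k clusters
#'
#' @param dendrogram An [stats::hclust] object.
#' @param k Number of clusters (1..n).
#' @return Named integer vector of cluster labels.
#' @export
cut_dendrogram <- function(dendrogram, k) {
  n <- length(dendrogram$labels)
  if (k < 1 || k > n) stop("k must be between 1 and ", n)
  stats::cutree(dendrogram, k = k)
}

#' Per-gene fold change versus a reference condition
#'
#' @param mat Expression matrix (genes x conditions, values >= 0).
#' @param reference_condition Column used as denominator.
#' @return Matrix of `value / value(reference)`; genes with a zero reference
#'   value are flagged with a warning and reported as `NA`.
#' @export
tissue_fold_summary <- function(mat, reference_condition) {
  if (!reference_condition %in% colnames(mat))
    stop("reference condition not present: ", reference_condition)
  ref <- mat[, reference_condition]
  if (any(ref == 0)) {
    warning("zero reference value for gene(s): ",
            paste(rownames(mat)[ref == 0], collapse = ", "),
            "; folds reported as NA")
    ref[ref == 0] <- NA_real_
  }
  sweep(mat, 1, ref, "/")
}
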