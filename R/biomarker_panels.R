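#' Select a top differentially abundant protein panel
#'
#' Picks the `k` most differentially abundant proteins from a DAP table:
#' ascending p, ties broken by larger absolute log2 difference, then by
#' protein id for full determinism. A pure function of the DAP table.
#'
#' @param dap_table A DAP table from [anova_bh()].
#' @param k Panel size (default 12).
#' @return Character vector of `k` protein ids, in rank order.
#' @export
select_top_daps <- function(dap_table, k = 12L) {
  stopifnot(k >= 2)
  tested <- dap_table[!is.na(dap_table$p), ]
  if (nrow(tested) < k)
    stop("only ", nrow(tested), " tested proteins; need ", k)
  ord <- order(tested$p, -abs(tested$log2_diff), tested$protein)
  tested$protein[ord[seq_len(k)]]
}

#' PCA of samples on a biomarker panel
#'
#' Z-scores the panel rows (median-imputing residual missing values),
#' excludes samples missing more than half of the panel, and computes the
#' first two principal components over samples, with per-group centroids
#' and standard errors.
#'
#' @param matrix Proteins x samples log2 matrix.
#' @param panel Character vector of panel protein ids.
#' @param traits Traits data.frame (`sample_id`, `group`).
#' @return List: `scores` (data.frame sample_id, PC1, PC2, group),
#'   `var_explained` (length-2 fraction per component), `centroids`
#'   (data.frame group, PC1, PC2, se1, se2, n), `excluded` (sample ids).
#' @export
panel_pca <- function(matrix, panel, traits) {
  missing_panel <- setdiff(panel, rownames(matrix))
  if (length(missing_panel) > 0)
    stop("panel proteins absent from matrix: ",
         paste(missing_panel, collapse = ", "))
  sub <- matrix[panel, , drop = FALSE]
  frac_miss <- colMeans(is.na(sub))
  excluded <- colnames(sub)[frac_miss > 0.5]
  sub <- sub[, frac_miss <= 0.5, drop = FALSE]
  if (ncol(sub) < 3) stop("fewer than 3 samples retained for panel PCA")
  Z <- .standardize_rows(sub)
  sv <- svd(t(Z))                      # samples x proteins
  scores <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2, 2)
  ve <- (sv$d^2 / sum(sv$d^2))[1:2]
  grp <- traits$group[match(colnames(sub), traits$sample_id)]
  sc <- data.frame(sample_id = colnames(sub), PC1 = scores[, 1],
                   PC2 = scores[, 2], group = grp, stringsAsFactors = FALSE)
  cent <- do.call(rbind, lapply(split(sc, sc$group), function(d)
    data.frame(group = d$group[1], PC1 = mean(d$PC1), PC2 = mean(d$PC2),
               se1 = stats::sd(d$PC1) / sqrt(nrow(d)),
               se2 = stats::sd(d$PC2) / sqrt(nrow(d)),
               n = nrow(d), stringsAsFactors = FALSE)))
  rownames(cent) <- NULL
  list(scores = sc, var_explained = ve, centroids = cent,
       excluded = excluded)
}

#' Two-way hierarchical clustering of a biomarker panel
#'
#' Clusters samples and panel proteins (Euclidean distance on the z-scored
#' panel submatrix, average linkage), cuts the sample tree into two classes,
#' and tabulates each class's diagnosis-group composition so classes can be
#' described as e.g. "ALS-enriched" vs "control-enriched".
#'
#' @inheritParams panel_pca
#' @param linkage Agglomeration method (default `"average"`).
#' @return List: `sample_tree`, `protein_tree` (hclust), `two_class_cut`
#'   (named integer 1/2 per sample), `composition` (class x group table),
#'   `excluded`.
#' @export
panel_cluster <- function(matrix, panel, traits, linkage = "average") {
  sub <- matrix[panel, , drop = FALSE]
  frac_miss <- colMeans(is.na(sub))
  excluded <- colnames(sub)[frac_miss > 0.5]
  sub <- sub[, frac_miss <= 0.5, drop = FALSE]
  if (ncol(sub) < 3) stop("fewer than 3 samples retained for clustering")
  Z <- .standardize_rows(sub)
  sample_tree <- stats::hclust(stats::dist(t(Z)), method = linkage)
  protein_tree <- stats::hclust(stats::dist(Z), method = linkage)
  cut2 <- stats::cutree(sample_tree, k = 2)
  grp <- traits$group[match(colnames(sub), traits$sample_id)]
  composition <- table(class = cut2, group = grp)
  list(sample_tree = sample_tree, protein_tree = protein_tree,
       two_class_cut = cut2, composition = composition, excluded = excluded)
}
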