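#' Remove proteins with too many missing values
#'
#' Drops every protein that is absent in at least `max_missing_frac` of the
#' subject specimens (pooled-reference channels are excluded from the
#' denominator). The published rule removes proteins "absent in 50% or more
#' of specimens", hence the default and the closed lower bound.
#'
#' @param matrix Proteins x samples log2 matrix, `NA` = missing.
#' @param max_missing_frac Removal threshold; rows with missing fraction
#'   `>= max_missing_frac` are dropped. Default 0.5.
#' @param is_reference Optional logical (named or aligned to columns)
#'   flagging pooled-reference channels.
#' @return The filtered matrix, row order preserved.
#' @export
filter_by_missingness <- function(matrix, max_missing_frac = 0.5,
                                  is_reference = NULL) {
  stopifnot(nrow(matrix) > 0, ncol(matrix) > 0,
            max_missing_frac > 0, max_missing_frac <= 1)
  subj <- seq_len(ncol(matrix))
  if (!is.null(is_reference)) {
    ref <- if (!is.null(names(is_reference)))
      is_reference[colnames(matrix)] else is_reference
    subj <- which(!ref)
  }
  frac <- rowMeans(is.na(matrix[, subj, drop = FALSE]))
  keep <- frac < max_missing_frac
  if (!any(keep))
    stop("missingness filter removed every protein (threshold ",
         max_missing_frac, ")")
  matrix[keep, , drop = FALSE]
}

#' TAMPOR: median polish of ratio normalization across batches
#'
#' Harmonizes log2 abundances across TMT batches or collection centers.
#' Values are first converted to log2 ratios against a per-batch, per-protein
#' denominator — the median of the batch's pooled-reference (GIS) channels
#' (`"gis_denominator"`, the TMT-style mode) or the median over all samples
#' in the batch (`"all_sample_denominator"`, the label-free mode). The ratio
#' matrix then undergoes alternating median polish (subtract per-protein row
#' medians, then per-sample column medians, missing values ignored) until
#' both residual median magnitudes fall to `tol` or `max_iter` is reached.
#' The global per-protein median abundance is added back so output stays on
#' the log2-abundance scale.
#'
#' @param matrix Proteins x samples log2 matrix (reference channels
#'   included for GIS mode).
#' @param batch Character/factor of batch (or center) ids, one per column;
#'   may be named by sample id.
#' @param is_reference Logical per column flagging reference channels
#'   (required for `"gis_denominator"`).
#' @param mode Denominator choice, see above.
#' @param tol Convergence tolerance in log2 units.
#' @param max_iter Maximum polish iterations.
#' @return List with `normalized` (matrix, same shape) and `report`
#'   (iterations, max_abs_row_median, max_abs_col_median, converged).
#' @export
tampor_normalize <- function(matrix, batch, is_reference = NULL,
                             mode = c("gis_denominator",
                                      "all_sample_denominator"),
                             tol = 1e-4, max_iter = 250L) {
  mode <- match.arg(mode)
  stopifnot(tol > 0, max_iter >= 1)
  if (!is.null(names(batch))) batch <- batch[colnames(matrix)]
  if (length(batch) != ncol(matrix) || anyNA(batch))
    stop("every sample must be assigned a batch/center")
  batch <- as.character(batch)
  if (!is.null(is_reference) && !is.null(names(is_reference)))
    is_reference <- is_reference[colnames(matrix)]
  if (mode == "gis_denominator") {
    if (is.null(is_reference))
      stop("gis_denominator mode requires is_reference flags")
    for (b in unique(batch))
      if (!any(is_reference[batch == b]))
        stop("batch '", b, "' has no reference channel for gis mode")
  }

  row_center <- apply(matrix, 1, stats::median, na.rm = TRUE)
  ratio <- matrix
  for (b in unique(batch)) {
    cols <- which(batch == b)
    denom_cols <- if (mode == "gis_denominator")
      cols[is_reference[cols]] else cols
    denom <- apply(matrix[, denom_cols, drop = FALSE], 1,
                   stats::median, na.rm = TRUE)
    ratio[, cols] <- matrix[, cols, drop = FALSE] - denom
  }

  iter <- 0L
  repeat {
    rm_ <- apply(ratio, 1, stats::median, na.rm = TRUE)
    rm_[is.na(rm_)] <- 0
    ratio <- ratio - rm_
    cm_ <- apply(ratio, 2, stats::median, na.rm = TRUE)
    cm_[is.na(cm_)] <- 0
    ratio <- sweep(ratio, 2, cm_)
    iter <- iter + 1L
    max_row <- max(abs(apply(ratio, 1, stats::median, na.rm = TRUE)), na.rm = TRUE)
    max_col <- max(abs(apply(ratio, 2, stats::median, na.rm = TRUE)), na.rm = TRUE)
    if ((max_row <= tol && max_col <= tol) || iter >= max_iter) break
  }
  list(normalized = ratio + row_center,
       report = list(iterations = iter,
                     max_abs_row_median = max_row,
                     max_abs_col_median = max_col,
                     converged = max_row <= tol && max_col <= tol))
}

#' Classical multidimensional scaling of samples for QC
#'
#' Projects samples into two dimensions by classical MDS on Euclidean
#' distances; missing cells are median-imputed per protein for the distance
#' computation only. Used to visualize batch/center structure before and
#' after normalization.
#'
#' @param matrix Proteins x samples matrix.
#' @param traits Optional traits data.frame (adds group/batch/center labels
#'   to the output for plotting).
#' @return Data.frame: sample_id, dim1, dim2, plus any label columns.
#' @export
mds_qc <- function(matrix, traits = NULL) {
  if (ncol(matrix) < 3) stop("MDS needs at least 3 samples")
  imp <- impute_row_medians(matrix)
  d <- stats::dist(t(imp))
  xy <- stats::cmdscale(d, k = 2)
  out <- data.frame(sample_id = colnames(matrix),
                    dim1 = xy[, 1], dim2 = xy[, 2],
                    stringsAsFactors = FALSE)
  if (!is.null(traits)) {
    idx <- match(out$sample_id, traits$sample_id)
    for (col in intersect(c("group", "batch", "center", "platform"),
                          colnames(traits)))
      out[[col]] <- traits[[col]][idx]
  }
  out
}

#' Flag outlier samples by standardized network connectivity
#'
#' Computes each sample's total connectivity (sum of its pairwise Pearson
#' correlations with all other samples), standardizes across samples, and
#' flags samples whose z-score falls below `outlier_z`. Flagging only; the
#' caller decides about removal.
#'
#' @param matrix Proteins x samples matrix.
#' @param outlier_z Z threshold, default -3 (flag if z below it).
#' @return Data.frame: sample_id, connectivity_z, flagged.
#' @export
detect_outliers <- function(matrix, outlier_z = -3) {
  if (ncol(matrix) < 4) stop("outlier screen needs at least 4 samples")
  cc <- stats::cor(matrix, use = "pairwise.complete.obs")
  diag(cc) <- 0
  k <- rowSums(cc, na.rm = TRUE)
  z <- as.numeric(scale(k))
  data.frame(sample_id = colnames(matrix), connectivity_z = z,
             flagged = z < outlier_z, stringsAsFactors = FALSE)
}

# Median-impute each row's missing values (in place, for distances/PCA only).
impute_row_medians <- function(matrix) {
  miss <- which(is.na(matrix), arr.ind = TRUE)
  if (nrow(miss) == 0L) return(matrix)
  med <- apply(matrix, 1, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  matrix[miss] <- med[miss[, 1]]
  matrix
}
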