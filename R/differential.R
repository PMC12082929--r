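# Vectorized one-way ANOVA across the rows of a matrix.
# labels: one group label per column. Proteins where any group has < 2
# non-missing values are reported untested (NA statistics).
oneway_anova_rows <- function(matrix, labels) {
  labels <- as.character(labels)
  groups <- unique(labels)
  n_g <- s_g <- ss_g <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    cols <- which(labels == groups[gi])
    sub <- matrix[, cols, drop = FALSE]
    obs <- !is.na(sub)
    n_g[[gi]] <- rowSums(obs)
    sub0 <- sub; sub0[!obs] <- 0
    s_g[[gi]] <- rowSums(sub0)
    ss_g[[gi]] <- rowSums(sub0^2)
  }
  n_mat <- do.call(cbind, n_g); s_mat <- do.call(cbind, s_g)
  ss_mat <- do.call(cbind, ss_g)
  tested <- rowSums(n_mat < 2) == 0
  N <- rowSums(n_mat)
  gm <- rowSums(s_mat) / N
  m_mat <- s_mat / n_mat
  ssb <- rowSums(n_mat * (m_mat - gm)^2)
  ssw <- rowSums(ss_mat - n_mat * m_mat^2)
  dfb <- length(groups) - 1
  dfw <- N - length(groups)
  F_stat <- (ssb / dfb) / (ssw / dfw)
  p <- stats::pf(F_stat, dfb, dfw, lower.tail = FALSE)
  # zero within-group variance with a real between-group difference
  p[tested & ssw <= 0 & ssb > 0] <- 0
  F_stat[!tested] <- NA_real_; p[!tested] <- NA_real_
  list(F_stat = F_stat, p = p, means = m_mat, ns = n_mat,
       groups = groups, tested = tested)
}

#' Differential protein abundance: one-way ANOVA with BH correction
#'
#' For each requested two-group comparison, computes a one-way (equal
#' variance) ANOVA F and p per protein on the two groups' non-missing
#' values, applies Benjamini-Hochberg correction across all tested proteins
#' within the comparison, and reports the log2 difference
#' (mean of `groupB` minus mean of `groupA`) with a direction call:
#' `up` if `p < alpha` and the difference is positive, `down` if negative,
#' `ns` otherwise. Proteins with fewer than two non-missing values in either
#' group are reported untested (`NA` statistics, direction `ns`).
#'
#' @param matrix Proteins x samples log2 matrix.
#' @param groups Named character vector mapping sample id to group label
#'   (or unnamed, aligned with columns).
#' @param comparisons List of length-2 character vectors `c(groupA, groupB)`.
#' @param alpha Significance level for the direction call (default 0.05).
#' @return A named list of DAP tables (one per comparison), each a
#'   data.frame: protein, comparison, log2_diff, F_stat, p, q, direction,
#'   n_A, n_B.
#' @export
anova_bh <- function(matrix, groups, comparisons, alpha = 0.05) {
  if (!is.null(names(groups))) groups <- groups[colnames(matrix)]
  if (length(groups) != ncol(matrix))
    stop("groups must map every sample column")
  out <- list()
  for (cmp in comparisons) {
    stopifnot(length(cmp) == 2)
    if (!all(cmp %in% groups))
      stop("unknown group label(s): ",
           paste(setdiff(cmp, groups), collapse = ", "))
    cols <- which(groups %in% cmp)
    res <- oneway_anova_rows(matrix[, cols, drop = FALSE], groups[cols])
    ia <- match(cmp[1], res$groups); ib <- match(cmp[2], res$groups)
    log2_diff <- res$means[, ib] - res$means[, ia]
    q <- rep(NA_real_, length(res$p))
    q[res$tested] <- stats::p.adjust(res$p[res$tested], method = "BH")
    direction <- rep("ns", length(res$p))
    direction[res$tested & res$p < alpha & log2_diff > 0] <- "up"
    direction[res$tested & res$p < alpha & log2_diff < 0] <- "down"
    name <- paste(cmp[2], "vs", cmp[1])
    out[[name]] <- data.frame(
      protein = rownames(matrix), comparison = name,
      log2_diff = log2_diff, F_stat = res$F_stat, p = res$p, q = q,
      direction = direction,
      n_A = res$ns[, ia], n_B = res$ns[, ib],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

#' Cross-tabulate DAP membership across comparisons
#'
#' Builds the per-protein significance membership vector across two or more
#' DAP tables (Venn-diagram content) and the aggregate count for every
#' intersection cell.
#'
#' @param tables Named list of DAP tables from [anova_bh()].
#' @param alpha Significance threshold on raw p (default 0.05).
#' @return List with `membership` (data.frame: protein, one logical column
#'   per table) and `counts` (data.frame: pattern, count; pattern is the
#'   `+`/`-` signature in table order).
#' @export
compare_dap_sets <- function(tables, alpha = 0.05) {
  stopifnot(length(tables) >= 2)
  if (is.null(names(tables)))
    names(tables) <- paste0("table", seq_along(tables))
  proteins <- unique(unlist(lapply(tables, `[[`, "protein")))
  membership <- data.frame(protein = proteins, stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    t_ <- tables[[nm]]
    sig <- t_$protein[!is.na(t_$p) & t_$p < alpha]
    membership[[nm]] <- proteins %in% sig
  }
  pattern <- apply(membership[, -1, drop = FALSE], 1,
                   function(v) paste(ifelse(v, "+", "-"), collapse = ""))
  counts <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  colnames(counts) <- c("pattern", "count")
  list(membership = membership, counts = counts)
}

#' Cross-platform effect-size concordance
#'
#' Restricts two DAP tables to the proteins significant (raw `p < alpha`) in
#' both, correlates their log2 differences by biweight midcorrelation with a
#' Student-t p-value, and counts sign-agreement quadrants.
#'
#' @param tableA,tableB DAP tables from [anova_bh()].
#' @param alpha Significance threshold (default 0.05).
#' @return List: bicor_r, p, n_shared, quadrant_counts (both_up, both_down,
#'   up_down, down_up), proteins.
#' @export
effectsize_concordance <- function(tableA, tableB, alpha = 0.05) {
  a <- tableA[!is.na(tableA$p) & tableA$p < alpha, ]
  b <- tableB[!is.na(tableB$p) & tableB$p < alpha, ]
  shared <- intersect(a$protein, b$protein)
  if (length(shared) < 5)
    stop("insufficient overlap: ", length(shared),
         " proteins significant in both tables (need >= 5)")
  da <- a$log2_diff[match(shared, a$protein)]
  db <- b$log2_diff[match(shared, b$protein)]
  r <- bicor(da, db)
  quadrants <- c(both_up = sum(da > 0 & db > 0),
                 both_down = sum(da < 0 & db < 0),
                 up_down = sum(da > 0 & db <= 0),
                 down_up = sum(da <= 0 & db > 0))
  list(bicor_r = r, p = cor_p_value(r, length(shared)),
       n_shared = length(shared), quadrant_counts = quadrants,
       proteins = shared)
}

#' Map peptides onto a canonical protein sequence
#'
#' Finds every exact-substring occurrence of each peptide in the canonical
#' sequence and returns 1-based inclusive coordinates; peptides with no
#' match are flagged unmapped. Used for peptide-level views such as the
#' SOD1 (P00441) coverage map.
#'
#' @param peptides Character vector of upper-case amino-acid strings.
#' @param canonical_seq Upper-case amino-acid string.
#' @return Data.frame: peptide, start, end, mapped (unmapped peptides get a
#'   single row with `NA` coordinates).
#' @export
map_peptides_to_sequence <- function(peptides, canonical_seq) {
  stopifnot(is.character(canonical_seq), length(canonical_seq) == 1)
  if (any(!nzchar(peptides))) stop("empty peptide string")
  rows <- list()
  for (pep in peptides) {
    hits <- gregexpr(pep, canonical_seq, fixed = TRUE)[[1]]
    if (hits[1] == -1) {
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, start = NA_integer_, end = NA_integer_,
        mapped = FALSE, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, start = as.integer(hits),
        end = as.integer(hits) + nchar(pep) - 1L,
        mapped = TRUE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname csfnet_io
#' @param dap_table A DAP table from [anova_bh()].
#' @export
write_dap_tsv <- function(dap_table, path) {
  utils::write.table(dap_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
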