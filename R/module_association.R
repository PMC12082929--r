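#' Module-trait association by biweight midcorrelation
#'
#' For each disease group, subsets the cohort to that group plus controls,
#' codes the trait as disease = 1 / control = 0, and correlates every module
#' eigenprotein with the binary trait using bicor; the p-value is the
#' Student-t tail at `n - 2` degrees of freedom. Star annotations follow the
#' conventional raw-p thresholds 0.05 / 0.01 / 0.001; BH q-values across the
#' table are also reported. Subsets with fewer than 5 samples are untestable
#' (`NA` statistics).
#'
#' @param eigenproteins An `eigenprotein_set`.
#' @param traits Traits data.frame (`sample_id`, `group`).
#' @param disease_groups Groups to test against control; default every
#'   non-control group present.
#' @param control_group Reference group label (default `"control"`).
#' @return Data.frame: module, trait, bicor_r, p, q, n_used, stars.
#' @export
module_trait_bicor <- function(eigenproteins, traits, disease_groups = NULL,
                               control_group = "control") {
  E <- eigenproteins$eigenproteins
  idx <- match(colnames(E), traits$sample_id)
  if (anyNA(idx)) stop("every eigenprotein sample needs a trait row")
  grp <- traits$group[idx]
  if (!any(grp == control_group)) stop("control group is empty")
  if (is.null(disease_groups))
    disease_groups <- setdiff(unique(grp), control_group)
  rows <- list()
  for (g in disease_groups) {
    if (!any(grp == g)) stop("disease group is empty: ", g)
    use <- which(grp %in% c(g, control_group))
    y <- as.numeric(grp[use] == g)
    for (m in rownames(E)) {
      if (length(use) < 5) {
        rows[[length(rows) + 1L]] <- data.frame(
          module = m, trait = g, bicor_r = NA_real_, p = NA_real_,
          n_used = length(use), stringsAsFactors = FALSE)
        next
      }
      r <- bicor(E[m, use], y)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, trait = g, bicor_r = r,
        p = cor_p_value(r, length(use)), n_used = length(use),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$stars <- ifelse(is.na(out$p), "",
                      ifelse(out$p < 0.001, "***",
                             ifelse(out$p < 0.01, "**",
                                    ifelse(out$p < 0.05, "*", ""))))
  rownames(out) <- NULL
  out
}

#' One-way ANOVA of eigenproteins across diagnosis groups
#'
#' Tests each module eigenprotein for any difference across all diagnosis
#' groups, with BH correction across modules.
#'
#' @param eigenproteins An `eigenprotein_set`.
#' @param groups Named character vector sample -> group (or aligned with
#'   eigenprotein columns).
#' @return Data.frame: module, F_stat, p, q.
#' @export
eigenprotein_anova <- function(eigenproteins, groups) {
  E <- eigenproteins$eigenproteins
  if (!is.null(names(groups))) groups <- groups[colnames(E)]
  if (length(groups) != ncol(E)) stop("groups must map every sample")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 samples each")
  res <- oneway_anova_rows(E, groups)
  data.frame(module = rownames(E), F_stat = res$F_stat, p = res$p,
             q = stats::p.adjust(res$p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlay differential abundance on network modules
#'
#' Per module (and for unassigned proteins as their own category), the
#' fraction of member proteins that are differentially abundant in the given
#' comparison and the mean log2 difference of those members.
#'
#' @param dap_table A DAP table from [anova_bh()].
#' @param partition A `module_partition` or named label vector.
#' @param alpha Significance threshold on raw p (default 0.05).
#' @return Data.frame: module, n_members, n_da, frac_da, mean_log2_diff
#'   (`NA` when a module has no DAPs).
#' @export
dap_module_overlay <- function(dap_table, partition, alpha = 0.05) {
  labels <- if (inherits(partition, "module_partition"))
    partition$labels else partition
  shared <- intersect(names(labels), dap_table$protein)
  if (length(shared) == 0) stop("partition and DAP table share no proteins")
  labels <- labels[shared]
  dt <- dap_table[match(shared, dap_table$protein), ]
  cat_ <- ifelse(is.na(labels), "unassigned", labels)
  mods <- unique(cat_)
  mods <- mods[order(match(mods != "unassigned", c(TRUE, FALSE)),
                     suppressWarnings(as.integer(sub("^M", "", mods))))]
  rows <- lapply(mods, function(m) {
    mem <- which(cat_ == m)
    sig <- mem[!is.na(dt$p[mem]) & dt$p[mem] < alpha]
    data.frame(module = m, n_members = length(mem), n_da = length(sig),
               frac_da = length(sig) / length(mem),
               mean_log2_diff = if (length(sig) > 0)
                 mean(dt$log2_diff[sig]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
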