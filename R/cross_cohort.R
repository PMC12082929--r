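#' Permutation Zsummary module preservation across cohorts
#'
#' Quantifies how well reference-cohort modules persist in a test cohort.
#' For each module, three observed statistics are computed on the module's
#' proteins shared with the test cohort: density (mean off-diagonal signed
#' adjacency in the test network), the correlation between reference and
#' test intramodular connectivity vectors, and the correlation between the
#' reference and test pairwise correlation entries. A null distribution
#' comes from `n_perm` random protein sets of the same size drawn uniformly
#' from the shared test proteins; each statistic is standardized to
#' `Z = (obs - null mean) / null SD`. `Z_density` is the density Z,
#' `Z_connectivity` the median of the two connectivity Zs, and
#' `Z_summary = (Z_density + Z_connectivity) / 2`. Under this permutation
#' null, `Z_summary` maps to an upper-tail normal probability, so 2 marks
#' nominal preservation (p ~ 0.05) and 10 strong preservation (p ~ 1e-23).
#' `median_rank` ranks modules by observed statistics (1 = best preserved),
#' insensitive to module size.
#'
#' @param ref_matrix,test_matrix Proteins x samples log2 matrices sharing a
#'   protein namespace.
#' @param partition Reference `module_partition` or named label vector.
#' @param n_perm Number of permutations (default 500; >= 50 recommended for
#'   stable Z scores).
#' @param beta Soft-threshold power for the signed adjacency.
#' @param max_p_outliers Bicor outlier cap.
#' @param seed Integer seed for the permutation draws.
#' @return Data.frame: module, size (shared proteins), Z_density,
#'   Z_connectivity, Z_summary, median_rank. Modules with fewer than 5
#'   shared proteins get `NA` statistics; modules with under 50% of their
#'   proteins present are flagged in `low_overlap`.
#' @export
module_preservation <- function(ref_matrix, test_matrix, partition,
                                n_perm = 500L, beta = 4,
                                max_p_outliers = 0.05, seed = 1L) {
  labels <- if (inherits(partition, "module_partition"))
    partition$labels else partition
  stopifnot(n_perm >= 1)
  shared <- intersect(intersect(names(labels), rownames(ref_matrix)),
                      rownames(test_matrix))
  if (length(shared) < 10) stop("too few shared proteins for preservation")
  cor_ref <- bicor_matrix(ref_matrix[shared, , drop = FALSE],
                          max_p_outliers = max_p_outliers)
  cor_test <- bicor_matrix(test_matrix[shared, , drop = FALSE],
                           max_p_outliers = max_p_outliers)
  shared <- intersect(rownames(cor_ref), rownames(cor_test))
  cor_ref <- cor_ref[shared, shared]; cor_test <- cor_test[shared, shared]
  adj_ref <- signed_adjacency(cor_ref, beta)
  adj_test <- signed_adjacency(cor_test, beta)

  stats_for <- function(idx) {
    s <- length(idx)
    at <- adj_test[idx, idx]; ar <- adj_ref[idx, idx]
    dens <- (sum(at) - s) / (s * (s - 1))
    kim_r <- rowSums(ar) - 1; kim_t <- rowSums(at) - 1
    c(density = dens,
      cor_kim = suppressWarnings(stats::cor(kim_r, kim_t)),
      cor_cor = suppressWarnings(stats::cor(
        cor_ref[idx, idx][upper.tri(ar)], cor_test[idx, idx][upper.tri(at)])))
  }

  mods <- unique(stats::na.omit(labels))
  mods <- mods[order(suppressWarnings(as.integer(sub("^M", "", mods))), mods)]
  set.seed(derive_seed(seed, "module_preservation"))
  rows <- list(); obs_mat <- list()
  for (m in mods) {
    all_mem <- names(labels)[which(labels == m)]
    idx <- match(intersect(all_mem, shared), shared)
    low_overlap <- length(idx) < 0.5 * length(all_mem)
    if (length(idx) < 5) {
      rows[[m]] <- data.frame(module = m, size = length(idx),
                              Z_density = NA_real_, Z_connectivity = NA_real_,
                              Z_summary = NA_real_, median_rank = NA_real_,
                              low_overlap = low_overlap,
                              stringsAsFactors = FALSE)
      next
    }
    obs <- stats_for(idx)
    null_mat <- matrix(NA_real_, nrow = n_perm, ncol = 3)
    for (b in seq_len(n_perm))
      null_mat[b, ] <- stats_for(sample.int(length(shared), length(idx)))
    mu <- colMeans(null_mat, na.rm = TRUE)
    sdv <- apply(null_mat, 2, stats::sd, na.rm = TRUE)
    z <- (obs - mu) / sdv
    z_dens <- z[["density"]]
    z_conn <- stats::median(c(z[["cor_kim"]], z[["cor_cor"]]))
    obs_mat[[m]] <- obs
    rows[[m]] <- data.frame(module = m, size = length(idx),
                            Z_density = z_dens, Z_connectivity = z_conn,
                            Z_summary = (z_dens + z_conn) / 2,
                            median_rank = NA_real_,
                            low_overlap = low_overlap,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  ok <- !is.na(out$Z_summary)
  if (sum(ok) > 1) {
    om <- do.call(rbind, obs_mat)
    ranks <- apply(-om, 2, rank, ties.method = "average")
    out$median_rank[ok] <- apply(ranks, 1, stats::median)
  } else if (sum(ok) == 1) out$median_rank[ok] <- 1
  rownames(out) <- NULL
  out
}

#' Map a preservation Z score to its upper-tail significance
#'
#' Under the permutation null, a module's standardized preservation
#' statistic is approximately standard normal, so the conventional guide
#' thresholds translate directly: Zsummary = 2 corresponds to p ~ 0.05
#' (nominal preservation) and Zsummary = 10 to p ~ 1e-23 (strong
#' preservation).
#'
#' @param z Zsummary value(s).
#' @return Upper-tail standard normal probability.
#' @export
zsummary_significance <- function(z) stats::pnorm(z, lower.tail = FALSE)

#' Synthetic eigenproteins from top-kME hubs
#'
#' Projects reference-cohort modules into a test cohort without rebuilding
#' the network there: each module's members are ranked by reference
#' intramodular kME, the top `hub_fraction` (at least `min_hubs`, extending
#' down the ranking as needed when hubs are absent from the test cohort)
#' are taken, and the synthetic module eigenprotein is the first principal
#' component of the standardized hub rows in the test matrix, sign-aligned
#' to a positive mean hub correlation.
#'
#' @param ref_kme kME matrix from [kme_table()] on the reference cohort.
#' @param partition Reference `module_partition` or named label vector.
#' @param test_matrix Proteins x samples matrix of the test cohort.
#' @param hub_fraction Fraction of members counted as hubs (default 0.20).
#' @param min_hubs Minimum hubs that must be found in the test cohort
#'   (default 4); modules that cannot reach it are skipped with a warning.
#' @return An `eigenprotein_set` over test-cohort samples, with an extra
#'   `hubs` element listing the proteins used per module.
#' @export
synthetic_eigenproteins <- function(ref_kme, partition, test_matrix,
                                    hub_fraction = 0.20, min_hubs = 4L) {
  labels <- if (inherits(partition, "module_partition"))
    partition$labels else partition
  stopifnot(hub_fraction > 0, hub_fraction <= 1, min_hubs >= 2)
  mods <- intersect(colnames(ref_kme), unique(stats::na.omit(labels)))
  E <- list(); ve <- c(); hubs_used <- list()
  for (m in mods) {
    mem <- names(labels)[which(labels == m)]
    mem <- mem[mem %in% rownames(ref_kme)]
    ranked <- mem[order(-ref_kme[mem, m])]
    n_hub <- ceiling(hub_fraction * length(ranked))
    take <- ranked[seq_len(n_hub)]
    hubs <- intersect(take, rownames(test_matrix))
    i <- n_hub
    while (length(hubs) < min_hubs && i < length(ranked)) {
      i <- i + 1L
      if (ranked[i] %in% rownames(test_matrix))
        hubs <- c(hubs, ranked[i])
    }
    if (length(hubs) < min_hubs) {
      warning("module ", m, ": fewer than ", min_hubs,
              " hubs found in test cohort; skipped")
      next
    }
    Z <- test_matrix[hubs, , drop = FALSE]
    if (all(apply(Z, 1, function(v) stats::sd(v, na.rm = TRUE)) == 0)) {
      warning("module ", m, ": hub profiles constant in test cohort ",
              "(degenerate variance); skipped")
      next
    }
    Zs <- .standardize_rows(Z)
    sv <- svd(Zs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    e <- (e - mean(e)) / stats::sd(e)
    if (mean(Zs %*% e) < 0) e <- -e
    E[[m]] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
    hubs_used[[m]] <- hubs
  }
  if (length(E) == 0) stop("no module could be projected into the test cohort")
  Em <- do.call(rbind, E)
  colnames(Em) <- colnames(test_matrix)
  structure(list(eigenproteins = Em, var_explained = ve, hubs = hubs_used),
            class = "eigenprotein_set")
}
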