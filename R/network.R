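#' Parameters for signed co-expression network construction
#'
#' Defaults follow the published CSF network build: soft-threshold power
#' beta = 4, deepSplit sensitivity 4, minimum module size 15, eigenprotein
#' merge cut height 0.07, signed network with a PAM-like assignment stage.
#'
#' @param beta Soft-threshold power (>= 1).
#' @param deep_split Branch-split sensitivity, integer 0-4; higher yields
#'   more, smaller modules.
#' @param min_module_size Smallest retainable module.
#' @param merge_cut_height Eigenprotein dissimilarity (1 - correlation)
#'   below which modules merge.
#' @param pam_stage Assign leftover proteins to the nearest module medoid
#'   (within that module's radius) after branch detection.
#' @param max_p_outliers Outlier cap fraction for bicor.
#' @return A `network_params` list.
#' @export
network_params <- function(beta = 4, deep_split = 4L, min_module_size = 15L,
                           merge_cut_height = 0.07, pam_stage = TRUE,
                           max_p_outliers = 0.05) {
  stopifnot(beta >= 1, deep_split %in% 0:4, min_module_size >= 2,
            merge_cut_height >= 0, merge_cut_height < 1)
  structure(list(beta = beta, deep_split = as.integer(deep_split),
                 min_module_size = as.integer(min_module_size),
                 merge_cut_height = merge_cut_height,
                 pam_stage = isTRUE(pam_stage),
                 network_type = "signed",
                 max_p_outliers = max_p_outliers),
            class = "network_params")
}

#' Signed soft-threshold adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2) ^ beta`, so anticorrelated proteins get
#' adjacency near 0 and perfectly correlated proteins 1.
#'
#' @param cor_matrix Symmetric correlation matrix, entries in `[-1, 1]`.
#' @param beta Soft-threshold power.
#' @return Adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
signed_adjacency <- function(cor_matrix, beta = 4) {
  stopifnot(all(abs(cor_matrix) <= 1 + 1e-12))
  a <- ((1 + cor_matrix) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_k a_ik a_kj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over `k != i, j` and `k_i` the connectivity of node i excluding
#' itself. Two proteins are topologically similar when they share network
#' neighbors even if their direct adjacency is modest. Diagonal is 1; the
#' clustering input is `1 - TOM`.
#'
#' @param adjacency Symmetric adjacency in `[0, 1]`, unit diagonal.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric")
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a                  # sum_k a_ik a_kj, k != i because diag 0
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# Mean within-subtree dissimilarity for every internal node of an hclust
# tree, computed bottom-up in O(n^2) via cross-block sums.
.node_stats <- function(hc, diss) {
  n <- nrow(diss)
  n_nodes <- nrow(hc$merge)
  members <- vector("list", n_nodes)
  pair_sum <- numeric(n_nodes)
  pair_n <- numeric(n_nodes)
  for (k in seq_len(n_nodes)) {
    ch <- hc$merge[k, ]
    get_m <- function(c) if (c < 0) -c else members[[c]]
    ma <- get_m(ch[1]); mb <- get_m(ch[2])
    cross <- sum(diss[ma, mb])
    sa <- if (ch[1] > 0) pair_sum[ch[1]] else 0
    sb <- if (ch[2] > 0) pair_sum[ch[2]] else 0
    na_ <- if (ch[1] > 0) pair_n[ch[1]] else 0
    nb_ <- if (ch[2] > 0) pair_n[ch[2]] else 0
    members[[k]] <- c(ma, mb)
    pair_sum[k] <- sa + sb + cross
    pair_n[k] <- na_ + nb_ + length(ma) * length(mb)
  }
  list(members = members, mean_within = pair_sum / pmax(pair_n, 1))
}

#' Detect network modules by dynamic-hybrid branch cutting
#'
#' Average-linkage hierarchical clustering of a TOM dissimilarity followed
#' by branch detection on the dendrogram. A subtree is a distinct branch
#' candidate if it has at least `min_module_size` members, its mean
#' within-branch dissimilarity (normalized to the tree's height range) does
#' not exceed a scatter ceiling mapped from `deep_split` 0-4 (0.64 at the
#' least sensitive to 0.95 at the most), and it sits below the height at
#' which it joins its sibling by an absolute cohesion gap, also mapped from
#' `deep_split` (0.16 down to 0.01 TOM-dissimilarity units). A candidate is
#' accepted whole when its deepest internal height gap shows no further
#' separable structure, and is otherwise descended into; on unstructured
#' data dendrogram gaps sit an order of magnitude below the smallest
#' threshold, so nothing is called a module there. Proteins in no distinct
#' branch stay unassigned unless the PAM stage places them: each leftover
#' protein joins the module with the nearest medoid (the member minimizing
#' total within-module dissimilarity), provided it lies within that
#' module's member-to-medoid radius. Ties and labels are deterministic.
#'
#' @param tom_dissim Square symmetric dissimilarity (`1 - TOM`), zero
#'   diagonal, with protein rownames.
#' @param params A [network_params()].
#' @return A `module_partition`: list with `labels` (named character, `NA`
#'   for unassigned), `sizes` (named, decreasing), `dendrogram` (hclust),
#'   `medoids`.
#' @export
detect_modules <- function(tom_dissim, params = network_params()) {
  n <- nrow(tom_dissim)
  ids <- rownames(tom_dissim) %||% paste0("p", seq_len(n))
  labels <- stats::setNames(rep(NA_character_, n), ids)
  if (n < params$min_module_size)
    return(structure(list(labels = labels, sizes = integer(0),
                          dendrogram = NULL, medoids = character(0)),
                     class = "module_partition"))
  if (any(abs(diag(tom_dissim)) > 1e-8)) stop("dissimilarity needs zero diagonal")
  hc <- stats::hclust(stats::as.dist(tom_dissim), method = "average")
  st <- .node_stats(hc, tom_dissim)

  h_lo <- stats::quantile(hc$height, 0.05, names = FALSE)
  h_hi <- max(hc$height)
  norm_h <- function(x) pmin(pmax((x - h_lo) / max(h_hi - h_lo, 1e-12), 0), 1)
  max_scatter <- c(0.64, 0.73, 0.82, 0.91, 0.95)[params$deep_split + 1L]
  # absolute cohesion gap (TOM-dissimilarity units): a branch must sit this
  # far below the height at which it joins its sibling; on unstructured
  # data dendrogram gaps are an order of magnitude smaller, so nothing is
  # called a module there
  abs_gap <- c(0.16, 0.08, 0.04, 0.02, 0.01)[params$deep_split + 1L]

  distinct <- function(node, h_join, gap) {
    node > 0 &&
      length(st$members[[node]]) >= params$min_module_size &&
      norm_h(st$mean_within[node]) <= max_scatter &&
      (h_join - hc$height[node]) >= gap
  }
  n_nodes <- nrow(hc$merge)
  # deepest internal separation of each subtree: the largest height gap
  # between an internal node and a sizable internal child anywhere below.
  # A branch whose deep gap is small is an indivisible cluster; a large
  # deep gap means real substructure to descend into.
  deep_gap <- numeric(n_nodes)
  gap_floor <- ceiling(params$min_module_size / 2)  # sub-minimum cores count
  for (k in seq_len(n_nodes)) {
    g <- 0
    for (c_ in hc$merge[k, ]) {
      if (c_ < 0) next
      g <- max(g, deep_gap[c_],
               if (length(st$members[[c_]]) >= gap_floor)
                 hc$height[k] - hc$height[c_] else 0)
    }
    deep_gap[k] <- g
  }

  modules <- list()
  stack <- list(list(node = n_nodes, mode = "explore"))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    k <- top$node
    if (top$mode == "try" && deep_gap[k] < 2 * abs_gap) {
      # distinct and internally indivisible: a module
      modules[[length(modules) + 1L]] <- st$members[[k]]
    } else {
      # keep descending; distinct children become candidates
      for (c_ in hc$merge[k, ]) {
        if (c_ < 0) next
        mode <- if (distinct(c_, hc$height[k], abs_gap)) "try" else "explore"
        stack[[length(stack) + 1L]] <- list(node = c_, mode = mode)
      }
    }
  }
  for (i in seq_along(modules))
    labels[modules[[i]]] <- paste0("raw", i)

  medoids <- character(0)
  if (length(modules) > 0 && params$pam_stage) {
    for (lab in unique(stats::na.omit(labels))) {
      mem <- which(labels == lab)
      med <- mem[which.min(rowSums(tom_dissim[mem, mem, drop = FALSE]))]
      medoids[lab] <- ids[med]
    }
    free <- which(is.na(labels))
    if (length(free) > 0) {
      labs <- names(medoids)
      med_idx <- match(medoids, ids)
      d_mat <- tom_dissim[free, med_idx, drop = FALSE]
      radii <- vapply(labs, function(lab) {
        mem <- which(labels == lab)
        max(tom_dissim[mem, med_idx[match(lab, labs)]])
      }, numeric(1))
      best <- apply(d_mat, 1, which.min)
      best_d <- d_mat[cbind(seq_along(free), best)]
      ok <- best_d < radii[best]
      labels[free[ok]] <- labs[best[ok]]
    }
  } else if (length(modules) > 0) {
    for (lab in unique(stats::na.omit(labels))) {
      mem <- which(labels == lab)
      medoids[lab] <- ids[mem[which.min(rowSums(
        tom_dissim[mem, mem, drop = FALSE]))]]
    }
  }

  relabeled <- .rank_module_labels(labels)
  structure(list(labels = relabeled$labels, sizes = relabeled$sizes,
                 dendrogram = hc,
                 medoids = stats::setNames(unname(medoids),
                                           relabeled$map[names(medoids)])),
            class = "module_partition")
}

# Rank module labels M1..Mk by decreasing size; ties broken by the
# lexicographically first member protein (determinism contract).
.rank_module_labels <- function(labels) {
  labs <- unique(stats::na.omit(labels))
  if (length(labs) == 0)
    return(list(labels = labels, sizes = integer(0),
                map = stats::setNames(character(0), character(0))))
  size <- vapply(labs, function(l) sum(labels == l, na.rm = TRUE), integer(1))
  first <- vapply(labs, function(l) sort(names(labels)[which(labels == l)])[1],
                  character(1))
  ord <- order(-size, first)
  map <- stats::setNames(paste0("M", seq_along(labs)), labs[ord])
  new_labels <- stats::setNames(
    ifelse(is.na(labels), NA_character_, map[labels]), names(labels))
  list(labels = new_labels,
       sizes = stats::setNames(size[ord], paste0("M", seq_along(labs))),
       map = map)
}

#' Module eigenproteins (first principal components)
#'
#' Per module, member rows are z-scored over samples (residual missing
#' values median-imputed), the first right-singular vector across samples is
#' extracted, standardized to zero mean and unit variance, and sign-aligned
#' so the mean correlation with member profiles is positive.
#' `var_explained` is the leading singular value's share of total variance.
#'
#' @param matrix Proteins x samples matrix.
#' @param labels Named character vector protein -> module (`NA` allowed), or
#'   a `module_partition`.
#' @return An `eigenprotein_set`: list with `eigenproteins` (modules x
#'   samples matrix) and `var_explained` (named numeric).
#' @export
module_eigenproteins <- function(matrix, labels) {
  if (inherits(labels, "module_partition")) labels <- labels$labels
  labels <- labels[rownames(matrix)]
  mods <- unique(stats::na.omit(labels))
  mods <- mods[order(suppressWarnings(as.integer(sub("^M", "", mods))), mods)]
  if (length(mods) == 0) stop("no modules to summarize")
  E <- base::matrix(NA_real_, nrow = length(mods), ncol = ncol(matrix),
                    dimnames = list(mods, colnames(matrix)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    rows <- which(labels == m)
    Z <- .standardize_rows(matrix[rows, , drop = FALSE])
    sv <- svd(Z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    e <- (e - mean(e)) / stats::sd(e)
    if (mean(Z %*% e) < 0) e <- -e
    E[m, ] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(eigenproteins = E, var_explained = ve),
            class = "eigenprotein_set")
}

# Row z-score with median imputation of residual missing cells.
.standardize_rows <- function(X) {
  X <- impute_row_medians(X)
  mu <- rowMeans(X)
  s <- apply(X, 1, stats::sd)
  s[s == 0 | is.na(s)] <- 1
  (X - mu) / s
}

#' Module membership (kME) table
#'
#' Biweight midcorrelation of every protein profile with every module
#' eigenprotein; the intramodular column ranks module hubs.
#'
#' @param matrix Proteins x samples matrix.
#' @param eigenproteins An `eigenprotein_set` from [module_eigenproteins()].
#' @param max_p_outliers Outlier cap fraction for bicor.
#' @return Proteins x modules numeric matrix of kME values in `[-1, 1]`.
#' @export
kme_table <- function(matrix, eigenproteins, max_p_outliers = 0.05) {
  E <- eigenproteins$eigenproteins
  stopifnot(identical(colnames(matrix), colnames(E)))
  bicor_cross(matrix, E, max_p_outliers = max_p_outliers)
}

#' Merge modules with correlated eigenproteins
#'
#' Iteratively merges the module pair whose eigenprotein dissimilarity
#' (1 - Pearson correlation) is smallest, while it is below
#' `merge_cut_height`, recomputing eigenproteins after each merge. Final
#' labels are re-ranked M1..Mk by size.
#'
#' @param matrix Proteins x samples matrix.
#' @param partition A `module_partition` (or named label vector).
#' @param params A [network_params()].
#' @return List with `partition` (relabeled `module_partition`) and
#'   `eigenproteins` (final `eigenprotein_set`).
#' @export
merge_modules <- function(matrix, partition, params = network_params()) {
  labels <- if (inherits(partition, "module_partition"))
    partition$labels else partition
  labels <- labels[rownames(matrix)]
  if (length(unique(stats::na.omit(labels))) == 0)
    stop("partition has no modules")
  repeat {
    eig <- module_eigenproteins(matrix, labels)
    E <- eig$eigenproteins
    if (nrow(E) < 2) break
    cc <- stats::cor(t(E))
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (1 - cc[best[1], best[2]] >= params$merge_cut_height) break
    a <- rownames(E)[best[1]]; b <- rownames(E)[best[2]]
    labels[labels == b] <- a
  }
  relabeled <- .rank_module_labels(labels)
  final_labels <- relabeled$labels
  eig <- module_eigenproteins(matrix, final_labels)
  part <- structure(list(labels = final_labels, sizes = relabeled$sizes,
                         dendrogram = if (inherits(partition,
                                                   "module_partition"))
                           partition$dendrogram else NULL,
                         medoids = character(0)),
                    class = "module_partition")
  list(partition = part, eigenproteins = eig)
}

#' Build the full signed co-expression network
#'
#' Runs bicor, signed adjacency, TOM, dynamic-hybrid module detection,
#' eigenprotein-based merging, and kME in one call. Detection proceeds in
#' extraction rounds: after a round's modules are set aside, adjacency and
#' TOM are recomputed on the remaining proteins and detection repeats until
#' no further module emerges. Because topological overlap is normalized by
#' total connectivity, small modules can be masked by the aggregate
#' background in the full matrix yet stand out cleanly once the dominant
#' modules are removed; re-extraction recovers them without touching any
#' detection threshold. The procedure is deterministic.
#'
#' @param matrix Proteins x samples log2 matrix (post-normalization,
#'   post-adjustment).
#' @param params A [network_params()].
#' @return List: `partition`, `eigenproteins`, `kme`, `correlation`
#'   (bicor matrix), `params`.
#' @export
build_network <- function(matrix, params = network_params()) {
  cc <- bicor_matrix(matrix, max_p_outliers = params$max_p_outliers)
  matrix <- matrix[rownames(cc), , drop = FALSE]  # rows dropped for low obs
  labels <- stats::setNames(rep(NA_character_, nrow(matrix)),
                            rownames(matrix))
  dendro <- NULL
  round_i <- 0L
  repeat {
    rem <- names(labels)[is.na(labels)]
    if (length(rem) < params$min_module_size) break
    adj <- signed_adjacency(cc[rem, rem, drop = FALSE], beta = params$beta)
    part <- detect_modules(1 - tom_similarity(adj), params)
    if (round_i == 0L) dendro <- part$dendrogram
    if (length(part$sizes) == 0) break
    found <- part$labels[!is.na(part$labels)]
    labels[names(found)] <- paste0("r", round_i, "_", found)
    round_i <- round_i + 1L
  }
  if (all(is.na(labels))) {
    part <- structure(list(labels = labels, sizes = integer(0),
                           dendrogram = dendro, medoids = character(0)),
                      class = "module_partition")
    return(list(partition = part, eigenproteins = NULL,
                kme = NULL, correlation = cc, params = params))
  }
  merged <- merge_modules(matrix, labels, params)
  merged$partition$dendrogram <- dendro
  kme <- kme_table(matrix, merged$eigenproteins,
                   max_p_outliers = params$max_p_outliers)
  list(partition = merged$partition, eigenproteins = merged$eigenproteins,
       kme = kme, correlation = cc, params = params)
}
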