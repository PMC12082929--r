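#' Module enrichment by one-tailed Fisher's exact test
#'
#' Tests every (module, gene set) pair for over-representation within the
#' measured proteome. The background is the detected network proteins'
#' gene symbols (CSF detectability differs enough from the genome that a
#' whole-genome background would inflate enrichment); sets are intersected
#' with the background first and skipped when their intersected size falls
#' outside `[min_set, max_set]`. The p-value is the hypergeometric upper
#' tail (enrichment direction only); the odds ratio uses a 0.5 continuity
#' correction when any cell is zero; BH correction is applied across all
#' (module, set) pairs of the collection.
#'
#' @param partition A `module_partition` or named label vector
#'   (protein ids follow `"UniProtAC|GeneSymbol"`).
#' @param collection A `gene_set_collection` ([parse_gmt()]) or a marker
#'   data.frame with columns `gene`, `cell_type`.
#' @param background Optional character vector of background gene symbols;
#'   default the partition's own symbols.
#' @param min_set,max_set Post-intersection set-size bounds.
#' @return Data.frame: module, set, overlap, module_size, set_size,
#'   background_size, odds_ratio, p, q.
#' @export
fisher_enrichment <- function(partition, collection, background = NULL,
                              min_set = 5L, max_set = 1000L) {
  labels <- if (inherits(partition, "module_partition"))
    partition$labels else partition
  if (is.data.frame(collection)) collection <- markers_to_collection(collection)
  sym <- gene_symbols(names(labels))
  keep <- !is.na(sym)
  n_dropped <- sum(!keep)
  labels <- labels[keep]; sym <- toupper(sym[keep])
  if (is.null(background)) background <- unique(sym)
  background <- unique(toupper(background))
  if (length(background) == 0) stop("empty background")
  N <- length(background)
  mods <- unique(stats::na.omit(labels))
  mods <- mods[order(suppressWarnings(as.integer(sub("^M", "", mods))), mods)]
  rows <- list()
  for (s in names(collection)) {
    set_bg <- intersect(unique(toupper(collection[[s]]$members)), background)
    K <- length(set_bg)
    if (K < min_set || K > max_set) next
    for (m in mods) {
      mod_genes <- unique(sym[which(labels == m)])
      mod_genes <- intersect(mod_genes, background)
      n_mod <- length(mod_genes)
      a <- length(intersect(mod_genes, set_bg))
      b <- n_mod - a
      c_ <- K - a
      d <- N - a - b - c_
      p <- stats::phyper(a - 1, K, N - K, n_mod, lower.tail = FALSE)
      cc <- if (a == 0 || b == 0 || c_ == 0 || d == 0) 0.5 else 0
      orat <- ((a + cc) * (d + cc)) / ((b + cc) * (c_ + cc))
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, set = s, overlap = a, module_size = n_mod,
        set_size = K, background_size = N, odds_ratio = orat, p = p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(module = character(), set = character(),
                      overlap = integer(), module_size = integer(),
                      set_size = integer(), background_size = integer(),
                      odds_ratio = numeric(), p = numeric(), q = numeric()))
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  attr(out, "symbols_dropped") <- n_dropped
  rownames(out) <- NULL
  out
}

#' Convert a two-column marker table to a gene-set collection
#'
#' @param markers Data.frame with columns `gene` and `cell_type`.
#' @return A `gene_set_collection` with one set per cell type.
#' @export
markers_to_collection <- function(markers) {
  stopifnot(all(c("gene", "cell_type") %in% colnames(markers)))
  sets <- lapply(split(toupper(markers$gene), markers$cell_type),
                 function(g) list(description = "cell-type markers",
                                  members = unique(g)))
  structure(sets, class = "gene_set_collection")
}
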