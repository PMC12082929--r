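#' Derive a child seed from a master seed and an operation name
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed and its stage name, so stages are reproducible independently of the
#' order in which they run.
#'
#' @param seed Integer master seed.
#' @param op Character scalar naming the operation.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(op))
  codes <- utf8ToInt(op)
  h <- sum(codes * ((seq_along(codes) - 1L) %% 11L + 3L))
  out <- (abs(as.numeric(seed)) * 69069 + h * 2654435761) %% 2147483629
  as.integer(out) + 1L
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Unassigned labels are treated as an ordinary category unless dropped by
#' the caller beforehand.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return Numeric scalar in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sum_ij <- sum_comb(tab)
  sum_a <- sum_comb(rowSums(tab))
  sum_b <- sum_comb(colSums(tab))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

# Split "UniProtAC|GeneSymbol" ids into gene symbols; NA where no symbol.
#' Extract gene symbols from protein identifiers
#'
#' Protein ids follow the `"UniProtAC|GeneSymbol"` convention; the symbol is
#' the part after the pipe, upper-cased. Ids without a pipe or with an empty
#' symbol yield `NA`.
#'
#' @param protein_ids Character vector of protein ids.
#' @return Character vector of gene symbols (may contain `NA`).
#' @export
gene_symbols <- function(protein_ids) {
  parts <- strsplit(protein_ids, "|", fixed = TRUE)
  out <- vapply(parts, function(p) {
    if (length(p) >= 2L && nzchar(p[[2L]])) toupper(p[[2L]]) else NA_character_
  }, character(1))
  names(out) <- protein_ids
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
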