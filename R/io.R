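#' Read and write pipeline tables
#'
#' Abundance matrices travel as TSV with a leading `ProteinID` column and one
#' column per sample; traits as CSV; gene sets as GMT; marker lists as
#' two-column TSV; ground truth as JSON.
#'
#' @param matrix Proteins x samples numeric matrix with dimnames.
#' @param path File path.
#' @return `read_abundance_tsv` returns the matrix; writers return `path`
#'   invisibly.
#' @name csfnet_io
NULL

#' @rdname csfnet_io
#' @export
write_abundance_tsv <- function(matrix, path) {
  df <- data.frame(ProteinID = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname csfnet_io
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "ProteinID")
    stop("expected first column 'ProteinID' in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$ProteinID
  storage.mode(m) <- "double"
  m
}

#' @rdname csfnet_io
#' @param traits Traits data.frame as produced by [generate_cohort()].
#' @export
write_traits_csv <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname csfnet_io
#' @export
read_traits_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Parse a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member symbols. Blank lines are skipped, duplicate
#' members within a set are dropped, and symbols are upper-cased.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: named list of `list(description,
#'   members)`. Empty files yield an empty collection with a warning.
#' @export
parse_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(structure(list(), class = "gene_set_collection", source = path))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    members <- unique(toupper(fields[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop("GMT parse error at line ", i, ": empty set '", fields[1], "'")
    sets[[fields[1]]] <- list(description = fields[2], members = members)
  }
  structure(sets, class = "gene_set_collection", source = path)
}

#' @rdname parse_gmt
#' @param collection A `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    paste(c(nm, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname csfnet_io
#' @param markers Data.frame with columns `gene`, `cell_type`.
#' @export
write_markers_tsv <- function(markers, path) {
  utils::write.table(markers[, c("gene", "cell_type")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname csfnet_io
#' @export
read_markers_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname csfnet_io
#' @param truth Realized ground-truth list from [generate_cohort()].
#' @export
write_truth_json <- function(truth, path) {
  truth$group_effects <- list(
    values = unname(as.data.frame(truth$group_effects)),
    modules = rownames(truth$group_effects),
    groups = colnames(truth$group_effects))
  truth$batch_offset <- list(
    values = unname(as.data.frame(truth$batch_offset)),
    proteins = rownames(truth$batch_offset),
    batches = colnames(truth$batch_offset))
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
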