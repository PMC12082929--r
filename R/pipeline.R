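#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. Every
#' stage block mirrors the corresponding function's arguments; unknown keys
#' are rejected so typos fail at validation time, and referenced input
#' files must exist.
#'
#' @param seed Master seed; every stage derives its own child seed.
#' @param output_dir Directory for emitted tables and the manifest.
#' @param reference,expanded Cohort blocks: either
#'   `list(design = "tmt_reference")` / `list(design = "dia_expanded")`
#'   (optionally with a `truth` block of [truth_params()] arguments) for
#'   synthetic cohorts, or `list(abundance = <tsv>, traits = <csv>)` for
#'   data on disk.
#' @param preprocess,adjust,network,preservation,synthetic_me,panels Stage
#'   parameter blocks (see [filter_by_missingness()], [tampor_normalize()],
#'   [bootstrap_regress()], [network_params()], [module_preservation()],
#'   [synthetic_eigenproteins()], [select_top_daps()]).
#' @param comparisons List of `c(groupA, groupB)` two-group comparisons.
#' @param genesets Either `list(n_decoy_sets = <n>)` to generate sets
#'   matched to the synthetic ground truth, or
#'   `list(gmt = <path>, markers = <path>)` for collections on disk.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            output_dir = tempfile("csfnet_run_"),
                            reference = list(design = "tmt_reference"),
                            expanded = list(design = "dia_expanded"),
                            preprocess = list(),
                            adjust = list(),
                            comparisons = list(c("control", "C9_ALS"),
                                               c("control", "sALS")),
                            network = list(),
                            preservation = list(n_perm = 100L),
                            synthetic_me = list(),
                            panels = list(),
                            genesets = list(n_decoy_sets = 10L)) {
  config <- list(seed = as.integer(seed), output_dir = output_dir,
                 reference = reference, expanded = expanded,
                 preprocess = preprocess, adjust = adjust,
                 comparisons = comparisons, network = network,
                 preservation = preservation, synthetic_me = synthetic_me,
                 panels = panels, genesets = genesets)
  validate_pipeline_config(config)
}

#' @rdname pipeline_config
#' @param config A raw configuration list (e.g. from [read_pipeline_config()]).
#' @export
validate_pipeline_config <- function(config) {
  allowed <- c("seed", "output_dir", "reference", "expanded", "preprocess",
               "adjust", "comparisons", "network", "preservation",
               "synthetic_me", "panels", "genesets")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (blk in c("reference", "expanded")) {
    b <- config[[blk]]
    if (is.null(b$design) && (is.null(b$abundance) || is.null(b$traits)))
      stop(blk, " block needs either a synthetic 'design' or ",
           "'abundance' + 'traits' paths")
    for (f in intersect(c("abundance", "traits"), names(b)))
      if (!file.exists(b[[f]]))
        stop(blk, " ", f, " file not found: ", b[[f]])
  }
  for (f in intersect(c("gmt", "markers"), names(config$genesets)))
    if (!file.exists(config$genesets[[f]]))
      stop("genesets ", f, " file not found: ", config$genesets[[f]])
  for (cmp in config$comparisons)
    if (length(cmp) != 2) stop("each comparison must name exactly 2 groups")
  structure(config, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$comparisons))
    raw$comparisons <- lapply(raw$comparisons, unlist)
  validate_pipeline_config(raw)
}

.load_cohort <- function(block, seed, op) {
  if (!is.null(block$design)) {
    design <- switch(block$design,
                     tmt_reference = tmt_reference_design(),
                     dia_expanded = dia_expanded_design(),
                     stop("unknown design: ", block$design))
    truth <- do.call(truth_params, block$truth %||% list())
    # both cohorts share one protein-level truth realization so that
    # cross-cohort preservation sees the same planted structure
    generate_cohort(design, truth, seed = derive_seed(seed, op),
                    truth_seed = derive_seed(seed, "protein_truth"))
  } else {
    mat <- read_abundance_tsv(block$abundance)
    traits <- read_traits_csv(block$traits)
    is_ref <- !(colnames(mat) %in% traits$sample_id)
    list(abundance = mat, traits = traits,
         is_reference = stats::setNames(is_ref, colnames(mat)), truth = NULL)
  }
}

.preprocess_cohort <- function(cohort, pp) {
  tmt <- identical(cohort$traits$platform[1], "TMT_like")
  filtered <- filter_by_missingness(
    cohort$abundance, max_missing_frac = pp$max_missing_frac %||% 0.5,
    is_reference = cohort$is_reference)
  block_of <- if (tmt) cohort$traits$batch else cohort$traits$center
  names(block_of) <- cohort$traits$sample_id
  if (tmt) {
    ref_ids <- names(cohort$is_reference)[cohort$is_reference]
    ref_batch <- sub("^(b[0-9]+)\\..*$", "\\1", ref_ids)
    block_of <- c(block_of, stats::setNames(ref_batch, ref_ids))
  }
  tam <- tampor_normalize(
    filtered, batch = block_of, is_reference = cohort$is_reference,
    mode = if (tmt) "gis_denominator" else "all_sample_denominator",
    tol = pp$tol %||% 1e-4, max_iter = pp$max_iter %||% 250L)
  subj <- cohort$traits$sample_id
  norm <- tam$normalized[, subj, drop = FALSE]
  outliers <- detect_outliers(norm, outlier_z = pp$outlier_z %||% -3)
  list(matrix = norm, report = tam$report, outliers = outliers)
}

#' Run the full CSF proteome pipeline
#'
#' Executes simulate (or load) -> missingness filter -> TAMPOR -> outlier
#' screen -> bootstrap covariate regression -> differential abundance ->
#' signed network (reference cohort) -> module-trait association and
#' enrichment -> cross-cohort preservation and synthetic eigenproteins ->
#' biomarker panels, writing every table plus a JSON manifest to the output
#' directory. With a fixed seed the run is fully deterministic.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @param output_dir Overrides the config's output directory.
#' @param seed Overrides the config's master seed.
#' @return Invisibly, a list with all in-memory stage results plus
#'   `manifest` (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, output_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(unclass(config))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(output_dir)) config$output_dir <- output_dir
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  emit <- function(stage, file, writer, object, n_rows) {
    path <- file.path(out, file)
    writer(object, path)
    manifest$stages[[stage]]$outputs <<-
      c(manifest$stages[[stage]]$outputs %||% character(), file)
    manifest$stages[[stage]]$row_counts[[file]] <<- n_rows
    path
  }

  ref <- .load_cohort(config$reference, config$seed, "reference_cohort")
  exp_ <- .load_cohort(config$expanded, config$seed, "expanded_cohort")
  manifest$stages$simulate <- list(
    parameters = list(reference = config$reference$design %||% "file",
                      expanded = config$expanded$design %||% "file"),
    n_reference_samples = nrow(ref$traits),
    n_expanded_samples = nrow(exp_$traits))
  emit("simulate", "reference_abundance.tsv", write_abundance_tsv,
       ref$abundance, nrow(ref$abundance))
  emit("simulate", "reference_traits.csv", write_traits_csv,
       ref$traits, nrow(ref$traits))
  emit("simulate", "expanded_abundance.tsv", write_abundance_tsv,
       exp_$abundance, nrow(exp_$abundance))
  emit("simulate", "expanded_traits.csv", write_traits_csv,
       exp_$traits, nrow(exp_$traits))

  ref_pp <- .preprocess_cohort(ref, config$preprocess)
  exp_pp <- .preprocess_cohort(exp_, config$preprocess)
  manifest$stages$preprocess <- list(
    reference = ref_pp$report, expanded = exp_pp$report,
    reference_proteins = nrow(ref_pp$matrix),
    expanded_proteins = nrow(exp_pp$matrix),
    reference_outliers = sum(ref_pp$outliers$flagged),
    expanded_outliers = sum(exp_pp$outliers$flagged))

  ref_adj <- bootstrap_regress(
    ref_pp$matrix, ref$traits, nuisance = c("age", "sex", "batch"),
    n_boot = config$adjust$n_boot %||% 200L,
    seed = derive_seed(config$seed, "adjust_reference"))
  exp_adj <- bootstrap_regress(
    exp_pp$matrix, exp_$traits, nuisance = c("age", "sex"),
    n_boot = config$adjust$n_boot %||% 200L,
    seed = derive_seed(config$seed, "adjust_expanded"))
  manifest$stages$adjust <- list(
    n_boot = config$adjust$n_boot %||% 200L,
    reference_skipped = length(ref_adj$skipped),
    expanded_skipped = length(exp_adj$skipped))

  dap <- list()
  for (cohort_name in c("reference", "expanded")) {
    adj <- if (cohort_name == "reference") ref_adj else exp_adj
    traits <- if (cohort_name == "reference") ref$traits else exp_$traits
    groups <- stats::setNames(traits$group, traits$sample_id)
    ok_cmp <- Filter(function(cmp) all(cmp %in% groups), config$comparisons)
    if (length(ok_cmp) == 0) next
    tabs <- anova_bh(adj$adjusted, groups, ok_cmp)
    for (nm in names(tabs))
      emit("differential",
           paste0("dap_", cohort_name, "_", gsub("[^A-Za-z0-9]+", "_", nm),
                  ".tsv"),
           write_dap_tsv, tabs[[nm]], nrow(tabs[[nm]]))
    dap[[cohort_name]] <- tabs
  }
  manifest$stages$differential <- list(
    comparisons = vapply(config$comparisons, paste, "", collapse = " vs "))

  net <- build_network(ref_adj$adjusted,
                       do.call(network_params, config$network))
  part_df <- data.frame(protein = names(net$partition$labels),
                        module = ifelse(is.na(net$partition$labels),
                                        "unassigned", net$partition$labels),
                        stringsAsFactors = FALSE)
  emit("network", "modules.tsv",
       function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE),
       part_df, nrow(part_df))
  emit("network", "eigenproteins.tsv", write_abundance_tsv,
       net$eigenproteins$eigenproteins,
       nrow(net$eigenproteins$eigenproteins))
  emit("network", "kme.tsv", write_abundance_tsv, net$kme, nrow(net$kme))
  manifest$stages$network <- list(
    parameters = unclass(net$params),
    n_modules = length(net$partition$sizes),
    sizes = as.list(net$partition$sizes),
    assigned_fraction = mean(!is.na(net$partition$labels)))

  groups_ref <- stats::setNames(ref$traits$group, ref$traits$sample_id)
  assoc <- module_trait_bicor(net$eigenproteins, ref$traits)
  eanova <- eigenprotein_anova(net$eigenproteins, groups_ref)
  overlay <- if (length(dap$reference) > 0)
    dap_module_overlay(dap$reference[[1]], net$partition) else NULL
  emit("association", "module_trait.tsv",
       function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE), assoc,
       nrow(assoc))
  emit("association", "eigenprotein_anova.tsv",
       function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE), eanova,
       nrow(eanova))
  if (!is.null(overlay))
    emit("association", "dap_module_overlay.tsv",
         function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE), overlay,
         nrow(overlay))
  manifest$stages$association <- list(n_traits = length(unique(assoc$trait)))

  if (!is.null(config$genesets$gmt)) {
    collection <- parse_gmt(config$genesets$gmt)
    markers <- read_markers_tsv(config$genesets$markers)
  } else {
    gs <- generate_genesets(ref$truth,
                            n_decoy_sets = config$genesets$n_decoy_sets %||% 10L,
                            seed = derive_seed(config$seed, "genesets"))
    collection <- gs$collection
    markers <- gs$markers
    emit("enrichment", "genesets.gmt", write_gmt, collection,
         length(collection))
    emit("enrichment", "markers.tsv", write_markers_tsv, markers,
         nrow(markers))
  }
  enr_go <- fisher_enrichment(net$partition, collection)
  enr_ct <- fisher_enrichment(net$partition, markers)
  emit("enrichment", "enrichment_genesets.tsv",
       function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE), enr_go,
       nrow(enr_go))
  emit("enrichment", "enrichment_celltypes.tsv",
       function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE), enr_ct,
       nrow(enr_ct))
  manifest$stages$enrichment <- list(
    n_sets = length(collection),
    n_significant = sum(enr_go$q < 0.05, na.rm = TRUE))

  pres <- module_preservation(
    ref_adj$adjusted, exp_adj$adjusted, net$partition,
    n_perm = config$preservation$n_perm %||% 100L,
    beta = net$params$beta,
    seed = derive_seed(config$seed, "preservation"))
  emit("preservation", "preservation.tsv",
       function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE), pres,
       nrow(pres))
  syn <- synthetic_eigenproteins(
    net$kme, net$partition, exp_adj$adjusted,
    hub_fraction = config$synthetic_me$hub_fraction %||% 0.20,
    min_hubs = config$synthetic_me$min_hubs %||% 4L)
  emit("preservation", "synthetic_eigenproteins.tsv", write_abundance_tsv,
       syn$eigenproteins, nrow(syn$eigenproteins))
  groups_exp <- stats::setNames(exp_$traits$group, exp_$traits$sample_id)
  syn_anova <- eigenprotein_anova(syn, groups_exp)
  emit("preservation", "synthetic_eigenprotein_anova.tsv",
       function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE), syn_anova,
       nrow(syn_anova))
  manifest$stages$preservation <- list(
    n_perm = config$preservation$n_perm %||% 100L,
    z_summary = stats::setNames(as.list(pres$Z_summary), pres$module))

  # ALS (symptomatic) vs control panel in the expanded cohort
  st <- exp_$traits
  panel_groups <- ifelse(st$symptomatic, "ALS",
                         ifelse(st$group == "control", "control", NA))
  keep <- !is.na(panel_groups)
  panel_dap <- anova_bh(exp_adj$adjusted[, st$sample_id[keep]],
                        stats::setNames(panel_groups[keep],
                                        st$sample_id[keep]),
                        list(c("control", "ALS")))[[1]]
  panel <- select_top_daps(panel_dap, k = config$panels$k %||% 12L)
  pca <- panel_pca(exp_adj$adjusted[, st$sample_id[keep]], panel,
                   st[keep, ])
  clus <- panel_cluster(exp_adj$adjusted[, st$sample_id[keep]], panel,
                        st[keep, ])
  emit("panels", "panel.tsv",
       function(o, p) utils::write.table(
         data.frame(rank = seq_along(o), protein = o), p, sep = "\t",
         quote = FALSE, row.names = FALSE), panel, length(panel))
  emit("panels", "panel_pca_scores.tsv",
       function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE), pca$scores,
       nrow(pca$scores))
  emit("panels", "panel_classes.tsv",
       function(o, p) utils::write.table(
         data.frame(sample_id = names(o), class = o), p, sep = "\t",
         quote = FALSE, row.names = FALSE), clus$two_class_cut,
       length(clus$two_class_cut))
  manifest$stages$panels <- list(
    k = config$panels$k %||% 12L, n_samples = nrow(pca$scores),
    var_explained = pca$var_explained)

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, reference = ref, expanded = exp_,
                 reference_preprocessed = ref_pp,
                 expanded_preprocessed = exp_pp,
                 reference_adjusted = ref_adj, expanded_adjusted = exp_adj,
                 dap = dap, network = net, association = assoc,
                 eigenprotein_anova = eanova, overlay = overlay,
                 enrichment = list(genesets = enr_go, celltypes = enr_ct),
                 preservation = pres, synthetic_me = syn,
                 synthetic_me_anova = syn_anova,
                 panel = panel, panel_pca = pca, panel_cluster = clus,
                 output_dir = out))
}
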