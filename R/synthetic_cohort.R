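#' Cohort design for a synthetic CSF proteomic study
#'
#' Describes a multi-group cohort on one of two quantification platforms:
#' a single-center TMT-like design with batches and pooled-reference (GIS)
#' channels, or a multicenter DIA-like design with centers and no reference
#' channels.
#'
#' @param platform `"TMT_like"` or `"DIA_like"`.
#' @param group_sizes Named integer vector of samples per diagnosis group.
#'   Allowed names: `control`, `sALS`, `C9_ALS`, `C9_asym`, `SOD1_ALS`,
#'   `SOD1_asym`.
#' @param n_batches Number of TMT batches (TMT-like only).
#' @param n_centers Number of collection centers (DIA-like only).
#' @param gis_per_batch Pooled-reference channels appended to each batch.
#' @param age_mean_sd Named list, one `c(mean, sd)` per group, in years.
#' @param sex_fraction Named numeric vector, fraction female per group.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(platform = c("TMT_like", "DIA_like"),
                          group_sizes,
                          n_batches = 6L,
                          n_centers = 4L,
                          gis_per_batch = 1L,
                          age_mean_sd = NULL,
                          sex_fraction = NULL) {
  platform <- match.arg(platform)
  groups <- c("control", "sALS", "C9_ALS", "C9_asym", "SOD1_ALS", "SOD1_asym")
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% groups))
    stop("group_sizes must be named with a subset of: ",
         paste(groups, collapse = ", "))
  group_sizes <- stats::setNames(as.integer(group_sizes), names(group_sizes))
  if (any(group_sizes < 0)) stop("group sizes must be >= 0")
  if (platform == "TMT_like" && n_batches < 1L)
    stop("TMT-like designs need at least one batch")
  if (is.null(age_mean_sd))
    age_mean_sd <- stats::setNames(
      rep(list(c(58, 11)), length(group_sizes)), names(group_sizes))
  if (is.null(sex_fraction))
    sex_fraction <- stats::setNames(
      rep(0.5, length(group_sizes)), names(group_sizes))
  structure(list(platform = platform,
                 group_sizes = group_sizes,
                 n_batches = if (platform == "TMT_like") as.integer(n_batches) else NA_integer_,
                 n_centers = if (platform == "DIA_like") as.integer(n_centers) else NA_integer_,
                 gis_per_batch = as.integer(gis_per_batch),
                 age_mean_sd = age_mean_sd,
                 sex_fraction = sex_fraction),
            class = "cohort_design")
}

#' Single-center TMT-like reference design (101 subjects, 6 batches)
#'
#' Group sizes, ages and sex ratios follow the published single-center ALS
#' CSF cohort: 44 controls, 6 asymptomatic C9orf72 carriers, 10 C9orf72 ALS,
#' 6 SOD1 ALS and 35 sporadic ALS, quantified in 6 TMT batches each carrying
#' a pooled-reference (GIS) channel.
#'
#' @param gis_per_batch Reference channels per batch (default 1).
#' @return A `cohort_design`.
#' @export
tmt_reference_design <- function(gis_per_batch = 1L) {
  cohort_design(
    platform = "TMT_like",
    group_sizes = c(control = 44L, C9_asym = 6L, C9_ALS = 10L,
                    SOD1_ALS = 6L, sALS = 35L),
    n_batches = 6L,
    gis_per_batch = gis_per_batch,
    age_mean_sd = list(control = c(64.1, 7.6), C9_asym = c(51.5, 18.5),
                       C9_ALS = c(57.2, 8.7), SOD1_ALS = c(59.3, 4.6),
                       sALS = c(56.7, 10.9)),
    sex_fraction = c(control = 27 / 44, C9_asym = 2 / 6, C9_ALS = 4 / 10,
                     SOD1_ALS = 2 / 6, sALS = 13 / 35))
}

#' Multicenter DIA-like expanded design (259 subjects, 4 centers)
#'
#' Group sizes, ages and sex ratios follow the published multicenter ALS CSF
#' cohort: 72 controls, 59 asymptomatic C9orf72 carriers, 43 C9orf72 ALS,
#' 13 asymptomatic SOD1 carriers, 22 SOD1 ALS and 50 sporadic ALS across
#' four centers, label-free (no reference channels).
#'
#' @return A `cohort_design`.
#' @export
dia_expanded_design <- function() {
  cohort_design(
    platform = "DIA_like",
    group_sizes = c(control = 72L, C9_asym = 59L, C9_ALS = 43L,
                    SOD1_asym = 13L, SOD1_ALS = 22L, sALS = 50L),
    n_centers = 4L,
    age_mean_sd = list(control = c(59.4, 12.5), C9_asym = c(44.8, 12.8),
                       C9_ALS = c(58.0, 7.0), SOD1_asym = c(54.3, 12.0),
                       SOD1_ALS = c(54.6, 12.2), sALS = c(58.4, 10.8)),
    sex_fraction = c(control = 41 / 72, C9_asym = 34 / 59, C9_ALS = 20 / 43,
                     SOD1_asym = 9 / 13, SOD1_ALS = 7 / 22, sALS = 22 / 50))
}

#' Ground-truth parameters for the synthetic generator
#'
#' Defines the planted latent-factor structure: each planted module m has a
#' per-sample latent factor f_m ~ N(0,1); a member protein i has abundance
#' `baseline_i + loading_i * (f_m + group_effect[m, group]) + covariate
#' terms + noise`. Loadings are drawn Uniform(`loading_range`), so the first
#' principal component of a module is a consistent eigenprotein estimate and
#' kME ordering follows the loadings.
#'
#' @param n_proteins Total proteins in the matrix.
#' @param module_sizes Planted module sizes, largest first. The default
#'   plants 12 detectable modules spaced geometrically from 384 down to 24
#'   members plus one 10-member module that sits below the default detection
#'   minimum (a built-in negative control).
#' @param group_effects Numeric matrix, planted modules x groups, log2 shift
#'   of the module factor per diagnosis group; the control column must be 0.
#'   `NULL` uses a default ALS-like pattern (immune/glial modules up in
#'   symptomatic ALS, neuronal modules down, muted effects in asymptomatic
#'   carriers). `"null"` sets every effect to 0.
#' @param loading_range Range of Uniform loadings.
#' @param noise_sd Residual SD, log2 units.
#' @param baseline_mean,baseline_sd Per-protein baseline abundance (log2).
#' @param age_frac Fraction of proteins with an age slope.
#' @param age_slope Log2 change per decade for age-affected proteins.
#' @param sex_frac Fraction of proteins with a sex offset.
#' @param sex_offset Log2 offset (female - male) for sex-affected proteins.
#' @param batch_sd SD of per-(protein, batch/center) offsets, log2 units.
#' @param mcar_rate Missing-completely-at-random rate applied by
#'   [generate_cohort()].
#' @param mnar_strength Strength of abundance-dependent missingness.
#' @return A `truth_params` list.
#' @export
truth_params <- function(n_proteins = 2000L,
                         module_sizes = c(384L, 298L, 232L, 180L, 140L, 109L,
                                          85L, 66L, 51L, 40L, 31L, 24L, 10L),
                         group_effects = NULL,
                         loading_range = c(0.4, 0.95),
                         noise_sd = 0.4,
                         baseline_mean = 20,
                         baseline_sd = 1.5,
                         age_frac = 0.2,
                         age_slope = 0.1,
                         sex_frac = 0.1,
                         sex_offset = 0.2,
                         batch_sd = 0.3,
                         mcar_rate = 0.02,
                         mnar_strength = 0.1) {
  module_sizes <- as.integer(module_sizes)
  if (sum(module_sizes) > n_proteins)
    stop("module_sizes sum exceeds n_proteins")
  groups <- c("control", "sALS", "C9_ALS", "C9_asym", "SOD1_ALS", "SOD1_asym")
  k <- length(module_sizes)
  if (is.null(group_effects)) {
    group_effects <- matrix(0, nrow = k, ncol = length(groups),
                            dimnames = list(if (k > 0) paste0("M", seq_len(k)),
                                            groups))
    up <- intersect(c(2L, 3L, 7L, 10L), seq_len(k))
    dn <- intersect(c(1L, 4L, 11L, 12L), seq_len(k))
    group_effects[up, c("sALS", "C9_ALS", "SOD1_ALS")] <- 0.8
    group_effects[dn, c("sALS", "C9_ALS", "SOD1_ALS")] <- -0.8
    group_effects[intersect(c(7L, 10L), seq_len(k)),
                  c("C9_asym", "SOD1_asym")] <- 0.3
  } else if (identical(group_effects, "null")) {
    group_effects <- matrix(0, nrow = k, ncol = length(groups),
                            dimnames = list(if (k > 0) paste0("M", seq_len(k)),
                                            groups))
  } else {
    group_effects <- as.matrix(group_effects)
    if (nrow(group_effects) != k) stop("group_effects needs one row per module")
    if (is.null(colnames(group_effects))) colnames(group_effects) <- groups
  }
  if (any(group_effects[, "control"] != 0))
    stop("control is the reference level: its group effects must be 0")
  structure(list(n_proteins = as.integer(n_proteins),
                 module_sizes = module_sizes,
                 group_effects = group_effects,
                 loading_range = loading_range, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 age_frac = age_frac, age_slope = age_slope,
                 sex_frac = sex_frac, sex_offset = sex_offset,
                 batch_sd = batch_sd,
                 mcar_rate = mcar_rate, mnar_strength = mnar_strength),
            class = "truth_params")
}

#' Parameters for a no-effect (null) cohort
#'
#' Removes every systematic effect — group, age, sex, batch, missingness —
#' and by default also the planted co-expression modules, so proteins are
#' independent and the fraction of p < 0.05 calls concentrates tightly
#' around the nominal level. (With correlated modules left in, marginal
#' p-values are still uniform but whole modules cross the threshold
#' together, so the observed fraction has large variance; pass explicit
#' `module_sizes` to study that regime.)
#'
#' @param n_proteins Total proteins.
#' @param module_sizes Planted module sizes (default none).
#' @param ... Passed to [truth_params()].
#' @return A `truth_params` list with all systematic effects zeroed.
#' @export
null_truth_params <- function(n_proteins = 2000L, module_sizes = integer(0),
                              ...) {
  truth_params(n_proteins = n_proteins, module_sizes = module_sizes,
               group_effects = "null",
               age_frac = 0, age_slope = 0, sex_frac = 0, sex_offset = 0,
               batch_sd = 0, mcar_rate = 0, mnar_strength = 0, ...)
}

# ALS marker and printed-panel gene names planted into signed modules so that
# paper-named proteins exist in synthetic fixtures. "up" names go to the
# largest module with a positive symptomatic effect, "down" to the largest
# with a negative one.
.known_markers <- list(
  up = c("CHIT1", "CHI3L1", "CHI3L2", "GFAP", "UCHL1", "NEFL", "NEFM",
         "TMEM198", "HYOU1", "XXYLT1", "C1QB", "FABP5", "MERTK", "WARS"),
  down = c("DPP6"))

#' Generate a synthetic two-platform CSF cohort with planted modules
#'
#' Simulates a quantified log2 protein-abundance matrix for the given cohort
#' design under the latent-factor ground truth of [truth_params()]:
#' module factors shared across member proteins, diagnosis-group shifts on
#' those factors, per-protein age/sex effects, per-batch (or per-center)
#' offsets, Gaussian noise, and MCAR+MNAR missingness. TMT-like designs also
#' receive pooled-reference (GIS) channels carrying each batch's average
#' signal. Well-known ALS marker gene names (NEFL, CHIT1, CHI3L1, UCHL1,
#' GFAP, ...) are planted in appropriately signed modules.
#'
#' @param design A [cohort_design()].
#' @param truth A [truth_params()].
#' @param seed Integer master seed; all randomness derives from it.
#' @param truth_seed Seed for the protein-level truth realization (module
#'   memberships, loadings, per-protein covariate effects). Defaults to a
#'   child of `seed`; pass the same `truth_seed` with different `seed`
#'   values to draw independent cohorts that share one ground truth, as in
#'   cross-cohort preservation studies.
#' @return A list with elements `abundance` (proteins x samples log2 matrix,
#'   missing allowed, reference channels included for TMT-like designs),
#'   `traits` (data.frame of subject samples: sample_id, group, symptomatic,
#'   age, sex, batch, center, platform), `is_reference` (named logical over
#'   columns of `abundance`), and `truth` (realized ground truth:
#'   module_of_protein, loading, group_effects, age_slope, sex_offset,
#'   batch_offset, noise_sd, mcar_rate, mnar_strength).
#' @export
generate_cohort <- function(design, truth = truth_params(), seed = 1L,
                            truth_seed = derive_seed(seed, "protein_truth")) {
  stopifnot(inherits(design, "cohort_design"), inherits(truth, "truth_params"))
  gs <- design$group_sizes
  for (g in names(gs)) {
    eff <- truth$group_effects[, g]
    if (gs[[g]] == 0L && any(eff != 0))
      stop("invalid design: group '", g,
           "' has size 0 but a nonzero planted effect")
  }

  # protein-level truth first, under its own seed, so cohorts generated
  # with a shared truth_seed plant identical loadings and effects
  set.seed(truth_seed)
  p <- truth$n_proteins
  k <- length(truth$module_sizes)
  module_of <- rep(NA_character_, p)
  pos <- 1L
  for (m in seq_len(k)) {
    module_of[pos:(pos + truth$module_sizes[m] - 1L)] <- paste0("M", m)
    pos <- pos + truth$module_sizes[m]
  }
  symbols <- sprintf("GENE%04d", seq_len(p))
  eff_sympt <- rowMeans(truth$group_effects[, c("sALS", "C9_ALS", "SOD1_ALS"),
                                            drop = FALSE])
  up_mod <- if (any(eff_sympt > 0)) paste0("M", which.max(eff_sympt)) else NA
  dn_mod <- if (any(eff_sympt < 0)) paste0("M", which.min(eff_sympt)) else NA
  place_markers <- function(symbols, names_to_place, target_mod) {
    if (is.na(target_mod)) return(symbols)
    slots <- which(module_of == target_mod)
    slots <- slots[seq_len(min(length(names_to_place), length(slots)))]
    symbols[slots] <- names_to_place[seq_along(slots)]
    symbols
  }
  symbols <- place_markers(symbols, .known_markers$up, up_mod)
  symbols <- place_markers(symbols, .known_markers$down, dn_mod)
  protein_ids <- sprintf("P%05d|%s", seq_len(p), symbols)
  loading <- stats::runif(p, truth$loading_range[1], truth$loading_range[2])
  loading[is.na(module_of)] <- 0
  baseline <- stats::rnorm(p, truth$baseline_mean, truth$baseline_sd)
  age_slope <- ifelse(stats::runif(p) < truth$age_frac,
                      truth$age_slope * sample(c(-1, 1), p, replace = TRUE), 0)
  sex_offset <- ifelse(stats::runif(p) < truth$sex_frac,
                       truth$sex_offset * sample(c(-1, 1), p, replace = TRUE), 0)

  set.seed(derive_seed(seed, "generate_cohort"))

  n_sub <- sum(gs)
  groups <- rep(names(gs), gs)
  sample_ids <- sprintf("S%03d", seq_len(n_sub))
  age <- numeric(n_sub); sex <- character(n_sub)
  for (g in names(gs)) {
    idx <- which(groups == g)
    ms <- design$age_mean_sd[[g]]
    a <- stats::rnorm(length(idx), ms[1], ms[2])
    a <- pmin(pmax(a, 18), 90)  # plausible adult sampling ages
    age[idx] <- round(a, 1)
    nf <- round(design$sex_fraction[[g]] * length(idx))
    sex[idx] <- sample(c(rep("F", nf), rep("M", length(idx) - nf)))
  }
  symptomatic <- groups %in% c("sALS", "C9_ALS", "SOD1_ALS")

  tmt <- design$platform == "TMT_like"
  n_blocks <- if (tmt) design$n_batches else design$n_centers
  block <- sample(rep_len(seq_len(n_blocks), n_sub))
  traits <- data.frame(
    sample_id = sample_ids, group = groups, symptomatic = symptomatic,
    age = age, sex = sex,
    batch = if (tmt) paste0("b", block) else NA_character_,
    center = if (tmt) NA_character_ else paste0("c", block),
    platform = design$platform,
    stringsAsFactors = FALSE)

  batch_offset <- matrix(stats::rnorm(p * n_blocks, 0, truth$batch_sd),
                         nrow = p,
                         dimnames = list(protein_ids, paste0(
                           if (tmt) "b" else "c", seq_len(n_blocks))))

  factors <- matrix(stats::rnorm(k * n_sub), nrow = k)  # latent module factors
  values <- matrix(baseline, nrow = p, ncol = n_sub)
  grp_idx <- match(groups, colnames(truth$group_effects))
  for (m in seq_len(k)) {
    rows <- which(module_of == paste0("M", m))
    f <- factors[m, ] + truth$group_effects[m, grp_idx]
    values[rows, ] <- values[rows, ] + outer(loading[rows], f)
  }
  values <- values +
    outer(age_slope, (age - mean(age)) / 10) +
    outer(sex_offset, as.numeric(sex == "F")) +
    batch_offset[, block] +
    matrix(stats::rnorm(p * n_sub, 0, truth$noise_sd), nrow = p)
  dimnames(values) <- list(protein_ids, sample_ids)

  is_reference <- stats::setNames(rep(FALSE, n_sub), sample_ids)
  if (tmt && design$gis_per_batch > 0L) {
    ref_cols <- list(); ref_flags <- c()
    for (b in seq_len(n_blocks)) {
      in_b <- which(block == b)
      avg <- rowMeans(values[, in_b, drop = FALSE])
      for (r in seq_len(design$gis_per_batch)) {
        id <- sprintf("b%d.GIS%d", b, r)
        ref_cols[[id]] <- avg + stats::rnorm(p, 0, 0.05)
        ref_flags[id] <- TRUE
      }
    }
    values <- cbind(values, do.call(cbind, ref_cols))
    is_reference <- c(is_reference, ref_flags)
  }

  if (truth$mcar_rate > 0 || truth$mnar_strength > 0)
    values <- inject_missingness(values, truth$mcar_rate,
                                 truth$mnar_strength,
                                 seed = derive_seed(seed, "missingness"))

  realized <- list(module_of_protein = stats::setNames(module_of, protein_ids),
                   loading = stats::setNames(loading, protein_ids),
                   group_effects = truth$group_effects,
                   age_slope = stats::setNames(age_slope, protein_ids),
                   sex_offset = stats::setNames(sex_offset, protein_ids),
                   batch_offset = batch_offset,
                   noise_sd = truth$noise_sd,
                   mcar_rate = truth$mcar_rate,
                   mnar_strength = truth$mnar_strength)
  list(abundance = values, traits = traits, is_reference = is_reference,
       truth = realized)
}

#' Inject missing values into an abundance matrix
#'
#' Each cell goes missing independently with probability `mcar_rate` plus an
#' abundance-dependent (missing-not-at-random) term that increases as
#' abundance decreases: `mnar_strength * plogis(8 * (0.3 - r))` where `r` is
#' the cell's rank among all observed values scaled to `[0, 1]`.
#'
#' @param matrix Numeric matrix (log2 abundances).
#' @param mcar_rate MCAR probability in `[0, 1)`.
#' @param mnar_strength Nonnegative scale of the low-abundance term.
#' @param seed Integer seed.
#' @return The matrix with additional `NA` cells.
#' @export
inject_missingness <- function(matrix, mcar_rate, mnar_strength, seed = 1L) {
  if (mcar_rate >= 1 || mcar_rate < 0) stop("mcar_rate must be in [0, 1)")
  if (mnar_strength < 0) stop("mnar_strength must be >= 0")
  if (mcar_rate == 0 && mnar_strength == 0) return(matrix)
  set.seed(derive_seed(seed, "inject_missingness"))
  obs <- !is.na(matrix)
  r <- matrix
  r[obs] <- (rank(matrix[obs]) - 1) / max(1, sum(obs) - 1)
  p_miss <- mcar_rate + mnar_strength * stats::plogis(8 * (0.3 - r))
  p_miss <- pmin(p_miss, 0.95)
  drop <- obs & (stats::runif(length(matrix)) < p_miss)
  matrix[drop] <- NA_real_
  matrix
}

#' Generate gene sets and cell-type marker lists matched to the ground truth
#'
#' Builds one gene set per planted module (80% drawn from the module, 20%
#' from the remaining background), `n_decoy_sets` size-matched decoy sets of
#' random background genes, and five cell-type marker lists (astrocyte,
#' microglia, neuron, oligodendrocyte, endothelia) that overlap designated
#' modules, mirroring the cell-type composition reported for CSF networks
#' (neuron/oligodendrocyte in the large "neuronal" modules, microglia in the
#' inflammatory modules, endothelia in the complement module).
#'
#' @param truth Realized ground truth from [generate_cohort()].
#' @param n_decoy_sets Number of decoy sets.
#' @param seed Integer seed.
#' @return A list with `collection` (a `gene_set_collection`: name ->
#'   list(description, members)) and `markers` (data.frame gene, cell_type).
#' @export
generate_genesets <- function(truth, n_decoy_sets = 0L, seed = 1L) {
  module_of <- truth$module_of_protein
  if (all(is.na(module_of))) stop("ground truth has no planted modules")
  set.seed(derive_seed(seed, "generate_genesets"))
  sym <- gene_symbols(names(module_of))
  keep <- !is.na(sym)
  sym <- sym[keep]; module_of <- module_of[keep]
  mods <- unique(stats::na.omit(module_of))
  mods <- mods[order(as.integer(sub("^M", "", mods)))]
  sets <- list()
  for (m in mods) {
    members <- sym[which(module_of == m)]
    n_in <- floor(0.8 * length(members))
    n_out <- length(members) - n_in
    bg <- sym[is.na(module_of) | module_of != m]
    picked <- c(sample(members, n_in), sample(bg, n_out))
    sets[[paste0("SET_", m)]] <- list(
      description = paste0("set matched to planted module ", m),
      members = unique(picked))
  }
  if (n_decoy_sets > 0L) {
    sizes <- sample(lengths(lapply(sets, `[[`, "members")),
                    n_decoy_sets, replace = TRUE)
    for (i in seq_len(n_decoy_sets)) {
      sets[[sprintf("DECOY_%03d", i)]] <- list(
        description = "random decoy set",
        members = unique(sample(sym, sizes[i])))
    }
  }
  cell_modules <- list(astrocyte = "M5", microglia = c("M7", "M8", "M9"),
                       neuron = c("M1", "M4", "M12"),
                       oligodendrocyte = c("M1", "M4"), endothelia = "M2")
  markers <- list()
  for (ct in names(cell_modules)) {
    target <- intersect(cell_modules[[ct]], mods)
    pool <- sym[module_of %in% target]
    n_mark <- min(length(pool), max(20L, floor(0.3 * length(pool))))
    core <- if (n_mark > 0) sample(pool, n_mark) else character()
    extra <- sample(sym[is.na(module_of)], min(10L, sum(is.na(module_of))))
    markers[[ct]] <- data.frame(gene = unique(c(core, extra)),
                                cell_type = ct, stringsAsFactors = FALSE)
  }
  markers <- do.call(rbind, markers)
  rownames(markers) <- NULL
  list(collection = structure(sets, class = "gene_set_collection"),
       markers = markers)
}
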