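#' Remove nuisance covariate effects by bootstrap regression
#'
#' Per protein, fits ordinary least squares of abundance on the protected
#' terms (diagnosis group, by default) plus the nuisance covariates (age,
#' sex, batch/center), over `n_boot` case-resampled complete-case datasets.
#' Each nuisance coefficient is summarized by its bootstrap mean and the
#' adjusted abundance is `observed - sum(nuisance_coef * covariate)`.
#' Protected terms are in the design (so group differences are not absorbed
#' into nuisance estimates) but are never subtracted. Missing abundances
#' stay missing; proteins with fewer than `min_complete` complete cases pass
#' through unadjusted and flagged.
#'
#' Age enters centered, in years; categorical covariates enter as treatment
#' contrasts. A nuisance covariate that is constant within a protein's
#' complete cases is dropped for that protein with a warning; a globally
#' rank-deficient design is an error naming the collinear columns.
#'
#' @param matrix Proteins x samples log2 matrix.
#' @param traits Traits data.frame with `sample_id` and every covariate.
#' @param nuisance Character vector of nuisance covariate names
#'   (e.g. `c("age", "sex", "batch")`).
#' @param protected Character vector of protected terms (default `"group"`).
#' @param n_boot Bootstrap resamples (default 200).
#' @param min_complete Minimum complete cases to attempt adjustment.
#' @param seed Integer seed.
#' @return List with `adjusted` (matrix), `coefficients` (data.frame:
#'   protein, term, estimate, se, n_complete) and `skipped` (character
#'   vector of pass-through proteins).
#' @export
bootstrap_regress <- function(matrix, traits, nuisance,
                              protected = "group", n_boot = 200L,
                              min_complete = 10L, seed = 1L) {
  stopifnot(n_boot >= 1, length(nuisance) >= 1)
  if (length(intersect(nuisance, protected)) > 0)
    stop("nuisance and protected terms overlap")
  idx <- match(colnames(matrix), traits$sample_id)
  if (anyNA(idx)) stop("every sample needs a trait row")
  tr <- traits[idx, , drop = FALSE]
  for (v in c(protected, nuisance))
    if (!v %in% colnames(tr)) stop("covariate not in traits: ", v)
  tr$age <- if ("age" %in% colnames(tr)) tr$age - mean(tr$age) else NULL

  fml <- stats::as.formula(paste("~", paste(c(protected, nuisance),
                                            collapse = " + ")))
  mf <- stats::model.frame(fml, data = tr)
  X <- stats::model.matrix(fml, mf)
  if (qr(X)$rank < ncol(X)) {
    bad <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  assign_map <- attr(X, "assign")
  term_labels <- attr(stats::terms(fml), "term.labels")
  col_term <- c("(Intercept)", term_labels)[assign_map + 1L]
  nuis_cols <- which(col_term %in% nuisance)

  set.seed(derive_seed(seed, "bootstrap_regress"))
  adjusted <- matrix
  skipped <- character()
  coef_rows <- vector("list", nrow(matrix))
  warned_const <- FALSE
  for (i in seq_len(nrow(matrix))) {
    y <- matrix[i, ]
    cc <- which(!is.na(y))
    if (length(cc) < min_complete) {
      skipped <- c(skipped, rownames(matrix)[i])
      next
    }
    Xi <- X[cc, , drop = FALSE]
    # drop protein-level constant columns (beyond intercept)
    keep_cols <- c(TRUE, apply(Xi[, -1, drop = FALSE], 2,
                               function(v) length(unique(v)) > 1L))
    if (!all(keep_cols) && !warned_const) {
      warning("covariate column(s) constant within complete cases for ",
              "some proteins; dropped there")
      warned_const <- TRUE
    }
    Xi <- Xi[, keep_cols, drop = FALSE]
    yi <- y[cc]
    nb <- length(cc)
    boot_sum <- numeric(ncol(Xi)); boot_sq <- numeric(ncol(Xi)); used <- 0L
    for (b in seq_len(n_boot)) {
      rows <- sample.int(nb, nb, replace = TRUE)
      fit <- stats::.lm.fit(Xi[rows, , drop = FALSE], yi[rows])
      cf <- fit$coefficients
      if (anyNA(cf) || fit$rank < ncol(Xi)) next
      boot_sum <- boot_sum + cf
      boot_sq <- boot_sq + cf^2
      used <- used + 1L
    }
    if (used == 0L) {
      skipped <- c(skipped, rownames(matrix)[i])
      next
    }
    est <- boot_sum / used
    se <- sqrt(pmax(boot_sq / used - est^2, 0) * used / max(used - 1L, 1L))
    names(est) <- names(se) <- colnames(Xi)
    nu <- intersect(colnames(Xi), colnames(X)[nuis_cols])
    if (length(nu) > 0) {
      removal <- as.numeric(X[, nu, drop = FALSE] %*% est[nu])
      adjusted[i, ] <- y - removal
    }
    coef_rows[[i]] <- data.frame(protein = rownames(matrix)[i],
                                 term = colnames(Xi),
                                 estimate = unname(est), se = unname(se),
                                 n_complete = length(cc),
                                 stringsAsFactors = FALSE)
  }
  coefficients <- do.call(rbind, coef_rows[!vapply(coef_rows, is.null,
                                                   logical(1))])
  rownames(coefficients) <- NULL
  list(adjusted = adjusted, coefficients = coefficients, skipped = skipped)
}
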