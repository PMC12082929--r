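# Two small cohorts sharing one planted truth, for preservation tests.
make_cohort_pair <- function(seed = 91, n_proteins = 300L,
                             module_sizes = c(80L, 50L, 30L)) {
  tp <- truth_params(n_proteins = n_proteins, module_sizes = module_sizes,
                     mcar_rate = 0, mnar_strength = 0)
  ts <- derive_seed(seed, "protein_truth")
  ref <- generate_cohort(
    cohort_design("DIA_like", c(control = 40L, sALS = 40L), n_centers = 2L),
    tp, seed = seed, truth_seed = ts)
  test <- generate_cohort(
    cohort_design("DIA_like", c(control = 40L, sALS = 40L), n_centers = 2L),
    tp, seed = seed + 1000L, truth_seed = ts)
  list(ref = ref, test = test, truth = ref$truth)
}

test_that("preserved planted modules score high Zsummary; random sets do not", {
  pair <- make_cohort_pair()
  labels <- pair$truth$module_of_protein
  pres <- module_preservation(pair$ref$abundance, pair$test$abundance,
                              labels, n_perm = 60, seed = 1)
  expect_true(all(pres$Z_summary > 10))
  expect_true(all(pres$size == c(80L, 50L, 30L)))
  # a random protein set labeled as a module sits inside the null band
  set.seed(92)
  rand_labels <- labels
  rand_labels[] <- NA
  rand_labels[sample(names(labels), 40)] <- "R1"
  pres_r <- module_preservation(pair$ref$abundance, pair$test$abundance,
                                rand_labels, n_perm = 60, seed = 1)
  expect_lt(abs(pres_r$Z_summary), 3)
})

test_that("ablating a module's co-expression collapses its Zsummary only", {
  pair <- make_cohort_pair(seed = 93)
  labels <- pair$truth$module_of_protein
  test_m <- pair$test$abundance
  mem <- names(labels)[which(labels == "M2")]
  set.seed(94)
  for (p in mem) test_m[p, ] <- sample(test_m[p, ])
  pres <- module_preservation(pair$ref$abundance, test_m, labels,
                              n_perm = 60, seed = 1)
  expect_lt(pres$Z_summary[pres$module == "M2"], 2)
  expect_true(all(pres$Z_summary[pres$module != "M2"] > 10))
})

test_that("Zsummary decreases monotonically with profile shuffling", {
  pair <- make_cohort_pair(seed = 95)
  labels <- pair$truth$module_of_protein
  mem <- names(labels)[which(labels == "M1")]
  z_at <- function(frac, seed) {
    test_m <- pair$test$abundance
    set.seed(seed)
    for (p in sample(mem, floor(frac * length(mem))))
      test_m[p, ] <- sample(test_m[p, ])
    module_preservation(pair$ref$abundance, test_m, labels,
                        n_perm = 40, seed = 1)$Z_summary[1]
  }
  z <- sapply(c(0, 0.5, 1), function(f)
    median(sapply(1:5, function(s) z_at(f, 200 + s))))
  expect_true(z[1] > z[2] && z[2] > z[3])
})

test_that("permutation results are bit-identical under a fixed seed", {
  pair <- make_cohort_pair(seed = 96, n_proteins = 150L,
                           module_sizes = c(50L, 30L))
  labels <- pair$truth$module_of_protein
  a <- module_preservation(pair$ref$abundance, pair$test$abundance, labels,
                           n_perm = 30, seed = 7)
  b <- module_preservation(pair$ref$abundance, pair$test$abundance, labels,
                           n_perm = 30, seed = 7)
  expect_identical(a, b)
})

test_that("Zsummary maps to the standard preservation significances", {
  expect_lte(zsummary_significance(10), 1e-23)
  expect_lte(zsummary_significance(2), 0.05)
  expect_gt(zsummary_significance(1.9), 0.025)
})

test_that("synthetic eigenproteins track native ones on the same data", {
  pair <- make_cohort_pair(seed = 97)
  labels <- pair$truth$module_of_protein
  m <- pair$ref$abundance
  native <- module_eigenproteins(m, labels)
  kme <- kme_table(m, native)
  syn <- synthetic_eigenproteins(kme, labels, m)
  for (mod in rownames(native$eigenproteins)) {
    r <- cor(native$eigenproteins[mod, ], syn$eigenproteins[mod, ])
    expect_gt(abs(r), 0.9)
  }
  # hub count: 20% of a 30-member module is 6 hubs; of 10 members -> 4 min
  expect_equal(length(syn$hubs$M3), 6L)
  small_labels <- setNames(rep(NA_character_, length(labels)), names(labels))
  small_labels[names(labels)[which(labels == "M3")][1:10]] <- "S1"
  kme_small <- kme_table(m, module_eigenproteins(m, small_labels))
  syn_small <- synthetic_eigenproteins(kme_small, small_labels, m)
  expect_equal(length(syn_small$hubs$S1), 4L)
})

test_that("degenerate or absent hubs skip the module with a warning", {
  pair <- make_cohort_pair(seed = 98, n_proteins = 150L,
                           module_sizes = c(50L, 30L))
  labels <- pair$truth$module_of_protein
  m <- pair$ref$abundance
  native <- module_eigenproteins(m, labels)
  kme <- kme_table(m, native)
  hubs_m2 <- names(labels)[which(labels == "M2")]
  test_m <- m
  test_m[hubs_m2, ] <- 5                 # constant profiles in test cohort
  expect_warning(syn <- synthetic_eigenproteins(kme, labels, test_m),
                 "degenerate")
  expect_false("M2" %in% rownames(syn$eigenproteins))
  dropped <- m[setdiff(rownames(m), hubs_m2), ]
  expect_warning(syn2 <- synthetic_eigenproteins(kme, labels, dropped),
                 "skipped")
  expect_false("M2" %in% rownames(syn2$eigenproteins))
})
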