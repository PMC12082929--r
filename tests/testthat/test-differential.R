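test_that("two-group ANOVA reproduces the closed-form toy", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
              dimnames = list("p1", paste0("s", 1:6)))
  groups <- setNames(rep(c("A", "B"), each = 3), colnames(m))
  tab <- anova_bh(m, groups, list(c("A", "B")))[[1]]
  expect_equal(tab$F_stat, 13.5, tolerance = 1e-10)
  expect_equal(tab$p, pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(tab$log2_diff, 3)
  expect_equal(tab$direction, "up")
  # location invariance
  tab2 <- anova_bh(m + 100, groups, list(c("A", "B")))[[1]]
  expect_equal(tab2$F_stat, tab$F_stat, tolerance = 1e-9)
})

test_that("two-group F equals the squared pooled-variance t statistic", {
  set.seed(31)
  for (i in 1:25) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    m <- matrix(c(x, y), nrow = 1,
                dimnames = list("p", paste0("s", seq_len(n1 + n2))))
    g <- setNames(rep(c("A", "B"), c(n1, n2)), colnames(m))
    tab <- anova_bh(m, g, list(c("A", "B")))[[1]]
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(tab$F_stat, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(tab$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("multi-group ANOVA matches the aov oracle", {
  set.seed(32)
  m <- matrix(rnorm(5 * 24), 5, dimnames = list(paste0("p", 1:5),
                                                paste0("s", 1:24)))
  g <- rep(c("a", "b", "c"), each = 8)
  res <- csfnet:::oneway_anova_rows(m, g)
  for (i in 1:5) {
    fit <- summary(aov(m[i, ] ~ factor(g)))[[1]]
    expect_equal(unname(res$F_stat[i]), fit[["F value"]][1],
                 tolerance = 1e-9)
    expect_equal(unname(res$p[i]), fit[["Pr(>F)"]][1], tolerance = 1e-9)
  }
})

test_that("BH correction matches a brute-force step-up on the toy and at random", {
  expect_equal(bh_oracle(c(0.01, 0.02, 0.04, 0.50)),
               c(0.04, 0.04, 0.16 / 3, 0.50), tolerance = 1e-12)
  set.seed(33)
  for (i in 1:100) {
    p <- runif(sample(1:20, 1))
    expect_equal(p.adjust(p, method = "BH"), bh_oracle(p),
                 tolerance = 1e-12)
  }
  # and the q column of a DAP table is that correction of its p column
  m <- matrix(rnorm(50 * 12), 50, dimnames = list(paste0("p", 1:50),
                                                  paste0("s", 1:12)))
  g <- setNames(rep(c("A", "B"), each = 6), colnames(m))
  tab <- anova_bh(m, g, list(c("A", "B")))[[1]]
  expect_equal(tab$q, bh_oracle(tab$p), tolerance = 1e-12)
  expect_true(all(tab$q >= tab$p))
})

test_that("proteins without two observations per group are untested", {
  m <- rbind(p1 = c(1, NA, NA, 4, 5, 6), p2 = c(1, 2, 3, 4, 5, 6))
  colnames(m) <- paste0("s", 1:6)
  g <- setNames(rep(c("A", "B"), each = 3), colnames(m))
  tab <- anova_bh(m, g, list(c("A", "B")))[[1]]
  expect_true(is.na(tab$p[1]))
  expect_equal(tab$direction[1], "ns")
  expect_false(is.na(tab$p[2]))
  expect_error(anova_bh(m, g, list(c("A", "Z"))), "unknown group")
})

test_that("DAP set comparison counts intersection cells correctly", {
  mk <- function(sig, all = paste0("p", 1:10)) {
    data.frame(protein = all, p = ifelse(all %in% sig, 0.001, 0.9),
               log2_diff = 1, stringsAsFactors = FALSE)
  }
  ident <- compare_dap_sets(list(a = mk(c("p1", "p2")), b = mk(c("p1", "p2"))))
  cnt <- setNames(ident$counts$count, ident$counts$pattern)
  expect_equal(unname(cnt["++"]), 2)
  expect_false("+-" %in% names(cnt))
  disj <- compare_dap_sets(list(a = mk(c("p1", "p2", "p3")),
                                b = mk(c("p4", "p5"))))
  cd <- setNames(disj$counts$count, disj$counts$pattern)
  expect_equal(unname(cd["+-"]), 3)
  expect_equal(unname(cd["-+"]), 2)
  expect_false("++" %in% names(cd))
  empt <- compare_dap_sets(list(a = mk("p1"), b = mk(character(0))))
  ce <- setNames(empt$counts$count, empt$counts$pattern)
  expect_false(any(grepl("^.\\+$", names(ce))))
})

test_that("effect-size concordance matches quadrant and bicor oracles", {
  mk <- function(eff, p = rep(0.01, length(eff))) {
    data.frame(protein = paste0("p", seq_along(eff)), p = p,
               log2_diff = eff, stringsAsFactors = FALSE)
  }
  a <- mk(c(1, 2, 3, -1, -2, 0.5))
  b <- mk(c(0.9, 2.2, 2.7, -1.2, -1.8, -0.4))
  res <- effectsize_concordance(a, b)
  expect_equal(unname(res$quadrant_counts[c("both_up", "both_down")]),
               c(3, 2))
  expect_equal(sum(res$quadrant_counts[c("up_down", "down_up")]), 1)
  expect_equal(res$bicor_r,
               bicor_oracle(c(1, 2, 3, -1, -2, 0.5),
                            c(0.9, 2.2, 2.7, -1.2, -1.8, -0.4)),
               tolerance = 1e-6)
  ident <- effectsize_concordance(a, a)
  expect_equal(ident$bicor_r, 1, tolerance = 1e-12)
  expect_equal(sum(ident$quadrant_counts[c("up_down", "down_up")]), 0)
  flip <- a; flip$log2_diff <- -flip$log2_diff
  anti <- effectsize_concordance(a, flip)
  expect_equal(anti$bicor_r, -1, tolerance = 1e-12)
  expect_equal(sum(anti$quadrant_counts[c("both_up", "both_down")]), 0)
  few <- mk(c(1, 2), c(0.01, 0.01))
  expect_error(effectsize_concordance(few, few), "insufficient overlap")
})

test_that("peptides map to 1-based inclusive coordinates", {
  out <- map_peptides_to_sequence("CDE", "ABCDEFG")
  expect_equal(out$start, 3L)
  expect_equal(out$end, 5L)
  none <- map_peptides_to_sequence("XYZ", "ABCDEFG")
  expect_false(none$mapped)
  expect_true(is.na(none$start))
  twice <- map_peptides_to_sequence("AB", "ABCAB")
  expect_equal(twice$start, c(1L, 4L))
  expect_equal(twice$end, c(2L, 5L))
  expect_error(map_peptides_to_sequence("", "ABC"), "empty peptide")
})

test_that("a null cohort rarely yields any q < 0.05 protein", {
  hits <- 0L
  for (s in 1:10) {
    co <- generate_cohort(
      cohort_design("DIA_like", c(control = 25L, sALS = 25L), n_centers = 2L),
      null_truth_params(n_proteins = 300L,
                        module_sizes = c(80L, 50L, 30L)),
      seed = 100 + s)
    g <- setNames(co$traits$group, co$traits$sample_id)
    tab <- anova_bh(co$abundance, g, list(c("control", "sALS")))[[1]]
    if (any(tab$q < 0.05, na.rm = TRUE)) hits <- hits + 1L
  }
  expect_lte(hits, 1L)                   # FDR control: >= 95% clean runs
})
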