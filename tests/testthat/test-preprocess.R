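test_that("missingness filter implements the >= 50% removal rule", {
  m <- rbind(p1 = c(1, NA, 3, NA),    # 50% missing -> removed
             p2 = c(1, 2, 3, NA),     # 25% -> retained
             p3 = c(1, 2, 3, 4))      # complete -> retained
  colnames(m) <- paste0("s", 1:4)
  out <- filter_by_missingness(m, 0.5)
  expect_identical(rownames(out), c("p2", "p3"))
  full <- m[c("p2", "p3"), ]
  expect_identical(filter_by_missingness(full, 0.5), full)
  expect_error(filter_by_missingness(m[1, , drop = FALSE], 0.5),
               "every protein")
})

test_that("missingness filter is monotone in its threshold", {
  set.seed(8)
  m <- matrix(rnorm(200 * 10), 200,
              dimnames = list(paste0("p", 1:200), paste0("s", 1:10)))
  m[runif(length(m)) < 0.4] <- NA
  kept <- lapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    tryCatch(rownames(filter_by_missingness(m, th)), error = function(e) NULL))
  for (i in seq_len(length(kept) - 1))
    expect_true(all(kept[[i]] %in% kept[[i + 1]]))
  # reference channels excluded from the denominator
  m2 <- cbind(m, ref = rnorm(200))
  is_ref <- c(rep(FALSE, 10), TRUE)
  expect_identical(rownames(filter_by_missingness(m2, 0.5, is_ref)),
                   rownames(filter_by_missingness(m, 0.5)))
})

test_that("TAMPOR reproduces the hand-polished 2x2 toy exactly", {
  m <- rbind(p1 = c(1, 3), p2 = c(2, 6))
  colnames(m) <- c("s1", "s2")
  res <- tampor_normalize(m, batch = c("b1", "b1"),
                          mode = "all_sample_denominator")
  # hand iteration: ratios {{-1,1},{-2,2}}; row medians 0; column medians
  # (-1.5, 1.5); residuals {{0.5,-0.5},{-0.5,0.5}}; add back per-protein
  # medians (2, 4)
  expect_equal(unname(res$normalized),
               rbind(c(2.5, 1.5), c(3.5, 4.5)), tolerance = 1e-12)
  expect_true(res$report$converged)
})

test_that("TAMPOR converges with centered sample medians and is idempotent", {
  set.seed(11)
  m <- matrix(rnorm(300 * 24, 20, 1), 300,
              dimnames = list(paste0("p", 1:300), paste0("s", 1:24)))
  batch <- rep(c("b1", "b2", "b3"), each = 8)
  m[, batch == "b2"] <- m[, batch == "b2"] + 1.5   # planted batch shift
  res <- tampor_normalize(m, batch, mode = "all_sample_denominator")
  expect_true(res$report$converged)
  expect_lte(res$report$max_abs_col_median, 1e-4)
  expect_lte(res$report$max_abs_row_median, 1e-4)
  # per-sample median log2 ratio at 0 after re-centering by row medians
  ratios <- res$normalized - apply(res$normalized, 1, median)
  expect_lt(max(abs(apply(ratios, 2, median))), 1e-3)
})

test_that("TAMPOR is idempotent on a single-batch matrix", {
  set.seed(16)
  m <- matrix(rnorm(200 * 12, 20, 1), 200,
              dimnames = list(paste0("p", 1:200), paste0("s", 1:12)))
  one <- rep("b1", 12)
  res <- tampor_normalize(m, one, mode = "all_sample_denominator")
  again <- tampor_normalize(res$normalized, one,
                            mode = "all_sample_denominator")
  expect_equal(again$report$iterations, 1L)
  expect_lt(max(abs(again$normalized - res$normalized)), 0.01)
})

test_that("gis mode requires a reference channel in every batch", {
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:4)))
  expect_error(
    tampor_normalize(m, rep(c("b1", "b2"), each = 2),
                     is_reference = c(TRUE, FALSE, FALSE, FALSE),
                     mode = "gis_denominator"),
    "no reference channel")
})

test_that("TAMPOR removes planted batch structure visible in MDS", {
  skip_if_not_installed("cluster")
  set.seed(12)
  m <- matrix(rnorm(400 * 30, 20, 0.5), 400,
              dimnames = list(paste0("p", 1:400), paste0("s", 1:30)))
  batch <- rep(c("b1", "b2"), each = 15)
  m[, batch == "b2"] <- m[, batch == "b2"] +
    rnorm(400, 0, 0.8)                   # per-protein batch offsets
  sil <- function(mat) {
    xy <- mds_qc(mat)
    mean(cluster::silhouette(as.integer(factor(batch)),
                             dist(as.matrix(xy[, c("dim1", "dim2")])))[, 3])
  }
  pre <- sil(m)
  post <- sil(tampor_normalize(m, batch,
                               mode = "all_sample_denominator")$normalized)
  expect_gt(pre, 0.2)
  expect_lt(post, 0.05)
})

test_that("MDS QC preserves distances and duplicates coincide", {
  set.seed(13)
  base <- matrix(rnorm(50 * 6), 50,
                 dimnames = list(paste0("p", 1:50), paste0("s", 1:6)))
  base[, 6] <- base[, 5]                 # duplicated sample
  xy <- mds_qc(base)
  expect_equal(xy[5, c("dim1", "dim2")], xy[6, c("dim1", "dim2")],
               tolerance = 1e-8, ignore_attr = TRUE)
  # rank-2 data embeds exactly: embedding distances match input distances
  plane <- matrix(rnorm(2 * 8), 2)
  lifted <- matrix(rnorm(50 * 2), 50) %*% plane
  dimnames(lifted) <- list(paste0("p", 1:50), paste0("s", 1:8))
  emb <- mds_qc(lifted)
  d_in <- as.numeric(dist(t(lifted)))
  d_out <- as.numeric(dist(as.matrix(emb[, c("dim1", "dim2")])))
  expect_gt(cor(d_in, d_out), 0.99)
  expect_error(mds_qc(base[, 1:2]), "3 samples")
})

test_that("outlier screen flags an independent-noise sample only", {
  set.seed(14)
  baseline <- rnorm(80, 20, 2)           # protein baselines drive sample cor
  m <- baseline + make_factor_block(80, 30, r = 0.3)
  dimnames(m) <- list(paste0("p", 1:80), paste0("s", 1:30))
  out <- detect_outliers(m)
  expect_false(any(out$flagged))         # homogeneous cohort: none flagged
  m[, 1] <- sample(baseline) + rnorm(80) # scrambled sample: cor ~ 0 vs >> 0
  out2 <- detect_outliers(m)
  expect_true(out2$flagged[1])
  expect_false(any(out2$flagged[-1]))
  expect_false(any(detect_outliers(m, outlier_z = -Inf)$flagged))
})
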