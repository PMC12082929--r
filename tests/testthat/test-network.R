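test_that("signed adjacency follows the soft-threshold arithmetic", {
  cc <- matrix(c(1, 0, -1, 0, 1, 0.5, -1, 0.5, 1), 3)
  a <- signed_adjacency(cc, beta = 4)
  expect_equal(a[1, 3], 0)               # cor -1 -> adjacency 0
  expect_equal(a[1, 2], 0.5^4)           # cor 0, beta 4 -> 0.0625
  expect_equal(a[2, 3], 0.75^4)
  expect_equal(unname(diag(a)), rep(1, 3))
  expect_equal(signed_adjacency(matrix(1, 1, 1), 4)[1, 1], 1)
})

test_that("TOM reproduces hand-computed values and boundary cases", {
  clique <- matrix(1, 3, 3)
  expect_equal(tom_similarity(clique)[1, 2], 1)   # clique: full overlap
  iso <- diag(3)                          # no edges, no shared neighbors
  expect_equal(tom_similarity(iso)[1, 2], 0)
  a <- diag(3)
  a[1, 2] <- a[2, 1] <- 0.5
  a[1, 3] <- a[3, 1] <- 0.4
  a[2, 3] <- a[3, 2] <- 0.2
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], (0.4 * 0.2 + 0.5) / (min(0.9, 0.7) + 1 - 0.5),
               tolerance = 1e-12)         # 0.58 / 1.2
  expect_error(tom_similarity(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
})

test_that("TOM is 1 for identical binary neighborhoods joined at full adjacency", {
  # nodes 1 and 2: a_12 = 1 and the same 0/1 neighborhood elsewhere
  a <- diag(5)
  a[1, 2] <- a[2, 1] <- 1
  for (k in 3:4) {
    a[1, k] <- a[k, 1] <- 1
    a[2, k] <- a[k, 2] <- 1
  }
  a[3, 4] <- a[4, 3] <- 1
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 1, tolerance = 1e-12)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  # weighted adjacency stays within [0, 1] too
  set.seed(42)
  w <- matrix(runif(36, 0, 0.9), 6); w <- (w + t(w)) / 2; diag(w) <- 1
  tw <- tom_similarity(w)
  expect_true(all(tw >= 0 & tw <= 1 + 1e-12))
})

test_that("TOM matches a triple-loop oracle on a random adjacency", {
  set.seed(41)
  n <- 8
  a <- matrix(runif(n * n, 0, 0.8), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  tom <- tom_similarity(a)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    num <- sum(a[i, -c(i, j)] * a[-c(i, j), j]) + a[i, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    expect_equal(tom[i, j], num / (min(ki, kj) + 1 - a[i, j]),
                 tolerance = 1e-12)
  }
})

test_that("dynamic-hybrid cut recovers planted blocks and rejects noise", {
  X <- make_three_block_matrix(seed = 51)
  truth <- attr(X, "truth")
  tom <- tom_similarity(signed_adjacency(bicor_matrix(X), 4))
  part <- detect_modules(1 - tom, network_params())
  expect_length(part$sizes, 3L)
  planted <- !is.na(truth)
  expect_equal(adjusted_rand_index(
    ifelse(is.na(part$labels), "un", part$labels)[planted], truth[planted]),
    1)
  # pure noise: almost everything unassigned
  set.seed(52)
  N <- matrix(rnorm(500 * 50), 500,
              dimnames = list(paste0("n", 1:500), paste0("s", 1:50)))
  pn <- detect_modules(1 - tom_similarity(signed_adjacency(bicor_matrix(N),
                                                           4)),
                       network_params())
  expect_gte(mean(is.na(pn$labels)), 0.8)
})

test_that("blocks below the minimum module size are dissolved", {
  set.seed(53)
  Y <- rbind(make_factor_block(10, 60), matrix(rnorm(100 * 60), 100))
  dimnames(Y) <- list(paste0("q", 1:110), paste0("s", 1:60))
  py <- detect_modules(1 - tom_similarity(signed_adjacency(bicor_matrix(Y),
                                                           4)),
                       network_params())
  expect_length(py$sizes, 0L)
  expect_true(all(is.na(py$labels)))
  # fewer proteins than the minimum: single all-unassigned partition
  tiny <- detect_modules(matrix(0, 5, 5,
                                dimnames = list(paste0("t", 1:5),
                                                paste0("t", 1:5))),
                         network_params())
  expect_true(all(is.na(tiny$labels)))
})

test_that("module labels rank by size and detection is deterministic", {
  X <- make_three_block_matrix(seed = 54)
  diss <- 1 - tom_similarity(signed_adjacency(bicor_matrix(X), 4))
  a <- detect_modules(diss, network_params())
  b <- detect_modules(diss, network_params())
  expect_identical(a$labels, b$labels)
  expect_true(all(diff(unname(a$sizes)) <= 0))
  expect_identical(names(a$sizes), paste0("M", seq_along(a$sizes)))
})

test_that("eigenproteins summarize modules as standardized first PCs", {
  prof <- rnorm(12)
  m <- rbind(p1 = prof, p2 = prof, p3 = prof)
  colnames(m) <- paste0("s", 1:12)
  eig <- module_eigenproteins(m, setNames(rep("M1", 3), rownames(m)))
  e <- eig$eigenproteins["M1", ]
  expect_equal(unname(e), unname((prof - mean(prof)) / sd(prof)),
               tolerance = 1e-8)
  expect_equal(unname(eig$var_explained["M1"]), 1, tolerance = 1e-12)
  # mean and variance normalization plus positive sign alignment
  set.seed(55)
  X <- make_factor_block(20, 30, r = 0.7)
  dimnames(X) <- list(paste0("p", 1:20), paste0("s", 1:30))
  eg <- module_eigenproteins(X, setNames(rep("M1", 20), rownames(X)))
  ev <- eg$eigenproteins["M1", ]
  expect_equal(mean(ev), 0, tolerance = 1e-12)
  expect_equal(sd(ev), 1, tolerance = 1e-12)
  expect_gt(mean(cor(t(X), ev)), 0)
})

test_that("var_explained matches a full-decomposition oracle", {
  set.seed(56)
  m <- matrix(rnorm(5 * 6), 5, dimnames = list(paste0("p", 1:5),
                                               paste0("s", 1:6)))
  eig <- module_eigenproteins(m, setNames(rep("M1", 5), rownames(m)))
  Z <- t(scale(t(m)))
  sv2 <- prcomp(t(Z), center = FALSE)$sdev^2
  expect_equal(unname(eig$var_explained["M1"]), sv2[1] / sum(sv2),
               tolerance = 1e-8)
})

test_that("kME ranks hub proteins by loading and stays bounded", {
  set.seed(57)
  hits <- 0L
  for (i in 1:20) {
    f <- rnorm(60)
    hi <- 0.9 * f + rnorm(60, 0, sqrt(1 - 0.81))
    lo <- 0.5 * f + rnorm(60, 0, sqrt(1 - 0.25))
    mem <- make_factor_block(18, 60, r = 0.6)
    m <- rbind(hi = hi, lo = lo, mem)
    rownames(m) <- c("hi", "lo", paste0("p", 1:18))
    colnames(m) <- paste0("s", 1:60)
    m[3:20, ] <- t(sapply(1:18, function(j)
      0.7 * f + rnorm(60, 0, sqrt(0.51))))
    labels <- setNames(rep("M1", 20), rownames(m))
    kme <- kme_table(m, module_eigenproteins(m, labels))
    expect_true(all(abs(kme) <= 1))
    if (kme["hi", "M1"] > kme["lo", "M1"]) hits <- hits + 1L
  }
  expect_gte(hits, 19L)                  # higher loading -> higher kME
  # single-protein pseudo-module: kME with own eigenprotein is 1
  x <- matrix(rnorm(10), 1, dimnames = list("solo", paste0("s", 1:10)))
  eig <- list(eigenproteins = matrix((x - mean(x)) / sd(x), 1,
                                     dimnames = list("M1", colnames(x))),
              var_explained = c(M1 = 1))
  class(eig) <- "eigenprotein_set"
  expect_equal(unname(kme_table(x, eig)[1, 1]), 1, tolerance = 1e-6)
})

test_that("modules merge if and only if eigenproteins nearly coincide", {
  set.seed(58)
  f <- rnorm(50)
  a <- t(sapply(1:20, function(i) 0.85 * f + rnorm(50, 0, 0.3)))
  b <- t(sapply(1:18, function(i) 0.85 * f + rnorm(50, 0, 0.3)))
  g <- make_factor_block(16, 50, r = 0.7)
  m <- rbind(a, b, g)
  dimnames(m) <- list(paste0("p", 1:54), paste0("s", 1:50))
  labels <- setNames(c(rep("A", 20), rep("B", 18), rep("C", 16)),
                     rownames(m))
  res <- merge_modules(m, labels, network_params(merge_cut_height = 0.07))
  merged_labels <- res$partition$labels
  expect_length(res$partition$sizes, 2L)  # A and B share a factor: merged
  expect_equal(length(unique(merged_labels[1:38])), 1L)
  expect_false(merged_labels[[1]] == merged_labels[[54]])
})
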