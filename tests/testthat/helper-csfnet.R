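# Shared fixtures, built in code.

# A block of n proteins sharing one latent factor across n_s samples.
make_factor_block <- function(n, n_s, r = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- rnorm(n_s)
  t(sapply(seq_len(n), function(i) sqrt(r) * f + sqrt(1 - r) * rnorm(n_s)))
}

# Planted 3-block matrix (60/40/20) plus unstructured background.
make_three_block_matrix <- function(n_s = 60, n_bg = 80, seed = 1) {
  set.seed(seed)
  X <- rbind(make_factor_block(60, n_s), make_factor_block(40, n_s),
             make_factor_block(20, n_s),
             matrix(rnorm(n_bg * n_s), n_bg))
  rownames(X) <- sprintf("P%05d|G%03d", seq_len(nrow(X)), seq_len(nrow(X)))
  colnames(X) <- paste0("s", seq_len(n_s))
  attr(X, "truth") <- c(rep("A", 60), rep("B", 40), rep("C", 20),
                        rep(NA, n_bg))
  X
}

# Independent biweight midcorrelation oracle: direct formula on one pair,
# written without reference to the package implementation.
bicor_oracle <- function(x, y) {
  w_bi <- function(v) {
    u <- (v - median(v)) / (9 * mad(v, constant = 1))
    (1 - u^2)^2 * (abs(u) < 1)
  }
  wx <- w_bi(x); wy <- w_bi(y)
  xc <- (x - median(x)) * wx
  yc <- (y - median(y)) * wy
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# Brute-force Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in rev(seq_len(n - 1))) q[i] <- min(q[i], q[i + 1])
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Small cohort truth for fast pipeline-level tests.
small_truth <- function(...) {
  truth_params(n_proteins = 500L,
               module_sizes = c(100L, 70L, 50L, 30L, 20L), ...)
}
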