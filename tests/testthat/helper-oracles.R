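# Independent naive-loop oracles and small constructed datasets shared
# across test files. Oracles deliberately re-derive every quantity with
# scalar loops, independent of the vectorized implementation paths.

# Naive loop re-implementations serve as independent oracles for every
# encoder; the large multi-fixture equivalence sweep lives in
# test-acceptance.R, the targeted exact cases live here.

oracle_aac_pssm <- function(p) {
  vapply(1:20, function(j) sum(p[, j]) / nrow(p), numeric(1))
}

oracle_pssm_comp <- function(p, seq) {
  chars <- strsplit(seq, "")[[1L]]
  out <- numeric(0)
  for (g in 1:20) {
    row <- numeric(20)
    for (j in 1:20) {
      for (k in seq_len(nrow(p))) {
        if (chars[k] == AA_ALPHABET[g]) row[j] <- row[j] + p[k, j]
      }
    }
    out <- c(out, row / nrow(p))
  }
  out
}

oracle_dpc_pssm <- function(p) {
  L <- nrow(p)
  out <- numeric(0)
  for (i in 1:20) {
    for (j in 1:20) {
      s <- 0
      for (k in 1:(L - 1)) s <- s + p[k, i] * p[k + 1, j]
      out <- c(out, s / (L - 1))
    }
  }
  unname(out)
}

oracle_medp <- function(p) {
  L <- nrow(p)
  eedp <- matrix(0, 20, 20)
  for (i in 1:20) {
    for (j in 1:20) {
      s <- 0
      for (k in 2:(L - 1)) s <- s + ((p[k - 1, i] - p[k + 1, j]) / 2)^2
      eedp[i, j] <- s / (L - 2)
    }
  }
  edp <- numeric(20)
  for (j in 1:20) edp[j] <- sum(eedp[, j]) / 20
  c(as.vector(t(eedp)), edp)
}

oracle_metrics <- function(TP, FP, TN, FN) {
  list(SN = TP / (TP + FN), SP = TN / (TN + FP),
       ACC = (TP + TN) / (TP + FP + TN + FN),
       F = 2 * (TP / (TP + FP)) * (TP / (TP + FN)) /
         (TP / (TP + FP) + TP / (TP + FN)),
       MCC = (TP * TN - FP * FN) /
         sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)),
       FPR = FP / (FP + TN))
}

# Two well-separated Gaussian clusters in 2-D: trivially separable by an
# RBF-SVM, used for grid-search sanity checks.
separable_xy <- function(n_per_class = 12L, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(2 * n_per_class, mean = 0, sd = 0.3),
                    ncol = 2),
             matrix(stats::rnorm(2 * n_per_class, mean = 4, sd = 0.3),
                    ncol = 2))
  y <- rep(c("virion", "nonvirion"), each = n_per_class)
  list(x = x, y = y)
}

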