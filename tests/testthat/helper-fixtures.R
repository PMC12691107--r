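# Small in-code fixtures and independent oracles used across the suite.

# tie-free random expression-like matrix
rand_matrix <- function(g = 20, s = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(g * s, mean = 8, sd = 2), g, s,
              dimnames = list(sprintf("G%03d", seq_len(g)),
                              sprintf("S%02d", seq_len(s))))
  m
}

tiny_counts <- function() {
  count_matrix(matrix(c(10, 5, 2, 20, 8, 3), nrow = 3,
                      dimnames = list(c("MYC", "CD3", "FOXP3"),
                                      c("S1", "S2"))),
               species = "canine")
}

# Brute-force geNorm oracle: naive double-loop M values and step-by-step
# exclusion, written independently of the package internals.
oracle_genorm_M <- function(l2) {
  n <- nrow(l2)
  M <- numeric(n)
  for (j in seq_len(n)) {
    a <- c()
    for (k in seq_len(n)) {
      if (k == j) next
      a <- c(a, sd(l2[j, ] - l2[k, ]))
    }
    M[j] <- mean(a)
  }
  names(M) <- rownames(l2)
  M
}

oracle_genorm_exclusion <- function(l2) {
  out <- character(0)
  cur <- l2
  while (nrow(cur) > 2) {
    M <- oracle_genorm_M(cur)
    w <- which.max(M)
    out <- c(out, rownames(cur)[w])
    cur <- cur[-w, , drop = FALSE]
  }
  out
}

# Exhaustive permutation p for the target-vs-rest delta statistic.
oracle_exhaustive_perm_p <- function(rho, is_target) {
  n <- length(rho); k <- sum(is_target)
  deltas <- apply(utils::combn(n, k), 2, function(idx) {
    flag <- logical(n); flag[idx] <- TRUE
    mean(rho[flag]) - mean(rho[!flag])
  })
  obs <- mean(rho[is_target]) - mean(rho[!is_target])
  mean(deltas >= obs - 1e-12)
}

# simulated clinical endpoint generator used by null-calibration tests
null_surv_groups <- function(n_per = 25, censor_q = 0.3) {
  t1 <- rexp(2 * n_per, rate = 1 / 300)
  cens <- runif(2 * n_per, 0, 900)
  list(time = pmin(t1, cens), event = t1 <= cens,
       group = rep(c("A", "B"), each = n_per))
}

# rank profiles straight from log2 matrices (per-sample scaling does not
# change ranks, so log2(count + 1) is a valid cross-species input)
profiles_from_log2 <- function(canine_l2, human_l2) {
  common_gene_ranks(canine_l2, human_l2)
}
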