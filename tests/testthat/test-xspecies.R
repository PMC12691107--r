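make_profiles <- function(g = 12, nc = 4, nh = 6, seed = 1) {
  ca <- rand_matrix(g, nc, seed = seed)
  hu <- rand_matrix(g, nh, seed = seed + 1000)
  common_gene_ranks(ca, hu)
}

test_that("common gene restriction and within-sample ranking behave as defined", {
  ca <- rand_matrix(6, 3, seed = 2)
  hu <- rand_matrix(6, 4, seed = 3)
  rownames(hu) <- c(rownames(ca)[1:4], "ONLYH1", "ONLYH2")
  rp <- common_gene_ranks(ca, hu)
  expect_equal(rp$canine$genes, rownames(ca)[1:4])
  expect_equal(rp$human$genes, rp$canine$genes)

  m <- matrix(c(5, 1, 3), 3, 1, dimnames = list(c("A", "B", "C"), "S1"))
  m2 <- matrix(c(2, 4, 9), 3, 1, dimnames = list(c("A", "B", "C"), "H1"))
  rp2 <- common_gene_ranks(m, m2)
  expect_equal(unname(rp2$canine$ranks[, 1]), c(3, 1, 2))

  rownames(hu) <- sprintf("Z%d", 1:6)
  expect_error(common_gene_ranks(ca, hu), "0 common")
})

test_that("subtype mean correlations hit the Spearman closed form", {
  # canine cohort of one sample: reference = its own rank vector
  ca <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(LETTERS[1:4], "C1"))
  hu <- cbind(H1 = c(1, 2, 3, 4), H2 = c(4, 3, 2, 1),
              H3 = c(2, 1, 3, 4), H4 = c(1, 2, 4, 3))
  rownames(hu) <- LETTERS[1:4]
  rp <- common_gene_ranks(ca, hu)
  subtypes <- c(H1 = "s1", H2 = "s1", H3 = "s2", H4 = "s2")
  rb <- subtype_mean_correlation(rp$canine, rp$human, subtypes)
  # s1: rho(identity) = 1, rho(reversal) = -1 -> mean 0
  expect_equal(unname(rb["s1"]), 0)
  # s2: one adjacent swap each: rho = 1 - 6*2/(4*15) = 0.8 -> mean 0.8
  expect_equal(unname(rb["s2"]), 0.8)
  expect_error(subtype_mean_correlation(rp$canine, rp$human,
                                        c(H1 = "s1", H2 = "s1", H3 = "s2",
                                          H4 = "s3")), "s2")
})

test_that("permutation p is valid, deterministic and one-sided upper tail", {
  rp <- make_profiles(seed = 8)
  subs <- c(rep("UPS", 3), rep("other", 3))
  names(subs) <- colnames(rp$human$ranks)
  p1 <- permutation_test(rp$canine, rp$human, subs, "UPS", B = 199, seed = 4)
  p2 <- permutation_test(rp$canine, rp$human, subs, "UPS", B = 199, seed = 4)
  expect_equal(p1$p, p2$p)
  expect_gt(p1$p, 0)
  expect_lte(p1$p, 1)
  expect_true(all(abs(p1$rho_bar) <= 1))
  expect_error(permutation_test(rp$canine, rp$human,
                                setNames(rep("UPS", 6), names(subs)), "UPS",
                                B = 199), "rest")
  expect_error(permutation_test(rp$canine, rp$human, subs, "UPS", B = 50),
               ">= 99")
})

test_that("perfect-signal target attains the minimal permutation p", {
  g <- 30
  ref <- matrix(seq_len(g), g, 2, dimnames = list(sprintf("G%d", 1:g),
                                                  c("C1", "C2")))
  hu <- cbind(H1 = seq_len(g), H2 = seq_len(g), H3 = seq_len(g),
              H4 = rev(seq_len(g)), H5 = rev(seq_len(g)), H6 = rev(seq_len(g)))
  rownames(hu) <- rownames(ref)
  rp <- common_gene_ranks(ref, hu)
  subs <- setNames(c("UPS", "UPS", "UPS", "rest", "rest", "rest"),
                   colnames(hu))
  fit <- permutation_test(rp$canine, rp$human, subs, "UPS", B = 999, seed = 1)
  expect_equal(fit$delta, 2)
  expect_lt(fit$p, 0.06)   # best attainable given 20 distinct splits
})

test_that("Monte Carlo permutation p agrees with exhaustive enumeration", {
  for (seed in 1:8) {
    rp <- make_profiles(g = 15, nc = 3, nh = 6, seed = seed)
    subs <- setNames(rep(c("t", "r"), each = 3), colnames(rp$human$ranks))
    fit <- permutation_test(rp$canine, rp$human, subs, "t",
                            B = 20000, seed = seed + 50)
    rho <- as.vector(cor(rp$human$ranks,
                         apply(rp$canine$ranks, 1, median),
                         method = "spearman"))
    p_ex <- oracle_exhaustive_perm_p(rho, subs[colnames(rp$human$ranks)] == "t")
    expect_lt(abs(fit$p - p_ex), 0.02)
  }
})

test_that("pairwise subtype tests are label-equivariant", {
  rp <- make_profiles(g = 20, nc = 4, nh = 8, seed = 21)
  subs <- setNames(rep(c("a", "b", "c", "d"), each = 2),
                   colnames(rp$human$ranks))
  t1 <- pairwise_subtype_test(rp$canine, rp$human, subs, B = 199, seed = 9)
  renamed <- c(a = "w", b = "x", c = "y", d = "z")[subs]
  names(renamed) <- names(subs)
  t2 <- pairwise_subtype_test(rp$canine, rp$human, renamed, B = 199, seed = 9)
  expect_equal(t1$p, t2$p)
  expect_equal(t1$rho_bar, t2$rho_bar)
  t3 <- pairwise_subtype_test(rp$canine, rp$human, subs, B = 199, seed = 9,
                              adjust = TRUE)
  expect_equal(t3$p_bh, p.adjust(t1$p, "BH"))
})

test_that("bootstrap closest-subtype output is a proper distribution", {
  rp <- make_profiles(g = 20, nc = 4, nh = 8, seed = 31)
  subs <- setNames(rep(c("a", "b"), each = 4), colnames(rp$human$ranks))
  bc <- bootstrap_closest(rp$canine, rp$human, subs, B = 100, seed = 3)
  expect_equal(sum(bc$closest_freq), 1)
  expect_lte(bc$interval[1], bc$interval[2])
  bc2 <- bootstrap_closest(rp$canine, rp$human, subs, B = 100, seed = 3)
  expect_equal(bc2$closest_freq, bc$closest_freq)
  # B = 1: degenerate interval at the single replicate value
  b1 <- bootstrap_closest(rp$canine, rp$human, subs, B = 1, seed = 5)
  expect_equal(b1$interval[1], b1$interval[2])
})

test_that("identically generated subtypes give near-uniform closest frequencies", {
  # within one dataset the bootstrap tracks that dataset's sampling noise,
  # so uniformity is assessed across independent null datasets
  winners <- vapply(1:60, function(s) {
    ca <- rand_matrix(40, 6, seed = 7000 + s)
    hu <- rand_matrix(40, 24, seed = 8000 + s)
    rp <- common_gene_ranks(ca, hu)
    subs <- setNames(rep(c("a", "b", "c", "d"), times = 6),
                     colnames(rp$human$ranks))
    bc <- bootstrap_closest(rp$canine, rp$human, subs, B = 50, seed = s)
    names(which.max(bc$closest_freq))
  }, character(1))
  counts <- table(factor(winners, levels = c("a", "b", "c", "d")))
  chi <- chisq.test(as.vector(counts), p = rep(1 / 4, 4))
  expect_gt(chi$p.value, 0.01)
})
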