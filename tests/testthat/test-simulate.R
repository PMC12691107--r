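test_that("configuration invariants are enforced", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(subtype_proportions = c(UPS = 0.5, lipo = 0.4)),
               "sum to 1")
  expect_error(sim_config(canine_ups_share = 1.2), "canine_ups_share")
  expect_error(sim_config(censor_fraction = 1), "censor_fraction")
  expect_error(sim_config(n_genes = 50, signature_size = 20),
               "panel too small")
  expect_error(sim_config(hazard_ratios = c(castrated_male = 2)),
               "hazard_ratios")
})

test_that("expression generation is deterministic and structured as configured", {
  cfg <- sim_config(n_canine = 8, n_human = 30, n_genes = 200,
                    signature_size = 10, seed = 7)
  e1 <- generate_expression(cfg)
  e2 <- generate_expression(cfg)
  expect_identical(unclass(e1$canine)[, ], unclass(e2$canine)[, ])
  expect_identical(unclass(e1$human)[, ], unclass(e2$human)[, ])
  expect_identical(e1$human_subtypes, e2$human_subtypes)

  expect_true("MYC" %in% rownames(e1$canine))
  expect_equal(length(e1$truth$housekeeping), 10)
  expect_true(all(unclass(e1$canine) >= 0))
  # disjoint signatures, none housekeeping
  sigs <- unlist(e1$truth$signature_genes)
  expect_false(anyDuplicated(sigs) > 0)
  expect_length(intersect(sigs, e1$truth$housekeeping), 0)
})

test_that("full UPS sharing equalizes expected means; zero sharing removes them", {
  cfg <- sim_config(n_canine = 5, n_human = 20, n_genes = 150,
                    signature_size = 8, canine_ups_share = 1, seed = 3)
  e <- generate_expression(cfg)
  ups_genes <- e$truth$signature_genes$UPS
  expect_equal(e$truth$canine_log2_mean[ups_genes],
               e$truth$subtype_log2_mean[ups_genes, "UPS"])

  cfg0 <- cfg; cfg0$canine_ups_share <- 0
  e0 <- generate_expression(cfg0)
  expect_equal(e0$truth$canine_log2_mean, e0$truth$baseline_log2)
})

test_that("housekeeping genes leak no subtype signal", {
  cfg <- sim_config(seed = 5)
  e <- generate_expression(cfg)
  hk <- e$truth$housekeeping
  spread <- apply(e$truth$subtype_log2_mean[hk, ], 1, function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("subtype sample counts track the configured proportions", {
  cfg <- sim_config(n_human = 400, n_genes = 150, signature_size = 5, seed = 11)
  e <- generate_expression(cfg)
  obs <- table(e$human_subtypes)[names(cfg$subtype_proportions)]
  chi <- chisq.test(as.vector(obs), p = cfg$subtype_proportions)
  expect_gt(chi$p.value, 0.01)
})

test_that("clinical generation honors censoring and hazard settings", {
  cfg <- sim_config(censor_fraction = 0, seed = 9)
  cl <- generate_clinical(cfg, sprintf("D%02d", 1:50))
  expect_true(all(cl$event_pfs))
  expect_true(all(cl$time_pfs >= 0))
  expect_true(all(cl$sex_status %in% c("intact_male", "intact_female",
                                       "castrated_male", "spayed_female")))

  cfg2 <- sim_config(censor_fraction = 0.4, seed = 9)
  cl2 <- generate_clinical(cfg2, sprintf("D%03d", 1:400))
  expect_lt(abs(mean(!cl2$event_pfs) - 0.4), 0.12)

  cl2b <- generate_clinical(cfg2, sprintf("D%03d", 1:400))
  expect_identical(cl2, cl2b)
})

test_that("null hazards give exchangeable groups (uniform log-rank p)", {
  cfg <- sim_config(hazard_ratios = c(castrated_male = 1, foxp3_pos = 1,
                                      myc_high = 1), seed = 2)
  ps <- vapply(1:120, function(s) {
    c2 <- cfg; c2$seed <- as.integer(5000 + s)
    myc <- rep(c(TRUE, FALSE), 20)
    cl <- generate_clinical(c2, sprintf("D%02d", 1:40), myc_high = myc,
                            foxp3_pos = rep(FALSE, 40))
    logrank(cl$time_pfs, cl$event_pfs, myc)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("IHC generation is deterministic with Poisson-tail grading", {
  cfg <- sim_config(seed = 13)
  samples <- sprintf("D%02d", 1:40)
  i1 <- generate_ihc(cfg, samples)
  i2 <- generate_ihc(cfg, samples)
  expect_identical(i1$records, i2$records)
  expect_true(all(i1$records$grade %in% 0:3))
  # zero latent intensity: all fields zero, grade 0
  zero <- i1$records[i1$records$marker == "FOXP3" &
                     i1$truth$latent[i1$records$sample[i1$records$marker == "FOXP3"],
                                     "FOXP3"] == 0, ]
  if (nrow(zero)) {
    expect_true(all(as.matrix(zero[, paste0("f", 1:5)]) == 0))
    expect_true(all(zero$grade == 0))
  }
  # strong latent intensity is graded 3 (Poisson tail: P(mean <= 10) ~ 1e-8)
  strong <- i1$truth$latent[, "CD204"] >= 20
  if (any(strong)) {
    rec <- i1$records[i1$records$marker == "CD204" &
                      i1$records$sample %in% samples[strong], ]
    expect_true(all(rec$grade == 3))
  }
  expect_gt(sum(i1$truth$latent[, "CD204"] >= 20), 0)
})

test_that("the cohort bundle is reproducible and internally linked", {
  cfg <- sim_config(n_canine = 12, n_human = 40, n_genes = 150,
                    signature_size = 8, seed = 21)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(unclass(b1$canine_counts)[, ], unclass(b2$canine_counts)[, ])
  expect_identical(b1$canine_clinical, b2$canine_clinical)
  expect_identical(b1$ihc, b2$ihc)

  # covariate linkage: myc_high is the median split of simulated MYC counts
  myc <- log2(unclass(b1$canine_counts)["MYC", ] + 1)
  expect_identical(unname(b1$truth$myc_high), unname(myc > median(myc)))
  expect_identical(b1$canine_clinical$foxp3_pos,
                   unname(b1$truth$foxp3_pos[b1$canine_clinical$sample]))
})
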