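#' Simulation configuration
#'
#' Parameters of the synthetic two-species NanoString-style cohort. Human
#' subtype proportions default to the composition of the human sarcoma
#' cohort used for comparison: liposarcoma 33%, undifferentiated pleomorphic
#' sarcoma (UPS) 25%, leiomyosarcoma 23%, synovial sarcoma 19%. Counts are
#' negative-binomial with variance mu + phi * mu^2 (phi = `nb_dispersion`
#' for tumor genes, `hk_dispersion` for housekeeping genes). The canine
#' cohort shares a fraction `canine_ups_share` of the UPS signature (same
#' genes, same sign, scaled effect).
#'
#' @param n_canine,n_human Cohort sizes.
#' @param subtype_proportions Named fractions per human subtype (sum to 1).
#' @param n_genes Panel size (includes housekeeping genes and MYC).
#' @param n_housekeeping Number of low-dispersion reference genes.
#' @param signature_size Signature genes per subtype.
#' @param effect_size_log2 Signature effect size on the log2 scale.
#' @param canine_ups_share Fraction of the UPS signature carried by canine
#'   samples, in [0, 1].
#' @param nb_dispersion,hk_dispersion Negative-binomial dispersion phi for
#'   tumor and housekeeping genes.
#' @param hazard_ratios Named positive hazard ratios for the clinical
#'   covariates `castrated_male`, `foxp3_pos`, `myc_high`.
#' @param censor_fraction Target fraction of censored records, in [0, 1).
#' @param seed Integer RNG seed.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_canine = 30L, n_human = 60L,
                       subtype_proportions = c(UPS = 0.25, liposarcoma = 0.33,
                                               leiomyosarcoma = 0.23,
                                               synovial = 0.19),
                       n_genes = 600L, n_housekeeping = 10L,
                       signature_size = 25L,
                       effect_size_log2 = 2, canine_ups_share = 0.75,
                       nb_dispersion = 0.1, hk_dispersion = 0.01,
                       hazard_ratios = c(castrated_male = 2.0, foxp3_pos = 2.0,
                                         myc_high = 2.5),
                       censor_fraction = 0.3, seed = 1L) {
  cfg <- list(n_canine = as.integer(n_canine), n_human = as.integer(n_human),
              subtype_proportions = subtype_proportions,
              n_genes = as.integer(n_genes),
              n_housekeeping = as.integer(n_housekeeping),
              signature_size = as.integer(signature_size),
              effect_size_log2 = effect_size_log2,
              canine_ups_share = canine_ups_share,
              nb_dispersion = nb_dispersion, hk_dispersion = hk_dispersion,
              hazard_ratios = hazard_ratios,
              censor_fraction = censor_fraction, seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_canine, n_human, n_genes, n_housekeeping, signature_size) <= 0))
      stop("all counts must be > 0")
    if (abs(sum(subtype_proportions) - 1) > 1e-9)
      stop("subtype proportions must sum to 1")
    if (is.null(names(subtype_proportions)) || anyDuplicated(names(subtype_proportions)))
      stop("subtype proportions must be uniquely named")
    if (canine_ups_share < 0 || canine_ups_share > 1)
      stop("canine_ups_share must be in [0, 1]")
    if (censor_fraction < 0 || censor_fraction >= 1)
      stop("censor_fraction must be in [0, 1)")
    if (nb_dispersion <= 0 || hk_dispersion <= 0)
      stop("dispersions must be positive")
    need_hr <- c("castrated_male", "foxp3_pos", "myc_high")
    if (!all(need_hr %in% names(hazard_ratios)) || any(hazard_ratios <= 0))
      stop("hazard_ratios must be positive and name ",
           paste(need_hr, collapse = ", "))
    n_sub <- length(subtype_proportions)
    if (signature_size * n_sub + n_housekeeping + 1L > n_genes)
      stop("panel too small: signature_size x subtypes + housekeeping + MYC exceeds n_genes")
  })
  structure(cfg, class = "sim_config")
}

# NB draw with variance mu + phi mu^2; phi -> 0 approaches Poisson
rnbinom_mu_phi <- function(n, mu, phi) {
  stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Generate the two-species expression matrices
#'
#' Counts are negative-binomial around 2^(baseline + effect). Baseline log2
#' means are Normal(5, 2) truncated at 0 (the typical nCounter dynamic
#' range). Each subtype owns a disjoint signature gene set whose effect is
#' `effect_size_log2` with a random sign per gene; housekeeping genes carry
#' no subtype effect and low dispersion. Canine samples carry
#' `canine_ups_share` of the UPS signature. MYC is always on the panel.
#'
#' @param config A [sim_config()].
#' @return List: `canine` and `human` [count_matrix()] objects,
#'   `human_subtypes` (label per human sample), and `truth` (signature gene
#'   sets and signs, baselines, expected log2 means, housekeeping set).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_sub <- length(config$subtype_proportions)
  subs <- names(config$subtype_proportions)
  if (!"UPS" %in% subs) stop("subtype proportions must include UPS")
  G <- config$n_genes

  hk_genes <- sprintf("HKG%02d", seq_len(config$n_housekeeping))
  n_tumor <- G - config$n_housekeeping - 1L
  tumor_genes <- c("MYC", sprintf("GENE%04d", seq_len(n_tumor)))
  genes <- c(hk_genes, tumor_genes)

  baseline <- pmax(stats::rnorm(G, mean = 5, sd = 2), 0)
  names(baseline) <- genes

  # disjoint signatures drawn from the non-MYC tumor genes
  pool <- setdiff(tumor_genes, "MYC")
  sig_idx <- split(pool[seq_len(config$signature_size * n_sub)],
                   rep(subs, each = config$signature_size))
  signs <- lapply(sig_idx, function(g)
    stats::setNames(sample(c(-1, 1), length(g), replace = TRUE), g))

  effect_for <- function(sub, scale = 1) {
    e <- stats::setNames(numeric(G), genes)
    e[names(signs[[sub]])] <- scale * config$effect_size_log2 * signs[[sub]]
    e
  }

  phi <- ifelse(genes %in% hk_genes, config$hk_dispersion, config$nb_dispersion)

  human_subtypes <- sample(subs, config$n_human, replace = TRUE,
                           prob = config$subtype_proportions)
  human_ids <- sprintf("HU%03d", seq_len(config$n_human))
  names(human_subtypes) <- human_ids

  human <- vapply(seq_len(config$n_human), function(i) {
    mu <- 2^(baseline + effect_for(human_subtypes[i]))
    rnbinom_mu_phi(G, mu, phi)
  }, numeric(G))
  dimnames(human) <- list(genes, human_ids)

  canine_effect <- effect_for("UPS", scale = config$canine_ups_share)
  canine_ids <- sprintf("CA%03d", seq_len(config$n_canine))
  canine <- vapply(seq_len(config$n_canine), function(i) {
    mu <- 2^(baseline + canine_effect)
    rnbinom_mu_phi(G, mu, phi)
  }, numeric(G))
  dimnames(canine) <- list(genes, canine_ids)

  truth <- list(baseline_log2 = baseline, signature_genes = sig_idx,
                signature_signs = signs, housekeeping = hk_genes,
                canine_log2_mean = baseline + canine_effect,
                subtype_log2_mean = vapply(subs, function(s)
                  baseline + effect_for(s), numeric(G)),
                config = config)
  list(canine = count_matrix(canine, "canine"),
       human = count_matrix(human, "human"),
       human_subtypes = human_subtypes, truth = truth)
}

# pick the uniform-censoring upper bound achieving the target censored
# fraction for the realized event times: mean(pmin(T/u, 1)) = target
censor_bound <- function(event_times, target) {
  frac <- function(u) mean(pmin(event_times / u, 1)) - target
  stats::uniroot(frac, lower = min(event_times) * 1e-3,
                 upper = max(event_times) * 1e3, extendInt = "downX")$root
}

#' Generate clinical covariates and right-censored endpoints
#'
#' Event times are Weibull (shape 1.2) under a proportional-hazards linear
#' predictor: log-hazard contributions log(HR) for castrated males,
#' FOXP3-positive tumors and MYC-high tumors. Censoring is independent
#' Uniform(0, u) with u calibrated so that approximately `censor_fraction`
#' of records are censored. Sex status is drawn from the four neuter-status
#' categories at the cohort frequencies of the clinical study population
#' (4% intact male, 1.3% intact female, 42.7% castrated male, 52% spayed
#' female); site, grade and margins likewise.
#'
#' @param config A [sim_config()].
#' @param samples Character vector of canine sample ids.
#' @param myc_high Logical per sample (MYC above cohort median); simulated
#'   from scratch when NULL.
#' @param foxp3_pos Logical per sample; simulated when NULL.
#' @return Validated clinical data.frame (see [validate_clinical()]).
#' @export
generate_clinical <- function(config, samples, myc_high = NULL,
                              foxp3_pos = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- length(samples)
  sex <- sample(c("intact_male", "intact_female", "castrated_male",
                  "spayed_female"), n, replace = TRUE,
                prob = c(3, 1, 32, 39) / 75)
  site <- sample(c("appendicular", "non_appendicular"), n, replace = TRUE,
                 prob = c(47, 28) / 75)
  grade <- sample(1:3, n, replace = TRUE, prob = c(29, 26, 20) / 75)
  margin <- sample(c("complete", "incomplete"), n, replace = TRUE,
                   prob = c(52, 23) / 75)
  second_surgery <- margin == "incomplete" & stats::runif(n) < 0.5
  if (is.null(myc_high)) myc_high <- stats::runif(n) < 0.5
  if (is.null(foxp3_pos)) foxp3_pos <- stats::runif(n) < 0.6

  hr <- config$hazard_ratios
  lp <- log(hr[["castrated_male"]]) * (sex == "castrated_male") +
        log(hr[["foxp3_pos"]]) * foxp3_pos +
        log(hr[["myc_high"]]) * myc_high

  shape <- 1.2
  draw_endpoint <- function(baseline_median) {
    lambda0 <- log(2) / baseline_median^shape
    t_ev <- (-log(stats::runif(n)) / (lambda0 * exp(lp)))^(1 / shape)
    if (config$censor_fraction == 0)
      return(list(time = t_ev, event = rep(TRUE, n)))
    u <- censor_bound(t_ev, config$censor_fraction)
    cens <- stats::runif(n, 0, u)
    list(time = pmin(t_ev, cens), event = t_ev <= cens)
  }
  pfs <- draw_endpoint(500); rfs <- draw_endpoint(600)
  ttm <- draw_endpoint(800); os <- draw_endpoint(700)

  validate_clinical(data.frame(
    sample = samples, sex_status = sex, site = site, grade = grade,
    margin = margin, second_surgery = second_surgery,
    time_pfs = pfs$time, event_pfs = pfs$event,
    time_rfs = rfs$time, event_rfs = rfs$event,
    time_ttm = ttm$time, event_ttm = ttm$event,
    time_os = os$time, event_os = os$event,
    recurrence = as.integer(rfs$event),
    myc_high = myc_high, foxp3_pos = foxp3_pos,
    stringsAsFactors = FALSE))
}

#' Generate five-field IHC counts
#'
#' Per sample and marker, a latent staining intensity is drawn (log-normal
#' around a marker-typical level, zero-inflated so some tumors are negative)
#' and the five field counts are Poisson around it. FOXP3 latent positivity
#' is returned so it can drive the clinical hazard covariate.
#'
#' @param config A [sim_config()].
#' @param samples Character vector of sample ids.
#' @return List: `records` (data.frame sample, marker, f1..f5, mean_count,
#'   grade) and `truth` (latent intensities, `foxp3_pos`).
#' @export
generate_ihc <- function(config, samples) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- length(samples)
  marker_mu <- c(CD204 = 12, CD3 = 6, FOXP3 = 2.5)
  marker_p0 <- c(CD204 = 0.06, CD3 = 0.2, FOXP3 = 0.4)
  records <- NULL
  latent <- matrix(0, n, 3, dimnames = list(samples, names(marker_mu)))
  for (mk in names(marker_mu)) {
    lam <- stats::rlnorm(n, meanlog = log(marker_mu[[mk]]), sdlog = 0.6)
    lam[stats::runif(n) < marker_p0[[mk]]] <- 0
    latent[, mk] <- lam
    fc <- t(vapply(lam, function(l) stats::rpois(5L, l), numeric(5)))
    records <- rbind(records, data.frame(
      sample = samples, marker = mk,
      f1 = fc[, 1], f2 = fc[, 2], f3 = fc[, 3], f4 = fc[, 4], f5 = fc[, 5],
      stringsAsFactors = FALSE))
  }
  records <- ihc_grade_table(records)
  list(records = records,
       truth = list(latent = latent,
                    foxp3_pos = stats::setNames(latent[, "FOXP3"] > 0, samples)))
}

#' Simulate a full two-species cohort bundle
#'
#' Runs [generate_expression()], [generate_ihc()] and [generate_clinical()]
#' with deterministically derived per-stage seeds and links the covariates:
#' `myc_high` comes from the canine MYC counts (median split on
#' log2(count + 1)), `foxp3_pos` from the latent IHC status.
#'
#' @param config A [sim_config()].
#' @return Object of class `cohort_bundle`: `canine_counts`, `human_counts`,
#'   `canine_clinical`, `human_subtypes`, `ihc`, `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  expr <- generate_expression(config)
  canine_ids <- colnames(expr$canine)
  ihc <- generate_ihc(config, canine_ids)
  myc <- log2(as_plain_matrix(expr$canine)["MYC", ] + 1)
  myc_high <- myc > stats::median(myc)
  clinical <- generate_clinical(config, canine_ids,
                                myc_high = unname(myc_high),
                                foxp3_pos = unname(ihc$truth$foxp3_pos))
  truth <- c(expr$truth, list(ihc_latent = ihc$truth$latent,
                              foxp3_pos = ihc$truth$foxp3_pos,
                              myc_high = myc_high,
                              hazard_ratios = config$hazard_ratios))
  structure(list(canine_counts = expr$canine, human_counts = expr$human,
                 canine_clinical = clinical,
                 human_subtypes = expr$human_subtypes,
                 ihc = ihc$records, truth = truth, config = config),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("cohort_bundle: %d canine + %d human samples, %d genes\n",
              ncol(x$canine_counts), ncol(x$human_counts),
              nrow(x$canine_counts)))
  cat("  human subtypes:", paste(sprintf("%s=%d",
      names(table(x$human_subtypes)), table(x$human_subtypes)),
      collapse = ", "), "\n")
  invisible(x)
}
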