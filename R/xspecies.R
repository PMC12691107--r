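#' Rank profiles over the common gene set
#'
#' Restricts both log2-normalized matrices to the gene-symbol intersection
#' (uppercase, 1:1 matches) and replaces each sample's values by within-sample
#' ranks (average convention for ties). These rank profiles are the basis of
#' every downstream Spearman-type comparison.
#'
#' @param canine,human Log2-normalized gene-by-sample matrices.
#' @return List of two `rank_profile` objects (`canine`, `human`), each a list
#'   with the rank matrix `ranks`, the common `genes`, and a `species` tag.
#' @export
common_gene_ranks <- function(canine, human) {
  for (m in list(canine, human)) {
    lb <- attr(m, "log_base")
    if (!is.null(lb) && !identical(lb, 2) && !identical(lb, "none"))
      stop("cross-species comparison expects log2-normalized matrices, got log base ", lb)
  }
  gc_ <- toupper(rownames(canine)); gh <- toupper(rownames(human))
  common <- intersect(gc_, gh)
  if (length(common) < 3L)
    stop("only ", length(common), " common gene(s); >= 3 required")
  rank_cols <- function(m, genes, species) {
    v <- as_plain_matrix(m)
    rownames(v) <- toupper(rownames(v))
    v <- v[genes, , drop = FALSE]
    r <- apply(v, 2L, rank, ties.method = "average")
    rownames(r) <- genes
    structure(list(ranks = r, genes = genes, species = species),
              class = "rank_profile")
  }
  list(canine = rank_cols(canine, common, "canine"),
       human = rank_cols(human, common, "human"))
}

# per-gene median rank over canine samples: the cohort reference profile
canine_reference <- function(canine_rp) {
  apply(canine_rp$ranks, 1L, stats::median)
}

# Spearman correlation of every human sample's rank vector with the canine
# reference; the permutation and bootstrap machinery all runs on this vector.
per_sample_rho <- function(canine_rp, human_rp,
                           reference = canine_reference(canine_rp)) {
  as.vector(stats::cor(human_rp$ranks, reference, method = "spearman"))
}

check_subtypes <- function(human_rp, subtypes, min_size = 2L) {
  ids <- colnames(human_rp$ranks)
  if (!is.null(names(subtypes))) subtypes <- subtypes[ids]
  if (length(subtypes) != length(ids) || any(is.na(subtypes)))
    stop("every human sample must carry a subtype label")
  f <- factor(subtypes)
  small <- names(which(table(f) < min_size))
  if (length(small))
    stop("subtype(s) with < ", min_size, " samples: ",
         paste(small, collapse = ", "))
  f
}

#' Mean rank correlation of canine STS to each human subtype
#'
#' The canine cohort is summarized by its per-gene median rank profile; for
#' each human subtype the mean Spearman correlation of its samples' rank
#' vectors with that reference is returned.
#'
#' @param canine_rp,human_rp `rank_profile` objects from
#'   [common_gene_ranks()].
#' @param subtypes Subtype label per human sample (named vector matched by
#'   sample id, or positional).
#' @return Named numeric vector of per-subtype mean correlations.
#' @export
subtype_mean_correlation <- function(canine_rp, human_rp, subtypes) {
  f <- check_subtypes(human_rp, subtypes)
  rho <- per_sample_rho(canine_rp, human_rp)
  vapply(split(rho, f), mean, numeric(1))
}

#' Permutation test of subtype-specific similarity
#'
#' Tests whether the canine cohort is closer (in mean Spearman correlation
#' over the common-gene rank profiles) to the target human subtype than to
#' the pooled remaining subtypes. The observed statistic is
#' `delta = rho_bar(target) - rho_bar(rest)`; the null distribution permutes
#' the target/rest split over human samples uniformly, preserving group
#' sizes; the one-sided upper-tail p-value uses the +1 correction
#' `p = (1 + #(delta* >= delta_obs)) / (B + 1)`.
#'
#' @param canine_rp,human_rp `rank_profile` objects.
#' @param subtypes Subtype label per human sample.
#' @param target Target subtype label.
#' @param B Number of permutations (>= 99; default 10000).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return Object of class `subtype_similarity` with per-subtype `rho_bar`,
#'   `delta`, `p`, `B` and `seed`.
#' @export
permutation_test <- function(canine_rp, human_rp, subtypes, target,
                             B = 10000L, seed = 1L) {
  if (B < 99L) stop("B must be >= 99")
  f <- check_subtypes(human_rp, subtypes)
  if (!target %in% levels(f)) stop("target subtype not present: ", target)
  n_t <- sum(f == target)
  n <- length(f)
  if (n_t == n) stop("target subtype covers all samples; no rest group")
  rho <- per_sample_rho(canine_rp, human_rp)
  rho_bar <- vapply(split(rho, f), mean, numeric(1))
  delta_of <- function(is_target)
    mean(rho[is_target]) - mean(rho[!is_target])
  delta_obs <- delta_of(f == target)
  set.seed(seed)
  perm <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n_t)
    flag <- logical(n); flag[idx] <- TRUE
    delta_of(flag)
  }, numeric(1))
  p <- (1 + sum(perm >= delta_obs)) / (B + 1)
  structure(list(rho_bar = rho_bar, target = target, delta = delta_obs,
                 p = p, B = B, seed = seed, kind = "permutation"),
            class = "subtype_similarity")
}

#' Per-subtype permutation tests
#'
#' Runs [permutation_test()] once with each subtype as target; per-target
#' seeds are derived deterministically from `seed`.
#'
#' @inheritParams permutation_test
#' @param adjust Add a Benjamini-Hochberg column (off by default, matching
#'   a raw-p report).
#' @return Data.frame with one row per subtype: `rho_bar`, `delta`, `p`
#'   (and `p_bh` when `adjust = TRUE`).
#' @export
pairwise_subtype_test <- function(canine_rp, human_rp, subtypes,
                                  B = 10000L, seed = 1L, adjust = FALSE) {
  f <- check_subtypes(human_rp, subtypes)
  subs <- levels(f)
  fits <- lapply(seq_along(subs), function(i)
    permutation_test(canine_rp, human_rp, subtypes, subs[i],
                     B = B, seed = seed + i))
  out <- data.frame(subtype = subs,
                    rho_bar = vapply(fits, function(x) x$rho_bar[[x$target]], numeric(1)),
                    delta = vapply(fits, function(x) x$delta, numeric(1)),
                    p = vapply(fits, function(x) x$p, numeric(1)),
                    stringsAsFactors = FALSE)
  if (adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Bootstrap closest-subtype inference
#'
#' Each bootstrap replicate resamples canine samples with replacement
#' (rebuilding the median reference profile) and human samples with
#' replacement stratified within subtype, then recomputes the per-subtype
#' mean correlations. Reported are the frequency with which each subtype is
#' the closest (argmax) and the 2.5-97.5 percentile interval of the winning
#' subtype's mean correlation across replicates.
#'
#' @inheritParams permutation_test
#' @param B Number of bootstrap replicates (default 2000).
#' @return Object of class `subtype_similarity` with `rho_bar` (observed),
#'   `closest_freq`, `interval`, `B`, `seed`.
#' @export
bootstrap_closest <- function(canine_rp, human_rp, subtypes,
                              B = 2000L, seed = 1L) {
  if (B < 1L) stop("B must be >= 1")
  f <- check_subtypes(human_rp, subtypes, min_size = 1L)
  subs <- levels(f)
  cr <- canine_rp$ranks
  # pre-rank human columns once; Spearman vs any reference is then Pearson
  hr <- apply(human_rp$ranks, 2L, rank, ties.method = "average")
  n_c <- ncol(cr)
  idx_by_sub <- split(seq_along(f), f)
  rho_obs <- per_sample_rho(canine_rp, human_rp)
  rho_bar <- vapply(split(rho_obs, f), mean, numeric(1))
  set.seed(seed)
  winner <- character(B); winner_rho <- numeric(B)
  for (b in seq_len(B)) {
    ref <- apply(cr[, sample.int(n_c, n_c, replace = TRUE), drop = FALSE],
                 1L, stats::median)
    cref <- rank(ref, ties.method = "average")
    h_idx <- unlist(lapply(idx_by_sub, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    rho_b <- as.vector(stats::cor(hr[, h_idx, drop = FALSE], cref))
    means <- vapply(split(rho_b, f[h_idx]), mean, numeric(1))
    w <- which.max(means)
    winner[b] <- names(means)[w]
    winner_rho[b] <- means[w]
  }
  freq <- table(factor(winner, levels = subs)) / B
  structure(list(rho_bar = rho_bar,
                 closest_freq = as.numeric(freq) |> stats::setNames(subs),
                 interval = stats::quantile(winner_rho, c(0.025, 0.975),
                                            names = FALSE, type = 7),
                 winner_rho = winner_rho,
                 B = B, seed = seed, kind = "bootstrap"),
            class = "subtype_similarity")
}

#' @export
print.subtype_similarity <- function(x, ...) {
  cat(sprintf("Cross-species subtype similarity (%s)\n", x$kind))
  cat("  mean Spearman correlation to canine reference, by subtype:\n")
  print(round(x$rho_bar, 4))
  if (x$kind == "permutation")
    cat(sprintf("  target %s: delta = %.4f, one-sided p = %.4g (B = %d)\n",
                x$target, x$delta, x$p, x$B))
  if (x$kind == "bootstrap") {
    cat("  closest-subtype frequencies:\n")
    print(round(x$closest_freq, 4))
    cat(sprintf("  95%% percentile interval of winning rho_bar: [%.4f, %.4f] (B = %d)\n",
                x$interval[1], x$interval[2], x$B))
  }
  invisible(x)
}

#' @export
summary.subtype_similarity <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.subtype_similarity <- function(x, ...) {
  if (x$kind == "bootstrap") {
    graphics::barplot(x$closest_freq, ylab = "closest-subtype frequency",
                      main = "Bootstrap closest human subtype", ...)
  } else {
    graphics::barplot(x$rho_bar, ylab = "mean Spearman rho",
                      main = "Canine STS similarity to human subtypes", ...)
  }
  invisible(x)
}
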