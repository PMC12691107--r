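#' Pooled-distribution quantile normalization
#'
#' Within each sample, the value at within-sample rank r (average convention
#' for ties) is replaced by the quantile of the pooled distribution of all
#' G x S values at relative rank (r - 1) / (G - 1), with linear interpolation
#' between pooled order statistics. Within-sample rank order is preserved and
#' all samples end up with an identical value multiset (up to ties in the
#' input).
#'
#' This is the nCounter-style variant that pools every value in the data set
#' into one reference distribution, rather than averaging sorted columns.
#'
#' @param m A [count_matrix()] or numeric gene-by-sample matrix (>= 2 genes).
#' @return A `normalized_matrix` with `method = "quantile"`, `log_base = "none"`.
#' @export
quantile_normalize <- function(m) {
  v <- as_plain_matrix(m)
  if (length(v) == 0L) stop("cannot quantile-normalize an empty matrix")
  if (nrow(v) < 2L) stop("quantile normalization needs >= 2 genes")
  if (any(!is.finite(v))) stop("matrix contains non-finite values")
  pooled <- sort(as.vector(v))
  g <- nrow(v)
  out <- apply(v, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    stats::quantile(pooled, probs = (r - 1) / (g - 1), type = 7, names = FALSE)
  })
  dimnames(out) <- dimnames(v)
  new_normalized_matrix(out, method = "quantile", log_base = "none")
}

#' Log-transform a normalized matrix
#'
#' Applies `log(value + offset)` in the given base. A matrix may be logged
#' at most once; the log base used is recorded on the result.
#'
#' @param m A `normalized_matrix` with `log_base = "none"` (or a plain matrix).
#' @param base Log base, 10 or 2.
#' @param offset Pseudocount added before logging (default 1).
#' @return A `normalized_matrix` with the log base recorded.
#' @export
log_transform <- function(m, base = 10, offset = 1) {
  if (!base %in% c(10, 2)) stop("log base must be 10 or 2")
  lb <- attr(m, "log_base")
  if (!is.null(lb) && !identical(lb, "none"))
    stop("matrix is already log-transformed (base ", lb, ")")
  v <- as_plain_matrix(m)
  if (any(v + offset <= 0))
    stop("log transform undefined: value + offset <= 0")
  out <- log(v + offset, base = base)
  new_normalized_matrix(out, method = attr(m, "method") %||% "none",
                        log_base = base)
}

#' geNorm housekeeping-gene stability ranking
#'
#' For each candidate reference gene j, the pairwise variation with gene k is
#' A_jk = SD across samples of log2(x_j / x_k), and the stability value M_j is
#' the mean of A_jk over all other candidates; lower M means more stable.
#' The least stable gene (highest M) is removed and M recomputed, iterating
#' until two genes remain. The pairwise variation V_{k,k+1} is the SD across
#' samples of the log2 ratio of normalization factors (geometric means) built
#' from the k most stable versus the k+1 most stable genes; the smallest k
#' with V below `v_threshold` determines how many reference genes suffice.
#'
#' @param m Positive expression matrix (raw scale), or a log2
#'   `normalized_matrix` (detected via its `log_base` attribute).
#' @param candidates Character vector of >= 3 candidate gene symbols.
#' @param v_threshold Pairwise-variation cutoff (default 0.15, the canonical
#'   published value).
#' @return An object of class `genorm_ranking`: initial stability values `M`,
#'   `exclusion_order`, `stability_order` (most stable first), the `V`
#'   sequence, `n_selected` and the `selected` gene set.
#' @export
genorm_stability <- function(m, candidates, v_threshold = 0.15) {
  candidates <- toupper(candidates)
  if (length(candidates) < 3L)
    stop("geNorm needs >= 3 candidate genes (pairs alone are only a terminal state)")
  missing_g <- setdiff(candidates, rownames(m))
  if (length(missing_g))
    stop("candidate gene(s) not in matrix: ", paste(missing_g, collapse = ", "))
  lb <- attr(m, "log_base")
  v <- as_plain_matrix(m)[candidates, , drop = FALSE]
  l2 <- if (!is.null(lb) && identical(lb, 2)) v else {
    if (any(v <= 0)) stop("geNorm requires strictly positive values before logging")
    log2(v)
  }
  if (ncol(l2) < 2L) stop("geNorm needs >= 2 samples")

  m_values <- function(x) {
    n <- nrow(x)
    vapply(seq_len(n), function(j) {
      a <- vapply(setdiff(seq_len(n), j),
                  function(k) stats::sd(x[j, ] - x[k, ]), numeric(1))
      mean(a)
    }, numeric(1))
  }

  M0 <- m_values(l2)
  names(M0) <- candidates

  remaining <- candidates
  exclusion <- character(0)
  cur <- l2
  while (length(remaining) > 2L) {
    M <- m_values(cur)
    worst <- which.max(M)   # ties: first (input order)
    exclusion <- c(exclusion, remaining[worst])
    remaining <- remaining[-worst]
    cur <- cur[-worst, , drop = FALSE]
  }
  # final pair ordered by original stability (lower M0 first)
  pair <- remaining[order(M0[remaining])]
  stability_order <- c(pair, rev(exclusion))

  n <- length(candidates)
  V <- numeric(0)
  if (n >= 3L) {
    V <- vapply(2:(n - 1L), function(k) {
      nf_k <- colMeans(l2[stability_order[1:k], , drop = FALSE])
      nf_k1 <- colMeans(l2[stability_order[1:(k + 1L)], , drop = FALSE])
      stats::sd(nf_k - nf_k1)
    }, numeric(1))
    names(V) <- paste0("V", 2:(n - 1L), "/", 3:n)
  }
  ok <- which(V < v_threshold)
  n_selected <- if (length(ok)) (2:(n - 1L))[ok[1L]] else n
  structure(list(candidates = candidates, M = M0,
                 exclusion_order = exclusion,
                 stability_order = stability_order,
                 V = V, v_threshold = v_threshold,
                 n_selected = n_selected,
                 selected = stability_order[seq_len(n_selected)]),
            class = "genorm_ranking")
}

#' @export
print.genorm_ranking <- function(x, ...) {
  cat("geNorm stability ranking\n")
  cat("  stability order (most stable first):",
      paste(x$stability_order, collapse = ", "), "\n")
  cat("  M values:\n")
  print(round(x$M[order(x$M)], 4))
  if (length(x$V)) {
    cat("  pairwise variation V:\n")
    print(round(x$V, 4))
  }
  cat(sprintf("  selected %d gene(s) at V < %.2f: %s\n",
              x$n_selected, x$v_threshold, paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' @export
plot.genorm_ranking <- function(x, ...) {
  graphics::barplot(x$V, ylab = "pairwise variation V",
                    main = "geNorm V (adding the next reference gene)", ...)
  graphics::abline(h = x$v_threshold, lty = 2)
  invisible(x)
}

#' Reference-gene (geNorm) normalization
#'
#' Divides each sample (on the raw scale) by the geometric mean of its
#' selected housekeeping genes, then rescales the factors so their
#' across-sample geometric mean is 1.
#'
#' @param m Positive gene-by-sample matrix (raw scale).
#' @param selected Nonempty character vector of housekeeping gene symbols
#'   present in `m`.
#' @return A `normalized_matrix` with `method = "genorm"`. The scaling factor
#'   applied to each sample is attached as attribute `factors`.
#' @export
genorm_normalize <- function(m, selected) {
  selected <- toupper(selected)
  if (!length(selected)) stop("selected housekeeping set is empty")
  v <- as_plain_matrix(m)
  missing_g <- setdiff(selected, rownames(v))
  if (length(missing_g))
    stop("selected gene(s) not in matrix: ", paste(missing_g, collapse = ", "))
  hk <- v[selected, , drop = FALSE]
  zero_s <- colnames(v)[apply(hk <= 0, 2L, any)]
  if (length(zero_s))
    stop("zero housekeeping count in sample(s): ", paste(zero_s, collapse = ", "))
  logf <- colMeans(log(hk))
  logf <- logf - mean(logf)            # geometric mean of factors = 1
  out <- sweep(v, 2L, exp(logf), "/")
  res <- new_normalized_matrix(out, method = "genorm", log_base = "none")
  attr(res, "factors") <- exp(logf)
  res
}
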