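#' Per-gene one-way ANOVA screen
#'
#' Classical fixed-effects one-way F test applied independently to every gene
#' (row), comparing expression across the sample groups. With two groups the
#' F statistic is the squared pooled-variance t statistic. Computed by a
#' vectorized sum-of-squares decomposition across the whole matrix.
#'
#' Degenerate genes are resolved explicitly: a gene constant across all
#' samples has F = 0, p = 1; a gene with zero within-group variance but a
#' real group difference gets the smallest representable p.
#'
#' @param m Normalized gene-by-sample matrix.
#' @param groups Vector (or factor) of group labels, one per sample, or a
#'   named vector matched against column names.
#' @return Data.frame with columns `gene`, `F`, `p`, `pass` (p < 0.05).
#' @export
anova_per_gene <- function(m, groups) {
  v <- as_plain_matrix(m)
  if (!is.null(names(groups)) && !is.null(colnames(v)))
    groups <- groups[colnames(v)]
  if (length(groups) != ncol(v))
    stop("groups must supply one label per sample")
  f <- factor(groups)
  sizes <- table(f)
  if (nlevels(f) < 2L) stop("ANOVA needs >= 2 groups")
  small <- names(sizes)[sizes < 2L]
  if (length(small))
    stop("group(s) with < 2 samples: ", paste(small, collapse = ", "))
  k <- nlevels(f)
  n <- ncol(v)

  grand <- rowMeans(v)
  ss_tot <- rowSums((v - grand)^2)
  group_means <- vapply(levels(f), function(g)
    rowMeans(v[, f == g, drop = FALSE]), numeric(nrow(v)))
  if (is.null(dim(group_means))) group_means <- matrix(group_means, nrow = 1L)
  ss_between <- as.vector((group_means - grand)^2 %*% as.vector(sizes))
  ss_within <- pmax(ss_tot - ss_between, 0)

  Fstat <- (ss_between / (k - 1)) / (ss_within / (n - k))
  p <- stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  eps <- .Machine$double.eps * pmax(ss_tot, 1)
  const <- ss_tot <= eps                 # flat gene: no signal at all
  sep <- !const & ss_within <= eps       # perfect separation
  Fstat[const] <- 0; p[const] <- 1
  Fstat[sep] <- Inf; p[sep] <- .Machine$double.xmin
  data.frame(gene = rownames(v), F = Fstat, p = p, pass = p < 0.05,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select significant genes from an ANOVA table
#'
#' Strictly p < alpha, matching a raw-p screen; optionally apply
#' Benjamini-Hochberg first.
#'
#' @param tbl Output of [anova_per_gene()].
#' @param alpha Significance cutoff (default 0.05, strict `<`).
#' @param adjust `"none"` (default, the raw-p rule) or `"BH"`.
#' @return Character vector of selected gene symbols.
#' @export
filter_significant <- function(tbl, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (nrow(tbl) == 0L) stop("gene test table is empty")
  p <- if (adjust == "BH") stats::p.adjust(tbl$p, method = "BH") else tbl$p
  tbl$gene[p < alpha]
}

#' Hierarchical clustering order for heatmaps
#'
#' Agglomerative clustering with Euclidean distance and average linkage on
#' genes (rows) and samples (columns); `hclust` ties are resolved
#' deterministically by input index.
#'
#' @param m Numeric matrix with >= 2 rows; non-finite values are rejected.
#' @param linkage Linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return Object of class `cluster_order`: `gene_order` and `sample_order`
#'   (leaf permutations), the two `hclust` trees, and method tags.
#' @export
hierarchical_order <- function(m, linkage = "average") {
  v <- as_plain_matrix(m)
  if (nrow(v) < 2L) stop("clustering needs >= 2 rows")
  if (any(!is.finite(v))) stop("matrix contains non-finite values")
  hg <- stats::hclust(stats::dist(v), method = linkage)
  hs <- if (ncol(v) >= 2L) stats::hclust(stats::dist(t(v)), method = linkage)
        else NULL
  structure(list(gene_order = hg$order,
                 sample_order = if (is.null(hs)) 1L else hs$order,
                 gene_tree = hg, sample_tree = hs,
                 linkage = linkage, distance = "euclidean"),
            class = "cluster_order")
}

#' @export
print.cluster_order <- function(x, ...) {
  cat(sprintf("cluster_order: %d genes, %d samples (%s linkage, %s distance)\n",
              length(x$gene_order), length(x$sample_order),
              x$linkage, x$distance))
  invisible(x)
}
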