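#' Construct a validated count matrix
#'
#' A count matrix is a numeric gene-by-sample matrix of nonnegative probe
#' counts with unique, uppercased gene symbols as row names, unique sample
#' identifiers as column names, and a `species` attribute.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param species Species label, e.g. `"canine"` or `"human"`.
#' @return The validated matrix with class `count_matrix`.
#' @export
count_matrix <- function(values, species) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("count matrix values must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("count matrix must have at least one gene and one sample")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("count matrix requires gene symbols as rownames and sample ids as colnames")
  rownames(values) <- toupper(rownames(values))
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate gene symbols after uppercasing: ", paste(dup, collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative value at gene %s, sample %s",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  if (any(!is.finite(values)))
    stop("count matrix contains non-finite values")
  structure(values, species = species, class = c("count_matrix", class(values)))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x), attr(x, "species") %||% "unknown species"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_normalized_matrix <- function(values, method, log_base = "none") {
  structure(values, method = method, log_base = log_base,
            class = c("normalized_matrix", class(unclass(values))))
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d samples (method %s, log %s)\n",
              nrow(x), ncol(x), attr(x, "method"), attr(x, "log_base")))
  invisible(x)
}

# strip classes/attrs down to a plain numeric matrix
as_plain_matrix <- function(m) {
  v <- unclass(m)
  attributes(v) <- list(dim = dim(m), dimnames = dimnames(m))
  v
}

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row, gene symbols in the first column, one column per
#' sample. Symbols are uppercased; duplicates and negative values are
#' rejected.
#'
#' @param path Path to a tab-delimited text file.
#' @param species Species label attached to the matrix.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, species) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count matrix file needs a gene column plus >= 1 sample column")
  genes <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  count_matrix(vals, species = species)
}

#' Write a count matrix as TSV
#'
#' @param m A [count_matrix()] or numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), as_plain_matrix(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

clinical_categories <- list(
  sex_status = c("intact_male", "intact_female", "castrated_male", "spayed_female"),
  site = c("appendicular", "non_appendicular"),
  margin = c("complete", "incomplete")
)

clinical_required <- c("sample", "sex_status", "site", "grade", "margin",
                       "second_surgery",
                       "time_pfs", "event_pfs", "time_rfs", "event_rfs",
                       "time_ttm", "event_ttm", "time_os", "event_os",
                       "recurrence")

#' Validate a clinical covariate table
#'
#' Checks the closed category sets (sex status, tumor site, surgical margin),
#' grade in 1..3, nonnegative endpoint times (missing allowed only for times),
#' and boolean event flags.
#'
#' @param df A data.frame of per-sample clinical covariates.
#' @return The validated data.frame (invisibly the same content).
#' @export
validate_clinical <- function(df) {
  missing_cols <- setdiff(clinical_required, names(df))
  if (length(missing_cols))
    stop("missing required clinical columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("clinical table is empty")
  if (anyDuplicated(df$sample))
    stop("duplicate sample ids in clinical table")
  for (col in names(clinical_categories)) {
    bad <- setdiff(unique(stats::na.omit(df[[col]])), clinical_categories[[col]])
    if (length(bad))
      stop(sprintf("unknown %s value(s): %s", col, paste(bad, collapse = ", ")))
  }
  if (!all(stats::na.omit(df$grade) %in% 1:3))
    stop("grade must be 1, 2 or 3")
  for (col in c("time_pfs", "time_rfs", "time_ttm", "time_os")) {
    v <- df[[col]]
    if (any(v < 0, na.rm = TRUE))
      stop(sprintf("negative %s for sample %s", col, df$sample[which(v < 0)[1L]]))
  }
  for (col in c("event_pfs", "event_rfs", "event_ttm", "event_os",
                "second_surgery")) {
    v <- df[[col]]
    if (!all(v %in% c(TRUE, FALSE, 0L, 1L, 0, 1)))
      stop(sprintf("%s must be boolean (TRUE/FALSE or 0/1)", col))
    df[[col]] <- as.logical(v)
  }
  if (!all(df$recurrence %in% c(0, 1)))
    stop("recurrence must be coded 0/1")
  df
}

#' Read a clinical sample sheet from CSV
#'
#' @param path Path to a CSV with the required clinical columns.
#' @return Validated clinical data.frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("clinical file is empty: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("clinical file has no rows: ", path)
  validate_clinical(df)
}

#' Write a clinical table as CSV
#'
#' @param df Clinical data.frame.
#' @param path Output path.
#' @export
write_clinical <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
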