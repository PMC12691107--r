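#' IHC grade from five field counts
#'
#' Converts five positive-cell counts (distinct 50x fields) into a 0-3
#' infiltration grade of their mean m: grade 0 for m < 1 (no infiltration),
#' grade 1 for 1 <= m < 5, grade 2 for 5 <= m <= 10, grade 3 for m > 10.
#' The overlapping published ranges ("1-5", "5-10", "more than 10") are
#' resolved half-open at 5 and closed at 10, the only reading consistent
#' with grade 3 requiring strictly more than 10.
#'
#' @param field_counts Exactly five nonnegative integer counts.
#' @return Integer grade in 0:3.
#' @export
grade_from_fields <- function(field_counts) {
  if (length(field_counts) != 5L)
    stop("exactly 5 field counts required, got ", length(field_counts))
  if (any(field_counts < 0)) stop("field counts must be nonnegative")
  if (any(field_counts != round(field_counts)))
    stop("field counts must be integers")
  ihc_grade(mean(field_counts))
}

#' Grade from a mean positive-cell count
#'
#' Vectorized grading rule on the mean of the five fields; see
#' [grade_from_fields()].
#'
#' @param m Mean positive-cell count(s).
#' @return Integer grade(s) in 0:3.
#' @export
ihc_grade <- function(m) {
  ifelse(m > 10, 3L, ifelse(m >= 5, 2L, ifelse(m >= 1, 1L, 0L)))
}

#' Build an IHC record table
#'
#' @param df Data.frame with columns `sample`, `marker` (CD3, CD204, FOXP3)
#'   and `f1`..`f5` (the five field counts).
#' @return The input with `mean_count` and `grade` columns appended.
#' @export
ihc_grade_table <- function(df) {
  need <- c("sample", "marker", paste0("f", 1:5))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing IHC columns: ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(df$marker), c("CD3", "CD204", "FOXP3"))
  if (length(bad)) stop("unknown marker(s): ", paste(bad, collapse = ", "))
  fc <- as.matrix(df[, paste0("f", 1:5)])
  if (any(fc < 0)) stop("field counts must be nonnegative")
  df$mean_count <- rowMeans(fc)
  df$grade <- ihc_grade(df$mean_count)
  df
}

#' Marker-combination groups for survival comparisons
#'
#' Positivity for a marker is grade >= 1. Emits per-sample flags used by the
#' survival comparisons: CD204 alone, CD204+CD3 dual positivity, triple
#' positivity (CD204+CD3+FOXP3), any FOXP3, any CD3, plus a `group` label
#' (`cd204_cd3_foxp3` > `cd204_cd3` > `cd204_only` > `other`).
#'
#' @param records Graded IHC table from [ihc_grade_table()], at most one
#'   record per sample and marker.
#' @return Data.frame with one row per sample and logical flag columns.
#' @export
marker_groups <- function(records) {
  if (!"grade" %in% names(records)) records <- ihc_grade_table(records)
  key <- paste(records$sample, records$marker)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("conflicting duplicate IHC records for: ", paste(dup, collapse = "; "))
  }
  samples <- unique(records$sample)
  pos <- function(marker) {
    v <- stats::setNames(rep(FALSE, length(samples)), samples)
    sub <- records[records$marker == marker, ]
    v[as.character(sub$sample)] <- sub$grade >= 1L
    v
  }
  cd204 <- pos("CD204"); cd3 <- pos("CD3"); foxp3 <- pos("FOXP3")
  group <- ifelse(cd204 & cd3 & foxp3, "cd204_cd3_foxp3",
           ifelse(cd204 & cd3, "cd204_cd3",
           ifelse(cd204 & !cd3 & !foxp3, "cd204_only", "other")))
  data.frame(sample = samples,
             cd204_pos = unname(cd204), cd3_pos = unname(cd3),
             foxp3_pos = unname(foxp3),
             cd204_only = unname(cd204 & !cd3 & !foxp3),
             cd204_cd3 = unname(cd204 & cd3),
             cd204_cd3_foxp3 = unname(cd204 & cd3 & foxp3),
             foxp3_any = unname(foxp3), cd3_any = unname(cd3),
             group = unname(group),
             stringsAsFactors = FALSE)
}
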