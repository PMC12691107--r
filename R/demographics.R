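breed_counts <- c(
  "Labrador retriever" = 12, "Mixed breed dog" = 11, "Golden retriever" = 8,
  "Pitbull terrier" = 5, "Miniature schnauzer" = 3, "German shepherd" = 3,
  "Boxer" = 3, "Border collie" = 2, "Chihuahua" = 2, "Cocker spaniel" = 2,
  "Australian shepherd" = 1, "Daschund" = 1, "Rhodesian ridgeback" = 1,
  "Shiba inu" = 1, "Yorkshire terrier" = 1, "Italian greyhound" = 1,
  "Great dane" = 1, "Blue tick coonhound" = 1, "Beagle" = 1,
  "American eskimo" = 1, "Jack Russell terrier" = 1, "Whippet" = 1,
  "Rottweiler" = 1, "Pembroke Welsh Corgi" = 1, "Black mouthed cur" = 1,
  "Vizsla" = 1, "Boston terrier" = 1, "English bulldog" = 1,
  "Dalmatian" = 1, "Cane Corso" = 1, "Husky" = 1, "Beauceron" = 1,
  "Bernese mountain dog" = 1, "Schnauzer" = 1)

histotype_counts <- c(
  "fibrosarcoma" = 18, "peripheral_nerve_sheath_tumor" = 14,
  "perivascular_wall_tumor" = 10, "myxosarcoma" = 1, "liposarcoma" = 1,
  "undifferentiated_pleomorphic_sarcoma" = 2, "anaplastic_sarcoma" = 4)

fill_column <- function(n, counts, rest = NA_character_) {
  v <- rep(rest, n)
  v[seq_len(sum(counts))] <- rep(names(counts), counts)
  v
}

#' Synthetic 75-dog demographics fixture
#'
#' A packaged clinical table whose marginal counts reproduce the published
#' cohort composition of the 75-dog study population: sex/neuter status
#' (3 intact male, 1 intact female, 32 castrated male, 39 spayed female),
#' breed distribution (34 breeds, Labrador retriever 12 the most common),
#' tumor site (47 appendicular, 28 non-appendicular), grade (29/26/20 for
#' grades 1-3), first-surgery margins (23 incomplete, 52 complete),
#' pre-operative radiation (13), post-operative radiation (5), chemotherapy
#' agents, tumor histotype (classified in 50/75) and concurrent neoplasia
#' (24 dogs). The joint assignment across rows is a deterministic block
#' layout with per-column offsets (only the marginals are published);
#' endpoint times are left missing. This is a synthetic reconstruction, not
#' patient data.
#'
#' @return Validated clinical data.frame with 75 rows, plus fixture-only
#'   columns (`breed`, `preop_rt`, `postop_rt`, `chemo`, `histotype`,
#'   `concurrent_neoplasia`).
#' @export
make_demographics_fixture <- function() {
  n <- 75L
  df <- data.frame(
    sample = sprintf("DOG%03d", seq_len(n)),
    sex_status = fill_column(n, c(intact_male = 3, intact_female = 1,
                                  castrated_male = 32, spayed_female = 39)),
    breed = fill_column(n, breed_counts),
    stringsAsFactors = FALSE)
  # offset each later column so categories cross rather than nest
  shift <- function(v, k) v[((seq_along(v) - 1L + k) %% length(v)) + 1L]
  df$site <- shift(fill_column(n, c(appendicular = 47, non_appendicular = 28)), 7L)
  df$grade <- as.integer(shift(fill_column(n, c("1" = 29, "2" = 26, "3" = 20)), 13L))
  df$margin <- shift(fill_column(n, c(incomplete = 23, complete = 52)), 23L)
  df$second_surgery <- shift(fill_column(n, c("TRUE" = 10, "FALSE" = 65)), 31L) == "TRUE"
  df$preop_rt <- shift(fill_column(n, c("TRUE" = 13, "FALSE" = 62)), 41L) == "TRUE"
  df$postop_rt <- shift(fill_column(n, c("TRUE" = 5, "FALSE" = 70)), 47L) == "TRUE"
  df$chemo <- shift(fill_column(n, c(
    doxorubicin = 3, doxorubicin_ifosphamide = 1, carboplatin = 5,
    intralesional_5fu = 1, chlorambucil = 3, ifosphamide = 1, palladia = 2,
    none = 59)), 53L)
  df$histotype <- shift(fill_column(n, histotype_counts, rest = "unclassified"), 17L)
  df$concurrent_neoplasia <- shift(
    fill_column(n, c("TRUE" = 24, "FALSE" = 51)), 61L) == "TRUE"
  for (col in c("time_pfs", "time_rfs", "time_ttm", "time_os"))
    df[[col]] <- NA_real_
  for (col in c("event_pfs", "event_rfs", "event_ttm", "event_os"))
    df[[col]] <- FALSE
  df$recurrence <- 0L
  validate_clinical(df)
}

#' Marginal counts and percentages of a clinical table
#'
#' @param df Clinical data.frame (e.g. [make_demographics_fixture()]).
#' @param columns Which categorical columns to tabulate.
#' @return Data.frame with `variable`, `level`, `count`, `percent`
#'   (of all rows, 2 decimals).
#' @export
demographics_summary <- function(df,
                                 columns = c("sex_status", "site", "grade",
                                             "margin")) {
  n <- nrow(df)
  out <- do.call(rbind, lapply(columns, function(col) {
    tb <- table(df[[col]])
    data.frame(variable = col, level = names(tb),
               count = as.integer(tb),
               percent = round(100 * as.integer(tb) / n, 2),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
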