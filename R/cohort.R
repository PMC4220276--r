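# CohortTable: one row per study participant.
#
# Column convention (all optional beyond sample_id + risk_group):
#   <criterion>_time / <criterion>_event        AIDS progression endpoints
#   <sequela>_time / <sequela>_event / <sequela>_first
#   haart_<endpoint>_time / haart_<endpoint>_event
#   sp_first_visit_baseline                     TRUE for SP rows whose
#                                               baseline is the first visit
# Times are years from baseline (seroconversion for SC, first visit for SP).

#' Read a clinical cohort table
#'
#' @param path CSV file. Must contain `sample_id` and `risk_group`
#'   (values among `r toString(RISK_GROUPS)`); endpoint, sequela and HAART
#'   columns follow the package column convention (see Details).
#' @details Endpoint columns come in `_time`/`_event` pairs per AIDS
#'   criterion (`CD4`, `AIDS87`, `AIDS93`, `DEATH`); sequelae add a
#'   `_first` flag marking the condition that occurred first; HAART
#'   outcomes use `haart_suppression_*` / `haart_rebound_*`. Missing cells
#'   exclude the sample from the affected tests only, never globally.
#' @return A data.frame of class `CohortTable`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cohort_table(df)
}

#' Validate a data.frame as a CohortTable
#'
#' @param df data.frame following the cohort column convention.
#' @return `df` with class `CohortTable` prepended.
#' @export
as_cohort_table <- function(df) {
  if (!all(c("sample_id", "risk_group") %in% names(df)))
    stop("cohort table needs sample_id and risk_group columns")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in cohort table")
  bad <- !df$risk_group %in% RISK_GROUPS
  if (any(bad))
    stop("unknown risk_group label(s): ",
         paste(unique(df$risk_group[bad]), collapse = ", "),
         " (row ", which(bad)[1], ")")

  time_cols <- grep("_time$", names(df), value = TRUE)
  for (tc in time_cols) {
    tv <- df[[tc]]
    neg <- which(!is.na(tv) & tv < 0)
    if (length(neg))
      stop(sprintf("negative time in column %s, row %d", tc, neg[1]))
    ec <- sub("_time$", "_event", tc)
    if (ec %in% names(df)) {
      orphan <- which(!is.na(df[[ec]]) & df[[ec]] != 0 & is.na(tv))
      if (length(orphan))
        stop(sprintf("event without time in column %s, row %d", ec, orphan[1]))
    }
  }

  first_cols <- grep("_first$", names(df), value = TRUE)
  first_cols <- first_cols[sub("_first$", "", first_cols) %in% SEQUELAE]
  if (length(first_cols) > 1) {
    nfirst <- rowSums(sapply(df[first_cols], function(x)
      !is.na(x) & x != 0))
    if (any(nfirst > 1))
      stop("row ", which(nfirst > 1)[1],
           ": more than one sequela flagged as first")
  }
  class(df) <- c("CohortTable", class(df))
  df
}

#' Patient-category predicates for cohort summaries
#'
#' The categories of the standard cohort summary are *memberships*, not a
#' partition: a seroconverter on antiretroviral treatment with an AIDS
#' sequela counts in three rows. `SP_LTS` means seroprevalent with no
#' AIDS-defining event within `lts_years` of baseline and follow-up
#' reaching that horizon.
#'
#' @param lts_years long-term-survivor horizon in years (default 10).
#' @return named list of predicate functions `CohortTable -> logical`.
#' @export
cohort_categories <- function(lts_years = 10) {
  seq_event <- function(df) {
    cols <- paste0(SEQUELAE, "_event")
    cols <- cols[cols %in% names(df)]
    if (!length(cols)) return(rep(FALSE, nrow(df)))
    rowSums(sapply(df[cols], function(x) !is.na(x) & x != 0)) > 0
  }
  haart_treated <- function(df) {
    cols <- grep("^haart_.*_time$", names(df), value = TRUE)
    if (!length(cols)) return(rep(FALSE, nrow(df)))
    rowSums(!is.na(df[cols])) > 0
  }
  is_lts <- function(df) {
    aids_cols <- intersect(paste0(c("AIDS87", "AIDS93"), "_time"), names(df))
    if (!length(aids_cols)) return(rep(FALSE, nrow(df)))
    early_aids <- rep(FALSE, nrow(df))
    horizon <- rep(FALSE, nrow(df))
    for (tc in aids_cols) {
      ec <- sub("_time$", "_event", tc)
      ev <- if (ec %in% names(df)) !is.na(df[[ec]]) & df[[ec]] != 0 else FALSE
      early_aids <- early_aids | (ev & !is.na(df[[tc]]) & df[[tc]] <= lts_years)
      horizon <- horizon | (!is.na(df[[tc]]) & df[[tc]] > lts_years)
    }
    horizon & !early_aids
  }
  list(
    HREU = function(df) df$risk_group == "HREU",
    EU = function(df) df$risk_group == "OSN",
    SC = function(df) df$risk_group == "SC",
    SP_LTS = function(df) df$risk_group == "SP" & is_lts(df),
    Sequelae = seq_event,
    HAART = haart_treated
  )
}

#' Cross-tabulate cohort sizes by patient category and study group
#'
#' Builds the "categories x groups" patient count table for one or more
#' cohorts: per-category membership counts per group, a combined column
#' summing groups declared disjoint, and a `Total` row of study
#' participants per group (categories overlap, so the total is the number
#' of rows, not the column sum).
#'
#' @param tables named list of `CohortTable` objects (names are group
#'   labels).
#' @param combine character vector of group names whose samples are
#'   disjoint; a `combined` column sums their counts row-wise and the
#'   combined total is the sum of those groups' participant totals.
#'   Overlapping sample_ids among these groups is an error.
#' @param categories named list of predicate functions as produced by
#'   [cohort_categories()].
#' @return data.frame: one row per category plus a `Total` row; one column
#'   per group plus `combined` when requested.
#' @export
summarize_cohorts <- function(tables, combine = NULL,
                              categories = cohort_categories()) {
  stopifnot(is.list(tables))
  if (!length(tables))
    return(data.frame(category = character(0)))
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be a named list")
  counts <- sapply(tables, function(t)
    vapply(categories, function(f) sum(f(t)), integer(1)))
  counts <- matrix(counts, nrow = length(categories),
                   dimnames = list(names(categories), names(tables)))
  totals <- vapply(tables, nrow, integer(1))
  out <- data.frame(category = names(categories), counts,
                    check.names = FALSE, row.names = NULL)
  total_row <- c(list(category = "Total"), as.list(totals))
  if (!is.null(combine)) {
    stopifnot(all(combine %in% names(tables)))
    ids <- unlist(lapply(tables[combine], function(t) t$sample_id))
    if (anyDuplicated(ids))
      stop("groups declared disjoint share sample(s): ",
           paste(head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
    out$combined <- rowSums(counts[, combine, drop = FALSE])
    total_row$combined <- sum(totals[combine])
  }
  rbind(out, as.data.frame(total_row, check.names = FALSE))
}
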