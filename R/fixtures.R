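# In-study fixtures: printed subgroup counts of the two characteristics
# tables, the study flow, and a per-subject reconstruction usable by the
# split and exclusion logic.

#' Printed study fixtures: subgroup tables and study-flow counts
#'
#' Returns the printed subgroup sizes and categorical row counts of the
#' training-set (Group 1) and validation-set (Group 2) characteristics
#' tables, the study-flow counts (337 women sampled, 1 excluded for asthma
#' without other atopic diseases, 336 analyzed: 211 training + 125
#' validation), and a per-subject reconstruction carrying group, category,
#' atopy flags and a sampling date consistent with the date-based split
#' (Group 1 sampled before 2018-03-01, Group 2 from then on).
#'
#' @return A list:
#' \describe{
#'   \item{group1, group2}{list with `n` (named subgroup sizes; the NA class
#'     is the union NA-AD + NA-NAD) and `rows` (data.frame: variable,
#'     category, count, n, percent_printed, printed_consistent).}
#'   \item{flow}{named list: sampled, excluded, analyzed, group1_n, group2_n,
#'     cutoff (the split date).}
#'   \item{subjects}{data.frame of 337 subjects: sample_id, subject_id,
#'     sample_type, pair_key, group, asthma, other_atopic, category,
#'     sampling_date.}
#' }
#' @export
study_fixtures <- function() {
  read_tab <- function(f) {
    # "NA" is the non-asthmatic subgroup label, not a missing value
    utils::read.delim(system.file("extdata", f, package = "breathdiscrim"),
                      sep = ",", stringsAsFactors = FALSE, na.strings = "")
  }
  g1 <- list(n = c("A-AD" = 25L, "NA" = 186L, "NA-AD" = 72L, "NA-NAD" = 114L),
             rows = read_tab("table1_counts.csv"))
  g2 <- list(n = c("A-AD" = 14L, "NA" = 111L, "NA-AD" = 47L, "NA-NAD" = 64L),
             rows = read_tab("table2_counts.csv"))
  flow <- list(sampled = 337L, excluded = 1L, analyzed = 336L,
               group1_n = 211L, group2_n = 125L, cutoff = as.Date("2018-03-01"))

  counts <- rbind(
    data.frame(group = 1L, category = "A-AD", k = 25L),
    data.frame(group = 1L, category = "NA-AD", k = 72L),
    data.frame(group = 1L, category = "NA-NAD", k = 114L),
    data.frame(group = 2L, category = "A-AD", k = 14L),
    data.frame(group = 2L, category = "NA-AD", k = 47L),
    data.frame(group = 2L, category = "NA-NAD", k = 64L),
    data.frame(group = 2L, category = "A-NAD", k = 1L) # the excluded subject
  )
  category <- rep(counts$category, counts$k)
  group <- rep(counts$group, counts$k)
  n <- length(category)
  # sampling dates: Group 1 cycles May 2017..Feb 2018, Group 2 Mar..Oct 2018
  g1_months <- seq(as.Date("2017-05-15"), as.Date("2018-02-15"), by = "month")
  g2_months <- seq(as.Date("2018-03-15"), as.Date("2018-10-15"), by = "month")
  dates <- rep(as.Date("1970-01-01"), n)
  dates[group == 1L] <- rep_len(g1_months, sum(group == 1L))
  dates[group == 2L] <- rep_len(g2_months, sum(group == 2L))
  subjects <- data.frame(
    sample_id = sprintf("B%03d", seq_len(n)),
    subject_id = sprintf("S%03d", seq_len(n)),
    sample_type = "breath",
    pair_key = sprintf("P%03d", seq_len(n)),
    group = group,
    asthma = as.integer(category %in% c("A-AD", "A-NAD")),
    other_atopic = as.integer(category %in% c("A-AD", "NA-AD")),
    category = ifelse(category == "A-NAD", NA_character_, category),
    sampling_date = as.character(dates),
    stringsAsFactors = FALSE
  )
  list(group1 = g1, group2 = g2, flow = flow, subjects = subjects)
}

#' Apply the study exclusion rule to a subject table
#'
#' Subjects with asthma but no other atopic disease fall outside the four
#' study categories and are excluded from analysis.
#'
#' @param subjects a data.frame with 0/1 columns `asthma` and `other_atopic`
#'   (e.g. `study_fixtures()$subjects`).
#' @return list with `sampled`, `excluded`, `analyzed` counts and the
#'   filtered `subjects` data.frame.
#' @export
apply_exclusion_rule <- function(subjects) {
  stopifnot(all(c("asthma", "other_atopic") %in% colnames(subjects)))
  excl <- subjects$asthma == 1L & subjects$other_atopic == 0L
  list(sampled = nrow(subjects), excluded = sum(excl),
       analyzed = sum(!excl), subjects = subjects[!excl, , drop = FALSE])
}
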