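# Cohort construction, eligibility filtering and descriptive statistics.

#' Read discharge records from CSV
#'
#' Expected columns: `patient_id, sex, age, year, insurance, admission_route,
#' outcome, los, bed_size, principal_dx, additional_dx`. `additional_dx` is a
#' semicolon-delimited list of ICD-10 codes and may be empty.
#'
#' @param path Path to the CSV file.
#' @return A data frame with `additional_dx` as a list column of character
#'   vectors.
#' @export
read_discharge_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  req <- c("patient_id", "sex", "age", "year", "principal_dx", "additional_dx")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("discharge CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  df$additional_dx <- split_dx(df$additional_dx)
  df
}

split_dx <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(v) trimws(v[nzchar(trimws(v))]))
}

#' Build the analysis cohort
#'
#' Applies the study eligibility rules: discharge year 2006-2016, age at
#' least 19 years, and a principal diagnosis in one of the seven mental and
#' behavioural disorder subgroups (see [principal_subgroup()]). Any
#' additional-diagnosis entry identical to the principal diagnosis is removed
#' so comorbidities never duplicate the principal code.
#'
#' @param records Data frame of discharge records (as from
#'   [read_discharge_csv()]; `additional_dx` may be a list column or
#'   semicolon-delimited strings).
#' @param table Block table defining the comorbidity item universe.
#' @return An object of class `cohort`: a list with `records` (with an added
#'   `subgroup` column), `block_table`, and `filter_report` (records removed
#'   per rule).
#' @export
build_cohort <- function(records, table = default_block_table()) {
  stopifnot(is.data.frame(records), inherits(table, "block_table"))
  if (!is.list(records$additional_dx)) {
    records$additional_dx <- split_dx(records$additional_dx)
  }
  n0 <- nrow(records)
  if (n0 == 0L) stop("no discharge records supplied")

  ok_age <- !is.na(records$age) & records$age >= 19
  report <- c(age_under_19 = sum(!ok_age))
  records <- records[ok_age, , drop = FALSE]

  ok_year <- !is.na(records$year) & records$year >= 2006 & records$year <= 2016
  report["year_out_of_range"] <- sum(!ok_year)
  records <- records[ok_year, , drop = FALSE]

  sub <- principal_subgroup(records$principal_dx)
  report["principal_excluded"] <- sum(sub == "EXCLUDED")
  records <- records[sub != "EXCLUDED", , drop = FALSE]
  records$subgroup <- sub[sub != "EXCLUDED"]

  # drop the principal code from the comorbidity list (same normalised form)
  principal_norm <- parse_icd_code(records$principal_dx)$code
  records$additional_dx <- Map(function(dx, p) {
    if (length(dx) == 0L) return(character(0))
    dx[parse_icd_code(dx)$code != p]
  }, records$additional_dx, principal_norm)

  rownames(records) <- NULL
  structure(list(records = records, block_table = table,
                 filter_report = report),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Discharge cohort:", nrow(x$records), "records,",
      sum(lengths(x$records$additional_dx) > 0L), "with comorbidity\n")
  cat("Blocks in universe:", nrow(x$block_table), "\n")
  invisible(x)
}

#' Comorbidity indicator per record
#'
#' @param x A `cohort` or a records data frame with an `additional_dx` list
#'   column.
#' @return Logical vector: `TRUE` where at least one additional diagnosis is
#'   recorded.
#' @export
has_comorbidity <- function(x) {
  records <- if (inherits(x, "cohort")) x$records else x
  lengths(records$additional_dx) > 0L
}

#' Comorbidity prevalence by principal-diagnosis subgroup
#'
#' One row per non-empty subgroup plus an `ALL` row summing the seven.
#' `percent_with` is the within-stratum prevalence 100 * n_with / n_total;
#' `percent_of_total` is the stratum share of the cohort. Percentages are
#' rounded half away from zero to 2 decimals.
#'
#' @param cohort A `cohort`.
#' @return Data frame with columns `subgroup, n_with, n_without, n_total,
#'   percent_with, percent_of_total`.
#' @export
prevalence_by_subgroup <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  rec <- cohort$records
  if (nrow(rec) == 0L) stop("empty cohort")
  com <- has_comorbidity(cohort)
  sub <- factor(rec$subgroup, levels = SUBGROUP_LEVELS)
  n_with <- as.integer(tapply(com, sub, sum, default = 0L))
  n_tot <- as.integer(table(sub))
  out <- data.frame(subgroup = SUBGROUP_LEVELS, n_with = n_with,
                    n_without = n_tot - n_with, n_total = n_tot,
                    stringsAsFactors = FALSE)
  out <- out[out$n_total > 0L, , drop = FALSE]
  all_row <- data.frame(subgroup = "ALL", n_with = sum(out$n_with),
                        n_without = sum(out$n_without),
                        n_total = sum(out$n_total))
  out <- rbind(out, all_row)
  out$percent_with <- round_half_up(100 * out$n_with / out$n_total, 2)
  out$percent_of_total <-
    round_half_up(100 * out$n_total / all_row$n_total, 2)
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction, as used for the
#' comorbidity distribution comparisons; df = (r-1)(c-1), p from the upper
#' tail.
#'
#' @param tab Matrix of observed counts, at least 2x2, all non-negative.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2x2 table")
  if (any(is.na(tab)) || any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal row or column")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom,
#' computed from group means, standard deviations and sizes (raw data are not
#' needed). The statistic is (mean1 - mean2) / SE with group 1 = the
#' with-comorbidity group in the descriptive tables.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return List with `t`, `df`, `p_value` (two-sided).
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in each group")
  if (!(sd1 > 0) || !(sd2 > 0)) stop("standard deviations must be positive")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Frequent comorbidity blocks
#'
#' Counts, for each block of the universe, the number of patients with at
#' least one additional diagnosis in that block. A patient contributes at
#' most 1 to a block however many of their codes fall in it. The denominator
#' is the full cohort size, including comorbidity-free patients.
#'
#' @param cohort A `cohort`.
#' @param min_percent Keep blocks with `percent >= min_percent` (default 1,
#'   the reporting threshold of the frequency table).
#' @return Data frame `block, label, count, percent` sorted by descending
#'   count (ties by block id); `percent` rounded to 2 decimals. The number of
#'   additional-diagnosis codes that mapped to no block is attached as
#'   attribute `n_unmapped`.
#' @export
frequent_blocks <- function(cohort, min_percent = 1) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.na(min_percent) || min_percent < 0 || min_percent > 100) {
    stop("min_percent must be in [0, 100]")
  }
  ts <- encode_transactions(cohort, "ALL")
  counts <- integer(length(ts$universe))
  for (tr in ts$transactions) counts[tr] <- counts[tr] + 1L
  out <- data.frame(block = ts$universe, count = counts,
                    stringsAsFactors = FALSE)
  out$label <- cohort$block_table$label[
    match(out$block, cohort$block_table$block_id)]
  out$percent <- round_half_up(100 * out$count / ts$n, 2)
  out <- out[out$percent >= min_percent, , drop = FALSE]
  out <- out[order(-out$count, out$block, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out[, c("block", "label", "count", "percent")],
            n_unmapped = attr(ts, "n_unmapped"))
}

#' Demographic summary by comorbidity status
#'
#' Cross-tabulates each available categorical demographic variable against
#' the comorbidity indicator, with row percentages and a Pearson chi-square
#' per variable (no continuity correction).
#'
#' @param cohort A `cohort`.
#' @return Data frame with columns `variable, level, n_with, n_without,
#'   percent_with, statistic, p_value` (test repeated on every row of its
#'   variable).
#' @export
demographics_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  rec <- cohort$records
  com <- has_comorbidity(cohort)
  vars <- intersect(c("sex", "insurance", "admission_route", "outcome",
                      "bed_size"), names(rec))
  rows <- lapply(vars, function(v) {
    tab <- table(rec[[v]], factor(com, levels = c(TRUE, FALSE)))
    ct <- if (nrow(tab) >= 2L && all(rowSums(tab) > 0))
      chi_square(unclass(tab)) else list(statistic = NA_real_,
                                         p_value = NA_real_)
    data.frame(variable = v, level = rownames(tab),
               n_with = as.integer(tab[, 1L]),
               n_without = as.integer(tab[, 2L]),
               percent_with = round_half_up(
                 100 * tab[, 1L] / rowSums(tab), 2),
               statistic = ct$statistic, p_value = ct$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean number of comorbidities per patient
#'
#' Counts distinct additional-diagnosis codes per patient (diagnosis level,
#' before block deduplication), over all patients or only those with at
#' least one comorbidity.
#'
#' @param cohort A `cohort`.
#' @param comorbid_only If `TRUE`, average over patients with >= 1
#'   comorbidity.
#' @return A single number.
#' @export
mean_comorbidity_count <- function(cohort, comorbid_only = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  k <- vapply(cohort$records$additional_dx,
              function(dx) length(unique(parse_icd_code_safe(dx))),
              integer(1))
  if (comorbid_only) k <- k[k > 0L]
  mean(k)
}

# normalised codes, empty in -> empty out
parse_icd_code_safe <- function(dx) {
  if (length(dx) == 0L) return(character(0))
  parse_icd_code(dx)$code
}
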