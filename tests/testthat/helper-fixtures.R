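# Fixtures are built in code; no data files.

# transaction set over single-letter items from a character shorthand,
# e.g. toy_ts("AB", "AB", "AC", "B", "") with universe LETTERS[1:3]
toy_ts <- function(..., universe = NULL, n = NULL) {
  trans <- lapply(list(...), function(s) {
    if (!nzchar(s)) character(0) else strsplit(s, "")[[1]]
  })
  if (is.null(universe)) {
    universe <- sort(unique(unlist(trans)))
  }
  if (is.null(n)) n <- length(trans)
  transaction_set(trans, universe, n = n)
}

# random transaction set: <= 12 items, some empty transactions
random_ts <- function(n_items = sample(2:12, 1), n_trans = sample(5:30, 1),
                      density = stats::runif(1, 0.1, 0.6)) {
  universe <- LETTERS[seq_len(n_items)]
  trans <- lapply(seq_len(n_trans), function(i) {
    universe[stats::runif(n_items) < density]
  })
  transaction_set(trans, universe, n = n_trans)
}

# discharge records with sensible defaults; additional as ";"-joined string
make_records <- function(principal, additional = "", age = 30, year = 2010,
                         sex = "female") {
  k <- length(principal)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(k)),
    sex = rep_len(sex, k), age = rep_len(age, k), year = rep_len(year, k),
    insurance = "national_health", admission_route = "outpatient",
    outcome = "improved", los = 7L, bed_size = "500-999",
    principal_dx = principal, additional_dx = rep_len(additional, k),
    stringsAsFactors = FALSE
  )
}

# cohort whose comorbidity structure is given per record as ";"-joined codes
make_cohort <- function(principal, additional = "", ...) {
  build_cohort(make_records(principal, additional, ...))
}

# reconstruct a cohort matching printed stratum counts: for each subgroup,
# n_with patients carry `code`, n_without carry nothing
counts_cohort <- function(n_with, n_without, code = "I10") {
  stopifnot(length(n_with) == 7L, length(n_without) == 7L)
  principal_codes <- c("F00", "F10", "F20", "F30", "F40", "F50", "F60")
  principal <- rep(rep(principal_codes, 2L), c(n_with, n_without))
  additional <- rep(rep(c(code, ""), each = 7L), c(n_with, n_without))
  make_cohort(principal, additional)
}

# direct Pearson chi-square sum, the hand oracle
pearson_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# frequent itemsets as a canonical count map "A,B" -> count, for comparing
# two mining routes independent of row order
freq_map <- function(freq) {
  stats::setNames(freq$count,
                  vapply(freq$items, paste, character(1), collapse = ","))
}
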