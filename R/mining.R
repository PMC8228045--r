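# Transaction encoding, Apriori frequent-itemset mining, rule induction,
# interestingness measures, and the filter-and-rank procedure.

#' Mining parameters
#'
#' Thresholds of the rule selection procedure. Rules are kept when
#' `support >= min_support`, `confidence >= min_confidence` and
#' `lift > min_lift` (the lift filter is strict). `max_itemset_size` bounds
#' the frequent itemsets mined, so antecedents have at most
#' `max_itemset_size - 1` items (consequents are always single items).
#'
#' @param min_support Minimum rule support, default 0.01. With 200+ candidate
#'   blocks an unconstrained support floor is computationally
#'   indiscriminate; every reported rule sits at or above 0.010.
#' @param min_confidence Minimum confidence, default 0.1.
#' @param min_lift Strict lower bound on lift, default 1.
#' @param max_itemset_size Largest itemset mined, default 3.
#' @return A list of class `mining_params`.
#' @export
mining_params <- function(min_support = 0.01, min_confidence = 0.1,
                          min_lift = 1, max_itemset_size = 3L) {
  if (is.na(min_support) || min_support < 0 || min_support > 1) {
    stop("min_support must be in [0, 1]")
  }
  if (is.na(min_confidence) || min_confidence < 0 || min_confidence > 1) {
    stop("min_confidence must be in [0, 1]")
  }
  if (is.na(min_lift) || min_lift < 0) stop("min_lift must be >= 0")
  max_itemset_size <- as.integer(max_itemset_size)
  if (is.na(max_itemset_size) || max_itemset_size < 2L) {
    stop("max_itemset_size must be at least 2")
  }
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 min_lift = min_lift, max_itemset_size = max_itemset_size),
            class = "mining_params")
}

#' Construct a transaction set
#'
#' @param transactions List of character vectors of item (block) identifiers;
#'   duplicates within a transaction are collapsed. Empty transactions are
#'   allowed and count in `n`.
#' @param universe Ordered character vector of all item identifiers.
#' @param n Number of patients represented; defaults to
#'   `length(transactions)` and must be at least the number of transactions
#'   supplied (patients without comorbidity may be given as empty vectors or
#'   folded into `n`).
#' @return An object of class `transaction_set` with elements `n`, `universe`
#'   and `transactions` (sorted integer indices into `universe`).
#' @export
transaction_set <- function(transactions, universe,
                            n = length(transactions)) {
  stopifnot(is.list(transactions), is.character(universe))
  if (anyDuplicated(universe)) stop("universe has duplicate items")
  if (n < length(transactions)) {
    stop("n must be >= number of transactions")
  }
  idx <- lapply(transactions, function(items) {
    if (length(items) == 0L) return(integer(0))
    i <- match(unique(items), universe)
    if (anyNA(i)) {
      stop("transaction item(s) outside universe: ",
           paste(unique(items)[is.na(i)], collapse = ", "))
    }
    sort(i)
  })
  structure(list(n = as.integer(n), universe = universe, transactions = idx),
            class = "transaction_set")
}

#' Encode a subgroup's comorbidities as transactions
#'
#' Selects the patients whose principal diagnosis falls in `subgroup`
#' (`"ALL"` = the union of the seven subgroups) and converts each patient's
#' additional diagnoses into the set of distinct blocks they occupy. Patients
#' without comorbidity contribute empty transactions and still count in `n`,
#' the support denominator. Codes mapping to no block are dropped from the
#' transactions; their number is attached as attribute `n_unmapped`.
#'
#' @param cohort A `cohort`.
#' @param subgroup One of `"F00-F03"`, ..., `"F60-F69"`, or `"ALL"`.
#' @return A `transaction_set` over the cohort's block universe.
#' @export
encode_transactions <- function(cohort, subgroup = "ALL") {
  stopifnot(inherits(cohort, "cohort"))
  if (!subgroup %in% c(SUBGROUP_LEVELS, "ALL")) {
    stop("unknown subgroup '", subgroup, "'; valid: ",
         paste(c(SUBGROUP_LEVELS, "ALL"), collapse = ", "))
  }
  rec <- cohort$records
  if (subgroup != "ALL") rec <- rec[rec$subgroup == subgroup, , drop = FALSE]
  if (nrow(rec) == 0L) stop("empty stratum: ", subgroup)

  n_unmapped <- 0L
  trans <- lapply(rec$additional_dx, function(dx) {
    if (length(dx) == 0L) return(character(0))
    b <- assign_block(dx, cohort$block_table)
    n_unmapped <<- n_unmapped + sum(is.na(b))
    unique(b[!is.na(b)])
  })
  ts <- transaction_set(trans, cohort$block_table$block_id, n = nrow(rec))
  attr(ts, "n_unmapped") <- n_unmapped
  attr(ts, "subgroup") <- subgroup
  ts
}

#' @export
print.transaction_set <- function(x, ...) {
  cat("Transaction set: n =", x$n, "patients,",
      sum(lengths(x$transactions) > 0L), "non-empty,",
      length(x$universe), "items in universe\n")
  invisible(x)
}

#' Rule interestingness measures
#'
#' Elementary measures of an association rule A -> B over a stratum of `n`
#' patients: `support` is the fraction of patients carrying all items of
#' A and B together; `confidence` the fraction of antecedent carriers that
#' also carry B; `lift` the joint support over the product of the marginal
#' supports (1 under independence); `is_scale` the interest-support measure
#' sqrt(support x lift), equivalently the cosine P(AB)/sqrt(P(A)P(B)), used
#' as the ranking key. All are computed at full precision; rounding happens
#' only at output.
#'
#' @param joint_count Patients carrying antecedent and consequent together.
#' @param n Stratum size (including comorbidity-free patients).
#' @param antecedent_count Patients carrying all antecedent items.
#' @param support_joint,support_A,support_B Supports as fractions.
#' @param support,lift Inputs of the IS scale.
#' @return A single numeric value (vectorised over inputs).
#' @name rule_measures
NULL

#' @rdname rule_measures
#' @export
support <- function(joint_count, n) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(joint_count < 0 | joint_count > n)) {
    stop("joint_count must be in [0, n]")
  }
  joint_count / n
}

#' @rdname rule_measures
#' @export
confidence <- function(joint_count, antecedent_count) {
  if (any(antecedent_count <= 0)) stop("antecedent_count must be positive")
  if (any(joint_count < 0 | joint_count > antecedent_count)) {
    stop("joint_count must be in [0, antecedent_count]")
  }
  joint_count / antecedent_count
}

#' @rdname rule_measures
#' @export
lift <- function(support_joint, support_A, support_B) {
  if (any(support_A <= 0) || any(support_B <= 0)) {
    stop("marginal supports must be positive")
  }
  support_joint / (support_A * support_B)
}

#' @rdname rule_measures
#' @export
is_scale <- function(support, lift) {
  if (any(support < 0) || any(lift < 0)) {
    stop("support and lift must be non-negative")
  }
  sqrt(support * lift)
}

# ---- frequent itemset mining -------------------------------------------

# canonical itemset key from sorted item index vector
itemset_key <- function(idx) paste(idx, collapse = " ")

# 0/1 incidence matrix (n x n_items) restricted to items that occur
incidence_matrix <- function(ts) {
  n_items <- length(ts$universe)
  m <- matrix(FALSE, nrow = ts$n, ncol = n_items)
  for (i in seq_along(ts$transactions)) {
    m[i, ts$transactions[[i]]] <- TRUE
  }
  m
}

freq_result <- function(item_idx, counts, ts) {
  items <- lapply(item_idx, function(i) ts$universe[i])
  data.frame(
    key = vapply(item_idx, itemset_key, character(1)),
    items = I(items),
    size = lengths(item_idx),
    count = as.integer(counts),
    support = counts / ts$n,
    stringsAsFactors = FALSE
  )
}

#' Apriori frequent-itemset mining
#'
#' Level-wise search for all itemsets of at most `max_size` items whose
#' support (`count / n`, with `n` the full stratum size) reaches
#' `min_support`. Size-k candidates are generated by prefix join of the
#' frequent (k-1)-itemsets and pruned when any (k-1)-subset is infrequent
#' (downward closure); counts are exact. Itemsets that occur in no
#' transaction are never reported, even at `min_support = 0`.
#'
#' @param ts A `transaction_set`.
#' @param min_support Minimum support fraction.
#' @param max_size Largest itemset size to mine.
#' @return Data frame with columns `key` (internal index key), `items` (list
#'   column of item ids), `size`, `count`, `support`, ordered by size then
#'   key.
#' @seealso [brute_force_frequent()] for the exhaustive reference
#'   implementation used in tests.
#' @export
apriori <- function(ts, min_support = 0.01, max_size = 3L) {
  stopifnot(inherits(ts, "transaction_set"))
  if (is.na(min_support) || min_support < 0) {
    stop("min_support must be >= 0")
  }
  max_size <- as.integer(max_size)
  m <- incidence_matrix(ts)
  counts1 <- colSums(m)
  keep1 <- which(counts1 >= 1L & counts1 / ts$n >= min_support)
  levels <- list()
  if (length(keep1) > 0L && max_size >= 1L) {
    levels[[1L]] <- list(sets = matrix(keep1, ncol = 1L),
                         counts = counts1[keep1])
  }
  k <- 2L
  while (k <= max_size && length(levels) == k - 1L &&
         nrow(levels[[k - 1L]]$sets) > 1L) {
    prev <- levels[[k - 1L]]$sets
    prev_keys <- apply(prev, 1L, itemset_key)
    cand <- candidate_join(prev, prev_keys)
    if (nrow(cand) == 0L) break
    counts <- count_itemsets(m, cand)
    keep <- which(counts >= 1L & counts / ts$n >= min_support)
    if (length(keep) == 0L) break
    levels[[k]] <- list(sets = cand[keep, , drop = FALSE],
                        counts = counts[keep])
    k <- k + 1L
  }
  if (length(levels) == 0L) {
    return(freq_result(list(), integer(0), ts))
  }
  parts <- lapply(levels, function(lv) {
    idx <- lapply(seq_len(nrow(lv$sets)), function(i) lv$sets[i, ])
    freq_result(idx, lv$counts, ts)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$size, out$key, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# prefix join of frequent (k-1)-sets (rows sorted item vectors) with
# subset pruning against the previous level
candidate_join <- function(prev, prev_keys) {
  k1 <- ncol(prev)
  ord <- do.call(order, c(lapply(seq_len(k1), function(j) prev[, j]),
                          list(method = "radix")))
  prev <- prev[ord, , drop = FALSE]
  out <- vector("list", 64L)
  n_out <- 0L
  prefix <- if (k1 > 1L) {
    apply(prev[, -k1, drop = FALSE], 1L, paste, collapse = " ")
  } else {
    rep("", nrow(prev))
  }
  groups <- split(seq_len(nrow(prev)), prefix)
  key_env <- new.env(parent = emptyenv(), size = length(prev_keys))
  for (key in prev_keys) assign(key, TRUE, envir = key_env)
  for (g in groups) {
    if (length(g) < 2L) next
    for (a in seq_len(length(g) - 1L)) {
      for (b in (a + 1L):length(g)) {
        cand <- c(prev[g[a], ], prev[g[b], k1])
        # prune: every (k-1)-subset must be frequent
        ok <- TRUE
        for (drop_i in seq_len(k1 + 1L)) {
          if (!exists(itemset_key(cand[-drop_i]), envir = key_env,
                      inherits = FALSE)) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          n_out <- n_out + 1L
          if (n_out > length(out)) out <- c(out, vector("list", length(out)))
          out[[n_out]] <- cand
        }
      }
    }
  }
  if (n_out == 0L) return(matrix(integer(0), ncol = k1 + 1L))
  do.call(rbind, out[seq_len(n_out)])
}

count_itemsets <- function(m, sets) {
  k <- ncol(sets)
  vapply(seq_len(nrow(sets)), function(i) {
    sum(rowSums(m[, sets[i, ], drop = FALSE]) == k)
  }, numeric(1))
}

#' Exhaustive frequent-itemset enumeration (test oracle)
#'
#' Counts every non-empty subset of the item universe directly, with no
#' candidate pruning. Only feasible for small universes; serves as the
#' independent reference against which [apriori()] is checked.
#'
#' @param ts A `transaction_set` whose universe has at most 20 items.
#' @param min_support Minimum support fraction.
#' @param max_size Largest subset size to enumerate (default: no bound below
#'   the universe size).
#' @return Data frame in the same layout and order as [apriori()].
#' @export
brute_force_frequent <- function(ts, min_support = 0,
                                 max_size = length(ts$universe)) {
  stopifnot(inherits(ts, "transaction_set"))
  n_items <- length(ts$universe)
  if (n_items > 20L) stop("universe too large for exhaustive enumeration")
  m <- incidence_matrix(ts)
  idx_list <- list()
  counts <- numeric(0)
  for (size in seq_len(min(max_size, n_items))) {
    sets <- utils::combn(n_items, size)
    for (j in seq_len(ncol(sets))) {
      s <- sets[, j]
      cnt <- sum(rowSums(m[, s, drop = FALSE]) == size)
      if (cnt >= 1L && cnt / ts$n >= min_support) {
        idx_list[[length(idx_list) + 1L]] <- s
        counts <- c(counts, cnt)
      }
    }
  }
  out <- freq_result(idx_list, counts, ts)
  out <- out[order(out$size, out$key, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- rule induction -----------------------------------------------------

#' Induce association rules from frequent itemsets
#'
#' For every frequent itemset of two or more items and every choice of a
#' single-item consequent, emits the rule antecedent -> consequent when it
#' passes the selection thresholds: `support >= min_support`,
#' `confidence >= min_confidence`, `lift > min_lift` (strict). The frequent
#' list must be closed downward (guaranteed by [apriori()]); a missing subset
#' count is an error.
#'
#' @param frequent Output of [apriori()].
#' @param ts The `transaction_set` the itemsets were mined from.
#' @param params A [mining_params()] object.
#' @return Data frame with columns `antecedent` (items joined by `","`),
#'   `consequent`, `joint_count`, `support`, `confidence`, `lift`,
#'   `is_scale`, all metrics at full precision.
#' @export
generate_rules <- function(frequent, ts, params = mining_params()) {
  stopifnot(inherits(ts, "transaction_set"),
            inherits(params, "mining_params"))
  count_of <- stats::setNames(frequent$count, frequent$key)
  lookup <- function(idx) {
    cnt <- count_of[itemset_key(idx)]
    if (is.na(cnt)) {
      stop("frequent set not closed downward: missing count for {",
           paste(ts$universe[idx], collapse = ", "), "}")
    }
    cnt
  }
  rows <- list()
  multi <- which(frequent$size >= 2L)
  for (i in multi) {
    idx <- match(frequent$items[[i]], ts$universe)
    joint <- frequent$count[i]
    for (j in seq_along(idx)) {
      cons <- idx[j]
      ante <- idx[-j]
      n_ante <- lookup(ante)
      n_cons <- lookup(cons)
      s <- support(joint, ts$n)
      cf <- confidence(joint, n_ante)
      lf <- lift(s, support(n_ante, ts$n), support(n_cons, ts$n))
      if (s >= params$min_support && cf >= params$min_confidence &&
          lf > params$min_lift) {
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = paste(ts$universe[ante], collapse = ","),
          consequent = ts$universe[cons],
          joint_count = as.integer(joint),
          support = s, confidence = cf, lift = lf,
          is_scale = is_scale(s, lf),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(antecedent = character(0), consequent = character(0),
                      joint_count = integer(0), support = numeric(0),
                      confidence = numeric(0), lift = numeric(0),
                      is_scale = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Rank rules by the IS scale
#'
#' Descending by `is_scale`, ties broken by descending `support`, then by
#' the rule label `"antecedent -> consequent"` in C-locale lexicographic
#' order. The sort is stable and deterministic.
#'
#' @param rules Data frame from [generate_rules()].
#' @return The same frame, reordered, with row names reset.
#' @export
rank_rules <- function(rules) {
  if (nrow(rules) == 0L) return(rules)
  label <- paste(rules$antecedent, "->", rules$consequent)
  out <- rules[order(-rules$is_scale, -rules$support, label,
                     method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine ranked association rules for one subgroup
#'
#' The full per-stratum pipeline: encode the subgroup's comorbidity
#' transactions, mine frequent itemsets with [apriori()], induce rules
#' passing the thresholds, and rank by IS scale.
#'
#' @param cohort A `cohort`.
#' @param subgroup Subgroup label or `"ALL"`.
#' @param params A [mining_params()] object.
#' @return Ranked rule data frame with a leading `stratum` column.
#' @examples
#' \donttest{
#' cfg <- synthetic_config(n = 2000, seed = 1,
#'   planted = list(planted_association("E10-E14", "I10-I15", 4)))
#' coh <- build_cohort(generate_cohort(cfg))
#' head(mine_subgroup(coh, "ALL"))
#' }
#' @export
mine_subgroup <- function(cohort, subgroup = "ALL",
                          params = mining_params()) {
  ts <- encode_transactions(cohort, subgroup)
  freq <- apriori(ts, min_support = params$min_support,
                  max_size = params$max_itemset_size)
  rules <- rank_rules(generate_rules(freq, ts, params))
  if (nrow(rules) > 0L) {
    rules <- cbind(stratum = subgroup, rules, stringsAsFactors = FALSE)
  } else {
    rules <- cbind(stratum = character(0), rules)
  }
  rules
}

#' Write a rule table to CSV
#'
#' Output dialect of the rule tables: metrics rounded half away from zero to
#' 3 decimals (ranking and filtering always use full precision), block
#' ranges with ASCII hyphens, antecedent items joined by `","`.
#'
#' @param rules Ranked rule frame from [mine_subgroup()].
#' @param path Output path; written atomically.
#' @export
write_rules <- function(rules, path) {
  out <- rules
  names(out)[names(out) == "joint_count"] <- "n_patients"
  for (col in c("support", "confidence", "lift", "is_scale")) {
    out[[col]] <- round_half_up(out[[col]], 3)
  }
  write_atomic(function(p) {
    utils::write.csv(out, p, row.names = FALSE, quote = TRUE)
  }, path)
  invisible(path)
}
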