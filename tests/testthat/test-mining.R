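test_that("encoding keeps the principal out but same-family comorbidities in", {
  coh <- make_cohort(c("F03", "F20"), c("F00", "I10;I13"))
  ts <- encode_transactions(coh, "F00-F03")
  expect_equal(ts$n, 1L)
  expect_equal(ts$universe[ts$transactions[[1]]], "F00-F03")
  ts2 <- encode_transactions(coh, "F20-F29")
  expect_equal(ts2$universe[ts2$transactions[[1]]], "I10-I15")  # deduplicated
})

test_that("comorbidity-free patients count in n with empty transactions", {
  coh <- make_cohort(c("F20", "F20", "F20"), c("I10", "", ""))
  ts <- encode_transactions(coh, "ALL")
  expect_equal(ts$n, 3L)
  expect_equal(lengths(ts$transactions), c(1L, 0L, 0L))
  expect_error(encode_transactions(coh, "F00-F03"), "F00-F03")
  expect_error(encode_transactions(coh, "bogus"), "valid")
})

test_that("measures follow their defining ratios", {
  expect_equal(comorbidrules:::round_half_up(support(152, 1361), 3), 0.112)
  expect_equal(support(0, 1000), 0)
  expect_equal(comorbidrules:::round_half_up(support(74, 4539), 3), 0.016)
  expect_error(support(1, 0), "positive")
  expect_equal(confidence(152, 266), 152 / 266)
  expect_equal(confidence(7, 7), 1)
  expect_error(confidence(1, 0), "positive")
  expect_error(confidence(5, 3), "joint_count")
  expect_equal(lift(0.112, 0.1753, 0.3204), 0.112 / (0.1753 * 0.3204))
  expect_equal(lift(0.2, 0.2, 0.2), 1 / 0.2)  # perfect overlap: 1/s
  expect_error(lift(0.1, 0, 0.5), "positive")
  expect_equal(is_scale(1, 1), 1)
  expect_equal(is_scale(0.25, 4), 1)
})

test_that("apriori on the five-transaction toy matches hand counts", {
  ts <- toy_ts("AB", "AB", "AC", "B", "")
  freq <- apriori(ts, min_support = 0.4, max_size = 3)
  expect_equal(freq_map(freq), c(A = 3, B = 3, "A,B" = 2))
  # brute-force route agrees
  expect_equal(freq_map(brute_force_frequent(ts, 0.4)), freq_map(freq))
  expect_equal(nrow(apriori(ts, min_support = 1.5)), 0L)
})

test_that("apriori equals exhaustive enumeration on random instances", {
  set.seed(20)
  for (i in 1:50) {
    ts <- random_ts()
    ms <- sample(c(0, 0.05, 0.1, 0.25, 0.5), 1)
    a <- apriori(ts, min_support = ms, max_size = length(ts$universe))
    b <- brute_force_frequent(ts, min_support = ms)
    expect_equal(freq_map(a), freq_map(b))
  }
  # max_size bound respected against the bounded oracle
  ts <- random_ts(n_items = 8, n_trans = 25)
  a2 <- apriori(ts, min_support = 0.1, max_size = 2)
  b2 <- brute_force_frequent(ts, min_support = 0.1, max_size = 2)
  expect_equal(freq_map(a2), freq_map(b2))
  expect_true(all(a2$size <= 2))
})

test_that("empty transactions alone yield no frequent itemsets", {
  ts <- toy_ts("", "", "", universe = c("A", "B"))
  expect_equal(nrow(apriori(ts, min_support = 0)), 0L)
  expect_equal(nrow(brute_force_frequent(ts, 0)), 0L)
})

test_that("frequent itemsets are closed downward with monotone counts", {
  set.seed(21)
  ts <- random_ts(n_items = 10, n_trans = 30, density = 0.5)
  freq <- apriori(ts, min_support = 0.1, max_size = 4)
  cmap <- freq_map(freq)
  for (i in which(freq$size >= 2)) {
    items <- freq$items[[i]]
    for (j in seq_along(items)) {
      sub_key <- paste(items[-j], collapse = ",")
      expect_true(sub_key %in% names(cmap))
      expect_gte(cmap[[sub_key]], freq$count[i])
    }
  }
})

test_that("brute force refuses universes above 20 items", {
  ts <- transaction_set(list(LETTERS[1:3]), LETTERS[1:21])
  expect_error(brute_force_frequent(ts, 0.1), "too large")
})

test_that("rules pass exactly the stated thresholds", {
  ts <- toy_ts("AB", "AB", "AC", "B", "")
  freq <- apriori(ts, min_support = 0.2, max_size = 2)
  rules <- generate_rules(freq, ts, mining_params(
    min_support = 0.2, min_confidence = 0.5, min_lift = 1))
  ab <- rules[rules$antecedent == "A" & rules$consequent == "B", ]
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$support, 0.4)
  expect_equal(ab$confidence, 2 / 3)
  expect_equal(ab$lift, 0.4 / (0.6 * 0.6), tolerance = 1e-12)
  # B -> A fails min_confidence 0.5? conf = 2/3 of B's 3 -> 2/3 passes;
  # A -> C (conf 1/3) does not appear
  expect_false(any(rules$consequent == "C"))
})

test_that("lift exactly at the threshold is rejected (strict filter)", {
  # A and B exactly independent: sAB = 0.25 = sA * sB
  ts <- toy_ts("AB", "A", "B", "")
  freq <- apriori(ts, min_support = 0.1, max_size = 2)
  rules <- generate_rules(freq, ts, mining_params(
    min_support = 0.1, min_confidence = 0, min_lift = 1))
  expect_equal(nrow(rules), 0L)
  # loosening the lift floor re-admits them
  rules2 <- generate_rules(freq, ts, mining_params(
    min_support = 0.1, min_confidence = 0, min_lift = 0.99))
  expect_equal(nrow(rules2), 2L)
})

test_that("a frequent list with a missing subset is rejected", {
  ts <- toy_ts("AB", "AB", "AC", "B", "")
  freq <- apriori(ts, min_support = 0.2, max_size = 2)
  broken <- freq[freq$size != 1 | !vapply(freq$items, identical, TRUE, "A"), ]
  expect_error(generate_rules(broken, ts, mining_params(0, 0, 0)),
               "closed downward")
})

test_that("ranking is by IS, then support, then label, and is stable", {
  rules <- data.frame(
    antecedent = c("B", "A", "C", "A"),
    consequent = c("X", "X", "X", "Y"),
    joint_count = c(4L, 4L, 3L, 9L),
    support = c(0.2, 0.2, 0.1, 0.5),
    confidence = c(0.5, 0.5, 0.4, 0.9),
    lift = c(2, 2, 8, 1.62),
    is_scale = c(sqrt(0.4), sqrt(0.4), sqrt(0.8), sqrt(0.81)),
    stringsAsFactors = FALSE)
  ranked <- rank_rules(rules)
  expect_equal(paste(ranked$antecedent, ranked$consequent),
               c("A Y", "C X", "A X", "B X"))  # ties A/B broken by label
  expect_equal(rank_rules(ranked), ranked)
})

test_that("bidirectional pairs share lift and IS in mined output", {
  cfg <- synthetic_config(n = 4000, seed = 9, planted = list(
    planted_association("E10-E14", "I10-I15", 3),
    planted_association("K20-K31", "K70-K77", 2.5)))
  rules <- mine_subgroup(build_cohort(generate_cohort(cfg)), "ALL",
                         mining_params(0.005, 0.05, 1))
  expect_gt(nrow(rules), 0L)
  one_one <- rules[!grepl(",", rules$antecedent), ]
  key <- ifelse(one_one$antecedent < one_one$consequent,
                paste(one_one$antecedent, one_one$consequent),
                paste(one_one$consequent, one_one$antecedent))
  for (k in unique(key[duplicated(key)])) {
    pair <- one_one[key == k, ]
    expect_equal(pair$lift[1], pair$lift[2], tolerance = 1e-12)
    expect_equal(pair$is_scale[1], pair$is_scale[2], tolerance = 1e-12)
    expect_equal(pair$support[1], pair$support[2])
  }
  # metric identities over every mined rule
  expect_equal(rules$is_scale^2, rules$support * rules$lift,
               tolerance = 1e-12)
  expect_true(all(rules$confidence >= rules$support - 1e-12))
})

test_that("mine_subgroup output is deterministic and carries the stratum", {
  cfg <- synthetic_config(n = 2000, seed = 5, planted = list(
    planted_association("E10-E14", "I10-I15", 4)))
  coh <- build_cohort(generate_cohort(cfg))
  r1 <- mine_subgroup(coh, "F30-F39")
  r2 <- mine_subgroup(coh, "F30-F39")
  expect_identical(r1, r2)
  if (nrow(r1) > 0) expect_true(all(r1$stratum == "F30-F39"))
})

test_that("rule CSV output rounds to 3 decimals half away from zero", {
  rules <- data.frame(stratum = "ALL", antecedent = "A", consequent = "B",
                      joint_count = 5L, support = 0.0125,
                      confidence = 0.6665, lift = 1.9945,
                      is_scale = 0.4715, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  write_rules(rules, path)
  back <- read.csv(path)
  expect_equal(names(back),
               c("stratum", "antecedent", "consequent", "n_patients",
                 "support", "confidence", "lift", "is_scale"))
  expect_equal(back$support, 0.013)   # 0.0125 rounds up, not to even
  expect_equal(back$confidence, 0.667)
  expect_equal(back$lift, 1.995)
  expect_equal(back$is_scale, 0.472)
})
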