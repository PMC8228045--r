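# Synthetic discharge-record generator: reproduces the statistical structure
# the analysis assumes (subgroup mix, per-block marginal prevalences,
# planted pairwise block dependencies with a target lift) with closed-form
# expected metrics for recovery testing.

#' Default subgroup mixture
#'
#' Proportions of the seven principal-diagnosis subgroups in the study
#' cohort (shares of 20,690 discharges).
#'
#' @return Named numeric vector summing to 1.
#' @export
default_subgroup_mix <- function() {
  c("F00-F03" = 0.0658, "F10-F19" = 0.1671, "F20-F29" = 0.2194,
    "F30-F39" = 0.3175, "F40-F48" = 0.2034, "F50-F59" = 0.0147,
    "F60-F69" = 0.0121)
}

#' Default comorbidity-block marginal prevalences
#'
#' The 35 blocks reaching at least 1% frequency in the study cohort, as
#' fractions of all patients. Blocks absent from this vector have marginal 0
#' in the generator.
#'
#' @return Named numeric vector of per-block probabilities.
#' @export
default_block_marginals <- function() {
  c("I10-I15" = 0.1106, "F30-F39" = 0.0834, "E10-E14" = 0.0798,
    "K20-K31" = 0.0704, "F40-F48" = 0.0668, "F00-F03" = 0.0658,
    "K70-K77" = 0.0531, "G40-G47" = 0.0385, "F10-F19" = 0.0320,
    "E70-E90" = 0.0285, "F20-F29" = 0.0278, "K55-K64" = 0.0267,
    "I60-I69" = 0.0261, "F60-F69" = 0.0253, "M40-M54" = 0.0251,
    "Z80-Z99" = 0.0243, "L20-L30" = 0.0204, "R50-R69" = 0.0192,
    "M60-M79" = 0.0173, "M00-M25" = 0.0166, "N30-N39" = 0.0164,
    "F50-F59" = 0.0159, "E00-E07" = 0.0153, "J00-J06" = 0.0152,
    "I30-I52" = 0.0131, "B35-B49" = 0.0128, "K00-K14" = 0.0127,
    "G20-G26" = 0.0127, "J40-J47" = 0.0123, "M80-M94" = 0.0115,
    "I20-I25" = 0.0114, "L80-L99" = 0.0110, "N40-N51" = 0.0106,
    "J09-J18" = 0.0102, "J30-J39" = 0.0101)
}

# feasibility of the 2x2 law with P11 = L * pA * pB
check_feasible <- function(pA, pB, L) {
  if (any(c(pA, pB) < 0) || any(c(pA, pB) > 1) || L < 0) {
    stop("need pA, pB in [0,1] and L >= 0")
  }
  p11 <- L * pA * pB
  if (p11 > min(pA, pB) + 1e-12) {
    stop(sprintf(
      "infeasible planted lift: L*pA*pB = %.6g exceeds min(pA, pB) = %.6g",
      p11, min(pA, pB)))
  }
  if (1 - pA - pB + p11 < -1e-12) {
    stop(sprintf(
      "infeasible planted lift: 1 - pA - pB + L*pA*pB = %.6g is negative",
      1 - pA - pB + p11))
  }
  c(p11 = p11, p10 = pA - p11, p01 = pB - p11,
    p00 = max(0, 1 - pA - pB + p11))
}

#' Correlated Bernoulli pair with a target lift
#'
#' Draws `n` pairs (a, b) of 0/1 indicators from the 2x2 law with marginals
#' `pA`, `pB` and joint probability `P(a = b = 1) = L * pA * pB`, so that the
#' population lift of the pair is exactly `L`. `L = 1` gives independent
#' draws; `L * pA * pB = min(pA, pB)` nests the rarer event inside the other.
#'
#' @param pA,pB Marginal prevalences.
#' @param L Target lift; the configuration must be feasible (joint
#'   probability at most `min(pA, pB)` and all four cell probabilities
#'   non-negative), otherwise an error names the violated bound.
#' @param n Number of draws.
#' @return List with integer vectors `a` and `b` of length `n`. Uses the
#'   current RNG state.
#' @export
joint_bernoulli <- function(pA, pB, L, n = 1L) {
  p <- check_feasible(pA, pB, L)
  cell <- sample.int(4L, n, replace = TRUE, prob = p)
  list(a = as.integer(cell %in% c(1L, 2L)),
       b = as.integer(cell %in% c(1L, 3L)))
}

#' Closed-form rule metrics of a planted pair
#'
#' The population values the mining pipeline should recover for a pair
#' planted at marginals `pA`, `pB` with lift `L`: support `L*pA*pB`,
#' confidence of A -> B `L*pB`, lift `L`, IS scale `L*sqrt(pA*pB)`.
#'
#' @inheritParams joint_bernoulli
#' @return List with `support`, `confidence_a_to_b`, `lift`, `is_scale`.
#' @export
expected_metrics <- function(pA, pB, L) {
  check_feasible(pA, pB, L)
  list(support = L * pA * pB, confidence_a_to_b = L * pB, lift = L,
       is_scale = L * sqrt(pA * pB))
}

#' Delta-method standard error of the sample lift
#'
#' First-order standard error of the empirical lift of a planted pair,
#' derived from the multinomial law of the four cell counts at sample size
#' `n`. Used to calibrate recovery tests (observed lift within `3 * SE` of
#' the planted value).
#'
#' @inheritParams joint_bernoulli
#' @param n Sample size.
#' @return Standard error of the lift estimate (numeric scalar).
#' @export
lift_se <- function(pA, pB, L, n) {
  p <- check_feasible(pA, pB, L)
  g <- c(1 / p[["p11"]] - 1 / pA - 1 / pB, -1 / pA, -1 / pB, 0)
  var_log <- (sum(p * g^2) - sum(p * g)^2) / n
  L * sqrt(var_log)
}

#' Rescale marginals to a target mean comorbidity count
#'
#' Under the generator's law the expected number of comorbidity blocks per
#' patient is the sum of the marginals. This multiplies all marginals by a
#' common factor so that sum equals `target_mean` (default 1.42, the
#' study's mean diagnosis count per patient), and asserts the achieved mean
#' is within 5% of the target.
#'
#' @param marginals Named numeric vector of block prevalences.
#' @param target_mean Desired expected comorbidity count per patient.
#' @return Rescaled marginals with attribute `scale_factor`.
#' @export
scale_marginals <- function(marginals, target_mean = 1.42) {
  if (target_mean <= 0) stop("target_mean must be positive")
  f <- target_mean / sum(marginals)
  out <- marginals * f
  if (any(out > 1)) {
    stop("target_mean pushes a marginal above 1; cannot rescale")
  }
  achieved <- sum(out)
  stopifnot(abs(achieved - target_mean) / target_mean <= 0.05)
  structure(out, scale_factor = f)
}

#' Planted pairwise association
#'
#' @param block_a,block_b Distinct block identifiers.
#' @param target_lift Population lift to plant between the two blocks.
#' @return A list of class `planted_association`.
#' @export
planted_association <- function(block_a, block_b, target_lift) {
  if (block_a == block_b) stop("planted pair must use distinct blocks")
  if (target_lift < 0) stop("target_lift must be >= 0")
  structure(list(block_a = block_a, block_b = block_b,
                 target_lift = target_lift),
            class = "planted_association")
}

default_demographics <- function() {
  list(
    sex = c(male = 0.4275, female = 0.5725),
    age_group = c("19-44" = 0.4465, "45-64" = 0.3421,
                  "65-74" = 0.1174, "75-94" = 0.0940),
    insurance = c(national_health = 0.7965, medicaid1 = 0.1484,
                  medicaid2 = 0.0242, other = 0.0309),
    admission_route = c(emergency = 0.3281, outpatient = 0.6713,
                        other = 0.0006),
    outcome = c(improved = 0.9059, not_improved = 0.0858,
                death = 0.0054, other = 0.0029),
    bed_size = c("100-299" = 0.2319, "300-499" = 0.1284,
                 "500-999" = 0.4865, ">=1000" = 0.1532),
    # heavy-tailed stay lengths, mean about 36 days
    los_meanlog = 2.7, los_sdlog = 1.3
  )
}

#' Synthetic cohort configuration
#'
#' Bundles everything the generator needs: cohort size, subgroup mixture,
#' per-block marginal prevalences, planted pairwise dependencies (their
#' block pairs must be disjoint so each marginal is controlled by exactly
#' one mechanism), demographic distributions, and a mandatory seed.
#'
#' @param n Number of discharge records.
#' @param seed Integer seed; generation is fully reproducible given the
#'   seed.
#' @param subgroup_mix Named probabilities over the seven subgroups, summing
#'   to 1.
#' @param marginals Named block prevalences; see
#'   [default_block_marginals()].
#' @param planted List of [planted_association()] objects.
#' @param demographics Demographic distributions (defaults reproduce the
#'   study's marginal frequencies).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n, seed,
                             subgroup_mix = default_subgroup_mix(),
                             marginals = default_block_marginals(),
                             planted = list(),
                             demographics = default_demographics()) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (missing(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop("an integer seed is required")
  }
  if (abs(sum(subgroup_mix) - 1) > 1e-6) {
    stop("subgroup_mix must sum to 1")
  }
  if (!all(names(subgroup_mix) %in% SUBGROUP_LEVELS)) {
    stop("subgroup_mix names must be the seven subgroup labels")
  }
  if (any(marginals < 0 | marginals > 1)) {
    stop("marginals must be probabilities in [0, 1]")
  }
  pair_blocks <- character(0)
  for (pl in planted) {
    stopifnot(inherits(pl, "planted_association"))
    blocks <- c(pl$block_a, pl$block_b)
    if (any(blocks %in% pair_blocks)) {
      stop("planted pairs must use disjoint block pairs")
    }
    pair_blocks <- c(pair_blocks, blocks)
    pA <- marginals[pl$block_a]
    pB <- marginals[pl$block_b]
    if (is.na(pA) || is.na(pB)) {
      stop("planted blocks must have marginals: ",
           paste(blocks[is.na(c(pA, pB))], collapse = ", "))
    }
    check_feasible(unname(pA), unname(pB), pl$target_lift)
  }
  structure(list(n = n, seed = as.integer(seed),
                 subgroup_mix = subgroup_mix, marginals = marginals,
                 planted = planted, demographics = demographics),
            class = "synthetic_config")
}

# run expr under a private RNG stream seeded with `seed`; global state
# is restored afterwards
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic discharge cohort
#'
#' Draws `n` discharge records under the configured law: the subgroup (and a
#' representative principal diagnosis code, the subgroup's first category),
#' demographics, and the comorbidity blocks — planted pairs through the
#' correlated 2x2 law of [joint_bernoulli()], all remaining blocks as
#' independent Bernoulli draws at their marginal. Present blocks are emitted
#' as the block's start code (bumped by one category in the rare case it
#' would collide with the principal diagnosis). All records pass the
#' eligibility filter of [build_cohort()] by construction.
#'
#' @param config A [synthetic_config()].
#' @return Data frame of discharge records with `additional_dx` as a list
#'   column, ready for [build_cohort()] or [write_cohort_csv()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  dem <- config$demographics
  n <- config$n
  tab <- default_block_table()
  with_rng(config$seed, {
    subgroup <- sample(names(config$subgroup_mix), n, replace = TRUE,
                       prob = config$subgroup_mix)
    principal <- substr(subgroup, 1L, 3L)

    sexv <- sample(names(dem$sex), n, TRUE, dem$sex)
    agegrp <- sample(names(dem$age_group), n, TRUE, dem$age_group)
    bounds <- matrix(as.integer(unlist(strsplit(agegrp, "-"))),
                     ncol = 2L, byrow = TRUE)
    age <- bounds[, 1L] +
      floor(stats::runif(n) * (bounds[, 2L] - bounds[, 1L] + 1L))
    year <- sample(2006:2016, n, replace = TRUE)
    insurance <- sample(names(dem$insurance), n, TRUE, dem$insurance)
    route <- sample(names(dem$admission_route), n, TRUE,
                    dem$admission_route)
    outcome <- sample(names(dem$outcome), n, TRUE, dem$outcome)
    bed <- sample(names(dem$bed_size), n, TRUE, dem$bed_size)
    los <- pmax(1L, as.integer(round(
      stats::rlnorm(n, dem$los_meanlog, dem$los_sdlog))))

    planted_blocks <- unlist(lapply(config$planted,
                                    function(p) c(p$block_a, p$block_b)))
    present <- matrix(FALSE, nrow = n, ncol = length(config$marginals),
                      dimnames = list(NULL, names(config$marginals)))
    for (pl in config$planted) {
      draw <- joint_bernoulli(unname(config$marginals[pl$block_a]),
                              unname(config$marginals[pl$block_b]),
                              pl$target_lift, n)
      present[, pl$block_a] <- draw$a == 1L
      present[, pl$block_b] <- draw$b == 1L
    }
    indep <- setdiff(names(config$marginals), planted_blocks)
    for (b in indep) {
      present[, b] <- stats::runif(n) < config$marginals[b]
    }

    start_code <- tab$start[match(colnames(present), tab$block_id)]
    if (anyNA(start_code)) {
      stop("marginal block(s) not in default block table: ",
           paste(colnames(present)[is.na(start_code)], collapse = ", "))
    }
    additional <- lapply(seq_len(n), function(i) {
      codes <- start_code[present[i, ]]
      clash <- codes == principal[i]
      if (any(clash)) {
        # next category in the block; subgroup starts are never at a
        # single-category block so the bump stays inside the range
        codes[clash] <- paste0(substr(codes[clash], 1L, 1L),
                               sprintf("%02d",
                                       as.integer(substr(codes[clash],
                                                         2L, 3L)) + 1L))
      }
      codes
    })

    data.frame(
      patient_id = sprintf("S%06d", seq_len(n)),
      sex = sexv, age = as.integer(age), year = year,
      insurance = insurance, admission_route = route, outcome = outcome,
      los = los, bed_size = bed, principal_dx = principal,
      additional_dx = I(additional),
      stringsAsFactors = FALSE
    )
  })
}

#' Write a cohort CSV with a YAML sidecar
#'
#' Serialises records in the input dialect of [read_discharge_csv()]
#' (`additional_dx` joined by semicolons) and, when a config is given,
#' writes `<path>.yaml` recording the generator settings and seed. Both
#' files are written atomically.
#'
#' @param records Records data frame (list-column `additional_dx`).
#' @param path Output CSV path.
#' @param config Optional `synthetic_config` to record in the sidecar.
#' @export
write_cohort_csv <- function(records, path, config = NULL) {
  out <- records
  out$additional_dx <- vapply(out$additional_dx, paste, character(1),
                              collapse = ";")
  write_atomic(function(p) {
    utils::write.csv(out, p, row.names = FALSE, quote = TRUE)
  }, path)
  if (!is.null(config)) {
    side <- list(
      n = config$n, seed = config$seed,
      subgroup_mix = as.list(config$subgroup_mix),
      marginals = as.list(config$marginals),
      planted = lapply(config$planted, function(p) {
        list(block_a = p$block_a, block_b = p$block_b,
             target_lift = p$target_lift)
      })
    )
    write_atomic(function(p) yaml::write_yaml(side, p),
                 paste0(path, ".yaml"))
  }
  invisible(path)
}
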