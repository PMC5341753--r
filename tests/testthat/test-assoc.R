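test_that("crude odds ratio matches the closed form", {
  r <- crude_or(35, 1055, 66, 4059)
  expect_equal(r$or, 35 * 4059 / (1055 * 66), tolerance = 1e-12)
  expect_equal(r$or, 2.0403, tolerance = 1e-4)
  expect_equal(r$ci_low, 1.347, tolerance = 1e-3)
  expect_equal(r$ci_high, 3.091, tolerance = 1e-3)
  expect_equal(crude_or(1, 1, 1, 1)$or, 1)
  expect_error(crude_or(0, 10, 0, 20), "no association computable")
  z <- crude_or(0, 10, 5, 20)
  expect_equal(z$or, 0)
  expect_true(is.na(z$ci_low))
})

test_that("Fisher probabilities agree with stats::fisher.test and enumeration", {
  set.seed(14)
  for (i in 1:40) {
    a <- rpois(1, 6); b <- rpois(1, 40); c <- rpois(1, 4); d <- rpois(1, 60)
    ft <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
    expect_equal(fisher_exact(a, b, c, d, "two_sided"), ft$p.value,
                 tolerance = 1e-10)
    # exhaustive enumeration over all tables with the observed margins
    m <- a + c; n <- b + d; k <- a + b
    xs <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(xs, m, n, k)
    obs <- stats::dhyper(a, m, n, k)
    expect_equal(fisher_exact(a, b, c, d, "point"), obs, tolerance = 1e-12)
    expect_equal(fisher_exact(a, b, c, d, "one_sided"),
                 sum(probs[xs >= a]), tolerance = 1e-12)
    expect_equal(fisher_exact(a, b, c, d, "two_sided"),
                 sum(probs[probs <= obs * (1 + 1e-7)]), tolerance = 1e-12)
  }
  expect_equal(fisher_exact(0, 10, 0, 20), 1)
})

test_that("published family-history tables reproduce under the point convention", {
  expect_equal(round(fisher_exact(13, 733, 1, 340, "point"), 3), 0.032)
  expect_equal(round(fisher_exact(9, 737, 2, 339, "point"), 3), 0.183)
})

test_that("logistic regression without covariates equals the crude odds ratio", {
  set.seed(8)
  for (i in 1:100) {
    a <- sample(3:40, 1); b <- sample(50:500, 1)
    c <- sample(3:40, 1); d <- sample(50:500, 1)
    coh <- cohort_from_2x2(a, b, c, d)
    fit <- logistic_dominant(coh, "v", covariates = character(0))
    oracle <- crude_or(a, b, c, d)
    expect_equal(fit$or, oracle$or, tolerance = 1e-6)
    # Wald CI and p agree to 4 significant figures (the dispersion matrix
    # uses the final IRLS working weights)
    expect_equal(fit$ci_low, oracle$ci_low, tolerance = 1e-4)
    expect_equal(fit$p, oracle$p, tolerance = 1e-4)
  }
})

test_that("logistic regression refuses separated tables", {
  coh <- cohort_from_2x2(10, 100, 0, 110)
  expect_error(logistic_dominant(coh, "v"), "fisher_exact")
})

test_that("age adjustment is nearly null when age is independent of genotype", {
  spec <- simulation_spec(cohorts = list(S = c(cases = 3500, controls = 3500)))
  pv <- planted_variant("v1", "G", "1", 1, cohort_or = 2,
                        control_carrier_freq = 0.05)
  coh <- generate_cohort(spec, list(pv), seed = 123)
  adj <- logistic_dominant(coh, "v1", covariates = "age")
  crude <- logistic_dominant(coh, "v1", covariates = character(0))
  expect_lt(abs(log(adj$or) - log(crude$or)), 0.02)
})

test_that("polytomous regression equals stratum-wise crude ORs without covariates", {
  coh <- rbind(cohort_from_2x2(20, 300, 30, 700),
               cohort_from_2x2(15, 100, 0, 0))
  coh$subject_id <- sprintf("s%05d", seq_len(nrow(coh)))
  coh$aggressiveness[coh$status == "case"] <-
    rep(c("non-aggressive", "aggressive"), c(320, 115))
  fit <- polytomous_logistic(coh, "v", covariates = character(0))
  non <- fit[fit$stratum == "non-aggressive", ]
  agg <- fit[fit$stratum == "aggressive", ]
  expect_equal(non$or, crude_or(20, 300, 30, 700)$or, tolerance = 1e-4)
  expect_equal(agg$or, crude_or(15, 100, 30, 700)$or, tolerance = 1e-4)
  # published aggressive-stratum counts reproduce the crude closed form
  coh2 <- rbind(cohort_from_2x2(35, 1055, 66, 4059))
  coh2$aggressiveness[coh2$status == "case"] <- "aggressive"
  coh2 <- rbind(coh2, {
    extra <- cohort_from_2x2(10, 90, 0, 0)
    extra$aggressiveness[extra$status == "case"] <- "non-aggressive"
    extra
  })
  coh2$subject_id <- sprintf("t%05d", seq_len(nrow(coh2)))
  fit2 <- polytomous_logistic(coh2, "v", covariates = character(0))
  expect_equal(fit2$or[fit2$stratum == "aggressive"], 2.0403, tolerance = 1e-3)
  expect_error(polytomous_logistic(cohort_from_2x2(5, 5, 5, 5), "v"), "stratum")
})

test_that("fixed-effect pooling matches the closed form and edge identities", {
  # closed-form inverse-variance oracle
  pool <- function(or, lo, hi) {
    y <- log(or); se <- (log(hi) - log(lo)) / (2 * 1.959964)
    w <- 1 / se^2
    exp(sum(w * y) / sum(w))
  }
  m <- meta_fixed(c(5.68, 3.78), c(1.67, 1.94), c(19.36, 8.28))
  expect_equal(m$or, pool(c(5.68, 3.78), c(1.67, 1.94), c(19.36, 8.28)),
               tolerance = 1e-9)
  # single study with a log-symmetric CI: identity
  one <- meta_fixed(2.5, 1.25, 5.0)
  expect_equal(one$or, 2.5, tolerance = 1e-9)
  expect_equal(one$ci_low, 1.25, tolerance = 1e-6)
  expect_equal(one$ci_high, 5.0, tolerance = 1e-6)
  # identical studies: same OR, CI narrower by sqrt(2) on the log scale
  two <- meta_fixed(c(2, 2), c(1.5, 1.5), c(8 / 3, 8 / 3))
  expect_equal(two$or, 2, tolerance = 1e-9)
  expect_equal(log(two$ci_high / two$ci_low),
               log((8 / 3) / 1.5) / sqrt(2), tolerance = 1e-6)
  expect_error(meta_fixed(c(2, NA), c(1, NA), c(4, NA)), "refused")
})

test_that("risk score reproduces category arithmetic from published counts", {
  # rebuild a cohort realizing the printed category counts
  counts <- list(case = c(`0` = 5087, `1` = 367, `2` = 17),
                 control = c(`0` = 3928, `1` = 178, `2` = 3))
  rows <- list()
  for (st in names(counts)) {
    for (k in names(counts[[st]])) {
      n <- counts[[st]][[k]]
      block <- data.frame(
        subject_id = "x", study = "S", status = st, age = 65,
        family_history = "no",
        aggressiveness = ifelse(st == "case", "non-aggressive", "control"),
        va = as.integer(as.integer(k) >= 1), vb = as.integer(as.integer(k) >= 2),
        vc = 0L, vd = 0L, stringsAsFactors = FALSE)
      rows[[paste(st, k)]] <- block[rep(1, n), ]
    }
  }
  coh <- do.call(rbind, rows)
  coh$subject_id <- sprintf("s%05d", seq_len(nrow(coh)))
  rs <- genetic_risk_score(coh, c("va", "vb", "vc", "vd"),
                           covariates = character(0))
  expect_equal(rs$pct_cases[rs$category == "1"], 6.71)
  expect_equal(rs$pct_cases[rs$category == "0"], 92.98)
  expect_equal(rs$pct_controls[rs$category == "1"], 4.33)
  expect_equal(rs$n_cases[rs$category == ">=1"], 384)
  expect_equal(rs$or[rs$category == ">=1"],
               (384 * 3928) / (181 * 5087), tolerance = 1e-6)
  expect_equal(rs$or[rs$category == ">=1"], 1.638, tolerance = 1e-3)
  # percentages sum to 100 within each group over the exclusive categories
  excl <- rs$category %in% c("0", "1", "2-3")
  expect_equal(sum(rs$pct_cases[excl]), 100, tolerance = 0.02)
  expect_equal(sum(rs$pct_controls[excl]), 100, tolerance = 0.02)
})

test_that("risk score excludes subjects missing any genotype in the set", {
  coh <- cohort_from_2x2(10, 90, 10, 90)
  coh$v2 <- 0L
  coh$v2[1:5] <- NA
  rs <- genetic_risk_score(coh, c("v", "v2"), covariates = character(0))
  expect_equal(attr(rs, "n_complete"), 195)
})

test_that("co-occurrence expectation and test behave on planted data", {
  expect_equal(cooccurrence_expected(5487, 0.0118, 0.0241), 1.56, tolerance = 1e-2)
  expect_equal(cooccurrence_expected(100, 0, 0.5), 0)
  expect_equal(cooccurrence_expected(100, 1, 1), 100)
  coh <- cohort_from_2x2(30, 470, 20, 480)
  coh$v2 <- coh$v  # identical variants: co-carriers are just carriers
  ct <- cooccurrence_test(coh, "v", "v2")
  expect_equal(ct$table["both", "case"], 30)
  expect_equal(ct$observed_cases, 30)
  # no co-carriers anywhere: p = 1
  coh$v3 <- 0L; coh$v3[coh$v == 0][1:10] <- 1L
  ct2 <- cooccurrence_test(coh, "v", "v3")
  expect_equal(ct2$table["both", "case"] + ct2$table["both", "control"], 0)
  expect_equal(ct2$p, 1)
})

test_that("stratified analysis recovers planted stratum-specific effects", {
  spec <- simulation_spec(cohorts = list(A = c(cases = 2000, controls = 2000),
                                         B = c(cases = 2000, controls = 2000)))
  pv <- planted_variant("v1", "G", "1", 1, cohort_or = 1.4,
                        control_carrier_freq = 0.06,
                        or_aggressive = 3.0, or_nonaggressive = 1.2)
  coh <- generate_cohort(spec, list(pv), seed = 55)
  res <- stratified_analysis(coh, "v1", "aggressiveness")
  meta_agg <- res[res$study == "meta" & res$stratum == "aggressive", ]
  meta_non <- res[res$study == "meta" & res$stratum == "non-aggressive", ]
  expect_gt(meta_agg$or, meta_non$or)
  expect_true(meta_agg$ci_low <= 3.0 && 3.0 <= meta_agg$ci_high)
  expect_true(meta_non$ci_low <= 1.2 && 1.2 <= meta_non$ci_high)

  # family-history stratification on null-history data yields both strata
  res_fh <- stratified_analysis(coh, "v1", "family_history")
  expect_setequal(unique(res_fh$stratum), c("no", "yes"))
  expect_true(all(c("A", "B", "meta") %in% res_fh$study))
})

test_that("zero-control-carrier strata fall back to Fisher", {
  coh <- rbind(cohort_from_2x2(8, 492, 0, 500, study = "A"),
               cohort_from_2x2(12, 488, 10, 490, study = "B"))
  coh$subject_id <- sprintf("s%05d", seq_len(nrow(coh)))
  res <- stratified_analysis(coh, "v", "family_history")
  no_meta <- res[res$stratum == "no" & res$study == "meta", ]
  expect_match(no_meta$method, "fisher")
  expect_true(is.na(no_meta$or))
  expect_equal(no_meta$p,
               fisher_exact(20, 980, 10, 990, "point"), tolerance = 1e-12)
})
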