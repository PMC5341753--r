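Z95 <- 1.959964

assoc_row <- function(variant, stratum = "overall", study = "all",
                      a = NA, b = NA, c = NA, d = NA,
                      or = NA, ci_low = NA, ci_high = NA, p = NA,
                      method = NA_character_) {
  out <- data.frame(variant = variant, stratum = stratum, study = study,
                    n_case_carrier = a, n_case_noncarrier = b,
                    n_control_carrier = c, n_control_noncarrier = d,
                    or = or, ci_low = ci_low, ci_high = ci_high, p = p,
                    method = method, stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' @export
print.assoc_result <- function(x, ...) {
  df <- as.data.frame(x)
  df$or <- round(df$or, 2)
  df$ci_low <- round(df$ci_low, 2)
  df$ci_high <- round(df$ci_high, 2)
  df$p <- signif(df$p, 2)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Crude odds ratio from a 2x2 table
#'
#' Closed-form dominant-model odds ratio with Wald confidence interval:
#' OR = ad/bc, CI = exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)). The
#' cells are case carriers (`a`), case non-carriers (`b`), control carriers
#' (`c`) and control non-carriers (`d`).
#'
#' @param a,b,c,d non-negative counts
#' @param continuity add 0.5 to every cell when any is zero (off by default)
#' @return an `assoc_result` row; with a zero cell and no continuity
#'   correction the OR may be 0 or Inf and the CI is NA
#' @export
crude_or <- function(a, b, c, d, continuity = FALSE) {
  if (a == 0 && c == 0) stop("no carriers in either group; no association computable")
  cells <- c(a, b, c, d)
  if (any(cells == 0) && continuity) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  if (any(cells == 0)) {
    return(assoc_row("2x2", a = a, b = b, c = c, d = d, or = or,
                     method = "crude"))
  }
  se <- sqrt(sum(1 / cells))
  lo <- exp(log(or) - Z95 * se)
  hi <- exp(log(or) + Z95 * se)
  p <- 2 * stats::pnorm(-abs(log(or) / se))
  assoc_row("2x2", a = a, b = b, c = c, d = d, or = or,
            ci_low = lo, ci_high = hi, p = p, method = "crude")
}

#' Fisher's exact probabilities for a 2x2 table
#'
#' Hypergeometric computation with three conventions: `two_sided` sums the
#' probabilities of all tables (at fixed margins) whose point probability
#' does not exceed the observed table's (the minimum-likelihood convention);
#' `one_sided` is the upper tail (enrichment of carriers in cases); `point`
#' is the probability of exactly the observed table. Published family-
#' history stratum p-values in this study design match the point
#' convention, which is why it is exposed explicitly.
#'
#' @param a,b,c,d counts: case carriers, case non-carriers, control
#'   carriers, control non-carriers
#' @param mode one of "two_sided", "one_sided", "point"
#' @return p-value; 1 when a margin is all zero
#' @export
fisher_exact <- function(a, b, c, d, mode = c("two_sided", "one_sided", "point")) {
  mode <- match.arg(mode)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + c   # carriers
  n <- b + d   # non-carriers
  k <- a + b   # cases
  if (m == 0 || n == 0 || k == 0 || c + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  switch(mode,
         point = obs,
         one_sided = sum(dens[support >= a]),
         two_sided = min(1, sum(dens[dens <= obs * (1 + 1e-7)])))
}

extract_carrier_counts <- function(status, carrier) {
  c(a = sum(status == "case" & carrier == 1),
    b = sum(status == "case" & carrier == 0),
    c = sum(status == "control" & carrier == 1),
    d = sum(status == "control" & carrier == 0))
}

#' Dominant-model logistic regression for one variant
#'
#' Unconditional logistic regression of case status on dominant carrier
#' coding (homozygous reference is the reference group), adjusted for the
#' given covariates (age by default). Subjects with a missing carrier call
#' are dropped listwise. Complete separation -- no carriers among cases or
#' among controls -- is refused with a pointer to [fisher_exact()].
#'
#' @param cohort cohort data.frame (see [generate_cohort()] for the layout)
#' @param variant name of the 0/1 carrier column
#' @param covariates character vector of adjustment columns; use
#'   `character(0)` for a crude fit
#' @return an `assoc_result` row
#' @export
logistic_dominant <- function(cohort, variant, covariates = "age") {
  df <- cohort[!is.na(cohort[[variant]]), , drop = FALSE]
  if (length(covariates)) {
    df <- df[stats::complete.cases(df[, covariates, drop = FALSE]), , drop = FALSE]
  }
  if (!any(df[[variant]] > 0)) stop("no carriers in cohort for ", variant)
  cnt <- extract_carrier_counts(df$status, as.integer(df[[variant]] > 0))
  if (cnt["a"] == 0 || cnt["c"] == 0) {
    stop("complete separation for ", variant,
         " (a carrier count is zero); use fisher_exact() on the 2x2 counts")
  }
  df$.y <- as.integer(df$status == "case")
  df$.carrier <- as.integer(df[[variant]] > 0)
  form <- stats::reformulate(c(".carrier", covariates), response = ".y")
  fit <- stats::glm(form, data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  est <- stats::coef(summary(fit))[".carrier", ]
  assoc_row(variant, a = cnt["a"], b = cnt["b"], c = cnt["c"], d = cnt["d"],
            or = exp(est["Estimate"]),
            ci_low = exp(est["Estimate"] - Z95 * est["Std. Error"]),
            ci_high = exp(est["Estimate"] + Z95 * est["Std. Error"]),
            p = est["Pr(>|z|)"],
            method = if (length(covariates)) {
              paste0("logistic+", paste(covariates, collapse = "+"))
            } else "logistic")
}

#' Polytomous logistic regression by disease aggressiveness
#'
#' Multinomial logistic regression of a three-level outcome (control
#' reference, non-aggressive disease, aggressive disease) on dominant
#' carrier coding, adjusted for covariates. Returns one `assoc_result` row
#' per disease stratum versus controls with Wald CIs and p-values.
#'
#' @inheritParams logistic_dominant
#' @return `assoc_result` with rows for "non-aggressive" and "aggressive"
#' @export
polytomous_logistic <- function(cohort, variant, covariates = "age") {
  df <- cohort[!is.na(cohort[[variant]]), , drop = FALSE]
  if (length(covariates)) {
    df <- df[stats::complete.cases(df[, covariates, drop = FALSE]), , drop = FALSE]
  }
  levels_out <- c("control", "non-aggressive", "aggressive")
  if (!all(levels_out %in% df$aggressiveness)) {
    stop("empty disease stratum; polytomous model needs controls, non-aggressive and aggressive subjects")
  }
  df$.out <- factor(df$aggressiveness, levels = levels_out)
  df$.carrier <- as.integer(df[[variant]] > 0)
  form <- stats::reformulate(c(".carrier", covariates), response = ".out")
  fit <- nnet::multinom(form, data = df, trace = FALSE, maxit = 500)
  sm <- summary(fit)
  rows <- lapply(c("non-aggressive", "aggressive"), function(stratum) {
    beta <- sm$coefficients[stratum, ".carrier"]
    se <- sm$standard.errors[stratum, ".carrier"]
    sub <- df[df$.out %in% c("control", stratum), ]
    cnt <- extract_carrier_counts(ifelse(sub$.out == "control", "control", "case"),
                                  sub$.carrier)
    assoc_row(variant, stratum = stratum,
              a = cnt["a"], b = cnt["b"], c = cnt["c"], d = cnt["d"],
              or = exp(beta), ci_low = exp(beta - Z95 * se),
              ci_high = exp(beta + Z95 * se),
              p = 2 * stats::pnorm(-abs(beta / se)),
              method = "polytomous")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Fixed-effect inverse-variance meta-analysis of odds ratios
#'
#' Pools study log odds ratios weighted by inverse variance, with standard
#' errors recovered from the 95% confidence intervals as
#' (log upper - log lower) / (2 x 1.959964). Fitted with metafor's
#' fixed-effect model.
#'
#' @param or,ci_low,ci_high per-study odds ratios and 95% CI bounds
#' @param labels optional study labels
#' @return an `assoc_result` row (study = "meta")
#' @export
meta_fixed <- function(or, ci_low, ci_high, labels = NULL) {
  if (any(!is.finite(or) | !is.finite(ci_low) | !is.finite(ci_high)) ||
      any(or <= 0 | ci_low <= 0)) {
    stop("non-estimable study effect (e.g. zero control carriers); ",
         "meta-analysis refused -- use fisher_exact() on the pooled counts")
  }
  stopifnot(length(or) >= 1, all(ci_low <= or), all(or <= ci_high))
  yi <- log(or)
  sei <- (log(ci_high) - log(ci_low)) / (2 * Z95)
  fit <- metafor::rma(yi = yi, sei = sei, method = "FE")
  assoc_row("meta", study = "meta",
            or = exp(as.numeric(fit$beta)),
            ci_low = exp(fit$ci.lb), ci_high = exp(fit$ci.ub),
            p = fit$pval, method = "meta_fixed")
}

#' Risk-allele count score over a variant set
#'
#' Counts, per subject, how many of the given variants are carried (dominant
#' coding per variant, summed). Subjects missing a genotype for any variant
#' in the set are excluded. Categories are 0, 1, "2-3" and ">=1" carried
#' alleles; within-group percentages and logistic odds ratios versus the
#' zero-carrier category are reported.
#'
#' @param cohort cohort data.frame
#' @param variants character vector of carrier column names
#' @param covariates adjustment covariates for the category ORs
#' @return data.frame with one row per category (`category`, `n_cases`,
#'   `pct_cases`, `n_controls`, `pct_controls`, `or`, `ci_low`, `ci_high`,
#'   `p`); OR columns are NA where a category is empty
#' @export
genetic_risk_score <- function(cohort, variants, covariates = "age") {
  g <- as.matrix(cohort[, variants, drop = FALSE])
  complete <- stats::complete.cases(g)
  df <- cohort[complete, , drop = FALSE]
  score <- rowSums(as.matrix(df[, variants, drop = FALSE]) > 0)
  cat_of <- function(s) ifelse(s == 0, "0", ifelse(s == 1, "1", "2-3"))
  df$.cat <- cat_of(score)
  n_ca <- sum(df$status == "case"); n_co <- sum(df$status == "control")
  rows <- lapply(c("0", "1", "2-3", ">=1"), function(cc) {
    inc <- if (cc == ">=1") df$.cat != "0" else df$.cat == cc
    nc <- sum(inc & df$status == "case"); nn <- sum(inc & df$status == "control")
    out <- data.frame(category = cc, n_cases = nc,
                      pct_cases = round(100 * nc / n_ca, 2),
                      n_controls = nn,
                      pct_controls = round(100 * nn / n_co, 2),
                      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE)
    if (cc != "0" && nc > 0 && nn > 0) {
      sub <- df[df$.cat == "0" | inc, , drop = FALSE]
      sub$.risk <- as.integer(sub$.cat != "0")
      fit <- logistic_dominant(sub, ".risk", covariates = covariates)
      out$or <- fit$or; out$ci_low <- fit$ci_low; out$ci_high <- fit$ci_high
      out$p <- fit$p
    }
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "n_complete") <- nrow(df)
  res
}

#' Expected co-carrier count under independence
#'
#' @param n_cases number of cases
#' @param f1,f2 carrier frequencies of the two variants in cases
#' @return expected number of cases carrying both variants if carriage is
#'   independent
#' @export
cooccurrence_expected <- function(n_cases, f1, f2) {
  stopifnot(f1 >= 0, f1 <= 1, f2 >= 0, f2 <= 1)
  n_cases * f1 * f2
}

#' Co-occurrence test for two variants
#'
#' Compares subjects carrying both variants against subjects carrying
#' neither, cases versus controls, by Fisher's exact test; also reports the
#' observed case co-carrier count against the independence expectation.
#'
#' @param cohort cohort data.frame
#' @param v1,v2 carrier column names
#' @param mode Fisher convention passed to [fisher_exact()]
#' @return list: `table` (2x2 counts), `p` (Fisher), `observed_cases`,
#'   `expected_cases`
#' @export
cooccurrence_test <- function(cohort, v1, v2, mode = "two_sided") {
  ok <- !is.na(cohort[[v1]]) & !is.na(cohort[[v2]])
  df <- cohort[ok, , drop = FALSE]
  both <- df[[v1]] > 0 & df[[v2]] > 0
  neither <- df[[v1]] == 0 & df[[v2]] == 0
  a <- sum(both & df$status == "case")
  b <- sum(neither & df$status == "case")
  c <- sum(both & df$status == "control")
  d <- sum(neither & df$status == "control")
  n_cases <- sum(df$status == "case")
  f1 <- mean(df[[v1]][df$status == "case"] > 0)
  f2 <- mean(df[[v2]][df$status == "case"] > 0)
  list(table = matrix(c(a, b, c, d), 2, 2,
                      dimnames = list(c("both", "neither"), c("case", "control"))),
       p = fisher_exact(a, b, c, d, mode = mode),
       observed_cases = a,
       expected_cases = cooccurrence_expected(n_cases, f1, f2))
}

#' Stratified association analysis with meta-analysis across studies
#'
#' Runs the per-study dominant-model regression (or the polytomous model
#' when stratifying by aggressiveness) within each stratum, then pools the
#' study estimates by fixed-effect meta-analysis. When a stratum has no
#' control carriers in some study the meta-analysis is refused and a
#' Fisher's exact p-value on the pooled stratum counts is reported instead.
#'
#' @param cohort cohort data.frame covering one or more studies (column
#'   `study`)
#' @param variant carrier column name
#' @param stratifier "family_history" or "aggressiveness"
#' @param covariates adjustment covariates
#' @param fisher_mode Fisher convention for the zero-carrier fallback
#'   ("point" matches how such strata are conventionally reported here)
#' @return `assoc_result` data.frame with per-study and pooled rows
#' @export
stratified_analysis <- function(cohort, variant,
                                stratifier = c("family_history", "aggressiveness"),
                                covariates = "age", fisher_mode = "point") {
  stratifier <- match.arg(stratifier)
  studies <- unique(cohort$study)
  out <- list()
  if (stratifier == "family_history") {
    for (stratum in c("no", "yes")) {
      sub_all <- cohort[cohort$family_history == stratum, , drop = FALSE]
      fits <- list()
      failed <- FALSE
      for (s in studies) {
        sub <- sub_all[sub_all$study == s, , drop = FALSE]
        fit <- tryCatch(logistic_dominant(sub, variant, covariates),
                        error = function(e) NULL)
        if (is.null(fit)) failed <- TRUE else {
          fit$study <- s; fit$stratum <- stratum
          fits[[s]] <- fit
        }
      }
      out <- c(out, fits)
      cnt <- extract_carrier_counts(
        sub_all$status[!is.na(sub_all[[variant]])],
        as.integer(sub_all[[variant]][!is.na(sub_all[[variant]])] > 0))
      if (failed || !length(fits)) {
        row <- assoc_row(variant, stratum = stratum, study = "meta",
                         a = cnt["a"], b = cnt["b"], c = cnt["c"], d = cnt["d"],
                         p = fisher_exact(cnt["a"], cnt["b"], cnt["c"], cnt["d"],
                                          mode = fisher_mode),
                         method = paste0("fisher_", fisher_mode))
      } else {
        ors <- vapply(fits, function(f) f$or, numeric(1))
        row <- meta_fixed(ors, vapply(fits, function(f) f$ci_low, numeric(1)),
                          vapply(fits, function(f) f$ci_high, numeric(1)))
        row$variant <- variant; row$stratum <- stratum
        row[c("n_case_carrier", "n_case_noncarrier", "n_control_carrier",
              "n_control_noncarrier")] <- as.list(cnt)
      }
      out <- c(out, list(row))
    }
  } else {
    fits <- lapply(studies, function(s) {
      polytomous_logistic(cohort[cohort$study == s, , drop = FALSE],
                          variant, covariates)
    })
    names(fits) <- studies
    for (s in studies) {
      fits[[s]]$study <- s
    }
    out <- c(out, fits)
    for (stratum in c("non-aggressive", "aggressive")) {
      per <- lapply(fits, function(f) f[f$stratum == stratum, , drop = FALSE])
      row <- meta_fixed(vapply(per, function(f) f$or, numeric(1)),
                        vapply(per, function(f) f$ci_low, numeric(1)),
                        vapply(per, function(f) f$ci_high, numeric(1)))
      row$variant <- variant; row$stratum <- stratum
      sub <- cohort[cohort$aggressiveness %in% c("control", stratum) &
                      !is.na(cohort[[variant]]), , drop = FALSE]
      cnt <- extract_carrier_counts(
        ifelse(sub$aggressiveness == "control", "control", "case"),
        as.integer(sub[[variant]] > 0))
      row[c("n_case_carrier", "n_case_noncarrier", "n_control_carrier",
            "n_control_noncarrier")] <- as.list(cnt)
      out <- c(out, list(row))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("assoc_result", "data.frame")
  res
}
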