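test_that("generated family collections match the planted bin marginals", {
  spec <- simulation_spec()
  peds <- generate_families(spec, seed = 202)
  expect_length(peds, 75)
  fs <- family_summary(peds)
  # each controlled marginal stays within a binomial 95% band of its weight
  for (stat in c("affected", "mean_dx_age")) {
    w <- switch(stat, affected = spec$affected_bin_weights,
                mean_dx_age = spec$age_bin_weights)
    p <- w / sum(w)
    obs <- fs$n_families[fs$statistic == stat]
    for (i in seq_along(p)) {
      band <- stats::qbinom(c(0.025, 0.975), 75, p[i])
      expect_gte(obs[i], band[1])
      expect_lte(obs[i], band[2])
    }
  }
  # WES counts are truncated by DNA availability, so compare only the
  # dominant single-WES bin
  n_wes1 <- fs$n_families[fs$statistic == "wes" & fs$bin == "1"]
  expect_gte(n_wes1, stats::qbinom(0.025, 75, 44 / 75))
})

test_that("generators are deterministic per seed", {
  spec <- simulation_spec()
  expect_identical(generate_families(spec, seed = 5), generate_families(spec, seed = 5))
  ped <- ped_three_gen()
  expect_identical(gene_drop(ped, seed = 9), gene_drop(ped, seed = 9))
  co1 <- generate_cohort(spec, seed = 3)
  co2 <- generate_cohort(spec, seed = 3)
  expect_identical(co1, co2)
  expect_equal(nrow(co1), 1265 + 1230 + 4222 + 2899)
})

test_that("gene drop is Mendelian consistent and conserves founder labels", {
  set.seed(11)
  for (rep in 1:20) {
    ped <- random_pedigree(sample(5:8, 1))
    hm <- gene_drop(ped, seed = rep)
    fnd <- founders(ped)
    expect_setequal(unique(c(hm$hap1[match(fnd, hm$individual_id)],
                             hm$hap2[match(fnd, hm$individual_id)])),
                    as.vector(outer(fnd, c(".1", ".2"), paste0)))
    # every child's labels come from its parents (checked for every trio)
    for (i in seq_len(nrow(ped))) {
      if (is.na(ped$father[i])) next
      child <- match(ped$id[i], hm$individual_id)
      f <- match(ped$father[i], hm$individual_id)
      m <- match(ped$mother[i], hm$individual_id)
      expect_true(hm$hap1[child] %in% c(hm$hap1[f], hm$hap2[f]))
      expect_true(hm$hap2[child] %in% c(hm$hap1[m], hm$hap2[m]))
    }
  }
})

test_that("founder haplotypes are transmitted at frequency one half", {
  ped <- ped_three_gen()
  hm <- gene_drop(ped, n_loci = 10000, seed = 1)
  # f1's paternal label across loci is gf.1 half the time
  f1 <- hm[hm$individual_id == "f1", ]
  p <- mean(f1$hap1 == "gf.1")
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(p - 0.5), 3 * se)
})

test_that("planted variants hit their carrier families and targets", {
  spec <- simulation_spec()
  peds <- generate_families(spec, seed = 31)
  # target 1.0: the chosen haplotype maximizes affected coverage
  pv_full <- planted_variant("full", "G1", "1", 100, n_carrier_families = 3,
                             target_carrier_frac = 1.0)
  res <- suppressWarnings(plant_risk_variant(peds, pv_full, seed = 8))
  expect_equal(nrow(res$truth), 3)
  # truth fraction is the closest achievable to the target
  expect_true(all(res$truth$true_frac > 0))
  # round trip: planted families are exactly the segregating families
  info <- do.call(rbind, lapply(peds, function(p) data.frame(
    sample_id = p$id, family_id = family_id(p), affected = p$affected,
    wes = p$wes, stringsAsFactors = FALSE)))
  geno <- matrix(res$genotypes, ncol = 1,
                 dimnames = list(names(res$genotypes), "full"))
  expect_equal(unname(segregating_families(geno, info)), 3L)
  expect_setequal(unique(info$family_id[info$sample_id %in%
                                          names(res$genotypes)[res$genotypes > 0]]),
                  res$truth$family_id)
})

test_that("cohort generator reproduces the null and is seed-stable", {
  spec <- simulation_spec(cohorts = list(S = c(cases = 4000, controls = 4000)))
  null_pv <- planted_variant("null", "G", "1", 1, cohort_or = 1,
                             control_carrier_freq = 0.05)
  coh <- generate_cohort(spec, list(null_pv), seed = 77)
  f_ca <- mean(coh$null[coh$status == "case"])
  f_co <- mean(coh$null[coh$status == "control"])
  se <- sqrt(0.05 * 0.95 * (1 / 4000 + 1 / 4000))
  expect_lt(abs(f_ca - f_co), 3 * se)
  # aggressive fraction and family-history prevalence roughly as specified
  expect_lt(abs(mean(coh$aggressiveness[coh$status == "case"] == "aggressive") - 0.2), 0.03)
  expect_lt(abs(mean(coh$family_history[coh$status == "case"] == "yes") - 0.14), 0.03)
  expect_true(all(coh$aggressiveness[coh$status == "control"] == "control"))
  expect_true(all(coh$age >= 40 & coh$age <= 90))
})

test_that("QC failure injection plants recoverable failures", {
  set.seed(5)
  n_s <- 120; n_v <- 60
  fams <- rep(sprintf("F%02d", 1:10), each = 6)
  info <- data.frame(
    sample_id = sprintf("s%03d", 1:n_s),
    family_id = c(fams, rep(NA, n_s - length(fams))),
    status = c(rep(NA, length(fams)),
               rep(c("case", "control"), each = (n_s - length(fams)) / 2)),
    stringsAsFactors = FALSE)
  # baseline passes all three rules: carriers in 4 families, none in controls
  geno <- matrix(0L, n_s, n_v,
                 dimnames = list(info$sample_id, sprintf("v%03d", 1:n_v)))
  for (v in seq_len(n_v)) {
    for (f in sample(unique(stats::na.omit(info$family_id)), 4)) {
      s <- sample(info$sample_id[info$family_id %in% f], 1)
      geno[s, v] <- 1L
    }
  }
  inj <- inject_qc_failures(geno, info,
                            failures = list(n_samples = 5, n_callrate = 4,
                                            n_control_freq = 3, n_family = 2),
                            seed = 9)
  sq <- sample_qc(inj$geno)
  expect_setequal(sq$removed, inj$truth$samples)
  vq <- variant_qc(sq$geno, info)
  expect_setequal(names(vq$removed)[vq$removed == "call_rate"], inj$truth$variants$callrate)
  expect_setequal(names(vq$removed)[vq$removed == "control_frequency"],
                  inj$truth$variants$control_freq)
  expect_setequal(names(vq$removed)[vq$removed == "family_count"],
                  inj$truth$variants$family)

  # zero planted failures: nothing removed
  clean <- inject_qc_failures(geno, info,
                              failures = list(n_samples = 0, n_callrate = 0,
                                              n_control_freq = 0, n_family = 0),
                              seed = 9)
  expect_identical(clean$geno, geno)
})
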