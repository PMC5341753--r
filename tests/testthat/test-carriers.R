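# Family with five affected men and a controlled haplotype layout:
# candidate A is carried by 3 affected men, candidate B by 2.
bounds_fixture <- function() {
  ped <- ped_three_gen()  # affected men: gf, f1, f2, c1, c2, c3 (6 affected)
  hap <- data.frame(
    family_id = "T3G",
    individual_id = c("gf", "gm", "f1", "f2", "m1", "m2", "c1", "c2", "c3"),
    hap1 = c("gf.1", "gm.1", "gf.1", "gf.2", "m1.1", "m2.1", "gf.1", "gf.1", "gf.2"),
    hap2 = c("gf.2", "gm.2", "gm.1", "gm.2", "m1.2", "m2.2", "m1.1", "m1.2", "m2.1"),
    stringsAsFactors = FALSE)
  list(ped = ped, hap = hap)
}

test_that("candidate haplotypes resolve by intersection of carrier label pairs", {
  fx <- bounds_fixture()
  ped <- fx$ped
  ped$wes <- ped$id %in% c("f1", "c1")
  # two carriers sharing only gf.1: resolved
  g <- stats::setNames(c(0L, 0L, 1L, 0L, 0L, 0L, 1L, 0L, 0L), ped$id)
  cand <- candidate_haplotypes(ped, g, fx$hap)
  expect_equal(cand$labels, "gf.1")
  expect_equal(cand$status, "resolved")

  # a single carrier leaves both its labels: ambiguous
  ped1 <- ped; ped1$wes <- ped1$id == "c1"
  g1 <- stats::setNames(as.integer(ped1$id == "c1"), ped1$id)
  cand1 <- candidate_haplotypes(ped1, g1, fx$hap)
  expect_setequal(cand1$labels, c("gf.1", "m1.1"))
  expect_equal(cand1$status, "ambiguous")

  # disjoint carrier pairs: inconsistent, union returned with a warning
  ped2 <- ped; ped2$wes <- ped2$id %in% c("c1", "c3")
  g2 <- stats::setNames(as.integer(ped2$id %in% c("c1", "c3")), ped2$id)
  expect_warning(cand2 <- candidate_haplotypes(ped2, g2, fx$hap), "inconsistent")
  expect_setequal(cand2$labels, c("gf.1", "m1.1", "gf.2", "m2.1"))
  expect_equal(cand2$status, "inconsistent")

  expect_error(candidate_haplotypes(ped, stats::setNames(rep(0L, 9), ped$id), fx$hap),
               "no sequenced affected carrier")
})

test_that("adding a sequenced carrier never enlarges the candidate set", {
  set.seed(19)
  for (rep in 1:30) {
    ped <- random_pedigree(8)
    ped$affected <- TRUE
    hm <- gene_drop(ped, seed = rep)
    # pick a founder haplotype as truth; carriers are its bearers
    h <- paste0(sample(founders(ped), 1), ".", sample(1:2, 1))
    carriers <- hm$individual_id[hm$hap1 == h | hm$hap2 == h]
    if (length(carriers) < 2) next
    g <- stats::setNames(as.integer(ped$id %in% carriers), ped$id)
    ped$wes <- ped$id == carriers[1]
    c1 <- candidate_haplotypes(ped, g, hm)
    ped$wes <- ped$id %in% carriers[1:2]
    c2 <- candidate_haplotypes(ped, g, hm)
    expect_true(all(c2$labels %in% c1$labels))
    expect_true(h %in% c2$labels)
  }
})

test_that("carrier bounds count affected bearers of each candidate", {
  fx <- bounds_fixture()
  ped <- fx$ped
  # candidates {gf.1, m1.1}: gf.1 in gf,f1,c1,c2; m1.1 in c1 -> on the
  # 6-man roster min 1, max 4
  b <- family_carrier_bounds(ped, list(labels = c("gf.1", "m1.1")), fx$hap)
  expect_equal(b$n_affected, 6)
  expect_equal(b$min_count, 1)
  expect_equal(b$max_count, 4)
  expect_equal(b$min_frac, 1 / 6)
  expect_equal(b$max_frac, 4 / 6)
  # a single resolved candidate collapses the bounds
  b1 <- family_carrier_bounds(ped, list(labels = "gf.1"), fx$hap)
  expect_equal(b1$min_count, b1$max_count)
  expect_equal(b1$min_frac, b1$max_frac)
  # affected man missing from the map: numerator excluded, denominator kept
  hap_missing <- fx$hap[fx$hap$individual_id != "c3", ]
  expect_warning(b2 <- family_carrier_bounds(ped, list(labels = "gf.2"), hap_missing),
                 "lack haplotype data")
  expect_equal(b2$n_affected, 6)
})

test_that("average carrier frequency is the unweighted mean in percent", {
  bounds <- data.frame(min_frac = c(0.4, 0.5, 1.0), max_frac = c(0.6, 0.5, 1.0))
  s <- average_carrier_frequency("v", bounds)
  expect_equal(s$min_avg, 63.3)
  expect_equal(s$max_avg, 70.0)
  expect_equal(s$n_carrier_families, 3)
  one <- average_carrier_frequency("v", data.frame(min_frac = 0.5, max_frac = 0.5))
  expect_equal(c(one$min_avg, one$max_avg), c(50, 50))
  expect_error(average_carrier_frequency("v", NULL), "no carrier families")
})

test_that("bounds bracket the truth and match brute-force enumeration", {
  set.seed(33)
  n_checked <- 0
  for (rep in 1:120) {
    ped <- random_pedigree(sample(6:9, 1))
    ped$affected <- stats::runif(nrow(ped)) < 0.7
    ped$sex[1] <- "male"
    if (sum(ped$affected & ped$sex == "male") < 2) next
    hm <- gene_drop(ped, seed = 1000 + rep)
    labels <- as.vector(outer(founders(ped), c(".1", ".2"), paste0))
    h <- sample(labels, 1)
    carriers <- hm$individual_id[hm$hap1 == h | hm$hap2 == h]
    aff <- ped$id[ped$affected & ped$sex == "male"]
    wes_carriers <- intersect(carriers, aff)
    if (!length(wes_carriers)) next
    ped$wes <- ped$id %in% sample(wes_carriers, sample(seq_along(wes_carriers), 1))
    g <- stats::setNames(as.integer(ped$id %in% carriers), ped$id)
    cand <- candidate_haplotypes(ped, g, hm)
    b <- family_carrier_bounds(ped, cand, hm)
    truth <- mean(aff %in% carriers)
    expect_lte(b$min_frac, truth + 1e-12)
    expect_gte(b$max_frac, truth - 1e-12)
    # oracle: enumerate all single-haplotype assignments consistent with
    # every sequenced carrier's label pair
    wes_ids <- ped$id[ped$wes]
    consistent <- Filter(function(hh) {
      all(vapply(wes_ids, function(i) {
        j <- match(i, hm$individual_id)
        hh %in% c(hm$hap1[j], hm$hap2[j])
      }, logical(1)))
    }, labels)
    counts <- vapply(consistent, function(hh) {
      j <- match(aff, hm$individual_id)
      sum(hm$hap1[j] == hh | hm$hap2[j] == hh)
    }, numeric(1))
    expect_equal(b$min_count, min(counts))
    expect_equal(b$max_count, max(counts))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 50)
})

test_that("genotyped carrier counts split by affection status", {
  info <- data.frame(sample_id = sprintf("s%02d", 1:20),
                     family_id = rep(c("F1", "F2"), each = 10),
                     affected = rep(c(TRUE, FALSE), 10),
                     stringsAsFactors = FALSE)
  g <- stats::setNames(rep(0L, 20), info$sample_id)
  g[info$affected][1:9] <- 1L
  g[!info$affected][1:4] <- 1L
  cnt <- genotyped_carrier_counts(g, info)
  expect_equal(unname(cnt), c(9L, 4L))
  expect_equal(unname(genotyped_carrier_counts(stats::setNames(rep(0L, 20), info$sample_id), info)),
               c(0L, 0L))
})

test_that("per-variant summaries report min <= max with equality iff resolved", {
  spec <- simulation_spec()
  st <- suppressWarnings(simulate_study(spec, n_background = 0, seed = 43))
  ids <- st$truth$planted_ids
  sm <- suppressWarnings(
    infer_carrier_summaries(ids, st$geno, st$peds, st$hap_maps))
  expect_true(all(sm$min_avg <= sm$max_avg, na.rm = TRUE))
  bounds <- attr(sm, "bounds")
  for (v in names(bounds)) {
    b <- bounds[[v]]
    resolved <- b$status == "resolved"
    expect_true(all(b$min_frac[resolved] == b$max_frac[resolved]))
    expect_true(all(b$min_count >= 0 & b$max_count <= b$n_affected))
  }
})
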