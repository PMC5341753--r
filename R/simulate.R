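#' Simulation specification for a synthetic family-WES study
#'
#' Bundles every tunable of the synthetic-data generators. The defaults
#' emulate the design of a 75-family hereditary prostate cancer WES study
#' with two replication case-control cohorts: family-size, diagnosis-age and
#' WES-count marginals matching the published family table, eleven reference
#' populations, planted low-frequency risk variants (population frequency
#' at most 2%, affected-carrier fractions in the 40-65% range), and cohorts
#' sized 1,265/1,230 and 4,222/2,899 with ~14%/8% first-degree family
#' history in cases/controls and ~20% aggressive disease among cases.
#'
#' @param n_families number of pedigrees to generate
#' @param affected_bin_weights named numeric, families per affected-count bin
#' @param age_bin_weights named numeric, families per mean-diagnosis-age bin
#' @param wes_bin_weights named numeric, families per WES-count bin
#' @param n_reference_populations number of reference panels
#' @param planted_variants list of `planted_variant` objects
#' @param n_non_european number of families of non-European ancestry
#'   (excluded from the proband frequency-ratio denominator cohort but kept
#'   for segregation and carrier inference)
#' @param cohorts named list; each element `c(cases = , controls = )`
#' @param age_mean,age_sd,age_range cohort age model: normal, truncated
#' @param family_history named c(case=, control=) first-degree family-history
#'   prevalence
#' @param aggressive_fraction fraction of cases with aggressive disease
#'   (Gleason 8-10 or regional/distant stage)
#' @param seed default integer seed for generators called without one
#' @return object of class `simulation_spec`
#' @export
simulation_spec <- function(n_families = 75,
                            affected_bin_weights = c("3-4" = 5, "5-6" = 30, "7-8" = 22,
                                                     "9-10" = 15, "11-18" = 3),
                            age_bin_weights = c("50-54.9" = 3, "55-59.9" = 7, "60-64.9" = 30,
                                                "65-69.9" = 28, "70-79.5" = 7),
                            wes_bin_weights = c("1" = 44, "2" = 2, "3" = 13, "4" = 8,
                                                "5" = 7, "6" = 1),
                            n_reference_populations = 11,
                            planted_variants = default_planted_variants(),
                            cohorts = list(FHCRC = c(cases = 1265, controls = 1230),
                                           PLCO = c(cases = 4222, controls = 2899)),
                            n_non_european = 3,
                            age_mean = 65, age_sd = 8, age_range = c(40, 90),
                            family_history = c(case = 0.14, control = 0.08),
                            aggressive_fraction = 0.20,
                            seed = 1L) {
  stopifnot(n_families > 0, n_reference_populations > 0,
            all(unlist(cohorts) > 0),
            all(family_history >= 0 & family_history <= 1),
            aggressive_fraction >= 0, aggressive_fraction <= 1,
            all(affected_bin_weights >= 0), sum(affected_bin_weights) > 0,
            all(age_bin_weights >= 0), all(wes_bin_weights >= 0))
  structure(list(n_families = n_families,
                 affected_bin_weights = affected_bin_weights,
                 age_bin_weights = age_bin_weights,
                 wes_bin_weights = wes_bin_weights,
                 n_reference_populations = n_reference_populations,
                 planted_variants = planted_variants,
                 n_non_european = n_non_european,
                 cohorts = cohorts,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 family_history = family_history,
                 aggressive_fraction = aggressive_fraction,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Describe one planted risk variant
#'
#' @param id variant id; `gene` symbol; `chrom`, `pos`, `ref`, `alt` locus
#' @param gene,chrom,pos,ref,alt locus and annotation fields
#' @param consequence one of stop_gained, stop_lost, start_lost, frameshift,
#'   splice_site, missense, other
#' @param sift_pred,sift_score,polyphen_pred,polyphen_score protein-impact
#'   annotations (NA for consequence classes the predictors do not score)
#' @param population_af reference-panel alternate-allele frequency (recycled
#'   across populations); must be <= 0.02 for a plantable risk variant
#' @param n_carrier_families number of families the variant is planted in
#' @param target_carrier_frac target fraction of a carrier family's affected
#'   men that carry the allele (moderate penetrance: 0.40-0.65 typical)
#' @param cohort_or planted dominant-model odds ratio in the case-control
#'   cohorts
#' @param control_carrier_freq carrier frequency among controls
#' @param or_aggressive,or_nonaggressive optional stratum-specific odds
#'   ratios; default to `cohort_or`
#' @return object of class `planted_variant`
#' @export
planted_variant <- function(id, gene, chrom, pos, ref = "A", alt = "T",
                            consequence = "missense",
                            sift_pred = "deleterious", sift_score = 0.01,
                            polyphen_pred = "probably", polyphen_score = 0.95,
                            population_af = 0.005,
                            n_carrier_families = 3,
                            target_carrier_frac = 0.5,
                            cohort_or = 1.5,
                            control_carrier_freq = 0.01,
                            or_aggressive = cohort_or,
                            or_nonaggressive = cohort_or) {
  stopifnot(cohort_or > 0, target_carrier_frac > 0, target_carrier_frac <= 1,
            all(population_af >= 0 & population_af <= 1),
            control_carrier_freq >= 0, control_carrier_freq <= 1)
  structure(list(id = id, gene = gene, chrom = as.character(chrom), pos = pos,
                 ref = ref, alt = alt, consequence = consequence,
                 sift_pred = sift_pred, sift_score = sift_score,
                 polyphen_pred = polyphen_pred, polyphen_score = polyphen_score,
                 population_af = population_af,
                 n_carrier_families = n_carrier_families,
                 target_carrier_frac = target_carrier_frac,
                 cohort_or = cohort_or,
                 control_carrier_freq = control_carrier_freq,
                 or_aggressive = or_aggressive,
                 or_nonaggressive = or_nonaggressive),
            class = "planted_variant")
}

#' Default planted risk variants
#'
#' Nine low-frequency variants whose parameters (segregating family counts,
#' affected-carrier fractions, control carrier frequencies and pooled
#' dominant odds ratios) mirror the nine risk variants validated in the
#' FHCRC/PLCO prostate cancer case-control studies, spanning missense and
#' stop-gain consequences and family counts from 3 to 9.
#'
#' @return list of `planted_variant` objects
#' @export
default_planted_variants <- function() {
  tab <- data.frame(
    gene = c("EPHA8", "D2HGDH", "OR5H14", "BRD2", "HOXB13", "CHAD", "SWSAP1",
             "TANGO2", "PPP6R2"),
    chrom = c("1", "2", "3", "6", "17", "17", "19", "22", "22"),
    pos = c(22923859, 242695399, 97868404, 32946119, 46805705, 48542714,
            11486354, 20024596, 50873415),
    consequence = c("missense", "missense", "missense", "missense", "missense",
                    "missense", "missense", "stop_gained", "missense"),
    sift_pred = c("deleterious", "deleterious", "deleterious", "tolerated",
                  "deleterious", "deleterious", "deleterious", NA, "tolerated"),
    sift_score = c(0.02, 0.04, 0, 0.37, 0, 0.02, 0, NA, 0.17),
    polyphen_pred = c("benign", "possibly", "probably", "possibly", "probably",
                      "possibly", "probably", NA, "probably"),
    polyphen_score = c(0.432, 0.774, 0.994, 0.870, 0.999, 0.608, 0.991, NA, 0.977),
    n_fam = c(7, 9, 7, 3, 5, 5, 5, 3, 3),
    target = c(0.537, 0.401, 0.349, 0.567, 0.513, 0.504, 0.460, 0.633, 0.643),
    or = c(1.14, 1.04, 1.39, 1.09, 4.20, 1.53, 1.41, 1.52, 1.26),
    co_freq = c(0.0165, 0.0163, 0.0177, 0.0056, 0.0029, 0.0080, 0.0121,
                0.0160, 0.0148),
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(tab)), function(i) {
    planted_variant(
      id = sprintf("%s:%d", tab$chrom[i], tab$pos[i]),
      gene = tab$gene[i], chrom = tab$chrom[i], pos = tab$pos[i],
      consequence = tab$consequence[i],
      sift_pred = tab$sift_pred[i], sift_score = tab$sift_score[i],
      polyphen_pred = tab$polyphen_pred[i], polyphen_score = tab$polyphen_score[i],
      population_af = tab$co_freq[i] / 2,
      n_carrier_families = tab$n_fam[i],
      target_carrier_frac = tab$target[i],
      cohort_or = tab$or[i],
      control_carrier_freq = tab$co_freq[i]
    )
  })
}

sample_bin <- function(weights) {
  names(weights)[sample.int(length(weights), 1L, prob = weights)]
}

value_in_bin <- function(label) {
  parts <- suppressWarnings(as.numeric(strsplit(label, "-", fixed = TRUE)[[1]]))
  if (length(parts) == 1L) return(parts)
  stats::runif(1, parts[1], parts[2])
}

count_in_bin <- function(label) {
  parts <- suppressWarnings(as.integer(strsplit(label, "-", fixed = TRUE)[[1]]))
  if (length(parts) == 1L) return(parts)
  sample(seq(parts[1], parts[2]), 1L)
}

# Build one three-generation pedigree with `n_affected` affected men.
build_family <- function(fid, n_affected, mean_dx_age, aggressive_p) {
  mk <- local({
    counter <- 0L
    function() {
      counter <<- counter + 1L
      sprintf("%s_%03d", fid, counter)
    }
  })
  rows <- list()
  add <- function(id, father, mother, sex) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, father = father, mother = mother, sex = sex,
      stringsAsFactors = FALSE)
    id
  }
  g1f <- add(mk(), NA, NA, "male")
  g1m <- add(mk(), NA, NA, "female")
  n_sons <- max(2L, ceiling(n_affected / 3))
  sons <- character(n_sons)
  males <- character(0)
  for (s in seq_len(n_sons)) {
    sons[s] <- add(mk(), g1f, g1m, "male")
    males <- c(males, sons[s])
  }
  add(mk(), g1f, g1m, "female")  # a daughter, to vary structure
  for (s in sons) {
    spouse <- add(mk(), NA, NA, "female")
    for (ch in seq_len(sample(2:3, 1L))) {
      sex <- if (stats::runif(1) < 0.6) "male" else "female"
      id <- add(mk(), s, spouse, sex)
      if (sex == "male") males <- c(males, id)
    }
  }
  while (length(males) < n_affected) {
    id <- add(mk(), sons[1L], rows[[which(vapply(rows, function(r)
      identical(r$father, sons[1L]), logical(1)))[1L]]]$mother, "male")
    males <- c(males, id)
  }
  mem <- do.call(rbind, rows)
  mem$affected <- FALSE
  affected_ids <- sample(males, n_affected)
  mem$affected[mem$id %in% affected_ids] <- TRUE
  # diagnosis ages recentred so the family mean lands exactly on target
  ages <- stats::rnorm(n_affected, 0, 4)
  ages <- mean_dx_age + (ages - mean(ages))
  ages <- pmin(pmax(ages, 40), 90)
  mem$dx_age <- NA_real_
  mem$dx_age[match(affected_ids, mem$id)] <- round(ages, 1)
  mem$aggressive <- NA
  mem$aggressive[mem$affected] <- stats::runif(n_affected) < aggressive_p
  mem$vital <- "alive"
  mem$vital[mem$affected] <- ifelse(stats::runif(n_affected) < 0.25, "deceased", "alive")
  mem$dna_available <- TRUE
  mem$dna_available[mem$affected] <- ifelse(
    mem$vital[mem$affected] == "deceased",
    stats::runif(n_affected) < 0.15,
    stats::runif(n_affected) < 0.95)
  mem$wes <- FALSE
  pedigree(mem, family_id = fid)
}

#' Generate synthetic high-risk pedigrees
#'
#' Draws per-family affected counts, mean diagnosis ages and WES counts from
#' the spec's bin weights, builds three-generation pedigrees realizing them,
#' and flags WES'd cases using the study's selection rule (aggressive first,
#' then early-onset, then maximally distant relatives).
#'
#' @param spec a `simulation_spec`
#' @param seed integer; defaults to `spec$seed`
#' @return named list of `pedigree` objects
#' @export
generate_families <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(seed)
  peds <- vector("list", spec$n_families)
  names(peds) <- sprintf("F%03d", seq_len(spec$n_families))
  for (i in seq_len(spec$n_families)) {
    fid <- names(peds)[i]
    n_aff <- count_in_bin(sample_bin(spec$affected_bin_weights))
    target_age <- value_in_bin(sample_bin(spec$age_bin_weights))
    ped <- build_family(fid, n_aff, target_age, spec$aggressive_fraction)
    n_elig <- sum(ped$affected & ped$sex == "male" & ped$dna_available)
    if (n_elig == 0L) {  # guarantee a sequenceable case
      j <- which(ped$affected)[1L]
      ped$dna_available[j] <- TRUE
      ped$vital[j] <- "alive"
      n_elig <- 1L
    }
    n_wes <- min(count_in_bin(sample_bin(spec$wes_bin_weights)), n_elig)
    ped$wes[ped$id %in% select_wes_candidates(ped, n_wes)] <- TRUE
    peds[[i]] <- ped
  }
  non_eu <- sample(names(peds), min(spec$n_non_european, length(peds)))
  for (fid in names(peds)) attr(peds[[fid]], "european") <- !(fid %in% non_eu)
  peds
}

#' Reference population labels
#'
#' @param n number of populations (default 11: the ESP and 1000 Genomes
#'   published and exome panels available to the original filter)
#' @return character vector; `ESP_EA` and `KG_EUR` are the European panels
#'   used in the frequency-ratio denominator
#' @export
reference_populations <- function(n = 11) {
  pops <- c("ESP_EA", "ESP_AA", "KG_EUR", "KG_AFR", "KG_AMR", "KG_EAS",
            "KG_SAS", "KG_ALL", "ESP_ALL", "KG_EX_EUR", "KG_EX_AFR")
  pops[seq_len(min(n, length(pops)))]
}

#' Generate synthetic reference-panel allele frequencies
#'
#' Produces a long panel table for a set of planted variants: each variant's
#' base population allele frequency, jittered independently per population
#' (and clamped to the valid range). A fraction of (variant, population)
#' pairs can be dropped to emulate variants absent from some panels.
#'
#' @param variants list of `planted_variant` objects
#' @param spec a `simulation_spec` (for the number of populations)
#' @param missing_rate fraction of variant-population entries absent
#' @param seed integer seed
#' @return data.frame with columns `variant_id`, `population`, `af`
#' @export
generate_panels <- function(variants, spec, missing_rate = 0.1, seed = spec$seed) {
  set.seed(seed)
  pops <- reference_populations(spec$n_reference_populations)
  out <- do.call(rbind, lapply(variants, function(pv) {
    af <- pmin(pmax(pv$population_af * stats::runif(length(pops), 0.6, 1.4), 0), 1)
    data.frame(variant_id = pv$id, population = pops, af = af,
               stringsAsFactors = FALSE)
  }))
  keep <- stats::runif(nrow(out)) >= missing_rate
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-drop founder haplotypes through a pedigree
#'
#' Labels each founder's two haplotypes uniquely ("<id>.1", "<id>.2") and
#' transmits one label from each parent to each child, independently per
#' locus. With recombination off (the default) a locus is a single point and
#' transmission is a fair coin per meiosis; the result is Mendelian
#' consistent by construction and is the ground truth that replaces
#' SNP-array-based haplotype reconstruction.
#'
#' @param ped a `pedigree`
#' @param n_loci number of independent loci to drop
#' @param seed integer seed
#' @return data.frame with columns `family_id`, `individual_id`, `locus`,
#'   `hap1` (paternal), `hap2` (maternal)
#' @export
gene_drop <- function(ped, n_loci = 1L, seed = 1L) {
  set.seed(seed)
  ord <- topological_order(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  out <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    h1 <- character(nrow(ped)); h2 <- character(nrow(ped))
    for (i in ord) {
      h1[i] <- if (is.na(fa[i])) paste0(ped$id[i], ".1") else
        c(h1[fa[i]], h2[fa[i]])[sample.int(2L, 1L)]
      h2[i] <- if (is.na(mo[i])) paste0(ped$id[i], ".2") else
        c(h1[mo[i]], h2[mo[i]])[sample.int(2L, 1L)]
    }
    out[[l]] <- data.frame(family_id = family_id(ped), individual_id = ped$id,
                           locus = l, hap1 = h1, hap2 = h2,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Plant a risk variant on founder haplotypes across families
#'
#' Chooses carrier families, gene-drops a locus in every family, and in each
#' carrier family assigns the alternate allele to the founder haplotype whose
#' affected-descendant carrier fraction is closest to the planted target.
#' Penetrance is therefore implicit in the haplotype choice; affection
#' status is never resampled, so the family-table structure is untouched.
#'
#' @param peds named list of `pedigree` objects
#' @param pv a `planted_variant`
#' @param seed integer seed
#' @return list with elements `variant` (one-row annotation data.frame),
#'   `genotypes` (named 0/1 vector over every member of every family),
#'   `truth` (per carrier family: chosen haplotype, true carrier ids,
#'   affected-carrier counts and fraction) and `hap_maps` (the gene-dropped
#'   haplotype maps, all families)
#' @export
plant_risk_variant <- function(peds, pv, seed = 1L) {
  stopifnot(inherits(pv, "planted_variant"),
            pv$n_carrier_families <= length(peds))
  set.seed(seed)
  carrier_fams <- sample(names(peds), pv$n_carrier_families)
  hap_seeds <- sample.int(.Machine$integer.max - 1L, length(peds))
  hap_maps <- lapply(seq_along(peds), function(i)
    gene_drop(peds[[i]], n_loci = 1L, seed = hap_seeds[i]))
  names(hap_maps) <- names(peds)
  genotypes <- integer(0)
  truth <- list()
  for (fid in names(peds)) {
    ped <- peds[[fid]]
    hm <- hap_maps[[fid]]
    g <- stats::setNames(integer(nrow(ped)), ped$id)
    if (fid %in% carrier_fams) {
      aff <- ped$id[ped$affected & ped$sex == "male"]
      # the variant must be discoverable: restrict to founder haplotypes
      # carried by at least one sequenced affected man
      wes_aff <- ped$id[ped$wes & ped$affected]
      wes_rows <- match(wes_aff, hm$individual_id)
      labels <- unlist(lapply(founders(ped), paste0, c(".1", ".2")))
      labels <- labels[labels %in% c(hm$hap1[wes_rows], hm$hap2[wes_rows])]
      frac <- vapply(labels, function(h) {
        mean(hm$hap1[match(aff, hm$individual_id)] == h |
               hm$hap2[match(aff, hm$individual_id)] == h)
      }, numeric(1))
      dist <- abs(frac - pv$target_carrier_frac)
      best <- labels[order(dist, labels)][1L]
      if (min(dist) > 0.25) {
        warning(sprintf(
          "family %s: no founder haplotype within 0.25 of target %.2f for %s (closest %.2f)",
          fid, pv$target_carrier_frac, pv$id, frac[labels == best]))
      }
      carriers <- hm$individual_id[hm$hap1 == best | hm$hap2 == best]
      g[carriers] <- 1L
      truth[[fid]] <- data.frame(
        family_id = fid, variant_id = pv$id, haplotype = best,
        n_affected = length(aff),
        n_affected_carriers = sum(aff %in% carriers),
        true_frac = mean(aff %in% carriers),
        target = pv$target_carrier_frac,
        carriers = paste(carriers, collapse = ","),
        stringsAsFactors = FALSE)
    }
    genotypes <- c(genotypes, g)
  }
  variant <- data.frame(
    id = pv$id, chrom = pv$chrom, pos = pv$pos, ref = pv$ref, alt = pv$alt,
    gene = pv$gene, consequence = pv$consequence,
    sift_pred = pv$sift_pred, sift_score = pv$sift_score,
    polyphen_pred = pv$polyphen_pred, polyphen_score = pv$polyphen_score,
    stringsAsFactors = FALSE)
  list(variant = variant, genotypes = genotypes,
       truth = if (length(truth)) do.call(rbind, truth) else NULL,
       hap_maps = hap_maps)
}

truncnorm <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < range[1] | x > range[2])) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generate a synthetic case-control cohort table
#'
#' Draws carrier status under a dominant model so that the planted odds
#' ratio holds in expectation: controls carry at the planted control carrier
#' frequency, and case carrier probabilities are set stratum-wise so that
#' case-versus-control carrier odds equal the planted (possibly
#' aggressiveness-specific) odds ratio. Age, first-degree family history and
#' disease aggressiveness are drawn independently per the spec.
#'
#' @param spec a `simulation_spec`
#' @param variants list of `planted_variant` objects (defaults to the spec's)
#' @param seed integer seed
#' @return data.frame with columns `subject_id`, `study`, `status`, `age`,
#'   `family_history`, `aggressiveness`, then one 0/1 carrier column per
#'   variant id
#' @export
generate_cohort <- function(spec, variants = spec$planted_variants, seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(seed)
  out <- list()
  for (study in names(spec$cohorts)) {
    n_ca <- spec$cohorts[[study]]["cases"]
    n_co <- spec$cohorts[[study]]["controls"]
    n <- n_ca + n_co
    status <- rep(c("case", "control"), c(n_ca, n_co))
    tab <- data.frame(
      subject_id = sprintf("%s_%05d", study, seq_len(n)),
      study = study, status = status,
      age = round(truncnorm(n, spec$age_mean, spec$age_sd, spec$age_range), 1),
      family_history = ifelse(
        stats::runif(n) < ifelse(status == "case",
                                 spec$family_history["case"],
                                 spec$family_history["control"]),
        "yes", "no"),
      stringsAsFactors = FALSE)
    tab$aggressiveness <- "control"
    is_case <- status == "case"
    tab$aggressiveness[is_case] <- ifelse(
      stats::runif(sum(is_case)) < spec$aggressive_fraction,
      "aggressive", "non-aggressive")
    for (pv in variants) {
      f0 <- pv$control_carrier_freq
      if (f0 * n < 1) {
        warning(sprintf("variant %s: fewer than one expected carrier in %s (freq %.4f, n %d)",
                        pv$id, study, f0, n))
      }
      odds0 <- f0 / (1 - f0)
      p_case <- function(or) { o <- or * odds0; o / (1 + o) }
      p <- ifelse(tab$aggressiveness == "control", f0,
                  ifelse(tab$aggressiveness == "aggressive",
                         p_case(pv$or_aggressive), p_case(pv$or_nonaggressive)))
      tab[[pv$id]] <- as.integer(stats::runif(n) < p)
    }
    out[[study]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Inject genotyping quality-control failures
#'
#' Degrades a genotype matrix so that known samples and variants fail the
#' standard post-genotyping filters, recording ground truth for QC-recovery
#' tests. Sample failures mask enough of a sample's calls to push its call
#' rate below 70%. Variant call-rate failures mask calls of retained,
#' non-carrier samples only; control-frequency failures add control
#' carriers until the carrier frequency exceeds 2%; family failures zero
#' out carriers until at most two families remain. Each planted variant
#' failure therefore trips exactly one rule.
#'
#' @param geno integer matrix, samples x variants (0/1/2, NA = missing)
#' @param sample_info data.frame with `sample_id`, `family_id` (NA for
#'   cohort samples), `status` ("case"/"control"/NA), `affected`, `wes`
#' @param failures list with counts `n_samples`, `n_callrate`,
#'   `n_control_freq`, `n_family`
#' @param seed integer seed
#' @return list: `geno` (degraded matrix), `truth` (list of planted failing
#'   sample ids and per-rule variant ids)
#' @export
inject_qc_failures <- function(geno, sample_info,
                               failures = list(n_samples = 20, n_callrate = 12,
                                               n_control_freq = 9, n_family = 6),
                               seed = 1L) {
  set.seed(seed)
  stopifnot(is.matrix(geno), !is.null(rownames(geno)), !is.null(colnames(geno)))
  fam_of <- stats::setNames(sample_info$family_id, sample_info$sample_id)
  fam_samples_all <- rownames(geno)[!is.na(fam_of[rownames(geno)])]
  carrier_fams <- function(g, samples) {
    unique(fam_of[samples[!is.na(g[samples]) & g[samples] > 0]])
  }
  orig_fams <- lapply(colnames(geno), function(v) carrier_fams(geno[, v], fam_samples_all))
  names(orig_fams) <- colnames(geno)

  fail_samples <- sample(rownames(geno), failures$n_samples)
  for (s in fail_samples) {
    idx <- sample(ncol(geno), ceiling(0.35 * ncol(geno)))
    geno[s, idx] <- NA
  }
  keep_samples <- setdiff(rownames(geno), fail_samples)
  controls <- sample_info$sample_id[sample_info$status %in% "control"]
  controls <- intersect(controls, keep_samples)
  # losing a failed sample must not collaterally knock a clean variant below
  # the family-count rule: re-seat lost family carriers in retained samples
  fam_keep <- intersect(fam_samples_all, keep_samples)
  for (v in colnames(geno)) {
    need <- min(length(orig_fams[[v]]), 3L)
    cur <- carrier_fams(geno[, v], fam_keep)
    missing_fams <- setdiff(orig_fams[[v]], cur)
    while (length(cur) < need && length(missing_fams)) {
      f <- missing_fams[1L]; missing_fams <- missing_fams[-1L]
      cand <- fam_keep[fam_of[fam_keep] == f]
      if (length(cand)) {
        geno[cand[1L], v] <- 1L
        cur <- c(cur, f)
      }
    }
  }

  pool <- sample(colnames(geno))
  take <- function(n) {
    picked <- utils::head(pool, n)
    pool <<- utils::tail(pool, -n)
    picked
  }
  v_call <- take(failures$n_callrate)
  for (v in v_call) {
    noncar <- keep_samples[which(geno[keep_samples, v] %in% 0L)]
    idx <- sample(noncar, ceiling(0.35 * length(keep_samples)))
    geno[idx, v] <- NA
  }
  v_freq <- take(failures$n_control_freq)
  for (v in v_freq) {
    need <- ceiling(0.025 * length(controls)) - sum(geno[controls, v] > 0, na.rm = TRUE)
    if (need > 0) {
      tgt <- sample(controls[which(geno[controls, v] %in% 0L)], need)
      geno[tgt, v] <- 1L
    }
  }
  v_fam <- take(failures$n_family)
  for (v in v_fam) {
    fam_samples <- keep_samples[!is.na(fam_of[keep_samples])]
    carrier <- fam_samples[which(geno[fam_samples, v] > 0)]
    fams <- unique(fam_of[carrier])
    if (length(fams) < 3L) {  # ensure it fails: plant carriers in 2 families only
      two <- utils::head(unique(stats::na.omit(fam_of[fam_samples])), 2L)
      geno[carrier, v] <- 0L
      for (f in two) {
        s <- fam_samples[fam_of[fam_samples] == f][1L]
        geno[s, v] <- 1L
      }
    } else {
      drop_fams <- utils::tail(fams, -2L)
      geno[carrier[fam_of[carrier] %in% drop_fams], v] <- 0L
    }
  }
  list(geno = geno,
       truth = list(samples = fail_samples,
                    variants = list(callrate = v_call, control_freq = v_freq,
                                    family = v_fam)))
}
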