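#' Simulate a complete synthetic family-WES study
#'
#' Convenience wrapper tying the generators together: pedigrees, per-variant
#' gene-dropped haplotype maps, planted risk variants, background variants
#' engineered to fail specific cascade stages, reference panels, proband
#' choices and per-sample metadata. The result feeds [run_cascade()]
#' directly and carries the full ground truth for testing.
#'
#' Background variants come in three classes: `common` (population
#' frequency above the 2% ceiling), `benign` (rare missense with tolerated/
#' benign predictions), and `low_ratio` (rare, damaging, but present in too
#' few families and not enriched).
#'
#' @param spec a [simulation_spec()]
#' @param n_background number of background variants per class
#' @param seed integer seed (defaults to `spec$seed`)
#' @return list of class `synthetic_study` with elements `peds`, `variants`
#'   (annotations), `geno` (family-member matrix), `panels`, `hap_maps`
#'   (per planted variant), `sample_info`, `probands`, `truth` (planted
#'   carrier truth and per-variant expected cascade fate)
#' @export
simulate_study <- function(spec = simulation_spec(), n_background = 30,
                           seed = spec$seed) {
  set.seed(seed)
  peds <- generate_families(spec, seed = seed)
  members <- do.call(rbind, lapply(peds, function(p) {
    data.frame(sample_id = p$id, family_id = family_id(p),
               affected = p$affected, wes = p$wes, sex = p$sex,
               european = isTRUE(attr(p, "european")),
               status = NA_character_, stringsAsFactors = FALSE)
  }))
  rownames(members) <- NULL

  plant_seeds <- sample.int(2^30, length(spec$planted_variants) + 3L * n_background)
  planted <- lapply(seq_along(spec$planted_variants), function(i) {
    plant_risk_variant(peds, spec$planted_variants[[i]], seed = plant_seeds[i])
  })
  variants <- do.call(rbind, lapply(planted, `[[`, "variant"))
  geno <- do.call(cbind, lapply(planted, `[[`, "genotypes"))
  colnames(geno) <- variants$id
  hap_maps <- lapply(planted, function(p) do.call(rbind, p$hap_maps))
  names(hap_maps) <- variants$id
  carrier_truth <- do.call(rbind, lapply(planted, `[[`, "truth"))
  panels <- generate_panels(spec$planted_variants, spec, seed = seed + 101L)

  # background variants, each engineered to fail one stage
  bg_rows <- list(); bg_geno <- list(); bg_panels <- list(); fate <- list()
  classes <- rep(c("common", "benign", "low_ratio"), each = n_background)
  pops <- reference_populations(spec$n_reference_populations)
  for (i in seq_along(classes)) {
    cls <- classes[i]
    id <- sprintf("BG%03d_%s", i, cls)
    af <- switch(cls, common = stats::runif(1, 0.05, 0.30), stats::runif(1, 0.002, 0.01))
    benign <- cls == "benign"
    bg_rows[[i]] <- data.frame(
      id = id, chrom = as.character(sample(1:22, 1)),
      pos = sample.int(5e7, 1), ref = "G", alt = "A",
      gene = sprintf("GENE%03d", i), consequence = "missense",
      sift_pred = if (benign) "tolerated" else "deleterious",
      sift_score = if (benign) stats::runif(1, 0.3, 0.9) else stats::runif(1, 0, 0.05),
      polyphen_pred = if (benign) "benign" else "probably",
      polyphen_score = if (benign) stats::runif(1, 0, 0.3) else stats::runif(1, 0.9, 1),
      stringsAsFactors = FALSE)
    g <- stats::setNames(integer(nrow(members)), members$sample_id)
    carrier_fams <- sample(names(peds), if (cls == "low_ratio") sample(1:2, 1) else 5L)
    for (fid in carrier_fams) {
      wes_ids <- members$sample_id[members$family_id == fid & members$wes]
      g[sample(wes_ids, 1L)] <- 1L
    }
    if (cls == "common") {  # common variants are carried widely
      extra <- sample(members$sample_id, round(0.2 * nrow(members)))
      g[extra] <- 1L
    }
    bg_geno[[i]] <- g
    bg_panels[[i]] <- data.frame(variant_id = id, population = pops,
                                 af = pmin(af * stats::runif(length(pops), 0.8, 1.2), 1),
                                 stringsAsFactors = FALSE)
    fate[[i]] <- data.frame(variant_id = id, class = cls,
                            fails_at = switch(cls, common = "population_frequency",
                                              benign = "impact", "enrichment"),
                            stringsAsFactors = FALSE)
  }
  variants <- rbind(variants, do.call(rbind, bg_rows))
  geno <- cbind(geno, do.call(cbind, bg_geno))
  colnames(geno) <- variants$id
  panels <- rbind(panels, do.call(rbind, bg_panels))

  probands <- vapply(peds[vapply(peds, function(p) isTRUE(attr(p, "european")), logical(1))],
                     function(p) {
                       wes <- p$id[p$wes & p$affected]
                       ord <- order(!(p$aggressive[match(wes, p$id)] %in% TRUE),
                                    !(p$dx_age[match(wes, p$id)] <= 65), wes)
                       wes[ord[1L]]
                     }, character(1))

  structure(list(peds = peds, variants = variants, geno = geno,
                 panels = panels, hap_maps = hap_maps,
                 sample_info = members, probands = unname(probands),
                 truth = list(carriers = carrier_truth,
                              planted_ids = vapply(spec$planted_variants, `[[`, "", "id"),
                              background = do.call(rbind, fate)),
                 spec = spec, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic family-WES study: %d families, %d variants (%d planted), %d samples\n",
              length(x$peds), nrow(x$variants), length(x$truth$planted_ids),
              nrow(x$geno)))
  invisible(x)
}

#' Run configuration for the prioritization cascade
#'
#' Collects thresholds, policy switches and the seed in one validated
#' object. Thresholds default to the published cascade values.
#'
#' @param pop_freq_max population-frequency ceiling (inclusive)
#' @param ratio_min minimum frequency ratio (inclusive)
#' @param fam_min minimum segregating families (inclusive)
#' @param criteria a [selection_criteria()] object
#' @param ratio_policy European-reference denominator policy ("max" or
#'   "first_available")
#' @param inconsistent_policy carrier-inference handling of inconsistent
#'   families ("union" or "drop")
#' @param fisher_mode Fisher convention for stratified fallbacks
#' @param seed integer seed for simulation-backed runs
#' @return list of class `run_config`
#' @export
run_config <- function(pop_freq_max = 0.02, ratio_min = 2, fam_min = 3,
                       criteria = selection_criteria(),
                       ratio_policy = c("max", "first_available"),
                       inconsistent_policy = c("union", "drop"),
                       fisher_mode = "point",
                       seed = 1L) {
  stopifnot(pop_freq_max > 0, pop_freq_max <= 1, ratio_min >= 0, fam_min >= 0)
  structure(list(pop_freq_max = pop_freq_max, ratio_min = ratio_min,
                 fam_min = fam_min, criteria = criteria,
                 ratio_policy = match.arg(ratio_policy),
                 inconsistent_policy = match.arg(inconsistent_policy),
                 fisher_mode = fisher_mode, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full prioritization cascade
#'
#' Executes the filtering cascade on a study: population-frequency filter,
#' protein-impact filter, frequency-ratio/segregation enrichment, carrier-
#' bound inference and four-criterion selection; returns per-stage counts,
#' the per-variant metric table and a reproducibility manifest.
#'
#' @param study a `synthetic_study` (from [simulate_study()]) or a list with
#'   the same elements built from real inputs
#' @param config a [run_config()]
#' @return object of class `cascade_result`: `stage_counts` (named integer
#'   vector), `selection` (metric table with criterion flags), `enrichment`,
#'   `carrier_summaries`, `manifest`
#' @export
run_cascade <- function(study, config = run_config()) {
  v0 <- study$variants
  if (nrow(v0) == 0L) {
    return(structure(list(stage_counts = c(input = 0L, population_frequency = 0L,
                                           impact = 0L, enrichment = 0L, selected = 0L),
                          selection = NULL, enrichment = NULL,
                          carrier_summaries = NULL,
                          manifest = cascade_manifest(config)),
                     class = "cascade_result"))
  }
  v1 <- population_frequency_filter(v0, study$panels, threshold = config$pop_freq_max)
  v2 <- impact_filter(v1)
  enr <- enrichment_stage(v2, study$geno, study$panels, study$sample_info,
                          study$probands, ratio_min = config$ratio_min,
                          fam_min = config$fam_min, policy = config$ratio_policy)
  v3_ids <- enr$variant_id[enr$retained]
  summaries <- if (length(v3_ids)) {
    infer_carrier_summaries(v3_ids, study$geno, study$peds,
                            study$hap_maps[v3_ids],
                            inconsistent = config$inconsistent_policy)
  }
  metrics <- if (!is.null(summaries)) {
    merge(enr[enr$retained, c("variant_id", "frequency_ratio",
                              "n_segregating_families")],
          summaries[, c("variant_id", "min_avg", "max_avg")],
          by = "variant_id")
  }
  sel <- if (!is.null(metrics) && nrow(metrics)) select_candidates(metrics, config$criteria)
  stage_counts <- c(input = nrow(v0), population_frequency = nrow(v1),
                    impact = nrow(v2), enrichment = length(v3_ids),
                    selected = if (is.null(sel)) 0L else sum(sel$selected))
  structure(list(stage_counts = stage_counts, selection = sel,
                 enrichment = enr, carrier_summaries = summaries,
                 manifest = cascade_manifest(config)),
            class = "cascade_result")
}

cascade_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$criteria <- unclass(cfg$criteria)
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(json, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  list(config = cfg, config_md5 = hash, seed = config$seed,
       package_version = as.character(utils::packageVersion("famvarsel")),
       r_version = R.version.string, timestamp = format(Sys.time(), tz = "UTC"))
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Variant prioritization cascade\n")
  for (nm in names(x$stage_counts)) {
    cat(sprintf("  %-22s %6d\n", nm, x$stage_counts[[nm]]))
  }
  if (!is.null(x$selection)) {
    rep <- attr(x$selection, "report")
    cat(sprintf("  criteria: many-families %d, ratio+carrier %d, min-avg %d, max-avg %d (multiple %d)\n",
                rep$n_per_criterion[1], rep$n_per_criterion[2],
                rep$n_per_criterion[3], rep$n_per_criterion[4], rep$n_multiple))
  }
  invisible(x)
}

#' Run the case-control validation arm
#'
#' Per-study dominant-model regressions with fixed-effect meta-analysis
#' across studies for each candidate variant, flagging risk-increasing
#' significant variants as confirmed; optional family-history and
#' aggressiveness stratified analyses and a risk-allele score over the
#' confirmed variants.
#'
#' @param cohort cohort data.frame (see [generate_cohort()])
#' @param variants character vector of carrier column names to test
#' @param covariates adjustment covariates (default age)
#' @param alpha significance level for confirmation (default 0.05)
#' @param stratify run the stratified analyses for confirmed variants
#' @return object of class `validation_result`: `overall` (per-study and
#'   meta rows per variant, with `confirmed` flags on meta rows),
#'   `confirmed` (variant ids), `risk_score`, `family_history`,
#'   `aggressiveness`
#' @export
run_validation <- function(cohort, variants, covariates = "age", alpha = 0.05,
                           stratify = TRUE) {
  studies <- unique(cohort$study)
  rows <- list()
  for (v in variants) {
    fits <- list()
    for (s in studies) {
      fit <- tryCatch(
        logistic_dominant(cohort[cohort$study == s, , drop = FALSE], v, covariates),
        error = function(e) NULL)
      if (!is.null(fit)) { fit$study <- s; fits[[s]] <- fit }
    }
    rows <- c(rows, fits)
    if (length(fits) > 1L) {
      meta <- meta_fixed(vapply(fits, function(f) f$or, numeric(1)),
                         vapply(fits, function(f) f$ci_low, numeric(1)),
                         vapply(fits, function(f) f$ci_high, numeric(1)))
      meta$variant <- v
      rows <- c(rows, list(meta))
    } else if (length(fits) == 1L) {
      meta <- fits[[1L]]; meta$study <- "meta"
      rows <- c(rows, list(meta))
    }
  }
  overall <- do.call(rbind, rows)
  rownames(overall) <- NULL
  class(overall) <- c("assoc_result", "data.frame")
  meta_rows <- overall[overall$study == "meta", , drop = FALSE]
  confirmed <- meta_rows$variant[meta_rows$or > 1 & meta_rows$p < alpha]
  overall$confirmed <- overall$study == "meta" & overall$variant %in% confirmed

  fh <- aggr <- NULL
  if (stratify && length(confirmed)) {
    fh <- do.call(rbind, lapply(confirmed, function(v)
      stratified_analysis(cohort, v, "family_history", covariates)))
    aggr <- do.call(rbind, lapply(confirmed, function(v)
      stratified_analysis(cohort, v, "aggressiveness", covariates)))
  }
  rs <- if (length(confirmed) >= 1L) genetic_risk_score(cohort, confirmed, covariates)
  structure(list(overall = overall, confirmed = confirmed, risk_score = rs,
                 family_history = fh, aggressiveness = aggr),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("Case-control validation: %d variants tested, %d confirmed risk-increasing\n",
              length(unique(x$overall$variant)), length(x$confirmed)))
  if (length(x$confirmed)) cat("  confirmed:", paste(x$confirmed, collapse = ", "), "\n")
  invisible(x)
}
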