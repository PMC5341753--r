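#' @name variant_filtering
#' @title Population-frequency and protein-impact filtering
#'
#' @description The upper half of the prioritization cascade. Variants are a
#' data.frame of annotations (one row per variant: `id`, `chrom`, `pos`,
#' `ref`, `alt`, `gene`, `consequence`, `sift_pred`, `sift_score`,
#' `polyphen_pred`, `polyphen_score`); genotypes travel separately as an
#' integer matrix (samples x variants, alternate-allele counts, NA =
#' missing); reference panels are a long table (`variant_id`, `population`,
#' `af`).
NULL

high_impact_consequences <- c("stop_gained", "stop_lost", "start_lost",
                              "frameshift", "splice_site")

#' Filter variants on reference-panel population frequency
#'
#' Retains variants whose alternate-allele frequency is at or below the
#' threshold in every population where a frequency exists. Absence from a
#' panel is a vacuous pass (a rare variant missing from a panel cannot fail
#' it); variants absent from all panels are retained and counted in the
#' report for transparency.
#'
#' @param variants variant annotation data.frame (see [variant_filtering])
#' @param panels long data.frame (`variant_id`, `population`, `af`)
#' @param threshold inclusive frequency ceiling, default 0.02
#' @return retained subset of `variants`, with a `report` attribute listing
#'   input/output counts, removed ids, and ids passing vacuously
#' @export
population_frequency_filter <- function(variants, panels, threshold = 0.02) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  max_af <- tapply(panels$af, panels$variant_id, max)
  m <- max_af[variants$id]
  keep <- is.na(m) | m <= threshold
  out <- variants[keep, , drop = FALSE]
  attr(out, "report") <- list(
    stage = "population_frequency", n_in = nrow(variants), n_out = sum(keep),
    removed = variants$id[!keep],
    vacuous_pass = variants$id[!variants$id %in% panels$variant_id])
  out
}

#' Filter variants on predicted protein impact
#'
#' High-impact consequences (stop gained/lost, start lost, frameshift,
#' splice site) pass unconditionally; missense variants pass if SIFT calls
#' them deleterious and/or PolyPhen2 calls them probably or possibly
#' damaging; everything else is removed. Missense variants with neither
#' prediction available are removed and counted separately in the report.
#'
#' @inheritParams population_frequency_filter
#' @return retained subset with a `report` attribute
#' @export
impact_filter <- function(variants) {
  high <- variants$consequence %in% high_impact_consequences
  missense <- variants$consequence == "missense"
  damaging <- (variants$sift_pred %in% "deleterious") |
    (variants$polyphen_pred %in% c("probably", "possibly"))
  unannotated <- missense & is.na(variants$sift_pred) & is.na(variants$polyphen_pred)
  keep <- high | (missense & damaging & !unannotated)
  out <- variants[keep, , drop = FALSE]
  attr(out, "report") <- list(
    stage = "impact", n_in = nrow(variants), n_out = sum(keep),
    removed = variants$id[!keep],
    missense_unannotated = variants$id[unannotated])
  out
}

#' Observed alternate-allele frequency among family probands
#'
#' One affected man per family of European ancestry serves as proband; the
#' observed frequency is the alternate-allele count over twice the number of
#' probands with a non-missing call.
#'
#' @param geno samples x variants integer matrix (0/1/2, NA missing)
#' @param probands character vector of proband sample ids (rows of `geno`)
#' @return named numeric vector over variants; NA (flagged via the
#'   `all_missing` attribute) where every proband call is missing
#' @export
observed_frequency <- function(geno, probands) {
  stopifnot(all(probands %in% rownames(geno)))
  g <- geno[probands, , drop = FALSE]
  called <- colSums(!is.na(g))
  af <- colSums(g, na.rm = TRUE) / (2 * called)
  af[called == 0] <- NA_real_
  structure(af, all_missing = colnames(geno)[called == 0])
}

#' Frequency ratio against European reference panels
#'
#' The enrichment statistic: observed proband allele frequency divided by
#' the European reference frequency. The default denominator policy takes
#' the maximum of the available European panel frequencies (conservative:
#' it minimizes the ratio); `"first_available"` uses the first European
#' panel carrying the variant. Variants absent from every European panel
#' get an infinite ratio (they pass any finite threshold) and are flagged.
#'
#' @param observed_af named numeric vector from [observed_frequency()]
#' @param panels long panel data.frame
#' @param european labels of the European reference panels
#' @param policy denominator policy, `"max"` (default) or `"first_available"`
#' @return named numeric vector of ratios (possibly `Inf`), with attribute
#'   `no_reference` listing variants absent from all European panels
#' @export
frequency_ratio <- function(observed_af, panels,
                            european = c("ESP_EA", "KG_EUR"),
                            policy = c("max", "first_available")) {
  policy <- match.arg(policy)
  eu <- panels[panels$population %in% european, , drop = FALSE]
  ref <- vapply(names(observed_af), function(v) {
    sub <- eu[eu$variant_id == v, , drop = FALSE]
    if (!nrow(sub)) return(NA_real_)
    if (policy == "max") return(max(sub$af))
    sub$af[order(match(sub$population, european))][1L]
  }, numeric(1))
  ratio <- ifelse(is.na(ref) | ref == 0, Inf, observed_af / ref)
  ratio[is.na(observed_af)] <- NA_real_
  structure(stats::setNames(ratio, names(observed_af)),
            reference_af = ref,
            no_reference = names(observed_af)[is.na(ref)])
}

#' Count families segregating each variant
#'
#' A family segregates a variant when at least one of its exome-sequenced
#' affected men carries the alternate allele.
#'
#' @param geno samples x variants matrix
#' @param sample_info data.frame with `sample_id`, `family_id`, `affected`,
#'   `wes` covering (at least) the rows of `geno`
#' @return named integer vector over variants
#' @export
segregating_families <- function(geno, sample_info) {
  wes_aff <- sample_info$sample_id[sample_info$wes & sample_info$affected &
                                     !is.na(sample_info$family_id)]
  wes_aff <- intersect(wes_aff, rownames(geno))
  fam <- sample_info$family_id[match(wes_aff, sample_info$sample_id)]
  apply(geno[wes_aff, , drop = FALSE], 2L, function(g) {
    length(unique(fam[!is.na(g) & g > 0]))
  })
}

#' Frequency-ratio enrichment stage
#'
#' Computes observed proband frequency, frequency ratio, and segregating
#' family count for each variant and retains those with ratio >= `ratio_min`
#' segregating in >= `fam_min` families (both thresholds inclusive).
#'
#' @inheritParams frequency_ratio
#' @param variants annotation data.frame (post population/impact filters)
#' @param geno samples x variants matrix
#' @param sample_info per-sample metadata (see [segregating_families()])
#' @param probands proband sample ids for [observed_frequency()]
#' @param ratio_min,fam_min inclusive retention thresholds
#' @return data.frame (`variant_id`, `observed_af`, `reference_af`,
#'   `frequency_ratio`, `n_segregating_families`, `retained`) with a
#'   `report` attribute of stage counts
#' @export
enrichment_stage <- function(variants, geno, panels, sample_info, probands,
                             ratio_min = 2, fam_min = 3,
                             european = c("ESP_EA", "KG_EUR"),
                             policy = "max") {
  g <- geno[, variants$id, drop = FALSE]
  af <- observed_frequency(g, probands)
  fr <- frequency_ratio(af, panels, european = european, policy = policy)
  nf <- segregating_families(g, sample_info)
  retained <- !is.na(fr) & fr >= ratio_min & nf >= fam_min
  res <- data.frame(variant_id = variants$id,
                    observed_af = as.numeric(af),
                    reference_af = as.numeric(attr(fr, "reference_af")),
                    frequency_ratio = as.numeric(fr),
                    n_segregating_families = as.integer(nf),
                    retained = retained,
                    stringsAsFactors = FALSE)
  attr(res, "report") <- list(stage = "enrichment", n_in = nrow(variants),
                              n_out = sum(retained),
                              no_reference = attr(fr, "no_reference"))
  res
}
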