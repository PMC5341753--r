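#' Selection criteria for the follow-up panel
#'
#' The four-criterion union used to pick candidates for follow-up
#' genotyping: (1) segregation in many families; (2) high frequency ratio
#' with a material maximum average carrier frequency; (3) high minimum
#' average carrier frequency (the true average can only be higher); (4) very
#' high maximum average carrier frequency. All thresholds are inclusive.
#'
#' @param fam_min_many families threshold for criterion 1 (default 6)
#' @param ratio_high frequency-ratio threshold for criterion 2 (default 4)
#' @param ratio_high_max_avg maximum average carrier frequency (percent)
#'   accompanying criterion 2 (default 40)
#' @param min_avg_min minimum average carrier frequency (percent) for
#'   criterion 3 (default 50)
#' @param max_avg_min maximum average carrier frequency (percent) for
#'   criterion 4 (default 67)
#' @return list of class `selection_criteria`
#' @export
selection_criteria <- function(fam_min_many = 6, ratio_high = 4,
                               ratio_high_max_avg = 40, min_avg_min = 50,
                               max_avg_min = 67) {
  structure(list(fam_min_many = fam_min_many, ratio_high = ratio_high,
                 ratio_high_max_avg = ratio_high_max_avg,
                 min_avg_min = min_avg_min, max_avg_min = max_avg_min),
            class = "selection_criteria")
}

#' Select candidate variants by the four-criterion union
#'
#' @param metrics data.frame with one row per variant and columns
#'   `variant_id`, `frequency_ratio`, `n_segregating_families`, `min_avg`,
#'   `max_avg` (the join of the enrichment results and carrier summaries)
#' @param criteria a [selection_criteria()] object
#' @return `metrics` augmented with logical columns `crit_many_families`,
#'   `crit_ratio_carrier`, `crit_min_avg`, `crit_max_avg` and `selected`;
#'   attribute `report` carries per-criterion counts, the count of variants
#'   meeting more than one criterion, and the union size
#' @export
select_candidates <- function(metrics, criteria = selection_criteria()) {
  needed <- c("variant_id", "frequency_ratio", "n_segregating_families",
              "min_avg", "max_avg")
  miss <- setdiff(needed, names(metrics))
  if (length(miss)) stop("metrics is missing columns: ", paste(miss, collapse = ", "))
  # Inf ratios are legitimate (variant absent from reference panels); NA is not
  incomplete <- apply(metrics[, c("n_segregating_families", "min_avg", "max_avg")],
                      1L, anyNA) | is.na(metrics$frequency_ratio)
  if (any(incomplete)) {
    warning(sum(incomplete), " variant(s) with missing metrics excluded from selection")
  }
  m <- metrics
  m$crit_many_families <- !incomplete & m$n_segregating_families >= criteria$fam_min_many
  m$crit_ratio_carrier <- !incomplete & m$frequency_ratio >= criteria$ratio_high &
    m$max_avg >= criteria$ratio_high_max_avg
  m$crit_min_avg <- !incomplete & m$min_avg >= criteria$min_avg_min
  m$crit_max_avg <- !incomplete & m$max_avg >= criteria$max_avg_min
  flags <- as.matrix(m[, c("crit_many_families", "crit_ratio_carrier",
                           "crit_min_avg", "crit_max_avg")])
  m$selected <- rowSums(flags) >= 1L
  attr(m, "report") <- list(
    n_per_criterion = colSums(flags),
    n_multiple = sum(rowSums(flags) >= 2L),
    n_selected = sum(m$selected),
    n_excluded_missing = sum(incomplete))
  m
}

#' Gene-list alternate filter
#'
#' The companion filter to the family-based cascade: retain variants that
#' are rare in every reference population (strictly below the threshold),
#' have a high-impact consequence, and fall in a supplied gene list
#' (e.g. a cancer gene census), regardless of how many families segregate
#' them.
#'
#' @param variants variant annotation data.frame
#' @param gene_list character vector of gene symbols
#' @param panels long panel data.frame (`variant_id`, `population`, `af`)
#' @param af_threshold strict population-frequency ceiling (default 0.02)
#' @return subset of `variants`
#' @export
gene_list_filter <- function(variants, gene_list, panels, af_threshold = 0.02) {
  if (!length(gene_list)) return(variants[0, , drop = FALSE])
  max_af <- tapply(panels$af, panels$variant_id, max)
  m <- max_af[variants$id]
  rare <- is.na(m) | m < af_threshold
  keep <- rare & variants$consequence %in% high_impact_consequences &
    variants$gene %in% gene_list
  variants[keep, , drop = FALSE]
}
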