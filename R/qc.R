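#' Sample-level genotyping quality control
#'
#' Removes samples whose call rate is strictly below the threshold. A call
#' rate of exactly the threshold is retained.
#'
#' @param geno samples x variants integer matrix (NA = missing call)
#' @param call_rate_min minimum acceptable call rate (default 0.70)
#' @return list: `geno` (retained rows), `removed` (sample ids), `report`
#'   (call rates of removed samples)
#' @export
sample_qc <- function(geno, call_rate_min = 0.70) {
  stopifnot(is.matrix(geno), nrow(geno) > 0)
  rate <- rowMeans(!is.na(geno))
  removed <- rownames(geno)[rate < call_rate_min]
  list(geno = geno[!rownames(geno) %in% removed, , drop = FALSE],
       removed = removed,
       report = data.frame(sample_id = removed, call_rate = rate[removed],
                           stringsAsFactors = FALSE))
}

#' Variant-level genotyping quality control
#'
#' Applies the three post-genotyping variant filters in order: call rate
#' strictly below `call_rate_min`; carrier frequency among controls
#' strictly above `control_freq_max`; present (at least one genotyped
#' carrier) in fewer than `fam_min` families. Each removed variant is
#' attributed to the first rule it fails, so per-rule counts partition the
#' removals; membership of the removed set itself does not depend on rule
#' order.
#'
#' @param geno samples x variants matrix (after [sample_qc()])
#' @param sample_info data.frame with `sample_id`, `family_id` (NA for
#'   cohort members), `status` ("case"/"control"/NA)
#' @param call_rate_min minimum variant call rate (default 0.70)
#' @param control_freq_max maximum control carrier frequency (default 0.02)
#' @param fam_min minimum number of families carrying the variant (default 3)
#' @return list: `geno` (retained columns), `removed` (named character:
#'   variant id -> rule), `report` (per-rule counts)
#' @export
variant_qc <- function(geno, sample_info, call_rate_min = 0.70,
                       control_freq_max = 0.02, fam_min = 3) {
  info <- sample_info[match(rownames(geno), sample_info$sample_id), , drop = FALSE]
  controls <- rownames(geno)[info$status %in% "control"]
  rule <- character(0)
  for (v in colnames(geno)) {
    g <- geno[, v]
    if (mean(!is.na(g)) < call_rate_min) {
      rule[v] <- "call_rate"
      next
    }
    gc <- g[controls]
    co_freq <- if (length(controls)) mean(gc > 0, na.rm = TRUE) else 0
    if (!is.nan(co_freq) && co_freq > control_freq_max) {
      rule[v] <- "control_frequency"
      next
    }
    fam <- info$family_id
    carrier_fams <- unique(fam[!is.na(fam) & !is.na(g) & g > 0])
    if (length(carrier_fams) < fam_min) rule[v] <- "family_count"
  }
  report <- data.frame(
    rule = c("call_rate", "control_frequency", "family_count"),
    n_removed = c(sum(rule == "call_rate"), sum(rule == "control_frequency"),
                  sum(rule == "family_count")),
    stringsAsFactors = FALSE)
  list(geno = geno[, !colnames(geno) %in% names(rule), drop = FALSE],
       removed = rule, report = report)
}

#' Genotype concordance between two call sets
#'
#' Fraction of jointly non-missing calls that agree, e.g. between two
#' genotyping platforms run on the same samples.
#'
#' @param calls_a,calls_b equally shaped matrices or vectors of genotype
#'   calls (NA = missing)
#' @return fraction in [0, 1]
#' @export
concordance <- function(calls_a, calls_b) {
  stopifnot(length(calls_a) == length(calls_b))
  joint <- !is.na(calls_a) & !is.na(calls_b)
  if (!any(joint)) stop("no jointly non-missing calls; concordance undefined")
  mean(calls_a[joint] == calls_b[joint])
}
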