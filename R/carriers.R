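#' @name carrier_inference
#' @title Haplotype-based affected-carrier frequency bounds
#'
#' @description The core of the prioritization method. Within each family
#' the alternate allele observed in exome-sequenced carriers is assigned to
#' one or two candidate founder haplotypes; counting, over all affected men
#' on the family roster (genotyped or not), how many carry a candidate
#' haplotype yields a minimum and maximum possible affected-carrier
#' fraction. Averaging the per-family bounds across carrier families gives
#' the minimum/maximum average carrier frequency used for candidate
#' selection. A haplotype map is a data.frame with columns `family_id`,
#' `individual_id`, `hap1`, `hap2` holding founder-haplotype labels at the
#' variant locus (the output format of [gene_drop()]).
NULL

#' Candidate carrier haplotypes for one family
#'
#' Intersects the haplotype label pairs of the family's sequenced affected
#' carriers. A single shared label resolves the carrier haplotype; a single
#' carrier (or carriers sharing both labels) leaves two candidates; an empty
#' intersection is inconsistent (e.g. recombination or two mutational
#' origins), in which case the union of the carriers' labels is returned
#' with a warning. Homozygous carriers contribute both labels.
#'
#' @param ped a `pedigree`
#' @param genotypes named 0/1/2 vector (NA missing) for this variant,
#'   covering at least the family's sequenced members
#' @param hap_map haplotype map data.frame (may span several families)
#' @return list with `labels` (character), `status` ("resolved",
#'   "ambiguous" or "inconsistent")
#' @export
candidate_haplotypes <- function(ped, genotypes, hap_map) {
  hm <- hap_map[hap_map$family_id == family_id(ped), , drop = FALSE]
  wes_carriers <- ped$id[ped$wes & ped$affected &
                           ped$id %in% names(genotypes) &
                           !is.na(genotypes[ped$id]) & genotypes[ped$id] > 0]
  if (!length(wes_carriers)) {
    stop("no sequenced affected carrier in family ", family_id(ped))
  }
  pairs <- lapply(wes_carriers, function(i) {
    j <- match(i, hm$individual_id)
    if (is.na(j)) stop("sequenced carrier ", i, " missing from haplotype map")
    unique(c(hm$hap1[j], hm$hap2[j]))
  })
  labels <- Reduce(intersect, pairs)
  if (!length(labels)) {
    warning(sprintf("family %s: carrier haplotypes are inconsistent; using union",
                    family_id(ped)))
    return(list(labels = sort(unique(unlist(pairs))), status = "inconsistent"))
  }
  list(labels = sort(labels),
       status = if (length(labels) == 1L) "resolved" else "ambiguous")
}

#' Per-family affected-carrier bounds
#'
#' For each candidate haplotype, counts how many affected men on the family
#' roster carry it; the smallest and largest counts bound the number of
#' affected carriers. The bounds coincide when the carrier haplotype is
#' resolved. Affected men absent from the haplotype map are excluded from
#' the numerator but (by default) kept in the denominator, with a warning.
#'
#' @param ped a `pedigree`
#' @param candidates result of [candidate_haplotypes()] (or a list with a
#'   `labels` element)
#' @param hap_map haplotype map data.frame
#' @param keep_unmapped_in_denominator keep affected men without haplotype
#'   data in the roster denominator (default TRUE)
#' @return one-row data.frame of class `carrier_bounds`: `family_id`,
#'   `candidates`, `status`, `min_count`, `max_count`, `n_affected`,
#'   `min_frac`, `max_frac`
#' @export
family_carrier_bounds <- function(ped, candidates, hap_map,
                                  keep_unmapped_in_denominator = TRUE) {
  labels <- candidates$labels
  stopifnot(length(labels) >= 1L)
  hm <- hap_map[hap_map$family_id == family_id(ped), , drop = FALSE]
  roster <- ped$id[ped$affected & ped$sex == "male"]
  mapped <- roster[roster %in% hm$individual_id]
  if (length(mapped) < length(roster)) {
    warning(sprintf("family %s: %d affected men lack haplotype data",
                    family_id(ped), length(roster) - length(mapped)))
    if (!keep_unmapped_in_denominator) roster <- mapped
  }
  counts <- vapply(labels, function(h) {
    j <- match(mapped, hm$individual_id)
    sum(hm$hap1[j] == h | hm$hap2[j] == h)
  }, numeric(1))
  n <- length(roster)
  out <- data.frame(family_id = family_id(ped),
                    candidates = paste(labels, collapse = ","),
                    status = if (!is.null(candidates$status)) candidates$status else NA_character_,
                    min_count = min(counts), max_count = max(counts),
                    n_affected = n,
                    min_frac = min(counts) / n, max_frac = max(counts) / n,
                    stringsAsFactors = FALSE)
  class(out) <- c("carrier_bounds", "data.frame")
  out
}

#' Average carrier frequency across carrier families
#'
#' Unweighted arithmetic means of the per-family minimum and maximum
#' affected-carrier fractions, reported as percentages.
#'
#' @param variant_id variant identifier
#' @param bounds a data.frame of stacked [family_carrier_bounds()] rows
#' @return one-row data.frame of class `carrier_summary`: `variant_id`,
#'   `n_carrier_families`, `min_avg`, `max_avg` (percent, 1 decimal)
#' @export
average_carrier_frequency <- function(variant_id, bounds) {
  if (is.null(bounds) || nrow(bounds) == 0L) {
    stop("no carrier families for variant ", variant_id)
  }
  out <- data.frame(variant_id = variant_id,
                    n_carrier_families = nrow(bounds),
                    min_avg = round(100 * mean(bounds$min_frac), 1),
                    max_avg = round(100 * mean(bounds$max_frac), 1),
                    stringsAsFactors = FALSE)
  class(out) <- c("carrier_summary", "data.frame")
  out
}

#' Genotyped carrier counts among family members
#'
#' Direct counts of affected and unaffected genotyped carriers after
#' follow-up genotyping of all family members with DNA.
#'
#' @param genotypes named 0/1/2 vector (NA missing) for one variant
#' @param sample_info data.frame with `sample_id`, `family_id`, `affected`
#' @return integer vector `c(n_affected_carriers, n_unaffected_carriers)`
#' @export
genotyped_carrier_counts <- function(genotypes, sample_info) {
  fam <- sample_info[!is.na(sample_info$family_id), , drop = FALSE]
  g <- genotypes[fam$sample_id]
  carrier <- !is.na(g) & g > 0
  c(n_affected_carriers = sum(carrier & fam$affected),
    n_unaffected_carriers = sum(carrier & !fam$affected))
}

#' Carrier-bound inference for a set of variants
#'
#' Runs [candidate_haplotypes()] and [family_carrier_bounds()] in every
#' family segregating each variant and averages the bounds into a
#' per-variant carrier summary.
#'
#' @param variant_ids character vector of variant ids (columns of `geno`)
#' @param geno samples x variants matrix over family members
#' @param peds named list of `pedigree` objects
#' @param hap_maps one combined haplotype-map data.frame shared by all
#'   variants, a list named by variant id (one map per variant locus), or a
#'   list of per-family maps to be combined
#' @param inconsistent "union" (default) keeps inconsistent families with
#'   union-based bounds; "drop" excludes them
#' @return data.frame, one row per variant (`variant_id`,
#'   `n_carrier_families`, `min_avg`, `max_avg`) with the per-family bounds
#'   in attribute `bounds`
#' @export
infer_carrier_summaries <- function(variant_ids, geno, peds, hap_maps,
                                    inconsistent = c("union", "drop")) {
  inconsistent <- match.arg(inconsistent)
  per_variant <- !is.data.frame(hap_maps) &&
    all(variant_ids %in% names(hap_maps))
  all_bounds <- list()
  rows <- lapply(variant_ids, function(v) {
    hap_map <- if (is.data.frame(hap_maps)) hap_maps else
      if (per_variant) hap_maps[[v]] else do.call(rbind, hap_maps)
    g <- geno[, v]
    fam_bounds <- list()
    for (fid in names(peds)) {
      ped <- peds[[fid]]
      wes_ids <- ped$id[ped$wes & ped$affected]
      gv <- g[intersect(wes_ids, names(g))]
      if (!any(!is.na(gv) & gv > 0)) next
      cand <- candidate_haplotypes(ped, g, hap_map)
      if (cand$status == "inconsistent" && inconsistent == "drop") next
      fam_bounds[[fid]] <- family_carrier_bounds(ped, cand, hap_map)
    }
    if (!length(fam_bounds)) {
      return(data.frame(variant_id = v, n_carrier_families = 0L,
                        min_avg = NA_real_, max_avg = NA_real_,
                        stringsAsFactors = FALSE))
    }
    bounds <- do.call(rbind, fam_bounds)
    all_bounds[[v]] <<- bounds
    average_carrier_frequency(v, bounds)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bounds") <- all_bounds
  out
}
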