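#' Read a long reference-panel table
#'
#' @param path TSV with columns `variant_id`, `population`, `af`
#' @return data.frame
#' @export
read_panels <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "population", "af") %in% names(out)),
            all(out$af >= 0 & out$af <= 1))
  out
}

#' Read a haplotype map
#'
#' @param path TSV with columns `family_id`, `individual_id`, `hap1`, `hap2`
#' @return data.frame
#' @export
read_hap_map <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("family_id", "individual_id", "hap1", "hap2") %in% names(out)))
  out
}

#' Read a case-control cohort table
#'
#' @param path TSV with `subject_id`, `study`, `status`, `age`,
#'   `family_history`, `aggressiveness` and one 0/1 carrier column per
#'   variant
#' @return data.frame
#' @export
read_cohort <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("subject_id", "study", "status", "age") %in% names(out)),
            all(out$status %in% c("case", "control")))
  out
}

#' Write a TSV report
#'
#' @param x data.frame
#' @param path output path
#' @return invisibly, `path`
#' @export
write_report <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a simulation specification or run configuration from YAML
#'
#' The YAML file holds any subset of the constructor arguments of
#' [simulation_spec()] (for `read_simulation_spec()`) or [run_config()]
#' (for `read_run_config()`); omitted fields keep their defaults. Planted
#' variants are given as a list of argument sets for [planted_variant()];
#' selection-criteria overrides as an argument set for
#' [selection_criteria()].
#'
#' @param path YAML file path
#' @return a `simulation_spec` / `run_config`
#' @export
read_simulation_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$planted_variants)) {
    cfg$planted_variants <- lapply(cfg$planted_variants, function(pv)
      do.call(planted_variant, pv))
  }
  for (nm in c("affected_bin_weights", "age_bin_weights", "wes_bin_weights",
               "family_history")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  }
  do.call(simulation_spec, cfg)
}

#' @rdname read_simulation_spec
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$criteria)) cfg$criteria <- do.call(selection_criteria, cfg$criteria)
  do.call(run_config, cfg)
}

#' Read variants and genotypes from a VCF
#'
#' Uses vcfR to parse the VCF; annotations (gene, consequence, SIFT and
#' PolyPhen fields) are supplied as a sidecar TSV keyed by variant id
#' `chrom:pos`, since consequence arbitration is upstream of this package.
#'
#' @param path VCF path
#' @param annotations optional sidecar TSV path or data.frame with column
#'   `id` plus annotation columns
#' @return list: `variants` (annotation data.frame), `geno` (samples x
#'   variants alternate-allele count matrix)
#' @export
read_variants_vcf <- function(path, annotations = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_variants_vcf() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.frame(id = paste0(fix$CHROM, ":", fix$POS),
                         chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), integer(1)))
  }
  geno <- apply(gt, 2L, count_alt)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1L,
                                         dimnames = list(NULL, colnames(gt)))
  geno <- t(geno)
  colnames(geno) <- variants$id
  if (!is.null(annotations)) {
    ann <- if (is.data.frame(annotations)) annotations else
      utils::read.delim(annotations, stringsAsFactors = FALSE)
    variants <- merge(variants, ann, by = "id", all.x = TRUE, sort = FALSE)
  }
  list(variants = variants, geno = geno)
}

#' Write variants and genotypes to a VCF
#'
#' @param variants annotation data.frame (`id`, `chrom`, `pos`, `ref`, `alt`)
#' @param geno samples x variants matrix of alternate-allele counts
#' @param path output path (".vcf.gz" appended by vcfR if absent)
#' @return invisibly, the path written
#' @export
write_variants_vcf <- function(variants, geno, path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("write_variants_vcf() requires the vcfR package")
  }
  g <- geno[, variants$id, drop = FALSE]
  body <- matrix(ifelse(is.na(g), "./.", c("0/0", "0/1", "1/1")[g + 1L]),
                 nrow = nrow(g), dimnames = dimnames(g))
  gt <- cbind(FORMAT = "GT", t(body))
  fix <- cbind(CHROM = variants$chrom, POS = as.character(variants$pos),
               ID = variants$id, REF = variants$ref, ALT = variants$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  v <- methods::new("vcfR",
                    meta = c("##fileformat=VCFv4.2",
                             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
                    fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
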