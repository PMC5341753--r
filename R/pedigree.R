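#' Construct a pedigree
#'
#' A pedigree holds one extended family: individuals with parent links, sex,
#' affection status and the phenotype/bookkeeping fields used throughout the
#' prioritization pipeline (diagnosis age, disease aggressiveness, vital
#' status, whether the individual was exome-sequenced and whether DNA is
#' available for follow-up genotyping).
#'
#' Invariants enforced at construction: every non-missing parent id resolves
#' to a member; fathers are male and mothers female; the parent graph is
#' acyclic; there is at least one founder (member with both parents missing);
#' the family forms a single connected graph; only affected individuals carry
#' a diagnosis age.
#'
#' @param members data.frame with columns `id`, `father`, `mother` (NA for
#'   founders), `sex` ("male"/"female"), `affected` (logical). Optional
#'   columns `dx_age` (years, affected only), `aggressive` (logical or NA;
#'   Gleason 8-10 or regional/distant stage disease), `vital`
#'   ("alive"/"deceased"), `wes` (logical, exome-sequenced), `dna_available`
#'   (logical). Missing optional columns are filled with defaults.
#' @param family_id single string naming the family.
#' @return An object of class `pedigree`: the completed member data.frame
#'   with attribute `family_id`.
#' @examples
#' trio <- pedigree(data.frame(
#'   id = c("f", "m", "s"), father = c(NA, NA, "f"), mother = c(NA, NA, "m"),
#'   sex = c("male", "female", "male"), affected = c(TRUE, FALSE, TRUE)
#' ), family_id = "FAM1")
#' founders(trio)
#' @export
pedigree <- function(members, family_id = "FAM") {
  stopifnot(is.data.frame(members), nrow(members) >= 1L)
  req <- c("id", "father", "mother", "sex", "affected")
  miss <- setdiff(req, names(members))
  if (length(miss)) stop("members is missing columns: ", paste(miss, collapse = ", "))
  members$id <- as.character(members$id)
  members$father <- as.character(members$father)
  members$mother <- as.character(members$mother)
  if (anyDuplicated(members$id)) stop("duplicate individual ids in family ", family_id)

  defaults <- list(dx_age = NA_real_, aggressive = NA, vital = "alive",
                   wes = FALSE, dna_available = TRUE)
  for (nm in names(defaults)) {
    if (is.null(members[[nm]])) members[[nm]] <- defaults[[nm]]
  }
  members$affected <- as.logical(members$affected)
  members$wes <- as.logical(members$wes)
  members$dna_available <- as.logical(members$dna_available)

  idx <- function(x) match(x, members$id)
  for (side in c("father", "mother")) {
    p <- members[[side]]
    bad <- !is.na(p) & is.na(idx(p))
    if (any(bad)) {
      stop("unresolved ", side, " id(s) in family ", family_id, ": ",
           paste(unique(p[bad]), collapse = ", "))
    }
  }
  fa <- idx(members$father); mo <- idx(members$mother)
  if (any(!is.na(fa) & members$sex[fa] != "male", na.rm = TRUE)) {
    stop("a father is not male in family ", family_id)
  }
  if (any(!is.na(mo) & members$sex[mo] != "female", na.rm = TRUE)) {
    stop("a mother is not female in family ", family_id)
  }
  if (any((!is.na(fa) & fa == seq_len(nrow(members))) |
          (!is.na(mo) & mo == seq_len(nrow(members))))) {
    stop("self-parenting in family ", family_id)
  }
  if (is.null(topological_order(members))) stop("pedigree cycle detected in family ", family_id)
  if (!any(is.na(fa) & is.na(mo))) stop("no founder in family ", family_id)
  if (any(!is.na(members$dx_age) & !members$affected)) {
    stop("dx_age present for unaffected individual(s) in family ", family_id)
  }
  # connectivity over the undirected parent-child graph
  if (nrow(members) > 1L) {
    adj <- cbind(seq_len(nrow(members)), fa)
    adj <- rbind(adj, cbind(seq_len(nrow(members)), mo))
    adj <- adj[stats::complete.cases(adj), , drop = FALSE]
    seen <- logical(nrow(members)); queue <- 1L; seen[1L] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- c(adj[adj[, 1L] == v, 2L], adj[adj[, 2L] == v, 1L])
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (!all(seen)) stop("pedigree is not a single connected family graph: ", family_id)
  }

  rownames(members) <- NULL
  structure(members, class = c("pedigree", "data.frame"), family_id = family_id)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree %s: %d members (%d affected, %d WES, %d founders)\n",
              family_id(x), nrow(x), sum(x$affected),
              sum(x$wes), length(founders(x))))
  invisible(x)
}

#' Family id of a pedigree
#' @param ped a `pedigree`
#' @return character scalar
#' @export
family_id <- function(ped) attr(ped, "family_id")

#' Founders of a pedigree
#' @param ped a `pedigree`
#' @return character vector of ids of members with both parents missing
#' @export
founders <- function(ped) ped$id[is.na(ped$father) & is.na(ped$mother)]

# Parent-before-child ordering; NULL if the parent graph has a cycle.
topological_order <- function(members) {
  n <- nrow(members)
  fa <- match(members$father, members$id)
  mo <- match(members$mother, members$id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) NULL else order
}

#' Kinship matrix of a pedigree
#'
#' Computes the full matrix of kinship coefficients by the standard recursion
#' over a parent-before-child ordering: founders are mutually unrelated,
#' phi(a,a) = (1 + phi(father_a, mother_a)) / 2, and for a not an ancestor of
#' b, phi(a,b) = (phi(father_a, b) + phi(mother_a, b)) / 2.
#'
#' @param ped a `pedigree`
#' @return numeric matrix with dimnames = member ids
#' @export
kinship_matrix <- function(ped) {
  ord <- topological_order(ped)
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    phi[i, i] <- if (is.na(fa[i]) || is.na(mo[i])) 0.5 else 0.5 * (1 + phi[fa[i], mo[i]])
    if (pos > 1L) {
      for (j in ord[seq_len(pos - 1L)]) {
        v <- 0
        if (!is.na(fa[i])) v <- v + 0.5 * phi[fa[i], j]
        if (!is.na(mo[i])) v <- v + 0.5 * phi[mo[i], j]
        phi[i, j] <- phi[j, i] <- v
      }
    }
  }
  phi
}

#' Kinship coefficient between two members
#'
#' @param ped a `pedigree`
#' @param a,b individual ids
#' @return probability in [0, 0.5] that alleles sampled at random from `a`
#'   and `b` are identical by descent
#' @examples
#' # parent-offspring kinship is 1/4
#' @export
kinship_coefficient <- function(ped, a, b) {
  for (x in c(a, b)) {
    if (!x %in% ped$id) stop("unknown individual id: ", x)
  }
  kinship_matrix(ped)[a, b]
}

#' Degree of relationship between two members
#'
#' Degree k corresponds to kinship (1/2)^(k+1): 1st degree 1/4
#' (parent-offspring, full siblings), 2nd degree 1/8 (avuncular,
#' grandparental, half-siblings), 3rd degree 1/16 (first cousins), and so
#' on. Non-dyadic kinship values arising from inbred loops are classified
#' numerically as round(-log2(kinship)) - 1.
#'
#' @inheritParams kinship_coefficient
#' @return integer degree (>= 1), or the string "unrelated" when kinship is 0
#' @export
relationship_degree <- function(ped, a, b) {
  if (identical(a, b)) stop("relationship degree requires two distinct individuals")
  phi <- kinship_coefficient(ped, a, b)
  if (phi == 0) return("unrelated")
  max(1L, as.integer(round(-log2(phi))) - 1L)
}

#' Largest set of sequenced cases that are pairwise distant relatives
#'
#' Finds the size of the largest subset of exome-sequenced affected men that
#' are pairwise second-degree relatives or more distant (kinship <= 1/8).
#' Families whose sequenced cases admit no such subset of size two or more
#' score 0; in particular every family with a single sequenced case scores 0.
#'
#' @param ped a `pedigree`
#' @param max_kinship pairwise kinship ceiling defining "distant"; the
#'   default 1/8 means at least 2nd degree
#' @return integer, 0 or >= 2
#' @export
max_distant_wes_set <- function(ped, max_kinship = 1 / 8) {
  ids <- ped$id[ped$wes & ped$affected]
  m <- length(ids)
  if (m < 2L) return(0L)
  phi <- kinship_matrix(ped)[ids, ids, drop = FALSE]
  ok <- phi <= max_kinship
  best <- 0L
  # families sequence at most a handful of cases; exhaustive subsets are cheap
  for (size in m:2L) {
    if (size <= best) break
    combs <- utils::combn(m, size)
    for (k in seq_len(ncol(combs))) {
      s <- combs[, k]
      sub <- ok[s, s, drop = FALSE]
      diag(sub) <- TRUE
      if (all(sub)) { best <- size; break }
    }
    if (best) break
  }
  if (best >= 2L) best else 0L
}

#' Rank affected men for exome sequencing
#'
#' Reproduces the study-design rule for choosing which affected men to
#' sequence: aggressive disease first, then early-onset disease (diagnosis
#' at or before 65 years), then greedy maximization of relationship distance
#' among those already chosen. Ties are broken lexicographically by id so
#' the ranking is deterministic.
#'
#' @param ped a `pedigree`
#' @param k number of candidates to return
#' @return character vector of `k` individual ids in selection order
#' @export
select_wes_candidates <- function(ped, k) {
  elig <- ped$id[ped$affected & ped$sex == "male" & ped$dna_available]
  if (k > length(elig)) {
    stop(sprintf("requested %d WES candidates but only %d eligible affected men in family %s",
                 k, length(elig), family_id(ped)))
  }
  phi <- kinship_matrix(ped)
  info <- data.frame(id = elig,
                     aggressive = ped$aggressive[match(elig, ped$id)] %in% TRUE,
                     early = !is.na(ped$dx_age[match(elig, ped$id)]) &
                       ped$dx_age[match(elig, ped$id)] <= 65,
                     stringsAsFactors = FALSE)
  chosen <- character(0)
  while (length(chosen) < k) {
    rem <- info[!info$id %in% chosen, , drop = FALSE]
    # closeness to the chosen set (0 for the first pick)
    rem$closeness <- vapply(rem$id, function(i) {
      if (!length(chosen)) 0 else sum(phi[i, chosen])
    }, numeric(1))
    ord <- order(!rem$aggressive, !rem$early, rem$closeness, rem$id)
    chosen <- c(chosen, rem$id[ord[1L]])
  }
  chosen
}

table1_bins <- list(
  affected = list(breaks = c(3, 5, 7, 9, 11, 18),
                  labels = c("3-4", "5-6", "7-8", "9-10", "11-18")),
  mean_dx_age = list(breaks = c(50, 55, 60, 65, 70, 79.5),
                     labels = c("50-54.9", "55-59.9", "60-64.9", "65-69.9", "70-79.5")),
  wes = list(values = 1:6, labels = as.character(1:6)),
  max_distant = list(values = c(0, 2, 3, 4), labels = c("0", "2", "3", "4"))
)

bin_label <- function(x, bins) {
  if (!is.null(bins$values)) {
    return(bins$labels[match(x, bins$values)])
  }
  br <- bins$breaks
  nb <- length(bins$labels)
  lab <- rep(NA_character_, length(x))
  for (i in seq_len(nb)) {
    inbin <- !is.na(x) & x >= br[i] & (if (i < nb) x < br[i + 1L] else x <= br[i + 1L])
    lab[inbin] <- bins$labels[i]
  }
  lab
}

#' Family summary table
#'
#' Tabulates a list of pedigrees into the standard descriptive bins for
#' high-risk family collections: affected men per family, mean age at
#' diagnosis per family, number of sequenced cases per family, and the
#' maximum number of sequenced cases that are pairwise at least
#' second-degree relatives.
#'
#' @param peds list of `pedigree` objects
#' @return data.frame with columns `statistic`, `bin`, `n_families`
#' @export
family_summary <- function(peds) {
  stopifnot(length(peds) >= 1L)
  aff <- vapply(peds, function(p) sum(p$affected & p$sex == "male"), numeric(1))
  mage <- vapply(peds, function(p) mean(p$dx_age[p$affected], na.rm = TRUE), numeric(1))
  nwes <- vapply(peds, function(p) sum(p$wes & p$affected), numeric(1))
  mdist <- vapply(peds, function(p) as.numeric(max_distant_wes_set(p)), numeric(1))
  vals <- list(affected = aff, mean_dx_age = mage, wes = nwes, max_distant = mdist)
  out <- do.call(rbind, lapply(names(table1_bins), function(stat) {
    bins <- table1_bins[[stat]]
    lab <- bin_label(vals[[stat]], bins)
    counts <- table(factor(lab, levels = bins$labels))
    data.frame(statistic = stat, bin = bins$labels,
               n_families = as.integer(counts), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read pedigrees from a PED file plus a phenotype table
#'
#' The PED file follows the LINKAGE convention (family, individual, father,
#' mother, sex with 1 = male / 2 = female, affection with 2 = affected /
#' 1 = unaffected / 0 = unknown; 0 parent codes mean founder). The phenotype
#' TSV is keyed by (family_id, individual_id) and carries `dx_age`,
#' `aggressive`, `vital`, `wes`, `dna_available`.
#'
#' @param ped_file path to a whitespace-delimited 6-column PED file
#' @param phenotype_file optional path to the phenotype TSV
#' @return named list of `pedigree` objects
#' @export
read_pedigrees <- function(ped_file, phenotype_file = NULL) {
  raw <- utils::read.table(ped_file, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family_id", "id", "father", "mother",
                                         "sex", "affected"))
  phen <- if (!is.null(phenotype_file)) {
    utils::read.delim(phenotype_file, stringsAsFactors = FALSE,
                      colClasses = c(family_id = "character",
                                     individual_id = "character"))
  }
  raw$family_id <- as.character(raw$family_id)
  raw$id <- as.character(raw$id)
  lapply(split(raw, raw$family_id), function(fam) {
    mem <- data.frame(
      id = fam$id,
      father = ifelse(fam$father %in% c("0", 0), NA_character_, as.character(fam$father)),
      mother = ifelse(fam$mother %in% c("0", 0), NA_character_, as.character(fam$mother)),
      sex = c("male", "female")[fam$sex],
      affected = fam$affected == 2,
      stringsAsFactors = FALSE
    )
    if (!is.null(phen)) {
      ph <- phen[phen$family_id == fam$family_id[1L], , drop = FALSE]
      j <- match(mem$id, ph$individual_id)
      for (col in c("dx_age", "aggressive", "vital", "wes", "dna_available")) {
        if (col %in% names(ph)) mem[[col]] <- ph[[col]][j]
      }
      for (col in c("aggressive", "wes", "dna_available")) {
        if (col %in% names(mem)) mem[[col]] <- as.logical(mem[[col]])
      }
    }
    pedigree(mem, family_id = fam$family_id[1L])
  })
}

#' Write pedigrees as PED plus phenotype TSV
#'
#' @param peds list of `pedigree` objects
#' @param ped_file,phenotype_file output paths
#' @return invisibly, the two paths
#' @export
write_pedigrees <- function(peds, ped_file, phenotype_file) {
  rows <- do.call(rbind, lapply(peds, function(p) {
    data.frame(family_id = family_id(p), id = p$id,
               father = ifelse(is.na(p$father), "0", p$father),
               mother = ifelse(is.na(p$mother), "0", p$mother),
               sex = ifelse(p$sex == "male", 1L, 2L),
               affected = ifelse(p$affected, 2L, 1L),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, ped_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  phen <- do.call(rbind, lapply(peds, function(p) {
    data.frame(family_id = family_id(p), individual_id = p$id,
               dx_age = p$dx_age, aggressive = p$aggressive, vital = p$vital,
               wes = p$wes, dna_available = p$dna_available,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(phen, phenotype_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(ped_file, phenotype_file))
}
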