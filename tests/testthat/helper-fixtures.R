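# Shared fixtures and independent oracles, built in code.

# Three-generation pedigree: founder couple, two married sons, three grandsons.
ped_three_gen <- function() {
  pedigree(data.frame(
    id = c("gf", "gm", "f1", "f2", "m1", "m2", "c1", "c2", "c3"),
    father = c(NA, NA, "gf", "gf", NA, NA, "f1", "f1", "f2"),
    mother = c(NA, NA, "gm", "gm", NA, NA, "m1", "m1", "m2"),
    sex = c("male", "female", "male", "male", "female", "female",
            "male", "male", "male"),
    affected = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE), family_id = "T3G")
}

# Ten members; S3, C1, C2 are affected WES men, pairwise avuncular/cousins.
ped_avuncular <- function() {
  pedigree(data.frame(
    id = c("GF", "GM", "S1", "S2", "S3", "D1", "W1", "W2", "C1", "C2"),
    father = c(NA, NA, "GF", "GF", "GF", "GF", NA, NA, "S1", "S2"),
    mother = c(NA, NA, "GM", "GM", "GM", "GM", NA, NA, "W1", "W2"),
    sex = c("male", "female", "male", "male", "male", "female", "female",
            "female", "male", "male"),
    affected = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                 TRUE, TRUE),
    wes = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
            TRUE, TRUE),
    stringsAsFactors = FALSE), family_id = "AVU")
}

# Random connected pedigree with both-or-no parents; possibly inbred loops.
random_pedigree <- function(n_members = 8) {
  mem <- data.frame(id = c("I1", "I2", "I3"),
                    father = c(NA, NA, "I1"), mother = c(NA, NA, "I2"),
                    sex = c("male", "female", sample(c("male", "female"), 1)),
                    affected = FALSE, stringsAsFactors = FALSE)
  nid <- function() paste0("I", nrow(mem) + 1L)
  while (nrow(mem) < n_members) {
    if (nrow(mem) <= n_members - 2L && stats::runif(1) < 0.4) {
      # marry in a founder and give the couple a child
      p <- mem$id[sample(nrow(mem), 1L)]
      psex <- mem$sex[mem$id == p]
      sid <- nid()
      mem <- rbind(mem, data.frame(id = sid, father = NA, mother = NA,
                                   sex = ifelse(psex == "male", "female", "male"),
                                   affected = FALSE))
      mem <- rbind(mem, data.frame(id = nid(),
                                   father = if (psex == "male") p else sid,
                                   mother = if (psex == "male") sid else p,
                                   sex = sample(c("male", "female"), 1),
                                   affected = FALSE))
    } else {
      f <- sample(mem$id[mem$sex == "male"], 1L)
      m <- sample(mem$id[mem$sex == "female"], 1L)
      mem <- rbind(mem, data.frame(id = nid(), father = f, mother = m,
                                   sex = sample(c("male", "female"), 1),
                                   affected = FALSE))
    }
  }
  pedigree(mem, family_id = "RND")
}

# Exact kinship by exhaustive enumeration of founder-allele inheritance
# vectors; independent of the tabular recursion in kinship_matrix().
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  ord <- famvarsel:::topological_order(ped)
  nonf <- ord[!is.na(fa[ord])]
  k <- length(nonf)
  founder_idx <- which(is.na(fa))
  combos <- if (k > 0) as.matrix(expand.grid(rep(list(1:4), k))) else matrix(0, 1, 0)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (r in seq_len(nrow(combos))) {
    A <- matrix(0L, n, 2)
    cnt <- 0L
    for (f in founder_idx) {
      A[f, ] <- c(cnt + 1L, cnt + 2L)
      cnt <- cnt + 2L
    }
    for (j in seq_len(k)) {
      i <- nonf[j]
      ch <- combos[r, j] - 1L
      A[i, 1L] <- A[fa[i], (ch %% 2L) + 1L]
      A[i, 2L] <- A[mo[i], (ch %/% 2L) + 1L]
    }
    e11 <- outer(A[, 1], A[, 1], "==")
    e12 <- outer(A[, 1], A[, 2], "==")
    e22 <- outer(A[, 2], A[, 2], "==")
    phi <- phi + (e11 + e12 + t(e12) + e22) / 4
  }
  phi / nrow(combos)
}

# Brute-force maximum pairwise-distant WES subset.
max_distant_oracle <- function(ped, max_kinship = 1 / 8) {
  ids <- ped$id[ped$wes & ped$affected]
  if (length(ids) < 2L) return(0L)
  phi <- kinship_matrix(ped)[ids, ids, drop = FALSE]
  best <- 0L
  for (size in 2:length(ids)) {
    combs <- utils::combn(length(ids), size)
    for (k in seq_len(ncol(combs))) {
      s <- combs[, k]
      sub <- phi[s, s, drop = FALSE]
      if (all(sub[upper.tri(sub)] <= max_kinship)) best <- max(best, size)
    }
  }
  best
}

# Expand a 2x2 carrier table into a subject-level cohort data.frame.
cohort_from_2x2 <- function(a, b, c, d, study = "S1") {
  data.frame(
    subject_id = sprintf("s%05d", seq_len(a + b + c + d)),
    study = study,
    status = rep(c("case", "case", "control", "control"), c(a, b, c, d)),
    age = 65,
    family_history = "no",
    aggressiveness = rep(c("non-aggressive", "non-aggressive", "control", "control"),
                         c(a, b, c, d)),
    v = rep(c(1L, 0L, 1L, 0L), c(a, b, c, d)),
    stringsAsFactors = FALSE)
}

# Small deterministic variant table covering every consequence/impact case.
variant_fixture <- function() {
  data.frame(
    id = paste0("V", 1:6),
    chrom = "1", pos = 1:6, ref = "A", alt = "T",
    gene = paste0("G", 1:6),
    consequence = c("missense", "missense", "stop_gained", "missense",
                    "other", "missense"),
    sift_pred = c("deleterious", "tolerated", NA, "tolerated", NA, NA),
    sift_score = c(0.02, 0.37, NA, 0.80, NA, NA),
    polyphen_pred = c("benign", "possibly", NA, "benign", NA, NA),
    polyphen_score = c(0.432, 0.870, NA, 0.10, NA, NA),
    stringsAsFactors = FALSE)
}
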