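---
title: "Prioritizing low-frequency, moderately penetrant risk variants from family exomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing low-frequency, moderately penetrant risk variants from family exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Multiplex disease families are enriched for inherited risk alleles, but a
moderately penetrant allele will neither be present in every affected
relative nor absent from every unaffected one. Classical segregation
analysis therefore has little power at realistic family counts, while
case-control studies cannot see alleles at a fraction of a percent
frequency without enormous samples. The approach implemented here assumes:

* **genetic heterogeneity** — any particular risk variant segregates in only
  a few of the ascertained families;
* **incomplete (moderate) penetrance** — within a carrier family, typically
  40–65% of affected men carry the allele, and some unaffected relatives
  carry it too;
* **identity by descent within a family** — a rare allele enters a family
  once, on a single founder haplotype.

The third assumption is what makes ungenotyped relatives informative: if
phased haplotypes are available for the family (here: simulated truth from
gene dropping, in practice reconstructed from SNP-array data), the allele
observed in the sequenced carriers can be pinned to one or two candidate
founder haplotypes, and every affected man's haplotype pair then says
whether he *could* carry the allele. The resulting per-family minimum and
maximum affected-carrier counts — equal when the haplotype is resolved —
are averaged (unweighted) across carrier families into the minimum/maximum
**average carrier frequency**, the selection metric that distinguishes this
design from naive carrier counting among sequenced men only.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `pop_freq_max` | 0.02 | inclusive population-AF ceiling, applied per panel where the variant is reported |
| `ratio_min` | 2 | minimum proband-AF / European-reference-AF ratio |
| `fam_min` | 3 | minimum number of segregating families |
| `fam_min_many` | 6 | criterion 1: segregation alone suffices |
| `ratio_high` / `ratio_high_max_avg` | 4 / 40% | criterion 2: strong enrichment with a material carrier frequency |
| `min_avg_min` | 50% | criterion 3: the true average carrier frequency can only be higher |
| `max_avg_min` | 67% | criterion 4: highest possible average carrier frequency |
| `call_rate_min` | 0.70 | sample and variant QC threshold (strict `<` removes) |
| `control_freq_max` | 0.02 | QC ceiling on control *carrier* frequency (strict `>` removes) |

All cascade thresholds are inclusive (`>=`, `<=`) exactly as printed in the
source study design; the gene-list companion filter
(`gene_list_filter()`) uses a strict `< 2%` because that criterion is
stated as "less than".

## Numerical and policy choices

Several points are underdetermined by the study design; each is an explicit
switch with a documented default:

* **Frequency-ratio denominator.** Two European reference panels are
  available ("ESP_EA", "KG_EUR"). The default takes the **maximum** of the
  available frequencies — the conservative choice, since it minimizes the
  ratio; `policy = "first_available"` reproduces a fixed panel preference.
  A variant absent from both European panels gets an infinite ratio (it
  passes any finite threshold) and is flagged in the report.
* **Observed frequency is an allele frequency**, not a carrier frequency:
  alternate alleles over `2 ×` called probands, the only quantity
  commensurable with panel allele frequencies.
* **Inconsistent families.** When sequenced carriers' haplotype pairs have
  an empty intersection (recombination between marker and variant, or two
  mutational origins), the default keeps the family with union-based bounds
  and a warning; `inconsistent = "drop"` excludes it.
* **Ungenotyped affected men** without haplotype data stay in the bound
  denominator by default (they are the reason the metric exists); a switch
  removes them.
* **Relationship degree** is defined numerically from the kinship
  coefficient, `degree = round(-log2(phi)) - 1`, so that looped/inbred
  pedigrees classify deterministically; "≥ 2nd degree" means kinship
  ≤ 1/8.
* **QC rule order.** Variant removals are attributed to the first failing
  rule in the order: call rate, control carrier frequency, family count.
  Membership of the removed set does not depend on the order; only the
  attribution does. "Frequency in controls" is interpreted as *carrier*
  frequency, consistent with how control frequencies are reported in the
  validation tables.
* **Meta-analysis** is fixed-effect inverse-variance pooling of log odds
  ratios, with standard errors recovered from 95% CIs as
  `(log U − log L) / (2 × 1.959964)`, fitted via metafor. Fixed-effect
  (not DerSimonian–Laird random-effects) pooling is the model that
  reproduces the published combined odds ratios from the published
  per-study results; this was established by recomputation and is asserted
  in the test suite. The SE-from-CI reconstruction is exact only for
  log-symmetric CIs, which is why pooled values from rounded published CIs
  carry a ±0.02 tolerance.
* **Wald inference throughout** (not profile likelihood), matching standard
  unconditional-logistic reporting; age enters as a continuous covariate.
* **Fisher's exact conventions.** `fisher_exact()` exposes `two_sided`
  (minimum-likelihood convention, identical to `stats::fisher.test`),
  `one_sided` (upper tail), and `point` (the hypergeometric probability of
  exactly the observed table). The point mode exists because published
  p-values for strata with no estimable odds ratio match the point
  probability rather than either standard convention — the package
  documents this rather than guessing intent; stratified fallbacks default
  to `point`.
* **Separation.** A stratum with zero carriers among cases or controls has
  no ML logistic estimate; `logistic_dominant()` refuses with a pointer to
  `fisher_exact()`, and `stratified_analysis()` performs that fallback on
  pooled stratum counts automatically.

## What the generators emulate — and what they do not

`generate_families()` draws per-family affected counts, mean diagnosis ages
and WES counts from the published family-table marginals (75 families;
bins such as 44 single-WES families), builds three-generation pedigrees
realizing them, and applies the real selection rule for sequencing
(aggressive disease, then diagnosis ≤ 65, then maximal pairwise
relationship distance; ties broken lexicographically for reproducibility).
`gene_drop()` transmits uniquely labelled founder haplotypes with a fair
coin per meiosis — recombination is off by default because a variant locus
is a point; the haplotype map it returns plays the role of SNP-array-based
haplotype reconstruction. `plant_risk_variant()` implements penetrance
*implicitly*: it chooses the founder haplotype whose affected-descendant
fraction is closest to the target (default targets 40–65%, drawn from the
published carrier-frequency range) among haplotypes carried by at least one
sequenced affected man (the variant must be discoverable), and warns when
no haplotype comes within 0.25 of the target. Affection status is never
resampled, so the family-table structure stays intact. `generate_cohort()`
draws carrier status so that case-versus-control carrier odds equal the
planted (possibly aggressiveness-specific) odds ratio, with ages
N(65, 8) truncated to [40, 90], ~14%/8% first-degree family history in
cases/controls, and ~20% aggressive disease among cases — the published
cohort composition.

Not emulated: linkage disequilibrium and haplotype-reconstruction error
(haplotypes are truth), sequencing error and genotype likelihoods,
population stratification, age-genotype confounding, and ascertainment
beyond the family-size marginals. Passing tests therefore demonstrate the
correctness of the inference machinery under the stated model, not
robustness to reconstruction error or substructure in real data.

## Problem sizes used by the test suite

The statistical property suites run at: 1,000 gene-drop replicates for
carrier-bound bracketing and brute-force equivalence; exhaustive
inheritance-vector enumeration (4^k vectors for k non-founders) as the
kinship oracle on pedigrees of up to 8 members; 500 replicates at n = 7,000
for planted log-OR recovery (|bias| < 0.05); 2,000 null cohorts of
n = 2,000 for the type-I error of the dominant test (nominal 0.05, accepted
band 0.035–0.065); and full enumeration of hypergeometric supports for
Fisher's tests at margins up to a few hundred. These sizes keep every
estimate's Monte-Carlo error well below the tested tolerance.

## Known limitations

* Carrier bounds are only as good as the haplotype map; with real,
  Merlin-style reconstructed haplotypes, switching errors would loosen the
  bracketing guarantee that holds exactly under simulated truth.
* The average carrier frequency is an unweighted mean over carrier
  families, so a small family with one affected man contributes as much as
  an eleven-case family.
* The co-occurrence test ignores population substructure, which could
  itself produce co-carriage in cases.
* Published stage counts from the original WES data (453,977 → 22,242 →
  998 → 381 candidates) require the private data and are out of reach of
  the synthetic generators, which validate structure and thresholds, not
  those totals.
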