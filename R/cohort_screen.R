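# Case/control carrier-frequency screening of candidate variants: per-group
# carrier tables, rarity classification against healthy-control frequency,
# and the autosomal-dominant consistency exclusion (a candidate observed
# homozygous in an unaffected control cannot act dominantly).

#' Carrier frequency as a printed percentage
#'
#' `100 * carriers / denominator`, rounded half-up to one decimal — the
#' rounding convention of published carrier tables.
#'
#' @param carriers Number of carriers (vectorized).
#' @param denominator Number of typed samples in the group (> 0).
#' @return Numeric percentage(s) with one decimal.
#' @export
carrier_frequency <- function(carriers, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(carriers < 0 | carriers > denominator))
    stop("carriers must lie in [0, denominator]")
  round_half_up(100 * carriers / denominator, 1L)
}

round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  # nudge by an ulp-scale epsilon so values like 84.615384*10 that land an ulp
  # below .5 due to binary representation still round half-up
  floor(x * m + 0.5 + sign(x) * .Machine$double.eps * abs(x) * m) / m
}

#' Classify a variant's rarity from its control frequency
#'
#' `RARE` below 1%, `COMMON` above 5%, `POLYMORPHISM` in between; both
#' boundaries belong to `POLYMORPHISM`, so a control frequency of exactly 1%
#' or 5% is a polymorphism.
#'
#' @param control_freq Carrier frequency among healthy controls, as a
#'   fraction in `[0, 1]` (vectorized).
#' @return Ordered factor with levels `RARE < POLYMORPHISM < COMMON`.
#' @export
classify_rarity <- function(control_freq) {
  stopifnot(all(control_freq >= 0 & control_freq <= 1))
  cls <- ifelse(control_freq < 0.01, "RARE",
                ifelse(control_freq > 0.05, "COMMON", "POLYMORPHISM"))
  factor(cls, levels = c("RARE", "POLYMORPHISM", "COMMON"), ordered = TRUE)
}

#' Autosomal-dominant consistency filter
#'
#' Excludes any variant observed homozygous for the alternate allele in at
#' least one healthy control: under a dominant susceptibility model an
#' unaffected homozygote is inconsistent with pathogenicity.
#'
#' @param av An `annotated_variants` object.
#' @param cohort A `cohort_design`.
#' @return List with `kept` and `excluded` (`annotated_variants` partitions
#'   of the input) and `reasons` (data.frame naming each excluded variant and
#'   a control homozygote).
#' @export
dominant_consistency_filter <- function(av, cohort) {
  ctl <- intersect(samples_in_group(cohort, "HEALTHY_CONTROL"), av_samples(av))
  if (!length(ctl)) {
    warning("no healthy-control genotypes available; dominant-consistency filter is vacuous")
    return(list(kept = av, excluded = subset_variants(av, integer(0)),
                reasons = data.frame(key = character(0), gene = character(0),
                                     homozygous_control = character(0))))
  }
  g <- av$geno[, ctl, drop = FALSE]
  hom <- !is.na(g) & g == 2L
  bad <- rowSums(hom) >= 1L
  first_hom <- apply(hom, 1L, function(r) if (any(r)) ctl[which(r)[1]] else NA_character_)
  list(kept = subset_variants(av, !bad),
       excluded = subset_variants(av, bad),
       reasons = data.frame(key = variant_keys(av)[bad],
                            gene = av$variants$gene[bad],
                            homozygous_control = first_hom[bad],
                            stringsAsFactors = FALSE))
}

#' Screen candidate variants across cohort groups
#'
#' Builds the carrier-frequency table over the MPM group (whole-exome plus
#' screened multiple-primary-melanoma cases), the familial-index group and the
#' healthy-control group; a group's denominator for each variant is the
#' number of samples with a defined genotype, so denominators may differ
#' across variants. Applies the dominant-consistency exclusion and classifies
#' rarity from the control carrier frequency.
#'
#' @param av `annotated_variants` of the candidates (nonempty).
#' @param cohort A `cohort_design`.
#' @return List with `table` (a `carrier_table`: one row per variant with
#'   per-group carriers/denominator/percent and `rarity`), `excluded`
#'   (`annotated_variants` dropped by the dominant-consistency rule),
#'   `exclusion_reasons`, and `kept` (`annotated_variants` retained).
#' @export
screen_candidates <- function(av, cohort) {
  if (n_variants(av) == 0L) stop("no candidate variants to screen")
  group_samples <- list(
    MPM = c(samples_in_group(cohort, "WES_CASE"),
            samples_in_group(cohort, "MPM_SCREEN")),
    INDEX = samples_in_group(cohort, "FAMILIAL_INDEX"),
    CONTROL = samples_in_group(cohort, "HEALTHY_CONTROL"))
  group_samples <- lapply(group_samples, intersect, av_samples(av))
  present <- names(group_samples)[lengths(group_samples) > 0L]
  for (g in setdiff(names(group_samples), present))
    warning("group ", g, " has no typed samples; its columns are omitted")

  tab <- data.frame(key = variant_keys(av), gene = av$variants$gene,
                    hgvs_c = av$variants$hgvs_c, hgvs_p = av$variants$hgvs_p,
                    stringsAsFactors = FALSE)
  for (g in present) {
    sm <- group_samples[[g]]
    geno <- av$geno[, sm, drop = FALSE]
    typed <- rowSums(!is.na(geno))
    carr <- rowSums(geno >= 1L, na.rm = TRUE)
    tab[[paste0(g, "_carriers")]] <- as.integer(carr)
    tab[[paste0(g, "_n")]] <- as.integer(typed)
    tab[[paste0(g, "_pct")]] <- ifelse(typed > 0, carrier_frequency(carr, pmax(typed, 1L)), NA_real_)
  }
  if ("CONTROL" %in% present) {
    ctrl_frac <- ifelse(tab$CONTROL_n > 0, tab$CONTROL_carriers / tab$CONTROL_n, 0)
    tab$rarity <- classify_rarity(ctrl_frac)
  }
  dom <- dominant_consistency_filter(av, cohort)
  tab$dominant_excluded <- tab$key %in% variant_keys(dom$excluded)
  attr(tab, "groups") <- present
  class(tab) <- c("carrier_table", "data.frame")
  list(table = tab, kept = dom$kept, excluded = dom$excluded,
       exclusion_reasons = dom$reasons)
}
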