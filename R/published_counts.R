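# The published candidate-variant screen: carrier counts of the 13 validated
# variants across 26 multiple-primary-melanoma cases, 37 familial indexes and
# 100-300 healthy controls, shipped as a plain-text table, plus a
# deterministic reconstruction of a genotype-level cohort consistent with
# those counts (used to exercise the screening and aggregation machinery on
# the published numbers).

#' Published candidate-variant screen counts
#'
#' Carrier counts of the 13 validated candidate variants by cohort group,
#' with per-variant control denominators (100/200/300) and the
#' control-homozygosity flags behind the dominant-consistency exclusion.
#'
#' @return data.frame with one row per variant.
#' @export
published_candidate_counts <- function() {
  path <- system.file("extdata", "candidate_screen_counts.tsv",
                      package = "melscreen", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' Reconstruct a genotype-level cohort from screen counts
#'
#' Builds an `annotated_variants` + `cohort_design` pair whose per-group
#' carrier counts and denominators reproduce a screen-count table exactly:
#' carriers are heterozygous (homozygous for flagged control carriers),
#' assigned cyclically within each group (carriers of one variant are
#' distinct samples; overlap across variants is allowed, as group carrier
#' totals can exceed the group size), and samples beyond a variant's control
#' denominator are untyped, so the varying denominators re-emerge from
#' missingness when the cohort is screened.
#'
#' @param counts data.frame in the layout of [published_candidate_counts()].
#' @return List with `av` and `cohort`.
#' @export
reconstruct_screen_cohort <- function(counts = published_candidate_counts()) {
  n_wes <- 8L
  n_scr <- max(counts$mpm_n) - n_wes
  n_idx <- max(counts$index_n)
  n_ctl <- max(counts$control_n)
  ids <- list(MPM = c(sprintf("WES%02d", seq_len(n_wes)),
                      sprintf("SCR%02d", seq_len(n_scr))),
              INDEX = sprintf("IDX%02d", seq_len(n_idx)),
              CONTROL = sprintf("CTL%03d", seq_len(n_ctl)))
  samples <- unlist(ids, use.names = FALSE)
  cohort <- cohort_design(data.frame(
    sample_id = samples,
    group = rep(c("WES_CASE", "MPM_SCREEN", "FAMILIAL_INDEX", "HEALTHY_CONTROL"),
                c(n_wes, n_scr, n_idx, n_ctl)),
    sibling_pair_id = c("SP1", "SP1", rep(NA, length(samples) - 2L)),
    stringsAsFactors = FALSE))

  m <- nrow(counts)
  geno <- matrix(0L, m, length(samples), dimnames = list(NULL, samples))
  assign_group <- function(col_ids, carriers, typed_n) {
    block <- matrix(0L, m, length(col_ids))
    ptr <- 0L
    for (j in seq_len(m)) {
      if (carriers[j] > 0L) {
        idx <- ((ptr + seq_len(carriers[j]) - 1L) %% typed_n[j]) + 1L
        if (anyDuplicated(idx)) stop("carrier count exceeds group denominator")
        block[j, idx] <- 1L
        ptr <- ptr + carriers[j]
      }
      if (typed_n[j] < length(col_ids))
        block[j, (typed_n[j] + 1L):length(col_ids)] <- NA_integer_
    }
    block
  }
  geno[, ids$MPM] <- assign_group(ids$MPM, counts$mpm_carriers, counts$mpm_n)
  geno[, ids$INDEX] <- assign_group(ids$INDEX, counts$index_carriers, counts$index_n)
  ctl <- matrix(0L, m, n_ctl)
  ptr <- 0L
  for (j in seq_len(m)) {
    k <- counts$control_carriers[j]
    if (k > 0L) {
      idx <- ((ptr + seq_len(k) - 1L) %% counts$control_n[j]) + 1L
      ctl[j, idx] <- 1L
      if (counts$control_hom[j] == 1L) ctl[j, idx[1]] <- 2L
      ptr <- ptr + k
    }
    if (counts$control_n[j] < n_ctl)
      ctl[j, (counts$control_n[j] + 1L):n_ctl] <- NA_integer_
  }
  geno[, ids$CONTROL] <- ctl

  unk <- function(n) rep("unknown", n)
  variants <- data.frame(
    chrom = counts$chrom, pos = counts$pos,
    ref = rep(c("A", "C", "G", "T"), length.out = m),
    alt = rep(c("G", "T", "A", "C"), length.out = m),
    gene = counts$gene, hgvs_c = counts$hgvs_c, hgvs_p = counts$hgvs_p,
    consequence = counts$consequence,
    af_global = NA_real_, af_european = NA_real_,
    sift = unk(m), polyphen2 = unk(m), metasvm = unk(m), metalr = unk(m),
    provean = unk(m), mutationtaster = unk(m), fathmm = unk(m),
    clinvar = "absent", ensembl_hq = TRUE, validated = TRUE,
    stringsAsFactors = FALSE)
  list(av = annotated_variants(variants, geno), cohort = cohort)
}

#' Case/control counts of the aggregation variant panel
#'
#' Extracts, from a screen-count table, the per-variant case/control carrier
#' counts of the panel entering the region-based aggregation tests.
#'
#' @param counts data.frame in the layout of [published_candidate_counts()].
#' @return data.frame with columns `gene`, `case_carriers`, `case_n`,
#'   `control_carriers`, `control_n`.
#' @export
aggregation_panel_counts <- function(counts = published_candidate_counts()) {
  sel <- counts[counts$aggregation_set == 1L, , drop = FALSE]
  data.frame(gene = sel$gene,
             case_carriers = sel$mpm_carriers, case_n = sel$mpm_n,
             control_carriers = sel$control_carriers, control_n = sel$control_n,
             stringsAsFactors = FALSE)
}
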