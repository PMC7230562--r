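# Shared fixture builders: small cohorts and variant sets constructed in code.

toy_cohort <- function(n_wes = 4L, n_screen = 4L, n_index = 2L, n_ctl = 6L,
                       with_pair = TRUE) {
  ids <- c(sprintf("W%d", seq_len(n_wes)),
           if (n_screen) sprintf("S%d", seq_len(n_screen)),
           if (n_index) sprintf("I%d", seq_len(n_index)),
           if (n_ctl) sprintf("C%d", seq_len(n_ctl)))
  pair <- rep(NA_character_, length(ids))
  if (with_pair) pair[1:2] <- "SP1"
  cohort_design(data.frame(
    sample_id = ids,
    group = rep(c("WES_CASE", "MPM_SCREEN", "FAMILIAL_INDEX", "HEALTHY_CONTROL"),
                c(n_wes, n_screen, n_index, n_ctl)),
    sibling_pair_id = pair, stringsAsFactors = FALSE))
}

# build an annotated_variants set from a compact spec; geno is a matrix with
# one row per variant and columns named after cohort samples
toy_variants <- function(geno, consequence = "exonic_missense",
                         gene = NULL, af_global = NA_real_,
                         af_european = NA_real_, sift = "unknown",
                         polyphen2 = "unknown", metasvm = "unknown",
                         metalr = "unknown", provean = "unknown",
                         mutationtaster = "unknown", fathmm = "unknown",
                         clinvar = "absent", ensembl_hq = FALSE,
                         qual = NULL) {
  geno <- as.matrix(geno)
  m <- nrow(geno)
  if (is.null(gene)) gene <- sprintf("G%03d", seq_len(m))
  v <- data.frame(
    chrom = "1", pos = 1000L + seq_len(m), ref = "A", alt = "G",
    gene = rep_len(gene, m),
    hgvs_c = sprintf("c.%dA>G", seq_len(m)),
    hgvs_p = sprintf("p.Lys%dArg", seq_len(m)),
    consequence = rep_len(consequence, m),
    af_global = rep_len(af_global, m), af_european = rep_len(af_european, m),
    sift = rep_len(sift, m), polyphen2 = rep_len(polyphen2, m),
    metasvm = rep_len(metasvm, m), metalr = rep_len(metalr, m),
    provean = rep_len(provean, m), mutationtaster = rep_len(mutationtaster, m),
    fathmm = rep_len(fathmm, m), clinvar = rep_len(clinvar, m),
    ensembl_hq = rep_len(ensembl_hq, m), validated = FALSE,
    stringsAsFactors = FALSE)
  annotated_variants(v, geno, qual)
}

# genotype row helper: named carrier counts over a cohort's samples
geno_row <- function(cohort, ...) {
  counts <- c(...)
  g <- stats::setNames(rep(0L, nrow(cohort)), cohort$sample_id)
  if (length(counts)) g[names(counts)] <- as.integer(counts)
  matrix(g, nrow = 1, dimnames = list(NULL, cohort$sample_id))
}

# fast simulation config for end-to-end tests
small_sim_config <- function(...) {
  simulation_config(n_background_variants = 120L, ...)
}
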