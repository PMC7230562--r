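# Deterministic synthetic cohort generator. Emulates the study design the
# cascade assumes: eight whole-exome cases including one sibling pair,
# additional screened cases, familial indexes and healthy controls; planted
# shared rare heterozygous candidate variants with known cascade fates;
# Hardy-Weinberg background variants on both sides of the 1% frequency
# filter; and the annotation bundle (consequence, population frequencies,
# predictor calls, ClinVar, quality flags) the cascade consumes.

#' Simulation configuration
#'
#' @param n_wes_cases Whole-exome cases (default 8, including one sibling
#'   pair).
#' @param n_screen_cases Additionally screened melanoma cases (default 18).
#' @param n_indexes Familial-melanoma index cases (default 37).
#' @param n_controls Healthy controls (default 100).
#' @param n_background_variants Background variants (default 400).
#' @param bg_common_fraction Fraction of background variants drawn as common
#'   polymorphisms (default 0.6); the rest are rare.
#' @param bg_common_beta Shape parameters of the Beta distribution of common
#'   background minor-allele fractions, truncated to `[0.01, 0.5]`.
#' @param bg_rare_range Range of rare background allele frequencies
#'   (default `[0.001, 0.009]`, below the 1% filter).
#' @param bg_af_unknown_rate Fraction of rare background variants whose
#'   population frequency is unknown rather than annotated.
#' @param bg_damaging_rate Per-tool probability of a damaging background
#'   predictor call (annotation noise).
#' @param bg_missing_rate Genotype missingness among screened/index/control
#'   samples (drives per-variant denominators).
#' @param planted data.frame of planted variants (see
#'   [default_planted_variants()]).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_wes_cases = 8L, n_screen_cases = 18L,
                              n_indexes = 37L, n_controls = 100L,
                              n_background_variants = 400L,
                              bg_common_fraction = 0.6,
                              bg_common_beta = c(0.5, 3),
                              bg_rare_range = c(0.001, 0.009),
                              bg_af_unknown_rate = 0.3,
                              bg_damaging_rate = 0.15,
                              bg_missing_rate = 0.01,
                              planted = default_planted_variants()) {
  stopifnot(n_wes_cases >= 2L, n_screen_cases >= 0L, n_indexes >= 0L,
            n_controls >= 0L, n_background_variants >= 0L,
            bg_common_fraction >= 0, bg_common_fraction <= 1)
  structure(list(n_wes_cases = as.integer(n_wes_cases),
                 n_screen_cases = as.integer(n_screen_cases),
                 n_indexes = as.integer(n_indexes),
                 n_controls = as.integer(n_controls),
                 n_background_variants = as.integer(n_background_variants),
                 bg_common_fraction = bg_common_fraction,
                 bg_common_beta = bg_common_beta,
                 bg_rare_range = bg_rare_range,
                 bg_af_unknown_rate = bg_af_unknown_rate,
                 bg_damaging_rate = bg_damaging_rate,
                 bg_missing_rate = bg_missing_rate,
                 planted = planted),
            class = "simulation_config")
}

#' Default planted variant panel
#'
#' Eight candidate variants expected to survive the default cascade (four
#' shared by the sibling pair plus one other case, four shared by two
#' non-sibling cases, all rare damaging missense with screened-case
#' carriers), plus decoys each designed to fall at one specific cascade
#' step: a quality failure, a siblings-only variant, a singleton, a common
#' polymorphism, a shared synonymous variant, four variants crowded into one
#' gene, a variant with no damaging predictor call, and a two-carrier
#' variant below the final recurrence threshold.
#'
#' @return data.frame describing the planted panel; columns include the
#'   sharing `pattern` (`SIBS_PLUS_ONE` or `TWO_NONSIB`), annotation fields,
#'   per-group extra carrier counts, and the expected `fate`/`drop_step`.
#' @export
default_planted_variants <- function() {
  kept <- data.frame(
    id = paste0("K", 1:8),
    gene = paste0("CANDG", 1:8),
    pattern = rep(c("SIBS_PLUS_ONE", "TWO_NONSIB"), 4),
    consequence = "exonic_missense",
    af_global = c(NA, 0.002, NA, 0.005, NA, NA, 0.001, 0.004),
    n_damaging_stringent = c(2L, 1L, 3L, 1L, 2L, 1L, 4L, 2L),
    n_damaging_other = c(1L, 0L, 2L, 1L, 0L, 1L, 3L, 0L),
    clinvar = c("uncertain", "absent", "pathogenic_or_likely", "absent",
                "uncertain", "absent", "absent", "uncertain"),
    ensembl_hq = TRUE,
    n_screen_carriers = c(2L, 1L, 3L, 2L, 1L, 2L, 1L, 3L),
    n_index_carriers = c(0L, 1L, 0L, 1L, 0L, 0L, 1L, 0L),
    n_control_carriers = c(0L, 1L, 0L, 2L, 1L, 0L, 0L, 1L),
    control_hom = FALSE,
    quality_fail = FALSE,
    fate = "kept",
    drop_step = NA_character_,
    stringsAsFactors = FALSE)
  decoys <- data.frame(
    id = c("D1", "D2", "D3", "D4", "D5", paste0("D6", letters[1:4]), "D7", "D8"),
    gene = c("DECOYQ", "DECOYSIB", "DECOYONE", "DECOYCOM", "DECOYSYN",
             rep("DECOYPOLY", 4), "DECOYPRED", "DECOYTWO"),
    pattern = c("SIBS_PLUS_ONE", "SIBS_ONLY", "SINGLETON", "TWO_NONSIB",
                "SIBS_PLUS_ONE", rep("TWO_NONSIB", 4), "SIBS_PLUS_ONE",
                "TWO_NONSIB"),
    consequence = c("exonic_missense", "exonic_missense", "exonic_missense",
                    "exonic_missense", "exonic_synonymous",
                    rep("exonic_missense", 4), "exonic_missense",
                    "exonic_missense"),
    af_global = c(NA, NA, NA, 0.05, NA, NA, 0.003, NA, 0.002, NA, NA),
    n_damaging_stringent = c(2L, 2L, 2L, 2L, 1L, 2L, 1L, 2L, 1L, 0L, 2L),
    n_damaging_other = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 0L, 1L),
    clinvar = c("uncertain", "absent", "absent", "absent", "absent",
                "absent", "absent", "uncertain", "absent", "absent", "absent"),
    ensembl_hq = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                   FALSE, TRUE),
    n_screen_carriers = c(2L, 2L, 2L, 2L, 2L, 1L, 2L, 1L, 2L, 2L, 0L),
    n_index_carriers = 0L,
    n_control_carriers = c(0L, 0L, 0L, 1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L),
    control_hom = FALSE,
    quality_fail = c(TRUE, rep(FALSE, 10)),
    fate = "dropped",
    drop_step = c("quality", "sharing", "sharing", "allele_frequency",
                  "synonymous", rep("polyvariant_genes", 4),
                  "final_selection", "final_selection"),
    stringsAsFactors = FALSE)
  rbind(kept, decoys)
}

random_predictor_calls <- function(n, damaging_rate) {
  sample(c("damaging", "tolerated", "unknown"), n, replace = TRUE,
         prob = c(damaging_rate, 0.85 - damaging_rate, 0.15))
}

#' Generate a synthetic annotated cohort
#'
#' Writes a multi-sample annotated VCF, a sample sheet and a truth table to
#' `dir`; also returns the in-memory objects. Rare background variants are
#' redrawn until fewer than two whole-exome cases carry them, so that by
#' construction no background variant can satisfy the sharing criteria and
#' the truth table is exact. Byte-identical outputs for identical
#' config + seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; the single source of randomness.
#' @param dir Output directory (created if missing); `NULL` skips writing.
#' @return List with `av` (`annotated_variants`), `cohort`
#'   (`cohort_design`), `truth` (truth table data.frame) and `paths`.
#' @export
generate_cohort <- function(config = simulation_config(), seed = 1L,
                            dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  nw <- config$n_wes_cases
  ids_wes <- sprintf("WES%02d", seq_len(nw))
  ids_scr <- if (config$n_screen_cases) sprintf("SCR%02d", seq_len(config$n_screen_cases)) else character(0)
  ids_idx <- if (config$n_indexes) sprintf("IDX%02d", seq_len(config$n_indexes)) else character(0)
  ids_ctl <- if (config$n_controls) sprintf("CTL%03d", seq_len(config$n_controls)) else character(0)
  samples <- c(ids_wes, ids_scr, ids_idx, ids_ctl)
  cohort <- cohort_design(data.frame(
    sample_id = samples,
    group = rep(c("WES_CASE", "MPM_SCREEN", "FAMILIAL_INDEX", "HEALTHY_CONTROL"),
                c(nw, length(ids_scr), length(ids_idx), length(ids_ctl))),
    sibling_pair_id = c("SP1", "SP1", rep(NA, length(samples) - 2L)),
    stringsAsFactors = FALSE))
  sibs <- ids_wes[1:2]
  nonsib_wes <- ids_wes[-(1:2)]
  planted <- config$planted
  pl_n <- nrow(planted)
  # satisfiability of the planted sharing patterns
  if (any(planted$pattern %in% c("SIBS_PLUS_ONE", "TWO_NONSIB")) && nw < 4L)
    stop("planted sharing patterns need at least four whole-exome cases")
  if (any(planted$n_screen_carriers > length(ids_scr)) ||
      any(planted$n_index_carriers > length(ids_idx)) ||
      any(planted$n_control_carriers > length(ids_ctl)))
    stop("planted carrier counts exceed group sizes")

  out <- with_seed(seed, {
    nbg <- config$n_background_variants
    n_total <- nbg + pl_n
    chrom <- as.character(rep(1:22, length.out = n_total))
    pos <- 100000L + seq_len(n_total) * 1013L
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_total, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

    n_common <- round(nbg * config$bg_common_fraction)
    n_rare <- nbg - n_common
    # frequencies kept at 6 decimals so annotation round-trips exactly
    maf_common <- if (n_common) round(pmin(pmax(
      stats::rbeta(n_common, config$bg_common_beta[1], config$bg_common_beta[2]),
      0.01), 0.5), 6) else numeric(0)
    maf_rare <- if (n_rare) round(stats::runif(n_rare, config$bg_rare_range[1],
                                               config$bg_rare_range[2]), 6) else numeric(0)
    maf_bg <- c(maf_common, maf_rare)
    is_rare_bg <- c(rep(FALSE, n_common), rep(TRUE, n_rare))

    ns <- length(samples)
    geno <- matrix(0L, n_total, ns, dimnames = list(NULL, samples))
    qual <- matrix(TRUE, n_total, ns, dimnames = list(NULL, samples))
    wes_idx <- match(ids_wes, samples)
    for (j in seq_len(nbg)) {
      g <- stats::rbinom(ns, 2L, maf_bg[j])
      if (is_rare_bg[j]) {
        tries <- 0L
        while (sum(g[wes_idx] >= 1L) >= 2L && tries < 100L) {
          g <- stats::rbinom(ns, 2L, maf_bg[j])
          tries <- tries + 1L
        }
        if (sum(g[wes_idx] >= 1L) >= 2L) g[wes_idx] <- 0L
      }
      geno[j, ] <- g
    }
    # genotype dropout outside the whole-exome group
    non_wes <- setdiff(samples, ids_wes)
    if (nbg && length(non_wes)) {
      drop <- matrix(stats::runif(nbg * length(non_wes)) < config$bg_missing_rate,
                     nbg, length(non_wes))
      sub <- geno[seq_len(nbg), non_wes, drop = FALSE]
      sub[drop] <- NA_integer_
      geno[seq_len(nbg), non_wes] <- sub
    }

    bg_af_global <- maf_bg
    unknown <- is_rare_bg & stats::runif(nbg) < config$bg_af_unknown_rate
    bg_af_global[unknown] <- NA_real_
    ratio <- stats::runif(nbg, 0.8, 1.2)
    bg_af_eur <- bg_af_global * ratio
    # the European frequency stays on the same side of the 1% filter
    bg_af_eur[!is_rare_bg] <- pmin(pmax(bg_af_eur[!is_rare_bg], 0.01), 0.5)
    bg_af_eur[is_rare_bg] <- pmin(bg_af_eur[is_rare_bg], 0.009)
    bg_af_eur <- round(bg_af_eur, 6)

    bg_cons <- sample(CONSEQUENCE_LEVELS, nbg, replace = TRUE,
                      prob = c(0.35, 0.2, 0.1, 0.25, 0.1))
    pred <- matrix("unknown", n_total, length(PREDICTOR_TOOLS),
                   dimnames = list(NULL, PREDICTOR_TOOLS))
    for (t in seq_along(PREDICTOR_TOOLS))
      pred[seq_len(nbg), t] <- random_predictor_calls(nbg, config$bg_damaging_rate)
    bg_clinvar <- sample(CLINVAR_LEVELS, nbg, replace = TRUE,
                         prob = c(0.01, 0.06, 0.03, 0.9))
    bg_hq <- stats::runif(nbg) < 0.5

    # planted variants
    pl_rows <- nbg + seq_len(pl_n)
    pl_af_eur <- rep(NA_real_, pl_n)
    for (i in seq_len(pl_n)) {
      p <- planted[i, ]
      row <- pl_rows[i]
      carriers <- switch(p$pattern,
        SIBS_PLUS_ONE = c(sibs, sample(nonsib_wes, 1L)),
        SIBS_ONLY = sibs,
        SINGLETON = sample(nonsib_wes, 1L),
        TWO_NONSIB = sample(nonsib_wes, 2L),
        stop("unknown sharing pattern: ", p$pattern))
      if (p$n_screen_carriers) carriers <- c(carriers, sample(ids_scr, p$n_screen_carriers))
      if (p$n_index_carriers) carriers <- c(carriers, sample(ids_idx, p$n_index_carriers))
      ctl_car <- if (p$n_control_carriers) sample(ids_ctl, p$n_control_carriers) else character(0)
      geno[row, c(carriers, ctl_car)] <- 1L
      if (p$control_hom && length(ctl_car)) geno[row, ctl_car[1]] <- 2L
      if (p$quality_fail) qual[row, sibs[1]] <- FALSE
      stringent_dmg <- sample(STRINGENT_TOOLS, p$n_damaging_stringent)
      other_dmg <- sample(setdiff(PREDICTOR_TOOLS, STRINGENT_TOOLS),
                          p$n_damaging_other)
      pred[row, ] <- "tolerated"
      pred[row, c(stringent_dmg, other_dmg)] <- "damaging"
      if (!is.na(p$af_global)) {
        pl_af_eur[i] <- min(p$af_global * stats::runif(1, 0.8, 1.2),
                            if (p$af_global >= 0.01) Inf else 0.009)
        if (p$af_global >= 0.01) pl_af_eur[i] <- max(pl_af_eur[i], 0.01)
        pl_af_eur[i] <- round(pl_af_eur[i], 6)
      }
    }

    variants <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      gene = c(sprintf("BGGENE%04d", seq_len(nbg)), planted$gene),
      hgvs_c = sprintf("c.%d%s>%s", seq_len(n_total), ref, alt),
      hgvs_p = c(ifelse(bg_cons == "exonic_synonymous",
                        sprintf("p.Pro%d=", seq_len(nbg)),
                        sprintf("p.Ala%dThr", seq_len(nbg))),
                 ifelse(planted$consequence == "exonic_synonymous",
                        sprintf("p.Pro%d=", pl_rows),
                        sprintf("p.Ala%dThr", pl_rows))),
      consequence = c(bg_cons, planted$consequence),
      af_global = c(bg_af_global, planted$af_global),
      af_european = c(bg_af_eur, pl_af_eur),
      sift = pred[, "sift"], polyphen2 = pred[, "polyphen2"],
      metasvm = pred[, "metasvm"], metalr = pred[, "metalr"],
      provean = pred[, "provean"], mutationtaster = pred[, "mutationtaster"],
      fathmm = pred[, "fathmm"],
      clinvar = c(bg_clinvar, planted$clinvar),
      ensembl_hq = c(bg_hq, planted$ensembl_hq),
      validated = FALSE,
      stringsAsFactors = FALSE)
    truth <- data.frame(key = variant_keys(variants)[pl_rows],
                        variant_id = planted$id, gene = planted$gene,
                        pattern = planted$pattern, fate = planted$fate,
                        drop_step = planted$drop_step,
                        stringsAsFactors = FALSE)
    list(av = annotated_variants(variants, geno, qual), truth = truth)
  })

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(vcf = file.path(dir, "cohort.vcf"),
               samples = file.path(dir, "samples.tsv"),
               truth = file.path(dir, "truth_table.tsv"))
    write_vcf(out$av, paths[["vcf"]])
    write_sample_sheet(cohort, paths[["samples"]])
    utils::write.table(out$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  list(av = out$av, cohort = cohort, truth = out$truth, paths = paths)
}

#' Simulate a null case/control genotype matrix
#'
#' Genotypes drawn `Binomial(2, maf)` per variant, independent of the
#' phenotype; `y` has exactly `n_case` ones followed by `n_ctrl` zeros.
#'
#' @param n_case,n_ctrl Group sizes.
#' @param m Number of variants.
#' @param mafs Per-variant minor-allele fractions in `(0, 0.5]` (recycled to
#'   length `m`).
#' @param seed Integer seed.
#' @return List with `G` and `y`.
#' @export
simulate_null_case_control <- function(n_case, n_ctrl, m, mafs, seed = 1L) {
  stopifnot(all(mafs > 0), all(mafs <= 0.5))
  mafs <- rep_len(mafs, m)
  n <- n_case + n_ctrl
  G <- with_seed(seed,
    matrix(stats::rbinom(n * m, 2L, rep(mafs, each = n)), n, m))
  list(G = G, y = c(rep(1, n_case), rep(0, n_ctrl)))
}

#' Simulate a case/control genotype matrix with planted effects
#'
#' Retrospective sampling under a per-variant multiplicative odds model:
#' control genotypes follow the population Hardy-Weinberg distribution (rare
#' disease approximation) while case genotype probabilities are tilted
#' proportionally to `OR^g`. Independent variants, no linkage.
#'
#' @inheritParams simulate_null_case_control
#' @param odds_ratios Per-allele odds ratios (> 0, recycled to length `m`);
#'   values below 1 encode protective variants.
#' @return List with `G` and `y`.
#' @export
simulate_effect_case_control <- function(n_case, n_ctrl, m, mafs, odds_ratios,
                                         seed = 1L) {
  stopifnot(all(mafs > 0), all(mafs <= 0.5), all(odds_ratios > 0))
  mafs <- rep_len(mafs, m)
  odds_ratios <- rep_len(odds_ratios, m)
  with_seed(seed, {
    Gcase <- sapply(seq_len(m), function(j) {
      hw <- stats::dbinom(0:2, 2L, mafs[j])
      pr <- hw * odds_ratios[j]^(0:2)
      sample(0:2, n_case, replace = TRUE, prob = pr / sum(pr))
    })
    Gctrl <- sapply(seq_len(m), function(j)
      stats::rbinom(n_ctrl, 2L, mafs[j]))
    list(G = rbind(matrix(Gcase, n_case, m), matrix(Gctrl, n_ctrl, m)),
         y = c(rep(1, n_case), rep(0, n_ctrl)))
  })
}
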