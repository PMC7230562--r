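# The variant-selection cascade: quality gate, cohort-sharing criteria,
# broad/stringent annotation selection, allele-frequency / synonymous /
# polyvariant-gene exclusions, and the final recurrence + pathogenicity
# selection. Every step maps a variant set to a subset; run_cascade chains
# them and reports the per-step funnel.

#' Cascade configuration
#'
#' @param criteria_mode Sharing rule: `CRITERIA1` (both siblings plus at least
#'   one other whole-exome case), `CRITERIA2` (at least two non-sibling cases)
#'   or `UNION` of the two.
#' @param approach Annotation selection: `BROAD` (all exonic variants),
#'   `STRINGENT` (exonic/intronic with quality, ClinVar or predictor support)
#'   or `UNION`.
#' @param af_threshold Population allele-frequency cutoff (fraction).
#' @param af_inclusive If `TRUE` (default) a frequency equal to the threshold
#'   is excluded (`af >= threshold`); if `FALSE`, strictly above only.
#' @param af_populations Which population frequencies trigger exclusion.
#' @param max_variants_per_gene Genes carrying at least this many surviving
#'   variants are excluded wholesale (default 4).
#' @param min_final_carriers Final recurrence threshold: a candidate must be
#'   carried by at least this many patients (whole-exome plus screened cases;
#'   default 3, i.e. "more than two").
#' @param min_damaging_tools Minimum number of damaging calls among the
#'   seven-tool predictor panel for the final selection (default 1).
#' @param keep_synonymous If `TRUE`, synonymous variants are not excluded.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(criteria_mode = c("UNION", "CRITERIA1", "CRITERIA2"),
                           approach = c("UNION", "BROAD", "STRINGENT"),
                           af_threshold = 0.01,
                           af_inclusive = TRUE,
                           af_populations = c("global", "european"),
                           max_variants_per_gene = 4L,
                           min_final_carriers = 3L,
                           min_damaging_tools = 1L,
                           keep_synonymous = FALSE) {
  criteria_mode <- match.arg(criteria_mode)
  approach <- match.arg(approach)
  af_populations <- match.arg(af_populations, several.ok = TRUE)
  stopifnot(af_threshold > 0, af_threshold <= 1,
            max_variants_per_gene >= 1L, min_final_carriers >= 1L,
            min_damaging_tools >= 0L)
  structure(list(criteria_mode = criteria_mode, approach = approach,
                 af_threshold = af_threshold, af_inclusive = af_inclusive,
                 af_populations = af_populations,
                 max_variants_per_gene = as.integer(max_variants_per_gene),
                 min_final_carriers = as.integer(min_final_carriers),
                 min_damaging_tools = as.integer(min_damaging_tools),
                 keep_synonymous = keep_synonymous),
            class = "cascade_config")
}

#' Quality gate
#'
#' Keeps variants whose whole-exome-case genotypes are all defined and flagged
#' quality-pass; the sharing logic downstream relies on these calls.
#'
#' @param av An `annotated_variants` object.
#' @param cohort A `cohort_design`.
#' @return The filtered `annotated_variants`.
#' @export
quality_filter <- function(av, cohort) {
  wes <- intersect(samples_in_group(cohort, "WES_CASE"), av_samples(av))
  if (!length(wes)) return(av)
  g <- av$geno[, wes, drop = FALSE]
  q <- av$qual[, wes, drop = FALSE]
  keep <- rowSums(is.na(g) | !q) == 0L
  subset_variants(av, keep)
}

#' Cohort-sharing filter
#'
#' Criteria 1 keeps variants carried by both members of a sibling pair and by
#' at least one other whole-exome case; Criteria 2 keeps variants carried by
#' at least two whole-exome cases that are not the two members of a single
#' sibling pair; `UNION` keeps variants satisfying either.
#'
#' @param av An `annotated_variants` object.
#' @param cohort A `cohort_design` (must contain a sibling pair for
#'   Criteria 1).
#' @param mode `"CRITERIA1"`, `"CRITERIA2"` or `"UNION"`.
#' @return The filtered `annotated_variants`.
#' @export
sharing_filter <- function(av, cohort, mode = c("UNION", "CRITERIA1", "CRITERIA2")) {
  mode <- match.arg(mode)
  wes <- intersect(samples_in_group(cohort, "WES_CASE"), av_samples(av))
  pairs <- sibling_pairs(cohort)
  pairs <- lapply(pairs, intersect, wes)
  pairs <- pairs[lengths(pairs) == 2L]
  if (mode %in% c("CRITERIA1", "UNION") && !length(pairs) && mode == "CRITERIA1")
    stop("Criteria 1 requires a sibling pair in the cohort")
  carr <- carrier_matrix(av)[, wes, drop = FALSE]
  c1 <- rep(FALSE, n_variants(av))
  for (p in pairs) {
    both <- carr[, p[1]] & carr[, p[2]]
    others <- rowSums(carr[, setdiff(wes, p), drop = FALSE]) >= 1L
    c1 <- c1 | (both & others)
  }
  # Criteria 2: two carriers that are not jointly one sibling pair
  nc <- rowSums(carr)
  c2 <- nc >= 2L
  for (p in pairs) {
    only_pair <- nc == 2L & carr[, p[1]] & carr[, p[2]]
    c2 <- c2 & !only_pair
  }
  keep <- switch(mode, CRITERIA1 = c1, CRITERIA2 = c2, UNION = c1 | c2)
  subset_variants(av, keep)
}

#' Annotation-based selection
#'
#' `BROAD` keeps all exonic variants; `STRINGENT` keeps exonic and intronic
#' variants featuring at least one of: Ensembl high-quality flag, any ClinVar
#' record, or a damaging call from SIFT, PolyPhen-2, MetaSVM or MetaLR;
#' `UNION` keeps variants passing either approach.
#'
#' @param av An `annotated_variants` object.
#' @param approach `"BROAD"`, `"STRINGENT"` or `"UNION"`.
#' @return The filtered `annotated_variants`.
#' @export
annotation_selection <- function(av, approach = c("UNION", "BROAD", "STRINGENT")) {
  approach <- match.arg(approach)
  v <- av$variants
  exonic <- startsWith(v$consequence, "exonic")
  broad <- exonic
  support <- v$ensembl_hq | v$clinvar != "absent"
  for (tool in STRINGENT_TOOLS) support <- support | v[[tool]] == "damaging"
  stringent <- (exonic | v$consequence == "intronic") & support
  keep <- switch(approach, BROAD = broad, STRINGENT = stringent,
                 UNION = broad | stringent)
  subset_variants(av, keep)
}

#' Exclude common polymorphisms
#'
#' Drops variants whose allele frequency in any selected population reaches
#' the threshold. Unknown frequencies never trigger exclusion.
#'
#' @param av An `annotated_variants` object.
#' @param af_threshold Frequency cutoff (default 0.01).
#' @param populations Subset of `c("global", "european")`.
#' @param inclusive If `TRUE` (default), `af >= threshold` is excluded.
#' @return The filtered `annotated_variants`.
#' @export
exclude_common <- function(av, af_threshold = 0.01,
                           populations = c("global", "european"),
                           inclusive = TRUE) {
  stopifnot(af_threshold > 0)
  populations <- match.arg(populations, several.ok = TRUE)
  v <- av$variants
  hit <- rep(FALSE, nrow(v))
  for (p in populations) {
    af <- v[[paste0("af_", p)]]
    h <- if (inclusive) af >= af_threshold else af > af_threshold
    h[is.na(h)] <- FALSE
    hit <- hit | h
  }
  subset_variants(av, !hit)
}

#' Exclude synonymous variants
#' @param av An `annotated_variants` object.
#' @return The filtered `annotated_variants`.
#' @export
exclude_synonymous <- function(av) {
  subset_variants(av, av$variants$consequence != "exonic_synonymous")
}

#' Exclude genes harbouring many variants
#'
#' Counts surviving variants per gene symbol and removes every variant of a
#' gene whose count reaches `max_variants_per_gene` (default 4, i.e. "four or
#' more"). The count is taken over the input set, so this step is
#' order-sensitive with respect to the preceding exclusions.
#'
#' @param av An `annotated_variants` object.
#' @param max_variants_per_gene Gene-level exclusion threshold.
#' @return The filtered `annotated_variants`.
#' @export
exclude_polyvariant_genes <- function(av, max_variants_per_gene = 4L) {
  stopifnot(max_variants_per_gene >= 1L)
  gene <- av$variants$gene
  cnt <- table(gene[!is.na(gene) & gene != ""])
  bad <- names(cnt)[cnt >= max_variants_per_gene]
  subset_variants(av, !(gene %in% bad))
}

#' Final candidate selection
#'
#' Keeps variants carried by at least `min_final_carriers` patients
#' (whole-exome cases plus screened cases) and called damaging by at least
#' `min_damaging_tools` of the seven-predictor panel.
#'
#' @param av An `annotated_variants` object.
#' @param cohort A `cohort_design`.
#' @param min_final_carriers Recurrence threshold (default 3).
#' @param min_damaging_tools Pathogenicity-support threshold (default 1).
#' @return The filtered `annotated_variants`.
#' @export
select_candidates <- function(av, cohort, min_final_carriers = 3L,
                              min_damaging_tools = 1L) {
  patients <- intersect(c(samples_in_group(cohort, "WES_CASE"),
                          samples_in_group(cohort, "MPM_SCREEN")),
                        av_samples(av))
  carr <- carrier_matrix(av)[, patients, drop = FALSE]
  enough <- rowSums(carr) >= min_final_carriers
  ndam <- rep(0L, n_variants(av))
  for (tool in PREDICTOR_TOOLS)
    ndam <- ndam + (av$variants[[tool]] == "damaging")
  subset_variants(av, enough & ndam >= min_damaging_tools)
}

#' Run the full selection cascade
#'
#' Applies, in order: quality gate, cohort-sharing filter, annotation
#' selection, common-polymorphism exclusion, synonymous exclusion,
#' polyvariant-gene exclusion, and final candidate selection. Returns the
#' candidates and a chained per-step funnel report.
#'
#' @param av An `annotated_variants` object.
#' @param cohort A `cohort_design`.
#' @param config A [cascade_config()].
#' @return List with elements `candidates` (an `annotated_variants`) and
#'   `funnel` (a `funnel_report` data.frame: step, n_in, n_out).
#' @export
run_cascade <- function(av, cohort, config = cascade_config()) {
  stopifnot(inherits(config, "cascade_config"))
  steps <- list(
    quality = function(x) quality_filter(x, cohort),
    sharing = function(x) sharing_filter(x, cohort, config$criteria_mode),
    annotation = function(x) annotation_selection(x, config$approach),
    allele_frequency = function(x)
      exclude_common(x, config$af_threshold, config$af_populations,
                     config$af_inclusive),
    synonymous = function(x) if (config$keep_synonymous) x else exclude_synonymous(x),
    polyvariant_genes = function(x)
      exclude_polyvariant_genes(x, config$max_variants_per_gene),
    final_selection = function(x)
      select_candidates(x, cohort, config$min_final_carriers,
                        config$min_damaging_tools))
  funnel <- data.frame(step = names(steps), n_in = NA_integer_,
                       n_out = NA_integer_, stringsAsFactors = FALSE)
  cur <- av
  for (i in seq_along(steps)) {
    funnel$n_in[i] <- n_variants(cur)
    cur <- steps[[i]](cur)
    funnel$n_out[i] <- n_variants(cur)
  }
  class(funnel) <- c("funnel_report", "data.frame")
  list(candidates = cur, funnel = funnel)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("variant-selection funnel:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-18s %6d -> %6d\n", x$step[i], x$n_in[i], x$n_out[i]))
  invisible(x)
}
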