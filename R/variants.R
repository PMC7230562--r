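# Internal data model: an annotated variant set is a data.frame of variant
# records plus parallel genotype / genotype-quality matrices (variants x samples).

CONSEQUENCE_LEVELS <- c("exonic_missense", "exonic_synonymous", "exonic_other",
                        "intronic", "other")
PREDICTOR_TOOLS <- c("sift", "polyphen2", "metasvm", "metalr",
                     "provean", "mutationtaster", "fathmm")
# tools consulted by the stringent annotation approach
STRINGENT_TOOLS <- c("sift", "polyphen2", "metasvm", "metalr")
PREDICTOR_LEVELS <- c("damaging", "tolerated", "unknown")
CLINVAR_LEVELS <- c("pathogenic_or_likely", "uncertain", "benign_or_likely", "absent")
GROUP_LEVELS <- c("WES_CASE", "MPM_SCREEN", "FAMILIAL_INDEX", "HEALTHY_CONTROL")

#' Variant keys
#'
#' Canonical `chrom:pos:ref:alt` key for each variant record.
#'
#' @param x An `annotated_variants` object or a data.frame with columns
#'   `chrom`, `pos`, `ref`, `alt`.
#' @return Character vector of keys.
#' @export
variant_keys <- function(x) {
  df <- if (inherits(x, "annotated_variants")) x$variants else x
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

chrom_rank <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  r <- suppressWarnings(as.integer(x))
  r[x %in% "X"] <- 23L
  r[x %in% "Y"] <- 24L
  r[x %in% c("M", "MT")] <- 25L
  # non-standard contigs sort after, alphabetically
  bad <- is.na(r)
  if (any(bad)) r[bad] <- 25L + as.integer(factor(x[bad], levels = sort(unique(x[bad]))))
  r
}

variant_order <- function(df) {
  order(chrom_rank(df$chrom), df$pos, df$ref, df$alt, method = "radix")
}

#' Construct an annotated variant set
#'
#' Bundles normalized bi-allelic variant records with per-sample genotype
#' calls. `geno` holds alternate-allele counts (0/1/2, `NA` = undefined
#' genotype); `qual` holds the genotype-level quality-pass flag. Rows are
#' sorted deterministically by (chrom, pos, ref, alt).
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `hgvs_c`, `hgvs_p`, `consequence`, `af_global`, `af_european`
#'   (`NA` = unknown frequency), one column per predictor tool
#'   (`sift`, `polyphen2`, `metasvm`, `metalr`, `provean`, `mutationtaster`,
#'   `fathmm`; values `damaging`/`tolerated`/`unknown`), `clinvar`,
#'   `ensembl_hq` (logical), `validated` (logical).
#' @param geno integer matrix (variants x samples) of alternate-allele counts.
#' @param qual logical matrix of the same shape; `TRUE` = quality pass.
#' @return An object of class `annotated_variants`.
#' @export
annotated_variants <- function(variants, geno, qual = NULL) {
  stopifnot(is.data.frame(variants))
  req <- c("chrom", "pos", "ref", "alt", "gene", "hgvs_c", "hgvs_p",
           "consequence", "af_global", "af_european", PREDICTOR_TOOLS,
           "clinvar", "ensembl_hq", "validated")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants is missing columns: ", paste(miss, collapse = ", "))
  if (any(grepl(",", variants$alt))) stop("variants must be bi-allelic (single alt allele)")
  if (!all(variants$consequence %in% CONSEQUENCE_LEVELS))
    stop("invalid consequence class")
  if (!all(variants$clinvar %in% CLINVAR_LEVELS)) stop("invalid clinvar class")
  for (tool in PREDICTOR_TOOLS)
    if (!all(variants[[tool]] %in% PREDICTOR_LEVELS))
      stop("invalid call for predictor ", tool)
  geno <- as.matrix(geno)
  mode(geno) <- "integer"
  if (nrow(geno) != nrow(variants)) stop("geno/variants row mismatch")
  if (!all(geno %in% c(0L, 1L, 2L, NA))) stop("allele counts must be 0, 1, 2 or NA")
  if (is.null(qual)) qual <- matrix(TRUE, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  qual <- as.matrix(qual)
  if (!identical(dim(qual), dim(geno))) stop("qual/geno shape mismatch")
  mode(qual) <- "logical"
  keys <- variant_keys(variants)
  if (anyDuplicated(keys)) stop("duplicate variant keys: ",
                                paste(keys[duplicated(keys)], collapse = ", "))
  if (is.null(colnames(geno))) stop("geno must have sample_id column names")
  ord <- variant_order(variants)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  geno <- geno[ord, , drop = FALSE]
  qual <- qual[ord, , drop = FALSE]
  rownames(geno) <- rownames(qual) <- keys[ord]
  colnames(qual) <- colnames(geno)
  structure(list(variants = variants, geno = geno, qual = qual),
            class = "annotated_variants")
}

#' @export
print.annotated_variants <- function(x, ...) {
  cat(sprintf("annotated_variants: %d variants x %d samples\n",
              nrow(x$variants), ncol(x$geno)))
  tab <- table(factor(x$variants$consequence, levels = CONSEQUENCE_LEVELS))
  cat("  consequence:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Number of variants in a set
#' @param av An `annotated_variants` object.
#' @return Integer count.
#' @export
n_variants <- function(av) nrow(av$variants)

#' Sample identifiers of a variant set
#' @param av An `annotated_variants` object.
#' @return Character vector of sample ids.
#' @export
av_samples <- function(av) colnames(av$geno)

#' Subset a variant set by row index or logical mask
#' @param av An `annotated_variants` object.
#' @param i Integer or logical index over variants.
#' @return The subsetted `annotated_variants` object (order preserved).
#' @export
subset_variants <- function(av, i) {
  v <- av$variants[i, , drop = FALSE]
  rownames(v) <- NULL
  structure(list(variants = v,
                 geno = av$geno[i, , drop = FALSE],
                 qual = av$qual[i, , drop = FALSE]),
            class = "annotated_variants")
}

# carriers: allele_count >= 1 (het or hom), missing counted as non-carrier
carrier_matrix <- function(av) {
  m <- av$geno >= 1L
  m[is.na(m)] <- FALSE
  m
}

#' Construct a cohort design
#'
#' Validates the sample sheet of the study: sample roles (whole-exome cases,
#' additionally screened multiple-primary-melanoma cases, familial-melanoma
#' indexes, healthy controls) and the sibling-pair structure among the
#' whole-exome cases.
#'
#' @param samples data.frame with columns `sample_id`, `group` (one of
#'   `WES_CASE`, `MPM_SCREEN`, `FAMILIAL_INDEX`, `HEALTHY_CONTROL`) and
#'   `sibling_pair_id` (`NA` or a pair label shared by exactly two WES cases).
#' @return An object of class `cohort_design` (a validated data.frame).
#' @export
cohort_design <- function(samples) {
  stopifnot(is.data.frame(samples))
  req <- c("sample_id", "group", "sibling_pair_id")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$group <- as.character(samples$group)
  sp <- as.character(samples$sibling_pair_id)
  sp[!is.na(sp) & sp == ""] <- NA_character_
  samples$sibling_pair_id <- sp
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(samples$group), GROUP_LEVELS)
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  pairs <- split(seq_len(nrow(samples)), samples$sibling_pair_id)
  for (pid in names(pairs)) {
    idx <- pairs[[pid]]
    if (length(idx) != 2L)
      stop("sibling_pair_id '", pid, "' is used by ", length(idx),
           " samples; a sibling pair must have exactly two members")
    if (!all(samples$group[idx] == "WES_CASE"))
      stop("sibling_pair_id '", pid, "' includes non-WES samples")
  }
  rownames(samples) <- NULL
  structure(samples[req], class = c("cohort_design", "data.frame"))
}

#' @export
print.cohort_design <- function(x, ...) {
  tab <- table(factor(x$group, levels = GROUP_LEVELS))
  cat(sprintf("cohort_design: %d samples (%s), %d sibling pair(s)\n",
              nrow(x), paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
              length(sibling_pairs(x))))
  invisible(x)
}

#' Samples belonging to a cohort group
#' @param cohort A `cohort_design`.
#' @param group One of the four group labels.
#' @return Character vector of sample ids.
#' @export
samples_in_group <- function(cohort, group) {
  group <- match.arg(group, GROUP_LEVELS)
  cohort$sample_id[cohort$group == group]
}

#' Sibling pairs of a cohort
#' @param cohort A `cohort_design`.
#' @return Named list; each element is the two sample ids of one pair.
#' @export
sibling_pairs <- function(cohort) {
  keep <- !is.na(cohort$sibling_pair_id)
  split(cohort$sample_id[keep], cohort$sibling_pair_id[keep])
}
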