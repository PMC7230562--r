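# VCF and tabular I/O. Parsing of multi-sample VCFs is delegated to vcfR;
# this layer normalizes records into the internal annotated_variants model:
# multi-allelic records are split, "./." becomes an undefined genotype, and a
# configurable annotation dialect maps a CSQ-style INFO transcript string onto
# the annotation bundle consumed by the filtering cascade.

#' Default annotation dialect
#'
#' Describes where the annotation bundle lives in a VCF. The default layout is
#' a VEP-CSQ-style pipe-delimited transcript string in `INFO/CSQ`, one entry
#' per alternate allele, with a fixed field order; genotype-level quality
#' lives in the per-sample `FT` field (`PASS` = quality pass).
#'
#' @param csq_tag INFO tag holding the annotation string.
#' @param fields Ordered names of the pipe-delimited subfields.
#' @param ft_tag FORMAT tag holding the per-genotype filter flag (optional in
#'   the file; absent means all genotypes pass).
#' @return A list of class `annotation_dialect`.
#' @export
default_dialect <- function(csq_tag = "CSQ",
                            fields = c("allele", "gene", "consequence",
                                       "hgvsc", "hgvsp",
                                       "af_global", "af_european",
                                       "sift", "polyphen2", "metasvm", "metalr",
                                       "provean", "mutationtaster", "fathmm",
                                       "clinvar", "ensembl_hq"),
                            ft_tag = "FT") {
  structure(list(csq_tag = csq_tag, fields = fields, ft_tag = ft_tag),
            class = "annotation_dialect")
}

# fixed vocabulary tables: raw annotation strings -> internal enums
normalize_consequence <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("other", length(x))
  out[x %in% c("exonic_missense", "missense_variant", "missense")] <- "exonic_missense"
  out[x %in% c("exonic_synonymous", "synonymous_variant", "synonymous")] <- "exonic_synonymous"
  out[x %in% c("exonic_other", "stop_gained", "stop_lost", "start_lost",
               "frameshift_variant", "inframe_insertion", "inframe_deletion",
               "protein_altering_variant", "coding_sequence_variant")] <- "exonic_other"
  out[x %in% c("intronic", "intron_variant", "splice_region_variant")] <- "intronic"
  out
}

normalize_predictor <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("unknown", length(x))
  out[x %in% c("damaging", "deleterious", "probably_damaging", "possibly_damaging",
               "disease_causing", "disease_causing_automatic", "d", "a", "h", "m")] <- "damaging"
  out[x %in% c("tolerated", "benign", "neutral", "polymorphism",
               "polymorphism_automatic", "t", "n", "p", "l")] <- "tolerated"
  out
}

normalize_clinvar <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("absent", length(x))
  out[x %in% c("pathogenic", "likely_pathogenic", "pathogenic/likely_pathogenic",
               "pathogenic_or_likely")] <- "pathogenic_or_likely"
  out[x %in% c("uncertain", "uncertain_significance", "vus")] <- "uncertain"
  out[x %in% c("benign", "likely_benign", "benign/likely_benign",
               "benign_or_likely")] <- "benign_or_likely"
  out
}

parse_af <- function(x) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  out[x == "" | toupper(x) == "NA" | x == "."] <- NA_real_
  out
}

# allele count of one GT string with respect to alt index k
gt_allele_count <- function(gt, k) {
  # vectorized over unique GT strings for speed
  u <- unique(gt)
  alleles <- strsplit(u, "[/|]")
  uc <- vapply(seq_along(u), function(i) {
    a <- alleles[[i]]
    if (is.na(u[i]) || !length(a) || any(a == ".")) return(NA_integer_)
    sum(a == as.character(k))
  }, integer(1))
  uc[match(gt, u)]
}

#' Read a multi-sample annotated VCF
#'
#' Parses a VCF 4.x file, splits multi-allelic records into bi-allelic
#' variants (per-sample allele counts recomputed per alternate allele), turns
#' `./.` genotypes into undefined calls, and maps the annotation dialect onto
#' the internal annotation bundle. Unknown population frequencies stay
#' distinct from zero.
#'
#' @param path VCF file path.
#' @param dialect An `annotation_dialect` (see [default_dialect()]).
#' @param cohort Optional `cohort_design`; if supplied, every VCF sample must
#'   be part of the cohort.
#' @return An `annotated_variants` object, sorted by (chrom, pos, ref, alt).
#' @export
read_vcf <- function(path, dialect = default_dialect(), cohort = NULL) {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#"))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 10L))
    stop("malformed VCF line ", body[which(nfield < 10L)[1L]],
         ": expected at least 10 tab-separated fields")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_raw)
  if (!is.null(cohort)) {
    extra <- setdiff(samples, cohort$sample_id)
    if (length(extra))
      stop("VCF sample(s) absent from cohort: ", paste(extra, collapse = ", "))
  }
  ft_raw <- NULL
  has_ft <- any(grepl(paste0("(^|:)", dialect$ft_tag, "(:|$)"), vcf@gt[, "FORMAT"]))
  if (has_ft) ft_raw <- vcfR::extract.gt(vcf, element = dialect$ft_tag)
  info <- vcf@fix[, "INFO"]

  rows <- list(); genos <- list(); quals <- list()
  nf <- length(dialect$fields)
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    csq <- sub(paste0(".*", dialect$csq_tag, "="), "", info[i])
    csq <- sub(";.*", "", csq)
    entries <- strsplit(csq, ",", fixed = TRUE)[[1]]
    parsed <- lapply(entries, function(e) {
      f <- strsplit(e, "|", fixed = TRUE)[[1]]
      length(f) <- nf
      f[is.na(f)] <- ""
      stats::setNames(as.list(f), dialect$fields)
    })
    csq_alleles <- vapply(parsed, function(p) p$allele, character(1))
    for (k in seq_along(alts)) {
      hit <- which(csq_alleles == alts[k])
      ann <- if (length(hit)) parsed[[hit[1]]] else if (length(parsed) >= k)
        parsed[[k]] else stats::setNames(as.list(rep("", nf)), dialect$fields)
      cnt <- gt_allele_count(gt_raw[i, ], k)
      qp <- if (is.null(ft_raw)) rep(TRUE, length(samples)) else {
        f <- ft_raw[i, ]
        is.na(f) | f == "" | f == "PASS"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k],
        gene = ann$gene, hgvs_c = ann$hgvsc, hgvs_p = ann$hgvsp,
        consequence = normalize_consequence(ann$consequence),
        af_global = parse_af(ann$af_global),
        af_european = parse_af(ann$af_european),
        sift = normalize_predictor(ann$sift),
        polyphen2 = normalize_predictor(ann$polyphen2),
        metasvm = normalize_predictor(ann$metasvm),
        metalr = normalize_predictor(ann$metalr),
        provean = normalize_predictor(ann$provean),
        mutationtaster = normalize_predictor(ann$mutationtaster),
        fathmm = normalize_predictor(ann$fathmm),
        clinvar = normalize_clinvar(ann$clinvar),
        ensembl_hq = ann$ensembl_hq %in% c("1", "TRUE", "true", "yes"),
        validated = FALSE,
        stringsAsFactors = FALSE)
      genos[[length(genos) + 1L]] <- cnt
      quals[[length(quals) + 1L]] <- qp
    }
  }
  variants <- do.call(rbind, rows)
  geno <- do.call(rbind, genos)
  qual <- do.call(rbind, quals)
  colnames(geno) <- colnames(qual) <- samples
  annotated_variants(variants, geno, qual)
}

#' Write a variant set as an annotated multi-sample VCF
#'
#' Inverse of [read_vcf()] for the default dialect: annotation bundle as a
#' CSQ-style INFO string, genotypes as `GT:FT` with `./.` for undefined calls.
#' Output is deterministic (byte-identical for identical input).
#'
#' @param av An `annotated_variants` object.
#' @param path Output file path.
#' @param dialect An `annotation_dialect`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(av, path, dialect = default_dialect()) {
  v <- av$variants
  fmt_af <- function(x) ifelse(is.na(x), "",
                               sub("\\.$", "", sub("0+$", "", sprintf("%.6f", x))))
  csq <- paste(v$alt, v$gene, v$consequence, v$hgvs_c, v$hgvs_p,
               fmt_af(v$af_global), fmt_af(v$af_european),
               v$sift, v$polyphen2, v$metasvm, v$metalr,
               v$provean, v$mutationtaster, v$fathmm,
               v$clinvar, ifelse(v$ensembl_hq, "1", "0"), sep = "|")
  gt_str <- matrix(c("0/0", "0/1", "1/1")[av$geno + 1L],
                   nrow = nrow(av$geno), ncol = ncol(av$geno))
  gt_str[is.na(av$geno)] <- "./."
  ft_str <- ifelse(av$qual, "PASS", "LOWQ")
  cells <- matrix(paste(gt_str, ft_str, sep = ":"), nrow = nrow(gt_str))
  body <- paste(v$chrom, v$pos, variant_keys(v), v$ref, v$alt, ".", "PASS",
                paste0(dialect$csq_tag, "=", csq), "GT:FT",
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=melscreen",
    sprintf("##INFO=<ID=%s,Number=.,Type=String,Description=\"Annotation bundle. Format: %s\">",
            dialect$csq_tag, paste(dialect$fields, collapse = "|")),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("##FORMAT=<ID=%s,Number=1,Type=String,Description=\"Genotype-level filter (PASS or LOWQ)\">",
            dialect$ft_tag),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(av$geno)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated file with header `sample_id`, `group`, `sibling_pair_id`;
#' returns a validated [cohort_design()].
#'
#' @param path TSV file path.
#' @return A `cohort_design`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("no such sample sheet: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = c("NA", ""))
  cohort_design(df)
}

#' Write a sample sheet
#' @param cohort A `cohort_design`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write the candidate report
#'
#' Tab-separated report in the layout of a published candidate-frequency
#' table — one row per variant with gene, coding/protein change and per-group
#' `(carriers/denominator) percent%` cells — plus a machine-readable JSON
#' sidecar with the raw counts.
#'
#' @param av `annotated_variants` of the candidate variants.
#' @param table A `carrier_table` whose rows correspond to `av` (same keys).
#' @param path Output prefix; writes `<path>.tsv` and `<path>.json`.
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_candidates <- function(av, table, path) {
  keys <- variant_keys(av)
  if (!setequal(keys, table$key) || nrow(table) != length(keys))
    stop("variant/table key mismatch")
  table <- table[match(keys, table$key), , drop = FALSE]
  groups <- attr(table, "groups")
  out <- data.frame(gene = table$gene, hgvs_c = table$hgvs_c,
                    hgvs_p = table$hgvs_p, stringsAsFactors = FALSE)
  for (g in groups) {
    k <- table[[paste0(g, "_carriers")]]
    n <- table[[paste0(g, "_n")]]
    p <- table[[paste0(g, "_pct")]]
    out[[g]] <- sprintf("(%d/%d) %.1f%%", k, n, p)
  }
  tsv <- paste0(path, ".tsv"); json <- paste0(path, ".json")
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.data.frame(table), json, digits = NA, na = "null", pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' Read back a candidate report JSON
#' @param path Path to the `.json` file written by [write_candidates()].
#' @param groups Group labels present in the table (default all three).
#' @return A `carrier_table` data.frame.
#' @export
read_candidates_json <- function(path, groups = c("MPM", "INDEX", "CONTROL")) {
  df <- jsonlite::fromJSON(path)
  groups <- groups[paste0(groups, "_carriers") %in% names(df)]
  attr(df, "groups") <- groups
  class(df) <- c("carrier_table", "data.frame")
  df
}
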