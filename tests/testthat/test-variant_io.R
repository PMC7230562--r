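# VCF / sample-sheet / report I-O and normalization into the internal model.

write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Annotation\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=FT,Number=1,Type=String,Description=\"Filter\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSA\tSB\tSC")
  writeLines(c(header, lines), path)
  path
}

csq <- function(alt, gene = "GENE1", cons = "missense_variant",
                af = "0.001", eur = "", sift = "deleterious") {
  paste(alt, gene, cons, "c.1A>G", "p.K1R", af, eur, sift,
        "", "", "", "", "", "", "", "1", sep = "|")
}

test_that("a toy VCF is parsed record-for-record with per-sample calls", {
  p <- write_toy_vcf(c(
    sprintf("1\t100\t.\tA\tG\t.\tPASS\tCSQ=%s\tGT:FT\t0/1:PASS\t0/0:PASS\t1/1:PASS", csq("G")),
    sprintf("2\t200\t.\tC\tT\t.\tPASS\tCSQ=%s\tGT:FT\t0/0:PASS\t./.:PASS\t0/1:LOWQ",
            csq("T", gene = "GENE2", cons = "intron_variant", af = ""))))
  av <- read_vcf(p)
  expect_equal(n_variants(av), 2L)
  expect_equal(ncol(av$geno), 3L)
  expect_equal(unname(av$geno[1, ]), c(1L, 0L, 2L))
  # "./." becomes an undefined genotype, and FT != PASS fails quality
  expect_true(is.na(av$geno[2, "SB"]))
  expect_false(av$qual[2, "SC"])
  # annotation mapping, with unknown frequency kept distinct from zero
  expect_equal(av$variants$consequence, c("exonic_missense", "intronic"))
  expect_equal(av$variants$sift, c("damaging", "damaging"))
  expect_equal(av$variants$af_global[1], 0.001)
  expect_true(is.na(av$variants$af_global[2]))
  expect_true(av$variants$ensembl_hq[1])
})

test_that("multi-allelic records are split with per-alt allele counts", {
  # hand-split oracle for GTs 1/2, 0/1, 2/2 at ALT A,T:
  #   alt A (index 1): 1, 1, 0 ; alt T (index 2): 1, 0, 2
  p <- write_toy_vcf(sprintf(
    "1\t100\t.\tC\tA,T\t.\tPASS\tCSQ=%s,%s\tGT:FT\t1/2:PASS\t0/1:PASS\t2/2:PASS",
    csq("A", gene = "GA"), csq("T", gene = "GB", cons = "synonymous_variant")))
  av <- read_vcf(p)
  expect_equal(n_variants(av), 2L)
  expect_equal(av$variants$alt, c("A", "T"))
  expect_equal(unname(av$geno[1, ]), c(1L, 1L, 0L))
  expect_equal(unname(av$geno[2, ]), c(1L, 0L, 2L))
  # the split conserves each sample's total non-reference allele count
  expect_equal(unname(colSums(av$geno)), c(2L, 1L, 2L))
  # annotation entries are matched to their alt allele
  expect_equal(av$variants$gene, c("GA", "GB"))
  expect_equal(av$variants$consequence, c("exonic_missense", "exonic_synonymous"))
})

test_that("malformed VCF bodies and unknown samples are rejected", {
  p <- write_toy_vcf(c(
    sprintf("1\t100\t.\tA\tG\t.\tPASS\tCSQ=%s\tGT:FT\t0/1:PASS\t0/0:PASS\t1/1:PASS", csq("G")),
    "2\t200\tbroken-line"))
  expect_error(read_vcf(p), "line 7")
  p2 <- write_toy_vcf(sprintf(
    "1\t100\t.\tA\tG\t.\tPASS\tCSQ=%s\tGT:FT\t0/1:PASS\t0/0:PASS\t1/1:PASS", csq("G")))
  cohort <- cohort_design(data.frame(sample_id = c("SA", "SB"),
                                     group = "WES_CASE",
                                     sibling_pair_id = NA))
  expect_error(read_vcf(p2, cohort = cohort), "SC")
})

test_that("sample sheets round-trip and invariants are enforced", {
  cohort <- toy_cohort(n_wes = 8L, n_screen = 0L, n_index = 0L, n_ctl = 100L)
  p <- tempfile(fileext = ".tsv")
  write_sample_sheet(cohort, p)
  back <- read_sample_sheet(p)
  expect_equal(nrow(back), 108L)
  expect_length(sibling_pairs(back), 1L)

  sheet <- data.frame(sample_id = c("a", "b", "c"), group = "WES_CASE",
                      sibling_pair_id = "SP1")
  expect_error(cohort_design(sheet), "exactly two")
  sheet2 <- data.frame(sample_id = c("a", "a"), group = "WES_CASE",
                       sibling_pair_id = NA)
  expect_error(cohort_design(sheet2), "duplicate")
  sheet3 <- data.frame(sample_id = "a", group = "PATIENT", sibling_pair_id = NA)
  expect_error(cohort_design(sheet3), "unknown group")
  # an empty control group is a valid design
  empty_ctl <- toy_cohort(n_ctl = 0L)
  expect_s3_class(empty_ctl, "cohort_design")
  expect_length(samples_in_group(empty_ctl, "HEALTHY_CONTROL"), 0L)
})

test_that("the candidate report prints (k/n) pct% cells and round-trips", {
  rec <- reconstruct_screen_cohort()
  scr <- screen_candidates(rec$av, rec$cohort)
  out <- tempfile()
  paths <- write_candidates(rec$av, scr$table, out)
  tsv <- utils::read.delim(paste0(out, ".tsv"), stringsAsFactors = FALSE)
  cdh <- tsv[tsv$gene == "CDH23", ]
  expect_equal(cdh$MPM, "(2/26) 7.7%")
  expect_equal(cdh$INDEX, "(0/37) 0.0%")
  expect_equal(cdh$CONTROL, "(2/300) 0.7%")
  back <- read_candidates_json(paste0(out, ".json"))
  expect_equal(back$MPM_carriers, scr$table$MPM_carriers)
  expect_equal(back$CONTROL_n, scr$table$CONTROL_n)
  expect_equal(back$CONTROL_pct, scr$table$CONTROL_pct)
  # mismatched keys are rejected
  expect_error(write_candidates(subset_variants(rec$av, 1:3), scr$table, out),
               "mismatch")
})

test_that("the generator's VCF output reads back losslessly", {
  sim <- generate_cohort(small_sim_config(), seed = 11, dir = tempfile())
  cohort <- read_sample_sheet(sim$paths[["samples"]])
  av <- read_vcf(sim$paths[["vcf"]], cohort = cohort)
  expect_identical(variant_keys(av), variant_keys(sim$av))
  expect_identical(unname(av$geno), unname(sim$av$geno))
  expect_identical(unname(av$qual), unname(sim$av$qual))
  cols <- setdiff(names(av$variants), "validated")
  expect_equal(av$variants[cols], sim$av$variants[cols])
})
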