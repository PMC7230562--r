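# The variant-selection cascade: per-step behaviour, chaining, and the
# algebraic properties of the filters.

test_that("the quality gate requires defined, passing whole-exome genotypes", {
  cohort <- toy_cohort()
  g <- rbind(geno_row(cohort, W1 = 1, W2 = 1, W3 = 1),
             geno_row(cohort, W1 = 1, W2 = 1),
             geno_row(cohort, W1 = 1, W1 = 1))
  g[2, "W3"] <- NA  # undefined genotype in a whole-exome case
  q <- matrix(TRUE, 3, nrow(cohort), dimnames = list(NULL, cohort$sample_id))
  q[3, "W2"] <- FALSE
  av <- toy_variants(g, qual = q)
  kept <- quality_filter(av, cohort)
  expect_equal(n_variants(kept), 1L)
  expect_equal(variant_keys(kept), variant_keys(av)[1])
  # all passing: identity
  expect_equal(n_variants(quality_filter(kept, cohort)), 1L)
})

test_that("sharing criteria implement the sibling-pair rules", {
  cohort <- toy_cohort()
  sibs_only <- toy_variants(geno_row(cohort, W1 = 1, W2 = 1))
  sibs_plus <- toy_variants(geno_row(cohort, W1 = 1, W2 = 1, W3 = 1))
  two_nonsib <- toy_variants(geno_row(cohort, W3 = 1, W4 = 1))
  one_sib_one_other <- toy_variants(geno_row(cohort, W1 = 1, W4 = 1))

  expect_equal(n_variants(sharing_filter(sibs_only, cohort, "CRITERIA1")), 0L)
  expect_equal(n_variants(sharing_filter(sibs_only, cohort, "CRITERIA2")), 0L)
  expect_equal(n_variants(sharing_filter(sibs_plus, cohort, "CRITERIA1")), 1L)
  expect_equal(n_variants(sharing_filter(two_nonsib, cohort, "CRITERIA2")), 1L)
  expect_equal(n_variants(sharing_filter(two_nonsib, cohort, "CRITERIA1")), 0L)
  # one sibling plus one unrelated case is two non-sibling carriers
  expect_equal(n_variants(sharing_filter(one_sib_one_other, cohort, "CRITERIA2")), 1L)
  expect_equal(n_variants(sharing_filter(sibs_only, cohort, "UNION")), 0L)

  no_pair <- toy_cohort(with_pair = FALSE)
  expect_error(sharing_filter(sibs_plus, no_pair, "CRITERIA1"), "sibling pair")
})

test_that("broad and stringent annotation selection differ as specified", {
  cohort <- toy_cohort()
  g <- geno_row(cohort, W1 = 1)
  bare_intronic <- toy_variants(g, consequence = "intronic")
  sift_intronic <- toy_variants(g, consequence = "intronic", sift = "damaging")
  bare_missense <- toy_variants(g, consequence = "exonic_missense")
  other_conseq <- toy_variants(g, consequence = "other", sift = "damaging")

  expect_equal(n_variants(annotation_selection(bare_intronic, "BROAD")), 0L)
  expect_equal(n_variants(annotation_selection(bare_intronic, "STRINGENT")), 0L)
  expect_equal(n_variants(annotation_selection(sift_intronic, "STRINGENT")), 1L)
  expect_equal(n_variants(annotation_selection(sift_intronic, "BROAD")), 0L)
  expect_equal(n_variants(annotation_selection(bare_missense, "BROAD")), 1L)
  expect_equal(n_variants(annotation_selection(bare_missense, "STRINGENT")), 0L)
  expect_equal(n_variants(annotation_selection(bare_missense, "UNION")), 1L)
  # neither exonic nor intronic is never selected
  expect_equal(n_variants(annotation_selection(other_conseq, "UNION")), 0L)
})

test_that("the frequency filter is inclusive by default and tri-state", {
  cohort <- toy_cohort()
  g <- rbind(geno_row(cohort, W1 = 1), geno_row(cohort, W1 = 1),
             geno_row(cohort, W1 = 1), geno_row(cohort, W1 = 1))
  av <- toy_variants(g, af_global = c(0.02, NA, 0.01, 0.005),
                     af_european = c(NA, NA, NA, 0.02))
  kept <- exclude_common(av)
  expect_equal(variant_keys(kept), variant_keys(av)[2])
  # strictly-above variant of the threshold keeps the boundary value
  kept2 <- exclude_common(av, inclusive = FALSE)
  expect_setequal(variant_keys(kept2), variant_keys(av)[c(2, 3)])
  # restricting to the global population ignores the European frequency
  kept3 <- exclude_common(av, populations = "global")
  expect_setequal(variant_keys(kept3), variant_keys(av)[c(2, 4)])
})

test_that("synonymous and polyvariant-gene exclusions count correctly", {
  cohort <- toy_cohort()
  g5 <- do.call(rbind, replicate(5, geno_row(cohort, W1 = 1), simplify = FALSE))
  syn <- toy_variants(g5, consequence = c("exonic_synonymous", "exonic_missense",
                                          "exonic_missense", "intronic", "other"))
  expect_equal(n_variants(exclude_synonymous(syn)), 4L)
  expect_equal(n_variants(exclude_synonymous(subset_variants(syn, integer(0)))), 0L)

  g7 <- do.call(rbind, replicate(7, geno_row(cohort, W1 = 1), simplify = FALSE))
  poly <- toy_variants(g7, gene = c(rep("GA", 4), rep("GB", 3)))
  expect_equal(unique(exclude_polyvariant_genes(poly)$variants$gene), "GB")
  poly2 <- toy_variants(g7, gene = c(rep("GA", 5), rep("GB", 2)))
  expect_equal(n_variants(exclude_polyvariant_genes(poly2)), 2L)
  expect_equal(n_variants(exclude_polyvariant_genes(poly, max_variants_per_gene = 5L)), 7L)
})

test_that("final selection combines recurrence and predictor support", {
  cohort <- toy_cohort()
  carried3 <- geno_row(cohort, W1 = 1, W3 = 1, S1 = 1)
  carried2 <- geno_row(cohort, W1 = 1, S1 = 1)
  av_fathmm <- toy_variants(carried3, fathmm = "damaging")
  av_none <- toy_variants(carried3)
  av_two <- toy_variants(carried2, fathmm = "damaging")
  expect_equal(n_variants(select_candidates(av_fathmm, cohort)), 1L)
  expect_equal(n_variants(select_candidates(av_none, cohort)), 0L)
  expect_equal(n_variants(select_candidates(av_two, cohort)), 0L)
  # index and control carriers do not count toward patient recurrence
  av_ctl <- toy_variants(geno_row(cohort, W1 = 1, W3 = 1, C1 = 1, I1 = 1),
                         fathmm = "damaging")
  expect_equal(n_variants(select_candidates(av_ctl, cohort)), 0L)
})

test_that("the full cascade chains, reports a consistent funnel, and can be
           neutralized down to its first three steps", {
  sim <- generate_cohort(small_sim_config(), seed = 5)
  res <- run_cascade(sim$av, sim$cohort)
  f <- res$funnel
  expect_equal(f$n_in[1], n_variants(sim$av))
  expect_equal(f$n_in[-1], f$n_out[-nrow(f)])
  expect_true(all(f$n_out <= f$n_in))
  expect_equal(f$n_out[nrow(f)], n_variants(res$candidates))
  expect_true(all(variant_keys(res$candidates) %in% variant_keys(sim$av)))

  neutral <- cascade_config(af_threshold = 1, min_final_carriers = 1L,
                            min_damaging_tools = 0L,
                            max_variants_per_gene = 1000000L,
                            keep_synonymous = TRUE)
  res_n <- run_cascade(sim$av, sim$cohort, neutral)
  manual <- annotation_selection(
    sharing_filter(quality_filter(sim$av, sim$cohort), sim$cohort, "UNION"),
    "UNION")
  expect_equal(variant_keys(res_n$candidates), variant_keys(manual))

  empty <- subset_variants(sim$av, integer(0))
  res_e <- run_cascade(empty, sim$cohort)
  expect_equal(n_variants(res_e$candidates), 0L)
  expect_true(all(res_e$funnel$n_in == 0L & res_e$funnel$n_out == 0L))
})

test_that("keeping synonymous variants is a single-flag change", {
  cohort <- toy_cohort()
  g <- geno_row(cohort, W1 = 1, W2 = 1, W3 = 1, S1 = 1)
  av <- toy_variants(g, consequence = "exonic_synonymous", sift = "damaging")
  drop <- run_cascade(av, cohort, cascade_config())
  keep <- run_cascade(av, cohort, cascade_config(keep_synonymous = TRUE))
  expect_equal(n_variants(drop$candidates), 0L)
  expect_equal(n_variants(keep$candidates), 1L)
})

test_that("filters are idempotent and frequency/synonymous exclusions commute", {
  for (seed in 1:5) {
    sim <- generate_cohort(small_sim_config(), seed = seed)
    av <- sim$av
    once <- list(
      quality = quality_filter(av, sim$cohort),
      common = exclude_common(av),
      synonymous = exclude_synonymous(av),
      poly = exclude_polyvariant_genes(av))
    expect_identical(variant_keys(quality_filter(once$quality, sim$cohort)),
                     variant_keys(once$quality))
    expect_identical(variant_keys(exclude_common(once$common)),
                     variant_keys(once$common))
    expect_identical(variant_keys(exclude_synonymous(once$synonymous)),
                     variant_keys(once$synonymous))
    expect_identical(variant_keys(exclude_polyvariant_genes(once$poly)),
                     variant_keys(once$poly))
    expect_identical(
      variant_keys(exclude_common(exclude_synonymous(av))),
      variant_keys(exclude_synonymous(exclude_common(av))))
  }
})

test_that("gene-level exclusion is order-sensitive relative to the
           annotation-level exclusions", {
  cohort <- toy_cohort()
  g4 <- do.call(rbind, replicate(4, geno_row(cohort, W1 = 1), simplify = FALSE))
  av <- toy_variants(g4, gene = "GA",
                     consequence = c("exonic_synonymous", rep("exonic_missense", 3)))
  # synonymous first: the gene drops to 3 variants and survives
  a <- exclude_polyvariant_genes(exclude_synonymous(av))
  # gene-level first: all 4 variants of the gene are removed
  b <- exclude_synonymous(exclude_polyvariant_genes(av))
  expect_equal(n_variants(a), 3L)
  expect_equal(n_variants(b), 0L)
})
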