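# Burden / SKAT / SKAT-O score tests: null model, weights, collapse and
# endpoint identities, contingency-table and permutation oracles, and the
# carrier-table reconstruction.

test_that("the intercept-only null model is the case fraction", {
  y <- c(rep(1, 26), rep(0, 100))
  null <- fit_null_binary(y)
  expect_equal(null$mu, 26 / 126)
  expect_equal(null$v, (26 / 126) * (100 / 126))
  expect_equal(sum(null$resid), 0)
  expect_error(fit_null_binary(rep(1, 10)), "both")
  expect_error(fit_null_binary(c(0, 1, 2)), "binary")
})

test_that("Beta-MAF weights match the closed-form density", {
  expect_equal(beta_maf_weights(0.1, 1, 25), 25 * 0.9^24)
  expect_equal(beta_maf_weights(0.5, 1, 1), 1)
  expect_equal(beta_maf_weights(1e-8, 1, 25), dbeta(1e-8, 1, 25))
  w <- beta_maf_weights(c(0.01, 0.05, 0.2), 1, 25)
  expect_true(all(diff(w) < 0))  # decreasing in maf
  expect_error(beta_maf_weights(0), "monomorphic")
  expect_error(beta_maf_weights(0.7), "folded")
})

test_that("single-variant burden equals the Pearson chi-square test", {
  set.seed(21)
  y <- c(rep(1, 40), rep(0, 160))
  g <- rbinom(200, 1, 0.15)
  g[1:10] <- 1  # enrich carriers among cases
  bt <- burden_test(matrix(g, ncol = 1), y, weights = 1)
  # Pearson chi-square on the 2x2 carrier/status table, by direct formula
  a <- sum(g == 1 & y == 1); b <- sum(g == 0 & y == 1)
  cc <- sum(g == 1 & y == 0); d <- sum(g == 0 & y == 0)
  n <- length(y)
  x2 <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(bt$stat, x2, tolerance = 1e-12)
  expect_equal(bt$p, pchisq(x2, 1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("burden, SKAT and the score chi-square coincide for one variant", {
  set.seed(8)
  y <- c(rep(1, 30), rep(0, 90))
  g <- matrix(rbinom(120, 2, 0.1), ncol = 1)
  w <- beta_maf_weights(empirical_maf(g))
  bt <- burden_test(g, y, w)
  st <- skat_test(g, y, w)
  expect_equal(st$p, bt$p, tolerance = 1e-10)
  expect_equal(st$Q, bt$Q, tolerance = 1e-12)
  ot <- skato_test(g, y, w)
  expect_equal(ot$p, bt$p, tolerance = 1e-6)
})

test_that("degenerate burden yields p = 1 with a warning", {
  y <- c(rep(1, 5), rep(0, 5))
  g <- matrix(1, 10, 2)  # every sample carries everything
  expect_warning(bt <- burden_test(g, y, c(1, 1)), "degenerate")
  expect_equal(bt$p, 1)
})

test_that("SKAT-O endpoint grids reproduce the component tests", {
  set.seed(13)
  sim <- simulate_null_case_control(50, 150, 5, c(0.05, 0.1, 0.2, 0.08, 0.3),
                                    seed = 13)
  w <- beta_maf_weights(empirical_maf(sim$G))
  bt <- burden_test(sim$G, sim$y, w)
  st <- skat_test(sim$G, sim$y, w)
  expect_equal(skato_test(sim$G, sim$y, w, rho_grid = 1)$p, bt$p,
               tolerance = 1e-12)
  expect_equal(skato_test(sim$G, sim$y, w, rho_grid = 0)$p, st$p,
               tolerance = 1e-12)
  ot <- skato_test(sim$G, sim$y, w)
  expect_gte(ot$p, ot$min_p)
  expect_lte(ot$p, min(1, ot$min_p * length(default_rho_grid())) + 1e-12)
  expect_error(skato_test(sim$G, sim$y, w, rho_grid = c(0.1, 0.5)), "contain")
})

test_that("permutation p-values are reproducible and correctly normalized", {
  set.seed(5)
  G <- matrix(rbinom(300, 2, 0.2), 100, 3)
  y <- c(rep(1, 30), rep(0, 70))
  stat <- function(G, y) abs(sum(crossprod(G, y - mean(y))))
  p1 <- permutation_pvalue(stat, G, y, n_permutations = 500, seed = 42)
  p2 <- permutation_pvalue(stat, G, y, n_permutations = 500, seed = 42)
  expect_identical(p1, p2)
  expect_error(permutation_pvalue(stat, G, y, n_permutations = 50), "100")
  # a label-invariant statistic ties with every permutation: p = 1
  expect_equal(permutation_pvalue(function(G, y) 1, G, y,
                                  n_permutations = 200, seed = 1), 1)
  # p is bounded below by 1/(B+1)
  expect_gte(p1, 1 / 501)
})

test_that("asymptotic p-values agree with the permutation oracle on a
           moderate-frequency instance", {
  set.seed(42)
  n <- 200
  maf <- c(0.1, 0.15, 0.25, 0.12, 0.3)
  G <- sapply(maf, function(f) rbinom(n, 2, f))
  y <- c(rep(1, 60), rep(0, 140))
  G[1:10, 1] <- pmax(G[1:10, 1], 1)
  w <- beta_maf_weights(empirical_maf(G))
  bt <- burden_test(G, y, w)
  st <- skat_test(G, y, w)
  ot <- skato_test(G, y, w)
  B <- 10000L
  orc <- melscreen:::aggregation_permutation_oracle(G, y, w,
                                                    default_rho_grid(),
                                                    n_permutations = B,
                                                    seed = 7)
  se <- function(p) sqrt(p * (1 - p) / B)
  expect_lt(abs(bt$p - orc$p_burden), 3 * se(orc$p_burden) + 1 / B)
  expect_lt(abs(st$p - orc$p_skat), 3 * se(orc$p_skat) + 1 / B)
  expect_lt(abs(ot$p - orc$p_skato), 3 * se(orc$p_skato) + 1 / B)
})

test_that("carrier-table reconstruction is exact, feasible and reversible", {
  counts <- data.frame(case_carriers = c(4, 5, 3, 3, 3, 4, 4),
                       case_n = 26,
                       control_carriers = c(5, 4, 3, 2, 5, 2, 3),
                       control_n = c(200, 100, 100, 100, 100, 100, 100))
  rec <- reconstruct_from_counts(counts)
  Gcase <- rec$G[rec$y == 1, ]
  # 26 carriers over 26 cases: each case carries exactly one variant, het
  expect_equal(colSums(Gcase), counts$case_carriers)
  expect_true(all(rowSums(Gcase) == 1))
  expect_true(all(Gcase %in% c(0, 1)))
  # control carriers within each variant's typed prefix
  Gctrl <- rec$G[rec$y == 0, ]
  expect_equal(colSums(Gctrl == 1), counts$control_carriers)
  expect_equal(nrow(Gctrl), 200L)
  # infeasible disjoint assignment is refused, naming the group
  bad <- counts; bad$case_carriers[1] <- 20
  expect_error(reconstruct_from_counts(bad), "case")
  worse <- counts; worse$control_carriers[1] <- 300
  expect_error(reconstruct_from_counts(worse), "denominator|control")
  # truncation policy uses the common denominator
  rec2 <- reconstruct_from_counts(counts, policy = "truncate_common")
  expect_equal(nrow(rec2$G), 126L)
  expect_true(all(rec2$G %in% c(0, 1)))
})

test_that("the three tests run jointly and report methods and eigenvalues", {
  sim <- simulate_null_case_control(40, 120, 6, 0.1, seed = 3)
  agg <- aggregation_tests(sim$G, sim$y)
  expect_true(all(c(agg$p_burden, agg$p_skat, agg$p_skato) >= 0))
  expect_true(all(c(agg$p_burden, agg$p_skat, agg$p_skato) <= 1))
  expect_length(agg$lambda, 6L)
  expect_true(all(agg$lambda > 0))
  expect_named(agg$method_used, c("burden", "skat", "skato"))
})
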