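# Region-based rare-variant aggregation tests for a binary case/control
# phenotype under an intercept-only null model: weighted burden (collapsing)
# score test, the variance-component kernel test (SKAT), and a permutation
# oracle. Genotypes enter as an n x m allele-count (dosage) matrix G; the
# score vector is S = G' (y - mu) with mu the case fraction, and the per-
# sample null variance is mu (1 - mu).

#' Fit the intercept-only binary null model
#'
#' @param y Binary phenotype vector (1 = case, 0 = control); both classes
#'   must be present.
#' @return List with `mu` (fitted mean, the case fraction), `resid`
#'   (`y - mu`), `v` (Bernoulli variance `mu * (1 - mu)`), `n`.
#' @export
fit_null_binary <- function(y) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("phenotype must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("both cases and controls are required to fit the null model")
  mu <- mean(y)
  list(mu = mu, resid = y - mu, v = mu * (1 - mu), n = length(y))
}

#' Beta-density minor-allele-frequency weights
#'
#' `w_j = dbeta(maf_j; a, b)`. The default `Beta(1, 25)` up-weights rarer
#' variants and is the conventional choice of the SKAT family.
#'
#' @param maf Minor-allele fractions in `(0, 0.5]`.
#' @param a,b Beta shape parameters (defaults 1 and 25).
#' @return Positive weights, one per variant.
#' @export
beta_maf_weights <- function(maf, a = 1, b = 25) {
  if (any(maf <= 0))
    stop("monomorphic variant (maf = 0) must be dropped before weighting")
  if (any(maf > 0.5)) stop("maf must be folded to (0, 0.5]")
  stats::dbeta(maf, a, b)
}

#' Empirical minor-allele fraction of a genotype matrix
#'
#' Column allele fractions `mean(G_j) / 2`, folded to `[0, 0.5]`.
#'
#' @param G n x m allele-count (dosage) matrix.
#' @return Numeric vector of length m.
#' @export
empirical_maf <- function(G) {
  f <- colMeans(G) / 2
  pmin(f, 1 - f)
}

#' Weighted burden (collapsing) score test
#'
#' Collapses each sample to a weighted allele-count burden
#' `b_i = sum_j w_j G_ij` and score-tests the burden against the binary
#' phenotype under the intercept-only null: `Q = (sum_i b_i (y_i - mu))^2`,
#' with `Q / Var` referred to the 1-df chi-square distribution (two-sided).
#'
#' @param G n x m allele-count (dosage) matrix (no monomorphic columns).
#' @param y Binary phenotype vector of length n.
#' @param weights Per-variant weights (default Beta(1,25) at the empirical
#'   minor-allele fractions).
#' @return List with `Q`, `stat` (normalized 1-df statistic), `p`,
#'   `method_used`.
#' @export
burden_test <- function(G, y, weights = NULL) {
  G <- as.matrix(G)
  null <- fit_null_binary(y)
  if (nrow(G) != null$n) stop("G and y dimensions disagree")
  if (is.null(weights)) weights <- beta_maf_weights(empirical_maf(G))
  if (length(weights) != ncol(G)) stop("one weight per variant is required")
  b <- as.numeric(G %*% weights)
  U <- sum(b * null$resid)
  Vb <- null$v * sum((b - mean(b))^2)
  if (Vb <= .Machine$double.eps * max(1, sum(b^2))) {
    warning("degenerate burden (no variance between samples); p = 1")
    return(list(Q = U^2, stat = 0, p = 1, method_used = "degenerate"))
  }
  stat <- U^2 / Vb
  list(Q = U^2, stat = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       method_used = "score_chisq")
}

#' Variance-component kernel association test (SKAT)
#'
#' `Q = sum_j w_j^2 S_j^2` with score `S_j = sum_i G_ij (y_i - mu)`; under
#' the null, `Q` is distributed as a positively weighted sum of 1-df
#' chi-squares whose weights are the eigenvalues of the variance-scaled,
#' centered, weighted genotype cross-product. Tail probability by
#' Davies-type inversion with Liu moment-matching fallback; a permutation
#' fallback is used if both fail.
#'
#' @inheritParams burden_test
#' @param pvalue_method `"davies"` (default, with fallbacks), `"liu"`, or
#'   `"permutation"`.
#' @param n_permutations,seed Permutation settings when the permutation route
#'   is requested or reached by fallback.
#' @return List with `Q`, `p`, `lambda` (eigenvalues), `method_used`.
#' @export
skat_test <- function(G, y, weights = NULL,
                      pvalue_method = c("davies", "liu", "permutation"),
                      n_permutations = 10000L, seed = 1L) {
  pvalue_method <- match.arg(pvalue_method)
  G <- as.matrix(G)
  null <- fit_null_binary(y)
  if (nrow(G) != null$n) stop("G and y dimensions disagree")
  if (is.null(weights)) weights <- beta_maf_weights(empirical_maf(G))
  if (length(weights) != ncol(G)) stop("one weight per variant is required")
  S <- as.numeric(crossprod(G, null$resid))
  Q <- sum((weights * S)^2)
  Z <- sweep(G, 2L, colMeans(G)) %*% diag(weights, ncol(G))
  K <- null$v * crossprod(Z)
  lambda <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-10 * max(lambda)]
  if (pvalue_method == "permutation") {
    p <- permutation_pvalue(function(G, y) {
      r <- y - mean(y)
      sum((weights * as.numeric(crossprod(G, r)))^2)
    }, G, y, n_permutations = n_permutations, seed = seed)
    return(list(Q = Q, p = p, lambda = lambda, method_used = "permutation"))
  }
  res <- quadform_pvalue(Q, lambda,
                         method = if (pvalue_method == "liu") "liu" else "davies")
  if (!is.finite(res$p)) {
    message("analytic tail probability unavailable; falling back to permutation")
    p <- permutation_pvalue(function(G, y) {
      r <- y - mean(y)
      sum((weights * as.numeric(crossprod(G, r)))^2)
    }, G, y, n_permutations = n_permutations, seed = seed)
    return(list(Q = Q, p = p, lambda = lambda, method_used = "permutation"))
  }
  list(Q = Q, p = res$p, lambda = lambda, method_used = res$method)
}

#' Permutation p-value for an arbitrary statistic
#'
#' Permutes the phenotype labels; `p = (1 + #{permuted >= observed}) /
#' (1 + B)`. Fully reproducible from `seed`.
#'
#' @param statistic_fn Function `(G, y) -> scalar` (larger = more extreme).
#' @param G Genotype matrix.
#' @param y Phenotype vector.
#' @param n_permutations Number of permutations B (>= 100).
#' @param seed Integer seed.
#' @return The permutation p-value.
#' @export
permutation_pvalue <- function(statistic_fn, G, y, n_permutations = 1000L,
                               seed = 1L) {
  if (n_permutations < 100L) stop("at least 100 permutations are required")
  obs <- statistic_fn(G, y)
  hits <- with_seed(seed, {
    h <- 0L
    for (b in seq_len(n_permutations))
      h <- h + (statistic_fn(G, sample(y)) >= obs)
    h
  })
  (1 + hits) / (1 + n_permutations)
}

# Vectorized joint permutation reference for burden / SKAT / SKAT-O on one
# instance: returns permutation p-values for all three tests, using the
# min-p-over-rho construction for the omnibus test.
aggregation_permutation_oracle <- function(G, y, weights, rho_grid,
                                           n_permutations = 1e5L, seed = 1L,
                                           chunk = 20000L) {
  G <- as.matrix(G)
  mu <- mean(y)
  wS <- function(r) weights * as.numeric(crossprod(G, r))
  ws_obs <- wS(y - mu)
  Qs_obs <- sum(ws_obs^2)
  Qb_obs <- sum(ws_obs)^2
  Qs <- numeric(n_permutations)
  Qb <- numeric(n_permutations)
  with_seed(seed, {
    done <- 0L
    while (done < n_permutations) {
      nb <- min(chunk, n_permutations - done)
      Y <- replicate(nb, sample(y))
      R <- Y - mu
      WS <- weights * crossprod(G, R)        # m x nb
      Qs[done + seq_len(nb)] <- colSums(WS^2)
      Qb[done + seq_len(nb)] <- colSums(WS)^2
      done <- done + nb
    }
  })
  p_skat <- (1 + sum(Qs >= Qs_obs)) / (1 + n_permutations)
  p_burden <- (1 + sum(Qb >= Qb_obs)) / (1 + n_permutations)
  # omnibus: per-rho empirical p for each permutation, then min over rho
  minp_perm <- rep(Inf, n_permutations)
  minp_obs <- Inf
  B <- n_permutations
  for (rho in rho_grid) {
    Qr <- (1 - rho) * Qs + rho * Qb
    Qr_obs <- (1 - rho) * Qs_obs + rho * Qb_obs
    # upper-tail empirical p of each value within the permutation draw
    r <- rank(-Qr, ties.method = "min")
    p_perm <- r / B
    minp_perm <- pmin(minp_perm, p_perm)
    minp_obs <- min(minp_obs, (1 + sum(Qr >= Qr_obs)) / (1 + B))
  }
  p_skato <- (1 + sum(minp_perm <= minp_obs)) / (1 + B)
  list(p_burden = p_burden, p_skat = p_skat, p_skato = p_skato,
       n_permutations = n_permutations)
}

#' Reconstruct a genotype matrix from a published carrier-count table
#'
#' Rebuilds individual-level case/control data consistent with per-variant
#' carrier counts: carriers are heterozygous by default and assigned
#' disjointly within each group (no sample carries two variants while
#' unassigned samples remain). Group sizes are the largest denominator in
#' the table; samples beyond a variant's own denominator are untyped and,
#' under the default policy, mean-imputed per variant (`"pad_impute"`), or
#' the cohort can be truncated to the smallest common denominator
#' (`"truncate_common"`, carrier counts rescaled proportionally).
#'
#' @param counts data.frame with columns `case_carriers`, `case_n`,
#'   `control_carriers`, `control_n` (one row per variant).
#' @param policy `"pad_impute"` (default) or `"truncate_common"`.
#' @return List with `G` (n x m dosage matrix), `y` (phenotype vector),
#'   `maf` (empirical minor-allele fractions) and `log` (character vector of
#'   reconstruction assumptions).
#' @export
reconstruct_from_counts <- function(counts,
                                    policy = c("pad_impute", "truncate_common")) {
  policy <- match.arg(policy)
  req <- c("case_carriers", "case_n", "control_carriers", "control_n")
  miss <- setdiff(req, names(counts))
  if (length(miss)) stop("counts is missing columns: ", paste(miss, collapse = ", "))
  if (any(counts$case_carriers > counts$case_n))
    stop("case carriers exceed denominator")
  if (any(counts$control_carriers > counts$control_n))
    stop("control carriers exceed denominator")
  m <- nrow(counts)
  logs <- c("carriers heterozygous (one alternate allele each)",
            "carriers disjoint within each group")
  build_block <- function(k, n_typed, n_total, group) {
    if (sum(k) > n_total)
      stop("disjoint heterozygous reconstruction infeasible in the ", group,
           " group: ", sum(k), " carriers for ", n_total, " samples")
    Gb <- matrix(0, n_total, m)
    ptr <- 0L
    for (j in seq_len(m)) {
      if (k[j] > 0) {
        idx <- ptr + seq_len(k[j])
        if (max(idx) > n_typed[j])
          stop("disjoint assignment infeasible within the typed samples of the ",
               group, " group")
        Gb[idx, j] <- 1
        ptr <- ptr + k[j]
      }
      if (n_typed[j] < n_total) Gb[(n_typed[j] + 1):n_total, j] <- NA
    }
    Gb
  }
  if (policy == "truncate_common") {
    n_case <- min(counts$case_n); n_ctrl <- min(counts$control_n)
    kc <- round(counts$case_carriers * n_case / counts$case_n)
    kk <- round(counts$control_carriers * n_ctrl / counts$control_n)
    logs <- c(logs, sprintf(
      "denominators truncated to common n (cases %d, controls %d); carrier counts rescaled proportionally",
      n_case, n_ctrl))
    Gcase <- build_block(kc, rep(n_case, m), n_case, "case")
    Gctrl <- build_block(kk, rep(n_ctrl, m), n_ctrl, "control")
  } else {
    n_case <- max(counts$case_n); n_ctrl <- max(counts$control_n)
    # carriers are assigned in order of ascending denominator so that every
    # carrier of a partially-typed variant falls inside its typed prefix
    ordc <- order(counts$case_n); ordk <- order(counts$control_n)
    Gcase <- matrix(0, n_case, m); Gctrl <- matrix(0, n_ctrl, m)
    Gcase[, ordc] <- build_block(counts$case_carriers[ordc],
                                 counts$case_n[ordc], n_case, "case")
    Gctrl[, ordk] <- build_block(counts$control_carriers[ordk],
                                 counts$control_n[ordk], n_ctrl, "control")
    logs <- c(logs, sprintf(
      "groups padded to the largest denominator (cases %d, controls %d); untyped sample-variant pairs mean-imputed per variant",
      n_case, n_ctrl))
  }
  G <- rbind(Gcase, Gctrl)
  for (j in seq_len(ncol(G))) {
    na <- is.na(G[, j])
    if (any(na)) G[na, j] <- mean(G[!na, j])
  }
  y <- c(rep(1, nrow(Gcase)), rep(0, nrow(Gctrl)))
  list(G = G, y = y, maf = empirical_maf(G), log = logs)
}

# evaluate expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
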