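# Omnibus combination of burden and kernel statistics over a grid of mixing
# parameters rho: Q_rho = (1 - rho) Q_skat + rho Q_burden. The omnibus
# p-value is the probability, under the null, that the minimum of the
# per-rho p-values falls below the observed minimum; it is computed by the
# standard decomposition of Q_rho into a common 1-df component (the squared
# projection on the average genotype) plus an independent mixture remainder,
# reducing the computation to a one-dimensional integral over the 1-df
# component.

#' Default rho grid for the omnibus test
#' @return Numeric grid `{0, 0.1^2, ..., 0.5^2, 0.5, 1}`.
#' @export
default_rho_grid <- function() c(0, 0.1^2, 0.2^2, 0.3^2, 0.4^2, 0.5^2, 0.5, 1)

# moments / decomposition parameters of the omnibus construction, computed
# from the standardized weighted genotype matrix Z1 = sqrt(v) * centered(G W)
skato_parameters <- function(Z1, rho_grid) {
  n <- nrow(Z1); m <- ncol(Z1)
  z_mean <- rowMeans(Z1)
  zbar2 <- sum(z_mean^2)
  cof1 <- as.numeric(crossprod(z_mean, Z1)) / zbar2
  Z_item1 <- outer(z_mean, cof1)
  Z_item2 <- Z1 - Z_item1
  K22 <- crossprod(Z_item2)
  lambda <- eigen(K22, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-10 * max(abs(lambda), .Machine$double.eps) & lambda > 0]
  var_remain <- sum(crossprod(Z_item1) * K22) * 4
  MuQ <- sum(lambda)
  VarQ <- sum(lambda^2) * 2 + var_remain
  tau <- vapply(rho_grid, function(rho)
    (m^2 * rho + (1 - rho) * sum(cof1^2)) * zbar2, numeric(1))
  list(MuQ = MuQ, VarQ = VarQ, VarRemain = var_remain, lambda = lambda,
       tau = tau)
}

#' Omnibus burden/SKAT test (SKAT-O)
#'
#' Evaluates `Q_rho = (1 - rho) * Q_skat + rho * Q_burden` over the rho grid,
#' takes the minimum per-rho p-value, and converts it to an omnibus p-value
#' by one-dimensional numerical integration over the shared 1-df component.
#' Endpoints are exact: a grid of `{1}` reproduces the burden p-value and a
#' grid of `{0}` the SKAT p-value. Internal mixture computations cap rho at
#' 0.999 to keep the rho-kernel full rank.
#'
#' @inheritParams burden_test
#' @param rho_grid Mixing grid in `[0, 1]`; must contain 0 and 1 for the
#'   default omnibus behaviour (a single-point grid degenerates to that
#'   test).
#' @param pvalue_method Tail-probability route for the mixture components.
#' @param acc Absolute accuracy of the per-rho mixture inversions (default
#'   `1e-4`; tails below this are evaluated by moment matching, which keeps
#'   relative precision).
#' @return List with `p`, `p_rho` (per-rho p-values), `rho_grid`, `Q_skat`,
#'   `Q_burden`, `min_p` and `method_used`.
#' @export
skato_test <- function(G, y, weights = NULL, rho_grid = default_rho_grid(),
                       pvalue_method = c("davies", "liu"), acc = 1e-4) {
  pvalue_method <- match.arg(pvalue_method)
  G <- as.matrix(G)
  null <- fit_null_binary(y)
  if (is.null(weights)) weights <- beta_maf_weights(empirical_maf(G))
  if (length(rho_grid) > 1L && !(0 %in% rho_grid && 1 %in% rho_grid))
    stop("a multi-point rho grid must contain both 0 and 1")
  if (any(rho_grid < 0 | rho_grid > 1)) stop("rho grid must lie in [0, 1]")
  rho_grid <- sort(unique(rho_grid))

  S <- as.numeric(crossprod(G, null$resid))
  wS <- weights * S
  Q_skat <- sum(wS^2)
  Q_burden <- sum(wS)^2
  Zc <- sweep(G, 2L, colMeans(G)) %*% diag(weights, ncol(G))
  Z1 <- sqrt(null$v) * Zc
  K <- crossprod(Z1)
  m <- ncol(G)

  # single-point grids degenerate to the component tests exactly
  if (length(rho_grid) == 1L) {
    rho <- rho_grid
    if (rho == 1) {
      bt <- burden_test(G, y, weights)
      return(list(p = bt$p, p_rho = bt$p, rho_grid = rho, Q_skat = Q_skat,
                  Q_burden = Q_burden, min_p = bt$p, method_used = bt$method_used))
    }
    if (rho == 0) {
      st <- skat_test(G, y, weights, pvalue_method = pvalue_method)
      return(list(p = st$p, p_rho = st$p, rho_grid = rho, Q_skat = Q_skat,
                  Q_burden = Q_burden, min_p = st$p, method_used = st$method_used))
    }
  }

  rho_eff <- pmin(rho_grid, 0.999)
  Q_rho <- (1 - rho_eff) * Q_skat + rho_eff * Q_burden
  lambda_rho <- vector("list", length(rho_eff))
  p_rho <- numeric(length(rho_eff))
  for (i in seq_along(rho_eff)) {
    rho <- rho_eff[i]
    Rm <- matrix(rho, m, m); diag(Rm) <- 1
    L <- chol(Rm, pivot = TRUE)
    L <- L[, order(attr(L, "pivot")), drop = FALSE]
    K1 <- L %*% K %*% t(L)
    lam <- eigen((K1 + t(K1)) / 2, symmetric = TRUE, only.values = TRUE)$values
    lam <- lam[lam > 1e-10 * max(lam)]
    lambda_rho[[i]] <- lam
    p_rho[i] <- quadform_pvalue(Q_rho[i], lam, method = pvalue_method,
                                acc = acc)$p
  }
  T_min <- min(p_rho)

  # quantile of each rho-mixture at the observed minimum p
  pmin_q <- vapply(seq_along(rho_eff), function(i)
    liu_quantile(T_min, lambda_rho[[i]]), numeric(1))

  par <- skato_parameters(Z1, rho_eff)
  sd_ratio <- sqrt(par$VarQ - par$VarRemain) / sqrt(par$VarQ)
  kappa_tail <- function(qk) {
    # upper tail of the remainder mixture, variance-adjusted for the
    # non-eigenvalue component; evaluated by moment matching, which is fast
    # and accurate in the bulk where the outer integral takes its mass
    q_std <- (qk - par$MuQ) * sd_ratio + par$MuQ
    liu_tail(q_std, par$lambda)
  }
  integrand <- function(x) {
    out <- numeric(length(x))
    for (i in seq_along(x)) {
      qk <- (pmin_q - par$tau * x[i]) / (1 - rho_eff)
      qmin <- min(qk)
      Fk <- if (!length(par$lambda)) as.numeric(qmin >= 0)
            else if (qmin > sum(par$lambda) * 1e4) 1
            else 1 - kappa_tail(qmin)
      out[i] <- Fk * stats::dchisq(x[i], df = 1)
    }
    out
  }
  int <- try(stats::integrate(integrand, 0, 40, subdivisions = 2000L,
                              abs.tol = 1e-25), silent = TRUE)
  if (inherits(int, "try-error") || !is.finite(int$value)) {
    # conservative Bonferroni combination if the integration fails
    p <- min(1, T_min * length(rho_grid))
    method <- "bonferroni_fallback"
  } else {
    p <- 1 - int$value
    method <- "integration"
  }
  # the true omnibus p lies in [min_p, min_p * n_rho]
  p <- min(max(p, T_min), min(1, T_min * length(rho_grid)))
  list(p = p, p_rho = p_rho, rho_grid = rho_grid, Q_skat = Q_skat,
       Q_burden = Q_burden, min_p = T_min, method_used = method)
}

#' Run all three aggregation tests on one variant set
#'
#' Convenience wrapper computing burden, SKAT and SKAT-O with shared weights.
#'
#' @inheritParams burden_test
#' @param rho_grid Mixing grid for the omnibus test.
#' @param weight_beta Two shape parameters for the Beta-MAF weights.
#' @return List of class `aggregation_result` with `Q_burden`, `Q_skat`,
#'   `p_burden`, `p_skat`, `p_skato`, `lambda`, `maf`, `weights` and the
#'   per-test methods.
#' @export
aggregation_tests <- function(G, y, weights = NULL,
                              rho_grid = default_rho_grid(),
                              weight_beta = c(1, 25)) {
  G <- as.matrix(G)
  maf <- empirical_maf(G)
  if (any(maf == 0)) stop("monomorphic columns must be dropped before testing")
  if (is.null(weights))
    weights <- beta_maf_weights(maf, weight_beta[1], weight_beta[2])
  bt <- burden_test(G, y, weights)
  st <- skat_test(G, y, weights)
  ot <- skato_test(G, y, weights, rho_grid)
  structure(list(Q_burden = bt$Q, Q_skat = st$Q,
                 p_burden = bt$p, p_skat = st$p, p_skato = ot$p,
                 lambda = st$lambda, maf = maf, weights = weights,
                 method_used = c(burden = bt$method_used,
                                 skat = st$method_used,
                                 skato = ot$method_used)),
            class = "aggregation_result")
}

#' @export
print.aggregation_result <- function(x, ...) {
  cat("region-based aggregation tests (binary trait, intercept-only null)\n")
  cat(sprintf("  burden: Q = %.4g  p = %.6g\n", x$Q_burden, x$p_burden))
  cat(sprintf("  SKAT:   Q = %.4g  p = %.6g\n", x$Q_skat, x$p_skat))
  cat(sprintf("  SKAT-O:          p = %.6g\n", x$p_skato))
  invisible(x)
}
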