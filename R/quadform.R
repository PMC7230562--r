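# Tail probabilities of positively weighted sums of 1-df chi-squares,
# Q = sum_k lambda_k chi^2_1k. Primary route: numerical inversion of the
# characteristic function (Imhof's integral, the construction behind Davies'
# method); fallback: Liu-style moment matching on a noncentral chi-square.
# These distributions are the null laws of the variance-component score
# statistics used by the region-based association tests.

#' Tail probability of a weighted sum of chi-squares (Davies-type inversion)
#'
#' Computes `P(sum_k lambda_k X_k > q)` with `X_k ~ chi^2_1` independent, by
#' numerically inverting the characteristic function:
#' `P(Q > q) = 1/2 + (1/pi) * Int_0^Inf sin(theta(u)) / (u * rho(u)) du` with
#' `theta(u) = (1/2) sum_k atan(lambda_k u) - q u / 2` and
#' `rho(u) = prod_k (1 + lambda_k^2 u^2)^(1/4)`.
#' Eigenvalues numerically indistinguishable from zero (below
#' `1e-10 * max(lambda)`) are truncated. The single-eigenvalue case is
#' evaluated in closed form.
#'
#' @param q Observed statistic (scalar).
#' @param lambda Positive eigenvalue weights.
#' @param acc Target absolute accuracy (default `1e-6`).
#' @return List with `p` (clamped to `[0, 1]`) and `ifault` (0 = converged,
#'   nonzero = failure; caller should fall back).
#' @export
davies_tail <- function(q, lambda, acc = 1e-6) {
  if (!length(lambda) || all(lambda <= 0))
    stop("davies_tail needs at least one positive eigenvalue")
  lambda <- lambda[lambda > 1e-10 * max(lambda)]
  if (any(lambda <= 0))
    stop("davies_tail needs at least one positive eigenvalue")
  if (length(lambda) == 1L)
    return(list(p = stats::pchisq(q / lambda, df = 1, lower.tail = FALSE),
                ifault = 0L))
  # equal weights: exactly a scaled chi-square with k degrees of freedom
  if (diff(range(lambda)) <= 1e-12 * max(lambda))
    return(list(p = stats::pchisq(q / mean(lambda), df = length(lambda),
                                  lower.tail = FALSE),
                ifault = 0L))
  # rescale so max(lambda) = 1; the tail probability is scale-invariant
  s <- max(lambda)
  lambda <- lambda / s
  q <- q / s
  k <- length(lambda)
  mu <- sum(lambda)
  sigma <- sqrt(2 * sum(lambda^2))
  # trivial regions: Q is almost surely nonnegative, and beyond a hundred
  # standard deviations the tail is far below any attainable accuracy
  if (q <= 0) return(list(p = 1, ifault = 0L))
  if (q > mu + 100 * sigma) return(list(p = 0, ifault = 0L))
  # integration step: aliasing error is bounded by the mass beyond
  # 2*pi/delta - q, pushed past mu + 20 sd
  delta <- 2 * pi / (abs(q) + mu + 20 * sigma)
  # truncation point U: the integrand envelope is 1/(u * prod(1+l^2u^2)^(1/4));
  # for u >= U the tail integral is bounded by 2 U^(-1/2) / C(U) with
  # C(U) = prod over the non-leading eigenvalues of (1+l^2 U^2)^(1/4)
  # (leading eigenvalue is 1 after rescaling). Doubling search on U.
  rest <- lambda[-which.max(lambda)]
  tail_bound <- function(U)
    2 / sqrt(U) * exp(-0.25 * sum(log1p(rest^2 * U^2)))
  U <- max(abs(q), mu + 10 * sigma, 1)
  while (tail_bound(U) > pi * acc / 2 && U < 1e9) U <- U * 2
  n_terms <- ceiling(U / delta)
  if (!is.finite(n_terms) || n_terms > 6e7)
    return(list(p = NA_real_, ifault = 1L))
  # midpoint sum of the inversion integral, in chunks
  total <- 0
  chunk <- 2e6
  done <- 0L
  while (done < n_terms) {
    idx <- seq(done, min(done + chunk, n_terms) - 1L)
    u <- (idx + 0.5) * delta
    lu <- outer(lambda, u)
    theta <- 0.5 * colSums(atan(lu)) - 0.5 * q * u
    log_rho <- 0.25 * colSums(log1p(lu^2))
    total <- total + sum(sin(theta) / (u * exp(log_rho)))
    done <- done + length(idx)
  }
  p <- 0.5 + total * delta / pi
  if (!is.finite(p) || p < -1e-3 || p > 1 + 1e-3)
    return(list(p = NA_real_, ifault = 2L))
  list(p = min(max(p, 0), 1), ifault = 0L)
}

# moments of Q and the matched noncentral chi-square (Liu et al. style, with
# the modified matching used throughout the SKAT family)
liu_params <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  muQ <- c1
  sigmaQ <- sqrt(2 * c2)
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  muX <- l + d
  sigmaX <- sqrt(2) * a
  list(muQ = muQ, sigmaQ = sigmaQ, muX = muX, sigmaX = sigmaX, l = l, d = d)
}

#' Liu moment-matching tail probability
#'
#' Approximates `P(sum_k lambda_k X_k > q)` by matching moments to a
#' noncentral chi-square; the standard fallback when characteristic-function
#' inversion fails to converge.
#'
#' @inheritParams davies_tail
#' @return The tail probability.
#' @export
liu_tail <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-10 * max(lambda)]
  pr <- liu_params(lambda)
  tstar <- (q - pr$muQ) / pr$sigmaQ
  stats::pchisq(tstar * pr$sigmaX + pr$muX, df = pr$l, ncp = pr$d,
                lower.tail = FALSE)
}

# quantile of the mixture at upper-tail probability p, via the same matching
liu_quantile <- function(p_upper, lambda) {
  lambda <- lambda[lambda > 1e-10 * max(lambda)]
  pr <- liu_params(lambda)
  qx <- stats::qchisq(p_upper, df = pr$l, ncp = pr$d, lower.tail = FALSE)
  (qx - pr$muX) / pr$sigmaX * pr$sigmaQ + pr$muQ
}

#' Quadratic-form p-value with fallback
#'
#' Davies-type inversion first; on failure, Liu moment matching.
#'
#' @inheritParams davies_tail
#' @param method `"davies"` (with Liu fallback) or `"liu"` directly.
#' @return List with `p` and `method` actually used.
#' @export
quadform_pvalue <- function(q, lambda, method = c("davies", "liu"), acc = 1e-6) {
  method <- match.arg(method)
  if (method == "davies") {
    res <- davies_tail(q, lambda, acc = acc)
    # below the inversion's absolute accuracy the moment-matched tail keeps
    # relative precision; use it there
    if (res$ifault == 0L && res$p >= acc)
      return(list(p = res$p, method = "davies"))
  }
  list(p = liu_tail(q, lambda), method = "liu")
}
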