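## Tail probabilities of positive quadratic forms in standard normals,
## P( sum_k lambda_k chi^2_{1,k} > q ), needed for the kernel score test.
##
## Primary route: numerical inversion of the exact characteristic
## function (Imhof's integral) with adaptive quadrature.  Fallback:
## moment matching to a (non-central) chi-square (Liu-style four-moment
## match), used when the integral fails to converge or returns a value
## outside [0, 1].

#' Upper-tail probability of a weighted chi-square mixture
#'
#' Computes `P(sum_k lambda_k X_k > q)` where the `X_k` are independent
#' 1-df chi-square variables, by exact characteristic-function inversion
#' (Imhof's method); falls back to a four-moment chi-square match when
#' the quadrature fails.  Monotone non-increasing in `q`; `q <= 0`
#' returns 1.
#'
#' @param lambda Positive eigenvalues (numeric vector; non-positive
#'   entries are dropped, at least one must remain).
#' @param q Quadratic-form value (scalar).
#' @param acc Target absolute accuracy of the integral.
#' @return Tail probability in \[0, 1\]; attribute `method` records
#'   `"imhof"` or `"liu"`.
#' @export
quadratic_form_tail <- function(lambda, q, acc = 1e-9) {
  lambda <- lambda[lambda > 0]
  if (!length(lambda)) stop("at least one positive eigenvalue required")
  if (q <= 0) return(structure(1, method = "exact"))
  ## deep left tail (probability ~ 1): the inversion grid would be huge
  ## and the value statistically irrelevant; the moment match suffices
  if (q < 0.005 * sum(lambda) &&
      max(lambda) / min(lambda) - 1 >= 1e-12) {
    p <- min(max(liu_tail(lambda, q), 0), 1)
    attr(p, "method") <- "liu"
    return(p)
  }
  p <- tryCatch(imhof_tail(lambda, q, acc = acc), error = function(e) NA_real_)
  if (!is.na(p) && p > 1e-8 && p < 1e3 * acc)  # near-floor: refine once
    p <- tryCatch(imhof_tail(lambda, q, acc = max(p / 100, 1e-11)),
                  error = function(e) NA_real_)
  if (is.na(p) || p < 1e-8 || p > 1 + 1e-8) {
    ## quadrature failed or the absolute-accuracy floor was hit: fall
    ## back to the moment match, which keeps relative order in the far tail
    p <- max(liu_tail(lambda, q), 1e-300)
    attr(p, "method") <- "liu"
  } else {
    p <- min(p, 1)
    attr(p, "method") <- "imhof"
  }
  p
}

## Imhof (1961) integral for central quadratic forms:
## P(Q > q) = 1/2 + (1/pi) * Int_0^Inf sin(theta(u)) / (u * rho(u)) du
## A mixture with all eigenvalues equal is exactly a scaled chi-square
## and is evaluated in closed form.  Otherwise the integral is truncated
## at U where the integration-by-parts (oscillation) bound
## |tail| <= 4 g(U) / q, g(u) = 1/(u rho(u)), drops below the target
## accuracy; theta'(u) ~ -q/2 there, so the bound is valid once
## sum(lambda / (1 + lambda^2 u^2)) < q/2.
imhof_tail <- function(lambda, q, acc = 1e-9) {
  k <- length(lambda)
  if (max(lambda) / min(lambda) - 1 < 1e-12)
    return(stats::pchisq(q / mean(lambda), df = k, lower.tail = FALSE))
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    ifelse(u == 0, 0.5 * (sum(lambda) - q),  # limit of sin(theta)/(u rho)
           sin(theta) / (u * rho))
  }
  ## truncation point: beyond u_phase the phase derivative is below
  ## -q/4, and two integrations by parts bound the discarded tail by
  ## ~ 128*(1 + k/2)*g(U) / (q^2 * U) with g(u) = 1/(u*rho(u))
  log_g <- function(u) -log(u) - 0.25 * sum(log1p(lambda^2 * u^2))
  ## past u_phase, sum(lambda/(1+lambda^2 u^2)) <= sum(1/lambda)/u^2 < q/4,
  ## so the phase derivative is below -q/4 (scale-invariant bound)
  u_phase <- 2 * sqrt(sum(1 / lambda) / q)
  tail_bound <- function(u) log(128 * (1 + k / 2)) + log_g(u) -
    2 * log(q) - log(u)
  target <- log(acc * pi)
  U <- if (tail_bound(u_phase) <= target) u_phase else {
    u_hi <- u_phase
    while (tail_bound(u_hi) > target && u_hi < 1e7) u_hi <- u_hi * 4
    if (tail_bound(u_hi) > target) u_hi else
      stats::uniroot(function(u) tail_bound(u) - target,
                     lower = u_phase, upper = u_hi, tol = 1e-3 * u_phase)$root
  }
  if (U * q > 2e7) stop("oscillatory truncation point out of reach")
  ## composite 8-point Gauss-Legendre over [0, U]; segments are one sine
  ## period (4*pi/q) at most, graded near u = 0 where atan(lambda_max u)
  ## varies on scale 1/lambda_max; the integrand is analytic (u = 0 is
  ## removable)
  seg_max <- max(min(4 * pi / q, u_phase / 4), U / 2e4)
  lmax <- max(lambda)
  seg0 <- min(1 / (2 * lmax), seg_max)       # resolves atan(lambda_max u)
  graded <- seg0 * 1.5^(0:ceiling(log(4 * seg_max / seg0, 1.5) + 1))
  graded <- cumsum(c(0, pmin(graded, seg_max)))
  graded <- graded[graded < U]
  last <- graded[length(graded)]
  brk <- c(graded, if (U - last > seg_max)
    seq(last + seg_max, U, by = seg_max), U)
  brk <- brk[!duplicated(brk)]
  if (length(brk) > 20001L) stop("inversion grid out of reach")
  a <- brk[-length(brk)]; b <- brk[-1]
  mid <- (a + b) / 2; half <- (b - a) / 2
  u <- as.vector(outer(half, .GL8_NODES) + mid)  # segments x nodes
  f <- matrix(integrand(u), length(a))
  0.5 + sum((f %*% .GL8_WEIGHTS) * half) / pi
}

## 8-point Gauss-Legendre rule on [-1, 1].
.GL8_NODES <- c(-0.9602898564975363, -0.7966664774136267, -0.5255324099163290,
                -0.1834346424956498,  0.1834346424956498,  0.5255324099163290,
                 0.7966664774136267,  0.9602898564975363)
.GL8_WEIGHTS <- c(0.1012285362903763, 0.2223810344533745, 0.3137066458778873,
                  0.3626837833783620, 0.3626837833783620, 0.3137066458778873,
                  0.2223810344533745, 0.1012285362903763)

## Shared-grid Imhof evaluation for several q values with one set of
## eigenvalues: the u-grid terms phi(u) = 0.5*sum(atan(lambda u)) and
## rho(u) depend on lambda only, so sin(phi - q u/2) can be formed for
## all q at once.  Truncation uses the smallest q (largest U), segment
## length the largest q (fastest oscillation).  Used by the omnibus
## integration, where dozens of tail calls share one eigenvalue set.
imhof_tail_multi <- function(lambda, q, acc = 1e-8) {
  k <- length(lambda)
  if (max(lambda) / min(lambda) - 1 < 1e-12)
    return(stats::pchisq(q / mean(lambda), df = k, lower.tail = FALSE))
  ## left-tail values (q << sum(lambda), probability ~ 1) go through the
  ## moment match directly; inverting them would need an enormous grid
  low <- q < 0.005 * sum(lambda)
  out <- numeric(length(q))
  if (any(low))
    out[low] <- pmin(pmax(liu_tail(lambda, pmax(q[low], 0)), 0), 1)
  if (!any(!low)) return(out)
  qq <- q[!low]
  q_min <- min(qq)
  q_max <- max(qq)
  log_g <- function(u) -log(u) - 0.25 * sum(log1p(lambda^2 * u^2))
  u_phase <- 2 * sqrt(sum(1 / lambda) / q_min)
  tail_bound <- function(u) log(128 * (1 + k / 2)) + log_g(u) -
    2 * log(q_min) - log(u)
  target <- log(acc * pi)
  U <- u_phase
  while (tail_bound(U) > target && U < 1e6) U <- U * 1.6
  seg_max <- max(min(4 * pi / q_max, u_phase / 4), U / 2e4)
  lmax <- max(lambda)
  seg0 <- min(1 / (2 * lmax), seg_max)
  graded <- seg0 * 1.5^(0:ceiling(log(4 * seg_max / seg0, 1.5) + 1))
  graded <- cumsum(c(0, pmin(graded, seg_max)))
  graded <- graded[graded < U]
  last <- graded[length(graded)]
  brk <- c(graded, if (U - last > seg_max)
    seq(last + seg_max, U, by = seg_max), U)
  brk <- brk[!duplicated(brk)]
  if (length(brk) > 20001L) {
    out[!low] <- pmin(pmax(liu_tail(lambda, qq), 1e-300), 1)
    return(out)
  }
  a <- brk[-length(brk)]; b <- brk[-1]
  mid <- (a + b) / 2; half <- (b - a) / 2
  u <- as.vector(outer(half, .GL8_NODES) + mid)
  phi <- 0.5 * colSums(atan(outer(lambda, u)))
  inv_urho <- exp(-log(u) - 0.25 * colSums(log1p(outer(lambda^2, u^2))))
  wts <- as.vector(outer(half, .GL8_WEIGHTS))   # segment x node weights
  out[!low] <- vapply(qq, function(qi) {
    f <- sin(phi - 0.5 * qi * u) * inv_urho
    p <- 0.5 + sum(f * wts) / pi
    if (is.na(p) || p < 1e-8 || p > 1) p <- max(liu_tail(lambda, qi), 1e-300)
    min(p, 1)
  }, numeric(1))
  out
}

## Liu et al. four-moment match of a quadratic form to a (non-central)
## chi-square; the modified version matching kurtosis when possible.
liu_params <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  list(muQ = c1, sigmaQ = sqrt(2 * c2), l = l, d = d,
       muX = l + d, sigmaX = sqrt(2) * a)
}

## Vectorised over q.
liu_tail <- function(lambda, q) {
  p <- liu_params(lambda)
  tstar <- (q - p$muQ) / p$sigmaQ
  qx <- tstar * p$sigmaX + p$muX
  stats::pchisq(qx, df = p$l, ncp = p$d, lower.tail = FALSE)
}

## Upper-tail quantile of the mixture at tail probability `prob`, by the
## same moment match (used to invert per-rho distributions for the
## omnibus minimum-p statistic).
liu_quantile <- function(lambda, prob) {
  p <- liu_params(lambda)
  qx <- stats::qchisq(prob, df = p$l, ncp = p$d, lower.tail = FALSE)
  (qx - p$muX) / p$sigmaX * p$sigmaQ + p$muQ
}
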