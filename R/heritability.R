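#' Standard bivariate normal upper tail
#'
#' `P(X > t, Y > t)` for standard normal `X`, `Y` with correlation `rho`,
#' by reducing to a one-dimensional integral
#' `int_t^Inf phi(x) * Phi-bar((t - rho x) / sqrt(1 - rho^2)) dx`
#' evaluated by adaptive quadrature to absolute accuracy well below
#' 1e-10. At `t = 0` this reproduces Sheppard's closed form
#' `1/4 + asin(rho) / (2 pi)`.
#'
#' @param t common threshold
#' @param rho correlation in (-1, 1]; `rho = 1` returns the univariate
#'   tail
#' @return upper orthant probability
#' @export
bivariate_normal_tail <- function(t, rho) {
  if (rho < -1 || rho > 1) stop("rho must be in [-1, 1]")
  if (rho == 0) return(stats::pnorm(t, lower.tail = FALSE)^2)
  if (rho >= 1 - 1e-12) return(stats::pnorm(t, lower.tail = FALSE))
  s <- sqrt(1 - rho^2)
  f <- function(x)
    stats::dnorm(x) * stats::pnorm((t - rho * x) / s, lower.tail = FALSE)
  stats::integrate(f, t, Inf, rel.tol = 1e-13, abs.tol = 0,
                   subdivisions = 500L)$value
}

#' Sibling relative risk implied by a liability heritability
#'
#' Under the liability-threshold model, disease occurs when a standard
#' normal liability exceeds `T = qnorm(1 - K)` for prevalence `K`; the
#' liabilities of a relative pair are bivariate normal with correlation
#' `rho = a * h2` (`a = 1/2` for full siblings under additive genetics,
#' no shared environment). The relative recurrence risk is then
#' `lambda_R = P(L1 > T, L2 > T; rho) / K^2`.
#'
#' @param h2 heritability of liability in [0, 1]
#' @param K population prevalence in (0, 1)
#' @param a relationship coefficient in (0, 1] (default 1/2, full
#'   siblings)
#' @return `lambda_R >= 1`
#' @export
lambda_from_h2 <- function(h2, K, a = 0.5) {
  stopifnot(h2 >= 0, h2 <= 1, K > 0, K < 1, a > 0, a <= 1)
  T_ <- stats::qnorm(1 - K)
  bivariate_normal_tail(T_, a * h2) / K^2
}

#' Heritability of liability from a sibling relative risk
#'
#' Inverts [lambda_from_h2()] by bracketed root-finding on [0, 1]
#' (`lambda_R` is strictly increasing in `h2` at fixed `K`).
#'
#' @param lambda_r observed relative recurrence risk, `>= 1`
#' @inheritParams lambda_from_h2
#' @return heritability `h2` in [0, 1] with
#'   `|lambda_from_h2(h2) - lambda_r| <= 1e-8`
#' @export
h2_from_lambda <- function(lambda_r, K, a = 0.5) {
  stopifnot(K > 0, K < 1, a > 0, a <= 1)
  if (lambda_r < 1)
    stop("lambda_r must be >= 1 (", lambda_r, " given)")
  upper <- lambda_from_h2(1, K, a)
  if (lambda_r > upper)
    stop(sprintf(paste0("lambda_r = %g exceeds the h2 = 1 bound %.6g for ",
                        "K = %g, a = %g"), lambda_r, upper, K, a))
  if (lambda_r == 1) return(0)
  root <- stats::uniroot(function(h) lambda_from_h2(h, K, a) - lambda_r,
                         c(0, 1), tol = 1e-12)
  res <- lambda_from_h2(root$root, K, a) - lambda_r
  if (abs(res) > 1e-8)
    stop("root-finding residual too large: ", res)
  root$root
}

#' Liability-threshold heritability model
#'
#' Convenience wrapper solving for the heritability of liability given a
#' prevalence and a sibling relative risk, returning the full model state
#' (threshold, pair liability correlation).
#'
#' @param lambda_s sibling relative risk (probability that a sibling of a
#'   case is a case, divided by the prevalence)
#' @param prevalence population prevalence `K` in (0, 1)
#' @param pair_coefficient relationship coefficient `a` (default 1/2)
#' @return object of class `liability_model`: list with `h2`,
#'   `prevalence`, `threshold`, `lambda_s`, `rho` (= `a * h2`) and
#'   `pair_coefficient`
#' @export
#' @examples
#' # centenarian prevalence ~1/5000; published sibling relative risks 8-17
#' liability_model(8, 1 / 5000)    # h2 ~ 0.33
#' liability_model(17, 1 / 5000)   # h2 ~ 0.48
liability_model <- function(lambda_s, prevalence, pair_coefficient = 0.5) {
  h2 <- h2_from_lambda(lambda_s, prevalence, pair_coefficient)
  structure(list(h2 = h2, prevalence = prevalence,
                 threshold = stats::qnorm(1 - prevalence),
                 lambda_s = lambda_s, rho = pair_coefficient * h2,
                 pair_coefficient = pair_coefficient),
            class = "liability_model")
}

#' @export
print.liability_model <- function(x, ...) {
  cat("liability-threshold model\n")
  cat(sprintf("  prevalence K = %g  (threshold T = %.4f)\n",
              x$prevalence, x$threshold))
  cat(sprintf("  sibling relative risk = %g (pair coefficient %g)\n",
              x$lambda_s, x$pair_coefficient))
  cat(sprintf("  heritability of liability h2 = %.4f  (pair correlation rho = %.4f)\n",
              x$h2, x$rho))
  invisible(x)
}
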