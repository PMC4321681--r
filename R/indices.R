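#' Root mean square error of approximation
#'
#' Steiger-Lind form \eqn{\sqrt{\max(\chi^2 - df, 0) / (df (N - 1))}}; the
#' primary fit criterion of the stepwise search because it is relatively
#' insensitive to sample size. Values of 0.05-0.08 are the conventional
#' acceptable band.
#'
#' @param chi_square Likelihood-ratio chi-square (>= 0).
#' @param df Model degrees of freedom (>= 1).
#' @param n Sample size (matching the `(N - 1)` chi-square convention).
#' @return Nonnegative scalar; 0 whenever `chi_square <= df`.
#' @export
rmsea <- function(chi_square, df, n) {
  if (df < 1) stop("RMSEA is undefined for df = 0")
  if (n < 2) stop("n must be >= 2")
  if (chi_square < 0) stop("chi_square must be >= 0")
  sqrt(max(chi_square - df, 0) / (df * (n - 1)))
}

#' Tucker-Lewis index
#'
#' \deqn{TLI = \frac{\chi^2_b/df_b - \chi^2/df}{\chi^2_b/df_b - 1},}
#' clipped to `[0, 1]` (the unclipped value exceeds 1 at perfect fit; the
#' reported range is 0 = no fit to 1 = perfect fit, with >= 0.95 indicating
#' a good model). The baseline is the autoregressive-only null model, the
#' explicitly defined starting model of the search. A saturated model
#' (`df = 0`, `chi_square = 0`) is treated as a perfect fit (ratio 0).
#'
#' @param chi_square,df Fitted model chi-square and degrees of freedom.
#' @param chi_square_baseline,df_baseline Null-model chi-square and df
#'   (`df_baseline >= 1`).
#' @return Value in `[0, 1]`.
#' @export
tli <- function(chi_square, df, chi_square_baseline, df_baseline) {
  if (df_baseline < 1) stop("baseline df must be >= 1")
  ratio_b <- chi_square_baseline / df_baseline
  if (abs(ratio_b - 1) < 1e-12)
    stop("TLI undefined: baseline chi-square/df ratio equals 1")
  ratio_m <- if (df >= 1) chi_square / df else if (chi_square < 1e-8) 0 else
    stop("TLI undefined for df = 0 with positive chi-square")
  val <- (ratio_b - ratio_m) / (ratio_b - 1)
  min(max(val, 0), 1)
}

#' Goodness-of-fit index
#'
#' ML form \eqn{1 - \mathrm{tr}[(\hat\Sigma^{-1} S - I)^2] /
#' \mathrm{tr}[(\hat\Sigma^{-1} S)^2]}, clipped to `[0, 1]`; equals 1
#' exactly when the implied covariance reproduces the sample covariance.
#' Scale-invariant: `gfi(c S, c Sigma)` is identical for any `c > 0`.
#'
#' @param S Sample covariance.
#' @param Sigma Implied covariance (same dimension, positive-definite).
#' @return Value in `[0, 1]`.
#' @export
gfi <- function(S, Sigma) {
  S <- as.matrix(S); Sigma <- as.matrix(Sigma)
  if (!all(dim(S) == dim(Sigma))) stop("S and Sigma dimensions differ")
  W <- tryCatch(solve(Sigma, S),
                error = function(e) stop("Sigma is singular"))
  I <- diag(nrow(S))
  val <- 1 - sum(diag((W - I) %*% (W - I))) / sum(diag(W %*% W))
  min(max(val, 0), 1)
}
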