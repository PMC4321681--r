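#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' The ML fit function minimized by [usem()]:
#' \deqn{F_{ML} = \ln|\hat\Sigma| + \mathrm{tr}(S \hat\Sigma^{-1})
#'       - \ln|S| - p,}
#' nonnegative, and zero exactly when \eqn{S = \hat\Sigma}. The likelihood
#' ratio chi-square testing the implied against the observed covariance is
#' `(N - 1) * F_ML`.
#'
#' @param S Sample covariance (positive-definite).
#' @param Sigma Implied covariance (positive-definite, same dimension).
#' @return Nonnegative scalar.
#' @export
fml_discrepancy <- function(S, Sigma) {
  S <- as.matrix(S); Sigma <- as.matrix(Sigma)
  p <- nrow(S)
  if (!all(dim(Sigma) == p)) stop("S and Sigma dimensions differ")
  cS <- tryCatch(chol(S), error = function(e) stop("S is not positive-definite"))
  cE <- tryCatch(chol(Sigma),
                 error = function(e) stop("Sigma is not positive-definite"))
  ldS <- 2 * sum(log(diag(cS)))
  ldE <- 2 * sum(log(diag(cE)))
  f <- ldE + sum(diag(chol2inv(cE) %*% S)) - ldS - p
  max(f, 0)
}

#' Model-implied covariance matrix
#'
#' Computes \eqn{\Sigma(\theta) = (I - A)^{-1} \Psi (I - A)^{-\top}} in
#' reticular-action form, where `A` holds the directed path coefficients
#' (row = target) and `Psi` the symmetric residual/exogenous covariance: the
#' residual variances of the current variables on its diagonal and the free
#' lag-block (co)variances, with no current-lag coupling.
#'
#' @param model A `usem_model`.
#' @param coefficients Path coefficients in `model$paths` row order (or a
#'   vector named `src->dst`).
#' @param resid_vars Residual variances, one per current variable.
#' @param lag_cov `R x R` exogenous covariance of the lag variables
#'   (default identity, the standardized-data scale).
#' @return `2R x 2R` symmetric matrix in `model$variables` order.
#' @export
implied_covariance <- function(model, coefficients, resid_vars,
                               lag_cov = diag(length(model$roi_labels))) {
  stopifnot(inherits(model, "usem_model"))
  R <- length(model$roi_labels)
  p <- 2L * R
  if (!is.null(names(coefficients))) {
    want <- paste0(model$paths$src, "->", model$paths$dst)
    if (!all(want %in% names(coefficients)))
      stop("missing coefficients: ",
           paste(setdiff(want, names(coefficients)), collapse = ", "))
    coefficients <- coefficients[want]
  }
  if (length(coefficients) != nrow(model$paths))
    stop("need one coefficient per path")
  if (length(resid_vars) != R) stop("need one residual variance per ROI")
  A <- matrix(0, p, p)
  si <- match(model$paths$src, model$variables)
  di <- match(model$paths$dst, model$variables)
  A[cbind(di, si)] <- coefficients
  Psi <- matrix(0, p, p)
  diag(Psi)[1:R] <- resid_vars
  Psi[(R + 1):p, (R + 1):p] <- as.matrix(lag_cov)
  ImA <- diag(p) - A
  E <- tryCatch(solve(ImA), error = function(e)
    stop("(I - A) is singular; path coefficients define a degenerate system"))
  Sigma <- E %*% Psi %*% t(E)
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(model$variables, model$variables)
  Sigma
}

# --- internal RAM bookkeeping -------------------------------------------

# index structure shared by the optimizer, the MI machinery and the
# multi-group fitter
ram_index <- function(model) {
  R <- length(model$roi_labels)
  p <- 2L * R
  si <- match(model$paths$src, model$variables)
  di <- match(model$paths$dst, model$variables)
  list(R = R, p = p, cur = seq_len(R), lag = (R + 1L):p,
       src = si, dst = di, n_paths = length(si))
}

# per-equation least squares on the covariance matrix: start values and the
# exact ML solution for recursive systems
ols_start <- function(model, S) {
  ix <- ram_index(model)
  beta <- numeric(ix$n_paths)
  psi <- numeric(ix$R)
  for (i in ix$cur) {
    rows <- which(ix$dst == i)
    if (length(rows)) {
      P <- ix$src[rows]
      b <- solve(S[P, P, drop = FALSE], S[P, i])
      beta[rows] <- b
      psi[i] <- S[i, i] - drop(S[i, P, drop = FALSE] %*% b)
    } else {
      psi[i] <- S[i, i]
    }
    if (psi[i] < 1e-8 * S[i, i]) psi[i] <- 1e-8 * S[i, i]
  }
  list(beta = beta, psi = psi)
}

# Sigma and E = (I - A)^{-1} for a parameter vector theta = (beta, log psi)
ram_sigma <- function(theta, ix, S_LL) {
  A <- matrix(0, ix$p, ix$p)
  A[cbind(ix$dst, ix$src)] <- theta[seq_len(ix$n_paths)]
  psi <- exp(theta[ix$n_paths + seq_len(ix$R)])
  Psi <- matrix(0, ix$p, ix$p)
  diag(Psi)[ix$cur] <- psi
  Psi[ix$lag, ix$lag] <- S_LL
  ImA <- diag(ix$p) - A
  E <- tryCatch(solve(ImA), error = function(e) NULL)
  if (is.null(E)) return(NULL)
  Sigma <- E %*% Psi %*% t(E)
  list(Sigma = (Sigma + t(Sigma)) / 2, E = E, psi = psi)
}

# F_ML and its analytic gradient in (beta, log psi)
ram_objective <- function(theta, ix, S, S_LL, ldS) {
  rs <- ram_sigma(theta, ix, S_LL)
  if (is.null(rs)) return(1e10)
  cE <- tryCatch(chol(rs$Sigma), error = function(e) NULL)
  if (is.null(cE)) return(1e10)
  ldE <- 2 * sum(log(diag(cE)))
  val <- ldE + sum(chol2inv(cE) * S) - ldS - ix$p
  if (!is.finite(val)) 1e10 else val
}

ram_gradient <- function(theta, ix, S, S_LL, ldS) {
  rs <- ram_sigma(theta, ix, S_LL)
  if (is.null(rs)) return(rep(0, length(theta)))
  cE <- tryCatch(chol(rs$Sigma), error = function(e) NULL)
  if (is.null(cE)) return(rep(0, length(theta)))
  Sinv <- chol2inv(cE)
  G <- Sinv %*% (rs$Sigma - S) %*% Sinv    # dF/dSigma
  gradA <- 2 * t(rs$E) %*% G %*% rs$Sigma  # [target, source]
  gb <- gradA[cbind(ix$dst, ix$src)]
  EGE <- t(rs$E) %*% G %*% rs$E
  gp <- diag(EGE)[ix$cur] * rs$psi         # chain rule through log psi
  c(gb, gp)
}

#' Fit a unified structural equation model by maximum likelihood
#'
#' Estimates the free path coefficients and residual variances of `model`
#' on the pooled sample covariance of a lag-augmented dataset, minimizing
#' the ML discrepancy [fml_discrepancy()] with analytic gradients (BFGS,
#' objective tolerance 1e-8, at most `maxit` iterations). Start values come
#' from per-equation least squares, which is already the ML solution for
#' recursive systems. The saturated lag-block estimate equals the sample
#' lag-block covariance and is concentrated out analytically; it still
#' counts among the free parameters for degrees of freedom.
#'
#' The returned fit carries the likelihood-ratio chi-square
#' `(N - 1) * F_ML`, degrees of freedom, and the descriptive indices RMSEA,
#' TLI (against the autoregressive-only null baseline) and GFI.
#'
#' @param data A `lagged_dataset` (see [lag_embed()]).
#' @param model A `usem_model`; defaults to the null model on the dataset's
#'   ROIs.
#' @param baseline Logical: also fit the null model for the TLI baseline
#'   (skipped automatically when `model` is itself the null model).
#' @param start Optional start values `list(beta, psi)` overriding the
#'   least-squares defaults.
#' @param maxit Maximum BFGS iterations (default 500).
#' @param reltol Relative objective tolerance for BFGS.
#' @return An object of class `usem`; see Details. Key fields: `estimates`
#'   (data.frame of paths and coefficients), `psi` (residual variances),
#'   `Sigma` (implied covariance), `fml`, `chisq`, `df`, `rmsea`, `tli`,
#'   `gfi`, `n`, `converged`.
#' @seealso [usem_search()], [fit_indices()], [compare_all_paths()]
#' @export
#' @examples
#' spec <- usem_sim_spec(2, Phi = diag(0.3, 2),
#'                       B = matrix(c(0, 0, 0.5, 0), 2, 2, byrow = TRUE),
#'                       n_time = 200, n_subjects = 4, seed = 7)
#' ld <- lag_embed(standardize_panel(simulate_usem(spec)))
#' fit <- usem(ld, add_connection(null_model(ld$roi_labels), "ROI1", "ROI2"))
#' coef(fit)
usem <- function(data, model = NULL, baseline = TRUE, start = NULL,
                 maxit = 500, reltol = 1e-10) {
  stopifnot(inherits(data, "lagged_dataset"))
  if (is.null(model)) model <- null_model(data$roi_labels)
  stopifnot(inherits(model, "usem_model"))
  if (!setequal(model$roi_labels, data$roi_labels))
    stop("model ROI labels (", paste(model$roi_labels, collapse = ", "),
         ") do not match dataset ROI labels (",
         paste(data$roi_labels, collapse = ", "), ")")
  S <- data$S[model$variables, model$variables]
  N <- data$n_effective
  if (kappa(S, exact = TRUE) > 1e12)
    stop("sample covariance is numerically singular (condition number > 1e12); ",
         "use more rows or fewer ROIs")
  df <- degrees_of_freedom(model)

  ix <- ram_index(model)
  S_LL <- S[ix$lag, ix$lag, drop = FALSE]
  ldS <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  st <- if (is.null(start)) ols_start(model, S) else start
  theta0 <- c(st$beta, log(st$psi))

  opt <- stats::optim(theta0, ram_objective, gr = ram_gradient, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol),
                      ix = ix, S = S, S_LL = S_LL, ldS = ldS)
  grad <- ram_gradient(opt$par, ix, S, S_LL, ldS)
  converged <- opt$convergence == 0 && max(abs(grad)) < 1e-4
  rs <- ram_sigma(opt$par, ix, S_LL)
  dimnames(rs$Sigma) <- dimnames(S)
  fml <- max(opt$value, 0)
  chisq <- max((N - 1) * fml, 0)

  est <- model$paths
  est$coefficient <- opt$par[seq_len(ix$n_paths)]
  psi <- rs$psi
  names(psi) <- model$roi_labels

  base <- NULL
  tli_val <- NA_real_
  is_null_model <- all(model$paths$kind == "autoregressive")
  if (is_null_model) {
    base <- list(chisq = chisq, df = df)
    tli_val <- if (df > 0 && abs(chisq / df - 1) > 1e-12) 0 else NA_real_
  } else if (isTRUE(baseline)) {
    bf <- usem(data, null_model(model$roi_labels), baseline = FALSE)
    base <- list(chisq = bf$chisq, df = bf$df)
    tli_val <- tryCatch(tli(chisq, df, base$chisq, base$df),
                        error = function(e) NA_real_)
  }

  structure(list(
    model = model, estimates = est, psi = psi,
    psi_lag = S_LL, S = S, Sigma = rs$Sigma, n = N,
    fml = fml, chisq = chisq, df = df,
    rmsea = rmsea_internal(chisq, df, N),
    tli = tli_val, gfi = gfi(S, rs$Sigma),
    baseline = base, converged = converged,
    optim = list(counts = opt$counts, convergence = opt$convergence,
                 max_grad = max(abs(grad))),
    group_label = data$group_label, condition_label = data$condition_label,
    call = match.call()
  ), class = "usem")
}

# RMSEA with the saturated-model convention: df = 0 and chi-square ~ 0 is a
# perfect fit (0); df = 0 with positive chi-square is undefined
rmsea_internal <- function(chisq, df, n) {
  if (df == 0) {
    if (chisq < 1e-6 * max(1, n)) return(0)
    return(NA_real_)
  }
  sqrt(max(chisq - df, 0) / (df * (n - 1)))
}

#' @export
print.usem <- function(x, digits = 3, ...) {
  cat(sprintf("Unified SEM fit: %d ROIs, %d paths (%d cross), N = %d\n",
              length(x$model$roi_labels), nrow(x$model$paths),
              sum(x$model$paths$kind != "autoregressive"), x$n))
  cat(sprintf("chi-square = %.3f on %d df;  RMSEA = %s  TLI = %s  GFI = %s\n",
              x$chisq, x$df, fmt_idx(x$rmsea), fmt_idx(x$tli), fmt_idx(x$gfi)))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

fmt_idx <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)

#' @export
summary.usem <- function(object, ...) {
  structure(list(fit = object), class = "summary.usem")
}

#' @export
print.summary.usem <- function(x, ...) {
  f <- x$fit
  print(f)
  est <- f$estimates
  cat("\nPath coefficients:\n")
  out <- data.frame(path = paste0(est$src, " -> ", est$dst), kind = est$kind,
                    coefficient = round(est$coefficient, 4))
  print(out, row.names = FALSE)
  cat("\nResidual variances:\n")
  print(round(f$psi, 4))
  invisible(x)
}

#' @export
coef.usem <- function(object, ...) {
  est <- object$estimates
  stats::setNames(est$coefficient, paste0(est$src, "->", est$dst))
}

#' @export
fitted.usem <- function(object, ...) object$Sigma

#' @export
residuals.usem <- function(object, ...) object$S - object$Sigma

#' @export
logLik.usem <- function(object, ...) {
  # pseudo log-likelihood of the pooled rows under N(0, Sigma)
  p <- nrow(object$Sigma)
  val <- -0.5 * object$n *
    (p * log(2 * pi) +
       as.numeric(determinant(object$Sigma, logarithm = TRUE)$modulus) +
       sum(solve(object$Sigma) * object$S) * (object$n - 1) / object$n)
  structure(val, df = n_free_params(object$model), nobs = object$n,
            class = "logLik")
}

#' Simulate new panels from a fitted unified SEM
#'
#' Converts the fitted contemporaneous block, lag block and residual
#' variances back into a generative specification ([usem_sim_spec()]) and
#' draws fresh subject series from it. Fails if the estimated system is
#' non-stationary.
#'
#' @param object A fitted `usem`.
#' @param nsim Number of panels to draw.
#' @param seed Seed for the first panel; panel `i` uses `seed + i - 1`.
#' @param n_time,n_subjects Panel dimensions (defaults: 150 volumes,
#'   14 subjects).
#' @param ... Unused.
#' @return A list of `roi_panel` objects (a single panel if `nsim = 1`).
#' @export
simulate.usem <- function(object, nsim = 1, seed = 1L, n_time = 150,
                          n_subjects = 14, ...) {
  R <- length(object$model$roi_labels)
  ix <- ram_index(object$model)
  A <- matrix(0, ix$p, ix$p)
  A[cbind(ix$dst, ix$src)] <- object$estimates$coefficient
  B <- A[ix$cur, ix$cur, drop = FALSE]
  Phi <- A[ix$cur, ix$lag, drop = FALSE]
  out <- lapply(seq_len(nsim), function(i) {
    spec <- usem_sim_spec(R, Phi = Phi, B = B,
                          innovation_vars = unname(object$psi),
                          n_time = n_time, n_subjects = n_subjects,
                          seed = as.integer(seed) + i - 1L,
                          roi_labels = object$model$roi_labels)
    simulate_usem(spec, group_label = object$group_label,
                  condition_label = object$condition_label)
  })
  if (nsim == 1) out[[1]] else out
}

#' Plot a fitted model as a directed path diagram
#'
#' ROIs on a circle; solid arrows are contemporaneous effects, dashed arrows
#' longitudinal (lag-1) effects; autoregressive self-paths are omitted.
#' Edge labels give the estimated coefficients.
#'
#' @param x A fitted `usem`.
#' @param digits Digits on edge labels.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.usem <- function(x, digits = 2, ...) {
  labs <- x$model$roi_labels
  R <- length(labs)
  ang <- pi / 2 - 2 * pi * (seq_len(R) - 1) / R
  xs <- cos(ang); ys <- sin(ang)
  graphics::plot(NA, xlim = c(-1.45, 1.45), ylim = c(-1.45, 1.45), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", ...)
  est <- x$estimates[x$estimates$kind != "autoregressive", , drop = FALSE]
  for (i in seq_len(nrow(est))) {
    from <- match(sub("^lag-", "", est$src[i]), labs)
    to <- match(est$dst[i], labs)
    lty <- if (est$kind[i] == "longitudinal") 2 else 1
    # shrink toward endpoints so arrows stop at the node circles
    dx <- xs[to] - xs[from]; dy <- ys[to] - ys[from]
    len <- sqrt(dx^2 + dy^2)
    sh <- 0.14 / len
    graphics::arrows(xs[from] + dx * sh, ys[from] + dy * sh,
                     xs[to] - dx * sh, ys[to] - dy * sh,
                     length = 0.1, lty = lty,
                     col = if (est$coefficient[i] >= 0) "black" else "red3")
    graphics::text(xs[from] + dx * 0.45, ys[from] + dy * 0.45,
                   format(round(est$coefficient[i], digits)), cex = 0.7,
                   pos = 3)
  }
  graphics::symbols(xs, ys, circles = rep(0.12, R), inches = FALSE,
                    add = TRUE, bg = "grey95")
  graphics::text(xs, ys, labs, cex = 0.8)
  graphics::legend("bottomright", lty = c(1, 2),
                   legend = c("contemporaneous", "longitudinal"), bty = "n",
                   cex = 0.8)
  invisible(x)
}

#' Export a fit's statistics as a one-row table
#'
#' Columns follow the conventional fit-table layout: RMSEA, chi-square,
#' dof, TLI, GFI.
#'
#' @param fit A fitted `usem`.
#' @return One-row `data.frame`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "usem"))
  data.frame(RMSEA = fit$rmsea, Chi_square = fit$chisq, dof = fit$df,
             TLI = fit$tli, GFI = fit$gfi)
}

#' Serialize a fit result as JSON
#'
#' @param fit A fitted `usem`.
#' @param path Output file.
#' @param provenance Optional named list merged into the record.
#' @export
write_fit_json <- function(fit, path, provenance = NULL) {
  obj <- c(list(
    roi_labels = fit$model$roi_labels,
    paths = cbind(fit$estimates[, c("src", "dst", "kind")],
                  coefficient = fit$estimates$coefficient),
    residual_variances = as.list(fit$psi),
    N = fit$n, F_ML = fit$fml,
    RMSEA = fit$rmsea, Chi_square = fit$chisq, dof = fit$df,
    TLI = fit$tli, GFI = fit$gfi, converged = fit$converged
  ), if (is.null(provenance)) list() else provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
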