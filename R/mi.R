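#' Modification indices for absent cross paths
#'
#' Score-test (Lagrange-multiplier) estimates of the chi-square drop from
#' freeing one currently fixed path, used to shortlist candidate
#' connections during the stepwise search. For each admissible absent path
#' (contemporaneous or longitudinal, between distinct ROIs) the index is
#' \deqn{MI = (N - 1) \, g^2 / (2 \tilde h),}
#' where `g` is the fit-function gradient with respect to the fixed
#' coefficient at the restricted optimum and \eqn{\tilde h} the Schur
#' complement of the expected information, accounting for the correlation
#' of the candidate with every free parameter (path coefficients, residual
#' variances, and the lag-block covariances).
#'
#' @param fit A converged `usem` fit.
#' @return `data.frame` with columns `src`, `dst`, `kind`, `mi`, sorted by
#'   decreasing index (ties broken by source then target name). Zero rows
#'   for a saturated model.
#' @export
modification_indices <- function(fit) {
  stopifnot(inherits(fit, "usem"))
  if (!fit$converged)
    warning("modification indices computed on a non-converged fit")
  model <- fit$model
  if (degrees_of_freedom(model) == 0)    # saturated: nothing left to free
    return(data.frame(src = character(), dst = character(),
                      kind = character(), mi = numeric()))
  ix <- ram_index(model)
  labs <- model$roi_labels
  S <- fit$S
  Sigma <- fit$Sigma
  A <- matrix(0, ix$p, ix$p)
  A[cbind(ix$dst, ix$src)] <- fit$estimates$coefficient
  E <- solve(diag(ix$p) - A)
  Sinv <- chol2inv(chol(Sigma))
  G <- Sinv %*% (Sigma - S) %*% Sinv

  d_path <- function(i, j) {           # dSigma/dA[i, j]
    M <- E[, i] %o% Sigma[j, ]
    M + t(M)
  }
  d_psi <- function(k, l) {            # dSigma/dPsi[k, l]
    M <- E[, k] %o% E[, l]
    if (k == l) M else M + t(M)
  }

  # derivative matrices of all free parameters
  Dfree <- vector("list", 0)
  for (r in seq_len(ix$n_paths))
    Dfree[[length(Dfree) + 1]] <- d_path(ix$dst[r], ix$src[r])
  for (k in ix$cur) Dfree[[length(Dfree) + 1]] <- d_psi(k, k)
  for (k in ix$lag) for (l in ix$lag) if (k <= l)
    Dfree[[length(Dfree) + 1]] <- d_psi(k, l)
  Kfree <- lapply(Dfree, function(D) Sinv %*% D)

  nf <- length(Kfree)
  Hff <- matrix(0, nf, nf)
  for (i in seq_len(nf)) for (j in i:nf) {
    Hff[i, j] <- Hff[j, i] <- sum(Kfree[[i]] * t(Kfree[[j]]))
  }

  cand <- list()
  for (a in labs) for (b in labs) {
    if (a == b) next
    if (!has_path(model, a, b))
      cand[[length(cand) + 1]] <- c(a, b, "contemporaneous")
    if (!has_path(model, paste0("lag-", a), b))
      cand[[length(cand) + 1]] <- c(paste0("lag-", a), b, "longitudinal")
  }
  if (!length(cand))
    return(data.frame(src = character(), dst = character(),
                      kind = character(), mi = numeric()))

  mi_one <- function(src, dst) {
    i <- match(dst, model$variables)
    j <- match(src, model$variables)
    Da <- d_path(i, j)
    Ka <- Sinv %*% Da
    g <- sum(G * Da)
    haa <- sum(Ka * t(Ka))
    Haf <- vapply(Kfree, function(K) sum(Ka * t(K)), numeric(1))
    w <- tryCatch(solve(Hff, Haf), error = function(e) {
      qr.solve(Hff, Haf, tol = 1e-12)
    })
    htilde <- haa - sum(Haf * w)
    if (htilde <= 1e-12) return(0)   # candidate not locally identified
    max((fit$n - 1) * g^2 / (2 * htilde), 0)
  }

  out <- do.call(rbind, lapply(cand, function(cc)
    data.frame(src = cc[1], dst = cc[2], kind = cc[3],
               mi = mi_one(cc[1], cc[2]), stringsAsFactors = FALSE)))
  out <- out[order(-out$mi, out$src, out$dst), , drop = FALSE]
  rownames(out) <- NULL
  out
}
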