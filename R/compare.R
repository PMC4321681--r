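#' Fit a fixed model structure to another group's data
#'
#' The reversed-model check: a best-fit model discovered on one group is
#' re-estimated, without any re-search, on the other group's lagged
#' dataset. Comparable fit indices indicate no substantial network
#' difference between groups.
#'
#' @param model A `usem_model` (e.g. one group's best-fit model).
#' @param dataset The other group's `lagged_dataset`; ROI labels must match.
#' @return A fitted `usem`.
#' @export
cross_fit <- function(model, dataset) usem(dataset, model)

#' Union ("hybrid") model of two groups' best-fit models
#'
#' The hybrid model comprises every path observed in either group's model,
#' so that the same structure can be fit to both data sets and compared
#' path by path.
#'
#' @param model_a,model_b `usem_model`s over the same ROI set.
#' @return A `usem_model` whose path set is the union (autoregressive paths
#'   present once).
#' @export
build_hybrid <- function(model_a, model_b) {
  stopifnot(inherits(model_a, "usem_model"), inherits(model_b, "usem_model"))
  if (!identical(sort(model_a$roi_labels), sort(model_b$roi_labels)))
    stop("models are defined over different ROI sets")
  hybrid <- usem_model(model_a$roi_labels)
  for (m in list(model_a, model_b)) {
    cross <- m$paths[m$paths$kind != "autoregressive", , drop = FALSE]
    for (i in seq_len(nrow(cross)))
      if (!has_path(hybrid, cross$src[i], cross$dst[i]))
        hybrid <- add_path(hybrid, cross$src[i], cross$dst[i], cross$kind[i])
  }
  hybrid
}

#' Two-group joint fit with optional equality constraints
#'
#' Fits the same model simultaneously to two groups by minimizing the
#' weighted sum \eqn{\sum_g (N_g - 1) F_{ML,g}}. All parameters are
#' group-specific except the path coefficients named in `constraints`,
#' which share a single value across groups. With no constraints the joint
#' fit separates exactly into the two single-group fits (total chi-square
#' equals the sum of the separate chi-squares). The joint RMSEA is computed
#' from the total chi-square, total degrees of freedom
#' (`2 * p(p+1)/2 - q_total`) and total effective `N`.
#'
#' @param model A `usem_model` (typically a hybrid model).
#' @param dataset_a,dataset_b `lagged_dataset`s sharing the model's ROI set.
#' @param constraints Character vector of path ids `"src->dst"` (or a
#'   data.frame with `src`, `dst`) whose coefficients are equated across
#'   groups; every named path must be in the model.
#' @param maxit,reltol Optimizer controls.
#' @return An object of class `usem_joint`: `chisq`, `df`, `n`, `rmsea`,
#'   per-group coefficient tables (`estimates_a`, `estimates_b`), `gfi_a`,
#'   `gfi_b`, `converged`.
#' @export
fit_joint <- function(model, dataset_a, dataset_b, constraints = character(),
                      maxit = 1000, reltol = 1e-10) {
  stopifnot(inherits(model, "usem_model"))
  for (d in list(dataset_a, dataset_b))
    if (!setequal(model$roi_labels, d$roi_labels))
      stop("dataset ROI labels do not match the model")
  ids <- paste0(model$paths$src, "->", model$paths$dst)
  if (is.data.frame(constraints))
    constraints <- paste0(constraints$src, "->", constraints$dst)
  cons <- match(constraints, ids)
  if (anyNA(cons))
    stop("constraint names a path absent from the model: ",
         paste(constraints[is.na(cons)], collapse = ", "))
  ix <- ram_index(model)
  p <- ix$p
  m_moments <- p * (p + 1) / 2
  df_total <- as.integer(2 * m_moments - (2 * n_free_params(model) - length(cons)))
  n_total <- dataset_a$n_effective + dataset_b$n_effective

  if (!length(cons)) {
    fa <- usem(dataset_a, model, baseline = FALSE)
    fb <- usem(dataset_b, model, baseline = FALSE)
    return(joint_result(model, fa$chisq + fb$chisq, df_total, n_total,
                        fa$estimates, fb$estimates,
                        gfi_a = fa$gfi, gfi_b = fb$gfi,
                        converged = fa$converged && fb$converged,
                        constraints = character()))
  }

  free <- setdiff(seq_len(ix$n_paths), cons)
  nb <- ix$n_paths; nc <- length(cons); nf <- length(free); R <- ix$R
  # theta = [beta_shared, beta_free_A, logpsi_A, beta_free_B, logpsi_B]
  slot_a <- function(theta) {
    beta <- numeric(nb)
    beta[cons] <- theta[seq_len(nc)]
    beta[free] <- theta[nc + seq_len(nf)]
    c(beta, theta[nc + nf + seq_len(R)])
  }
  slot_b <- function(theta) {
    beta <- numeric(nb)
    beta[cons] <- theta[seq_len(nc)]
    beta[free] <- theta[nc + nf + R + seq_len(nf)]
    c(beta, theta[nc + 2 * nf + R + seq_len(R)])
  }
  prep <- function(ds) {
    S <- ds$S[model$variables, model$variables]
    list(S = S, S_LL = S[ix$lag, ix$lag, drop = FALSE],
         ldS = as.numeric(determinant(S, logarithm = TRUE)$modulus),
         w = ds$n_effective - 1)
  }
  ga <- prep(dataset_a); gb <- prep(dataset_b)

  objective <- function(theta) {
    ga$w * ram_objective(slot_a(theta), ix, ga$S, ga$S_LL, ga$ldS) +
      gb$w * ram_objective(slot_b(theta), ix, gb$S, gb$S_LL, gb$ldS)
  }
  gradient <- function(theta) {
    da <- ga$w * ram_gradient(slot_a(theta), ix, ga$S, ga$S_LL, ga$ldS)
    db <- gb$w * ram_gradient(slot_b(theta), ix, gb$S, gb$S_LL, gb$ldS)
    g <- numeric(length(theta))
    g[seq_len(nc)] <- da[cons] + db[cons]
    g[nc + seq_len(nf)] <- da[free]
    g[nc + nf + seq_len(R)] <- da[nb + seq_len(R)]
    g[nc + nf + R + seq_len(nf)] <- db[free]
    g[nc + 2 * nf + R + seq_len(R)] <- db[nb + seq_len(R)]
    g
  }

  sa <- ols_start(model, ga$S); sb <- ols_start(model, gb$S)
  theta0 <- c((sa$beta[cons] + sb$beta[cons]) / 2, sa$beta[free],
              log(sa$psi), sb$beta[free], log(sb$psi))
  opt <- stats::optim(theta0, objective, gr = gradient, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  grad <- gradient(opt$par)
  # gradient scale follows the (N_g - 1) weights; normalize before testing
  converged <- opt$convergence == 0 &&
    max(abs(grad)) / (ga$w + gb$w) < 1e-5

  ta <- slot_a(opt$par); tb <- slot_b(opt$par)
  est_a <- model$paths; est_a$coefficient <- ta[seq_len(nb)]
  est_b <- model$paths; est_b$coefficient <- tb[seq_len(nb)]
  rs_a <- ram_sigma(ta, ix, ga$S_LL); rs_b <- ram_sigma(tb, ix, gb$S_LL)
  joint_result(model, max(opt$value, 0), df_total, n_total, est_a, est_b,
               gfi_a = gfi(ga$S, rs_a$Sigma), gfi_b = gfi(gb$S, rs_b$Sigma),
               converged = converged, constraints = constraints)
}

joint_result <- function(model, chisq, df, n, est_a, est_b, gfi_a, gfi_b,
                         converged, constraints) {
  structure(list(model = model, chisq = chisq, df = df, n = n,
                 rmsea = rmsea_internal(chisq, df, n),
                 estimates_a = est_a, estimates_b = est_b,
                 gfi_a = gfi_a, gfi_b = gfi_b, converged = converged,
                 constraints = constraints),
            class = "usem_joint")
}

#' @export
print.usem_joint <- function(x, ...) {
  cat(sprintf("Two-group uSEM fit (%d constraint%s): chi-square = %.3f on %d df, RMSEA = %s\n",
              length(x$constraints), if (length(x$constraints) == 1) "" else "s",
              x$chisq, x$df, fmt_idx(x$rmsea)))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' Per-path equality tests between two groups
#'
#' For each path of the hybrid model (cross paths by default), the
#' coefficient is constrained to be identical across groups in a joint
#' two-group fit; the chi-square increase over the unconstrained joint fit
#' is a 1-df likelihood-ratio statistic for a group difference on that
#' path. Raw p-values are reported with no multiplicity correction; apply
#' one downstream if desired.
#'
#' @param model The hybrid `usem_model`.
#' @param dataset_a,dataset_b The two groups' `lagged_dataset`s.
#' @param alpha Significance level for flagging (default 0.05; `alpha = 0`
#'   flags nothing).
#' @param include_autoregressive Also test autoregressive paths (default
#'   `FALSE`: the denominator counts contemporaneous + longitudinal cross
#'   paths).
#' @return An object of class `usem_path_comparison`: a `data.frame` with
#'   one row per tested path (`src`, `dst`, `kind`, `coef_a`, `coef_b`,
#'   `delta_chi2`, `p`, `flagged`); paths whose constrained fit does not
#'   converge get `NA` statistics and the run continues. Attributes carry
#'   the unconstrained joint fit and `alpha`.
#' @export
compare_all_paths <- function(model, dataset_a, dataset_b, alpha = 0.05,
                              include_autoregressive = FALSE) {
  base <- fit_joint(model, dataset_a, dataset_b)
  paths <- model$paths
  if (!include_autoregressive)
    paths <- paths[paths$kind != "autoregressive", , drop = FALSE]
  ids <- paste0(paths$src, "->", paths$dst)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    con <- tryCatch(fit_joint(model, dataset_a, dataset_b,
                              constraints = ids[i]),
                    error = function(e) NULL)
    ca <- base$estimates_a$coefficient[match(ids[i],
            paste0(base$estimates_a$src, "->", base$estimates_a$dst))]
    cb <- base$estimates_b$coefficient[match(ids[i],
            paste0(base$estimates_b$src, "->", base$estimates_b$dst))]
    if (is.null(con) || !con$converged) {
      rows[[i]] <- data.frame(src = paths$src[i], dst = paths$dst[i],
                              kind = paths$kind[i], coef_a = ca, coef_b = cb,
                              delta_chi2 = NA_real_, p = NA_real_,
                              flagged = NA, stringsAsFactors = FALSE)
      next
    }
    d <- max(con$chisq - base$chisq, 0)
    pval <- stats::pchisq(d, df = 1, lower.tail = FALSE)
    rows[[i]] <- data.frame(src = paths$src[i], dst = paths$dst[i],
                            kind = paths$kind[i], coef_a = ca, coef_b = cb,
                            delta_chi2 = d, p = pval,
                            flagged = is.finite(pval) && pval < alpha,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("usem_path_comparison", "data.frame"),
            base_fit = base, alpha = alpha,
            group_a = dataset_a$group_label, group_b = dataset_b$group_label)
}

#' @export
print.usem_path_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Per-path group comparison (%s vs %s), alpha = %g\n",
              attr(x, "group_a"), attr(x, "group_b"), attr(x, "alpha")))
  n_sig <- sum(x$flagged, na.rm = TRUE)
  cat(sprintf("%d of %d paths differ significantly\n", n_sig, nrow(x)))
  df <- as.data.frame(x)
  df$coef_a <- round(df$coef_a, digits)
  df$coef_b <- round(df$coef_b, digits)
  df$delta_chi2 <- round(df$delta_chi2, digits)
  df$p <- signif(df$p, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a path comparison as TSV (+ JSON summary)
#'
#' @param comparison A `usem_path_comparison`.
#' @param tsv_path Output TSV of per-path rows.
#' @param json_path Optional JSON summary path.
#' @param provenance Optional named list merged into the JSON summary.
#' @export
write_comparison <- function(comparison, tsv_path, json_path = NULL,
                             provenance = NULL) {
  utils::write.table(as.data.frame(comparison), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    base <- attr(comparison, "base_fit")
    obj <- c(list(n_paths = nrow(comparison),
                  n_flagged = sum(comparison$flagged, na.rm = TRUE),
                  alpha = attr(comparison, "alpha"),
                  joint_chisq = base$chisq, joint_df = base$df,
                  joint_rmsea = base$rmsea),
             if (is.null(provenance)) list() else provenance)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}

#' Concatenate two groups' rows into one pooled dataset
#'
#' Physical row concatenation conflates group covariance differences with
#' path differences, so the default comparison machinery keeps groups
#' separate (two-group SEM with equality constraints); this helper exists
#' for fidelity experiments with the pooled-rows convention.
#'
#' @param dataset_a,dataset_b `lagged_dataset`s with rows, same ROI labels.
#' @param group_label Label for the pooled dataset.
#' @return A pooled `lagged_dataset`.
#' @export
concat_datasets <- function(dataset_a, dataset_b, group_label = "pooled") {
  stopifnot(!is.null(dataset_a$data), !is.null(dataset_b$data))
  if (!identical(dataset_a$variables, dataset_b$variables))
    stop("datasets have different variables")
  data <- rbind(dataset_a$data, dataset_b$data)
  structure(list(data = data, S = stats::cov(data), n_effective = nrow(data),
                 roi_labels = dataset_a$roi_labels,
                 variables = dataset_a$variables,
                 group_label = group_label,
                 condition_label = dataset_a$condition_label),
            class = "lagged_dataset")
}
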