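#' Build the lag-augmented dataset for unified SEM
#'
#' Each ROI contributes two variables: its current series and a one-volume
#' delayed copy. For a subject with volumes \eqn{1..T}, rows pair volume
#' \eqn{t} (current) with volume \eqn{t-1} (lag), \eqn{t = 2..T}; rows are
#' pooled across subjects so no row ever pairs one subject's first volume
#' with another's last. The pooled sample covariance `S` (denominator
#' `N_effective - 1`) is what all model fitting consumes.
#'
#' Input series must already be standardized per subject and ROI
#' (see [standardize_panel()]); unstandardized input is rejected.
#'
#' @param panel An `roi_panel` of standardized series.
#' @param mean_tol,var_tol Tolerances for the standardization check. The
#'   variance band is loose enough to accept either the population (`N`) or
#'   sample (`N - 1`) denominator at typical series lengths.
#' @return An object of class `lagged_dataset`: list with `data`
#'   (`N_effective x 2R` matrix, current columns first, lag columns named
#'   `lag-<roi>`), `S`, `n_effective`, `roi_labels`, `variables`,
#'   `group_label`, `condition_label`.
#' @export
#' @examples
#' p <- roi_panel(list(cbind(x = standardize_series(c(1, 3, 2, 5)))), "x")
#' ld <- lag_embed(p)
#' ld$n_effective  # 3
lag_embed <- function(panel, mean_tol = 1e-6, var_tol = 0.05) {
  stopifnot(inherits(panel, "roi_panel"))
  R <- length(panel$roi_labels)
  cur_names <- panel$roi_labels
  lag_names <- paste0("lag-", panel$roi_labels)
  blocks <- vector("list", length(panel$subjects))
  for (s in seq_along(panel$subjects)) {
    X <- panel$subjects[[s]]
    Tn <- nrow(X)
    if (Tn < 3) stop("subject ", s, " has T < 3")
    m <- colMeans(X)
    v <- colMeans(sweep(X, 2, m)^2)
    bad <- abs(m) > mean_tol | abs(v - 1) > var_tol
    if (any(bad))
      stop("subject ", s, " series not standardized (ROI ",
           paste(cur_names[bad], collapse = ", "),
           "); run standardize_panel() first")
    block <- cbind(X[2:Tn, , drop = FALSE], X[1:(Tn - 1), , drop = FALSE])
    blocks[[s]] <- block
  }
  data <- do.call(rbind, blocks)
  colnames(data) <- c(cur_names, lag_names)
  S <- stats::cov(data)
  structure(list(data = data, S = S, n_effective = nrow(data),
                 roi_labels = cur_names,
                 variables = c(cur_names, lag_names),
                 group_label = panel$group_label,
                 condition_label = panel$condition_label),
            class = "lagged_dataset")
}

#' Construct a lagged dataset directly from a covariance matrix
#'
#' Covariance-only entry point for model fitting when raw rows are not
#' available. `S` must be ordered current variables first, then their lag
#' copies.
#'
#' @param S `2R x 2R` covariance matrix.
#' @param n_effective Pooled row count behind `S`.
#' @param roi_labels The `R` region names.
#' @param group_label,condition_label Labels.
#' @return A `lagged_dataset` without a `data` component.
#' @export
lagged_dataset_from_cov <- function(S, n_effective, roi_labels,
                                    group_label = "group",
                                    condition_label = "condition") {
  R <- length(roi_labels)
  S <- as.matrix(S)
  if (!all(dim(S) == 2 * R)) stop("S must be ", 2 * R, " x ", 2 * R)
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  vars <- c(roi_labels, paste0("lag-", roi_labels))
  dimnames(S) <- list(vars, vars)
  structure(list(data = NULL, S = (S + t(S)) / 2,
                 n_effective = as.integer(n_effective),
                 roi_labels = as.character(roi_labels), variables = vars,
                 group_label = group_label, condition_label = condition_label),
            class = "lagged_dataset")
}

#' @export
print.lagged_dataset <- function(x, ...) {
  cat(sprintf(
    "Lagged uSEM dataset: %d ROIs (%s), %d variables, N_effective = %d\n",
    length(x$roi_labels), paste(x$roi_labels, collapse = ", "),
    length(x$variables), x$n_effective))
  cat(sprintf("group: %s, condition: %s\n", x$group_label, x$condition_label))
  invisible(x)
}

#' Write / read a lagged dataset as a directory (design TSV + metadata JSON)
#'
#' @param dataset A `lagged_dataset` with rows.
#' @param dir Directory (created if needed).
#' @return `read_lagged_dataset` returns the reconstructed dataset; the
#'   covariance is recomputed from the rows on read.
#' @export
write_lagged_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "lagged_dataset"))
  if (is.null(dataset$data))
    stop("dataset has no rows to write (covariance-only)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dataset$data, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(roi_labels = dataset$roi_labels,
               n_effective = dataset$n_effective,
               group_label = dataset$group_label,
               condition_label = dataset$condition_label)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_lagged_dataset
#' @export
read_lagged_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  data <- as.matrix(utils::read.table(file.path(dir, "design.tsv"),
                                      header = TRUE, sep = "\t",
                                      check.names = FALSE))
  vars <- c(meta$roi_labels, paste0("lag-", meta$roi_labels))
  data <- data[, vars, drop = FALSE]
  structure(list(data = data, S = stats::cov(data), n_effective = nrow(data),
                 roi_labels = meta$roi_labels, variables = vars,
                 group_label = meta$group_label,
                 condition_label = meta$condition_label),
            class = "lagged_dataset")
}
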