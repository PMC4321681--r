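#' Specify a generative unified-SEM time-series model
#'
#' A simulation specification describes a stationary multivariate process
#' with both contemporaneous and lag-1 directed effects,
#' \deqn{x_t = (I - B)^{-1} (\Phi x_{t-1} + e_t), \quad
#'       e_t \sim N(0, \mathrm{diag}(\sigma^2)),}
#' the generative counterpart of the unified SEM fitted by [usem()]. `B`
#' holds contemporaneous coefficients (zero diagonal), `Phi` lag-1
#' coefficients (its diagonal are the autoregressive effects), both in
#' row = target, column = source orientation.
#'
#' @param n_rois Number of regions `R`.
#' @param Phi `R x R` lag-1 coefficient matrix (row = target).
#' @param B `R x R` contemporaneous coefficient matrix; diagonal must be 0.
#' @param innovation_vars Length-`R` vector of positive innovation variances.
#' @param n_time Retained volumes per subject (`T`).
#' @param n_subjects Number of independent subjects to draw.
#' @param burn_in Initial samples discarded per subject so the retained
#'   series is effectively stationary. Default 50.
#' @param seed Integer seed; all randomness in [simulate_usem()] flows from it.
#' @param roi_labels Optional region names; defaults to `ROI1 ... ROIR`.
#'
#' @return An object of class `usem_sim_spec`.
#' @seealso [simulate_usem()], [stationary_covariance()]
#' @export
#' @examples
#' spec <- usem_sim_spec(2, Phi = diag(0.4, 2),
#'                       B = matrix(c(0, 0, 0.5, 0), 2, 2, byrow = TRUE),
#'                       n_time = 100, n_subjects = 3, seed = 1)
#' panel <- simulate_usem(spec)
usem_sim_spec <- function(n_rois, Phi = matrix(0, n_rois, n_rois),
                          B = matrix(0, n_rois, n_rois),
                          innovation_vars = rep(1, n_rois),
                          n_time = 150, n_subjects = 14, burn_in = 50,
                          seed = 1L, roi_labels = NULL) {
  n_rois <- as.integer(n_rois)
  Phi <- as.matrix(Phi)
  B <- as.matrix(B)
  if (is.null(roi_labels)) roi_labels <- paste0("ROI", seq_len(n_rois))
  spec <- structure(list(
    n_rois = n_rois, Phi = Phi, B = B,
    innovation_vars = as.numeric(innovation_vars),
    n_time = as.integer(n_time), n_subjects = as.integer(n_subjects),
    burn_in = as.integer(burn_in), seed = as.integer(seed),
    roi_labels = as.character(roi_labels)
  ), class = "usem_sim_spec")
  validate_sim_spec(spec)
  spec
}

validate_sim_spec <- function(spec) {
  R <- spec$n_rois
  if (!all(dim(spec$Phi) == c(R, R)))
    stop("Phi must be ", R, "x", R)
  if (!all(dim(spec$B) == c(R, R)))
    stop("B must be ", R, "x", R)
  if (any(diag(spec$B) != 0))
    stop("invariant violated: diagonal of B must be exactly zero")
  if (length(spec$innovation_vars) != R || any(spec$innovation_vars <= 0))
    stop("invariant violated: innovation_vars must be ", R, " positive values")
  if (length(spec$roi_labels) != R || anyDuplicated(spec$roi_labels))
    stop("roi_labels must be ", R, " unique names")
  ImB <- diag(R) - spec$B
  d <- det(ImB)
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("invariant violated: (I - B) is singular")
  A <- solve(ImB, spec$Phi)
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf(
      "invariant violated: spectral radius of (I-B)^-1 Phi is %.3f >= 1 (non-stationary)",
      rho))
  if (spec$n_time < 3) stop("n_time must be at least 3")
  invisible(spec)
}

#' Simulate a multi-subject ROI time-series panel
#'
#' Draws `n_subjects` independent realizations of the process in `spec`,
#' discarding the first `burn_in` samples of each. Output series are raw
#' (not standardized); apply [standardize_panel()] before [lag_embed()].
#'
#' @param spec A [usem_sim_spec()].
#' @return An object of class `roi_panel`: a list with `subjects` (list of
#'   `T x R` matrices), `roi_labels`, `group_label`, `condition_label`.
#' @param group_label,condition_label Labels attached to the panel.
#' @export
simulate_usem <- function(spec, group_label = "group", condition_label = "condition") {
  validate_sim_spec(spec)
  set.seed(spec$seed)
  R <- spec$n_rois
  ImB_inv <- solve(diag(R) - spec$B)
  A <- ImB_inv %*% spec$Phi
  sdv <- sqrt(spec$innovation_vars)
  total <- spec$burn_in + spec$n_time
  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    X <- matrix(0, total, R)
    x <- numeric(R)
    for (t in seq_len(total)) {
      e <- rnorm(R) * sdv
      x <- drop(A %*% x + ImB_inv %*% e)
      X[t, ] <- x
    }
    X <- X[(spec$burn_in + 1):total, , drop = FALSE]
    colnames(X) <- spec$roi_labels
    subjects[[s]] <- X
  }
  roi_panel(subjects, spec$roi_labels, group_label, condition_label)
}

#' Construct an ROI time-series panel
#'
#' @param subjects List of `T x R` numeric matrices (rows = volumes,
#'   columns = regions), all sharing column count and order.
#' @param roi_labels Character vector of `R` region names.
#' @param group_label,condition_label Labels, e.g. `"controls"`, `"Wins"`.
#' @return An object of class `roi_panel`.
#' @export
roi_panel <- function(subjects, roi_labels, group_label = "group",
                      condition_label = "condition") {
  if (!length(subjects)) stop("panel needs at least one subject")
  R <- length(roi_labels)
  for (s in seq_along(subjects)) {
    X <- as.matrix(subjects[[s]])
    if (ncol(X) != R)
      stop("subject ", s, " has ", ncol(X), " columns, expected ", R)
    if (nrow(X) < 3)
      stop("subject ", s, " has fewer than 3 volumes")
    if (anyNA(X)) stop("subject ", s, " contains missing values")
    colnames(X) <- roi_labels
    subjects[[s]] <- X
  }
  structure(list(subjects = subjects, roi_labels = as.character(roi_labels),
                 group_label = group_label, condition_label = condition_label),
            class = "roi_panel")
}

#' @export
print.roi_panel <- function(x, ...) {
  Ts <- vapply(x$subjects, nrow, integer(1))
  cat(sprintf("ROI time-series panel: %d subjects, %d ROIs (%s), T = %s\n",
              length(x$subjects), length(x$roi_labels),
              paste(x$roi_labels, collapse = ", "),
              if (length(unique(Ts)) == 1) Ts[1] else paste(range(Ts), collapse = "-")))
  cat(sprintf("group: %s, condition: %s\n", x$group_label, x$condition_label))
  invisible(x)
}

#' Stationary covariance implied by a simulation specification
#'
#' Solves the discrete-time Lyapunov equation
#' \eqn{\Sigma = A \Sigma A^\top + Q} for the reduced-form VAR
#' \eqn{A = (I-B)^{-1}\Phi} with innovation covariance
#' \eqn{Q = (I-B)^{-1} \mathrm{diag}(\sigma^2) (I-B)^{-\top}}. The sample
#' covariance of [simulate_usem()] output converges to this matrix as `T`
#' grows, which makes it the analytic oracle for the simulator.
#'
#' @param spec A [usem_sim_spec()]; must be stationary.
#' @return Symmetric positive-definite `R x R` matrix.
#' @export
stationary_covariance <- function(spec) {
  validate_sim_spec(spec)
  R <- spec$n_rois
  ImB_inv <- solve(diag(R) - spec$B)
  A <- ImB_inv %*% spec$Phi
  Q <- ImB_inv %*% diag(spec$innovation_vars, R) %*% t(ImB_inv)
  vecS <- solve(diag(R * R) - kronecker(A, A), as.vector(Q))
  S <- matrix(vecS, R, R)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(spec$roi_labels, spec$roi_labels)
  S
}

#' Standardize every series in a panel to mean 0, variance 1
#'
#' Applies [standardize_series()] per subject and per ROI (population
#' variance, denominator `N`), the normalization applied to extracted ROI
#' series before lag embedding.
#'
#' @param panel An `roi_panel`.
#' @return The panel with each column of each subject standardized.
#' @export
standardize_panel <- function(panel) {
  stopifnot(inherits(panel, "roi_panel"))
  panel$subjects <- lapply(panel$subjects, function(X) {
    for (j in seq_len(ncol(X)))
      X[, j] <- standardize_series(X[, j], label = colnames(X)[j])
    X
  })
  panel
}

#' Write / read a panel as per-subject TSV files
#'
#' Each subject is written as `subject<i>.tsv` (rows = volumes, columns =
#' ROI labels, header row) plus a `panel.json` holding labels.
#'
#' @param panel An `roi_panel`.
#' @param dir Directory (created if needed).
#' @return `write_panel` returns `dir` invisibly; `read_panel` the panel.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "roi_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_along(panel$subjects)) {
    f <- file.path(dir, sprintf("subject%03d.tsv", s))
    utils::write.table(panel$subjects[[s]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  meta <- list(roi_labels = panel$roi_labels, group_label = panel$group_label,
               condition_label = panel$condition_label,
               n_subjects = length(panel$subjects))
  jsonlite::write_json(meta, file.path(dir, "panel.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "panel.json"), simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^subject[0-9]+\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no subject TSV files in ", dir)
  subjects <- lapply(files, function(f) {
    X <- as.matrix(utils::read.table(f, header = TRUE, sep = "\t",
                                     check.names = FALSE))
    X[, meta$roi_labels, drop = FALSE]
  })
  roi_panel(subjects, meta$roi_labels, meta$group_label, meta$condition_label)
}

#' Serialize / deserialize a simulation specification as JSON
#'
#' @param spec A `usem_sim_spec`.
#' @param path File path.
#' @return `read_sim_spec` returns the reconstructed `usem_sim_spec`.
#' @export
write_sim_spec <- function(spec, path) {
  stopifnot(inherits(spec, "usem_sim_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_sim_spec
#' @export
read_sim_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  usem_sim_spec(x$n_rois, Phi = x$Phi, B = x$B,
                innovation_vars = x$innovation_vars, n_time = x$n_time,
                n_subjects = x$n_subjects, burn_in = x$burn_in,
                seed = x$seed, roi_labels = x$roi_labels)
}

#' Random planted-network specification for recovery experiments
#'
#' Draws a directed network of `n_conn` ROI-pair connections (no two-cycles:
#' each unordered pair is used at most once, with a random direction), gives
#' every connection both a contemporaneous and a longitudinal coefficient
#' drawn uniformly from `coef_range`, and adds autoregressive effects
#' `ar` on every ROI. Draws whose reduced-form VAR is non-stationary are
#' rejected and redrawn. The defaults mirror the recovery experiment used
#' throughout the package: 6 ROIs, 5 connections with coefficients in
#' 0.4-0.6, 14 subjects of 150 volumes.
#'
#' @param seed Integer seed driving both the structure draw and, via the
#'   returned spec, the series simulation.
#' @param n_rois,n_conn Network size.
#' @param coef_range Range of the planted cross coefficients.
#' @param ar Autoregressive coefficient shared by all ROIs.
#' @param n_time,n_subjects Panel dimensions.
#' @return List with `spec` (a [usem_sim_spec()]), and `from`, `to`
#'   (ROI labels of the planted ordered pairs).
#' @export
planted_network_spec <- function(seed, n_rois = 6, n_conn = 5,
                                 coef_range = c(0.4, 0.6), ar = 0.35,
                                 n_time = 150, n_subjects = 14) {
  set.seed(seed)
  pairs_all <- t(utils::combn(n_rois, 2))
  repeat {
    pick <- pairs_all[sample(nrow(pairs_all), n_conn), , drop = FALSE]
    flip <- sample(c(TRUE, FALSE), n_conn, replace = TRUE)
    from <- ifelse(flip, pick[, 2], pick[, 1])
    to <- ifelse(flip, pick[, 1], pick[, 2])
    B <- matrix(0, n_rois, n_rois)
    Phi <- diag(ar, n_rois)
    for (i in seq_len(n_conn)) {
      B[to[i], from[i]] <- stats::runif(1, coef_range[1], coef_range[2])
      Phi[to[i], from[i]] <- stats::runif(1, coef_range[1], coef_range[2])
    }
    spec <- tryCatch(
      usem_sim_spec(n_rois, Phi = Phi, B = B, n_time = n_time,
                    n_subjects = n_subjects, seed = seed),
      error = function(e) NULL)
    if (!is.null(spec)) break
  }
  labs <- spec$roi_labels
  list(spec = spec, from = labs[from], to = labs[to])
}
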