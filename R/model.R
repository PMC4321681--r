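#' Path models over current and lag variables
#'
#' A uSEM path model is a set of directed edges among the `2R` observed
#' variables (R current series plus their lag-1 copies). Three path kinds
#' exist:
#' \describe{
#'   \item{autoregressive}{`lag-X -> X`, obligatory from the null model on;}
#'   \item{contemporaneous}{`A -> B` between distinct current variables;}
#'   \item{longitudinal}{`lag-A -> B`, a delayed cross effect.}
#' }
#' Lag variables are exogenous copies: they never receive paths, and their
#' variances/covariances are free parameters. Every current variable keeps a
#' free residual variance.
#'
#' @param roi_labels Character vector of unique region names.
#' @param paths Optional `data.frame` with columns `src`, `dst`, `kind` to
#'   add on top of the autoregressive backbone.
#' @return An object of class `usem_model`.
#' @export
usem_model <- function(roi_labels, paths = NULL) {
  roi_labels <- as.character(roi_labels)
  if (anyDuplicated(roi_labels)) stop("duplicate ROI labels")
  if (!length(roi_labels)) stop("need at least one ROI")
  m <- structure(list(
    roi_labels = roi_labels,
    variables = c(roi_labels, paste0("lag-", roi_labels)),
    paths = data.frame(src = paste0("lag-", roi_labels), dst = roi_labels,
                       kind = "autoregressive", step = NA_integer_,
                       stringsAsFactors = FALSE)
  ), class = "usem_model")
  if (!is.null(paths))
    for (i in seq_len(nrow(paths)))
      m <- add_path(m, paths$src[i], paths$dst[i], paths$kind[i])
  m
}

#' The null model: autoregressive paths only
#'
#' The starting model of the exploratory search: all measured variables are
#' uncorrelated except that each lag variable is causally linked to its
#' non-lag variable.
#'
#' @param roi_labels Character vector of unique region names.
#' @return A `usem_model` with exactly `R` autoregressive paths and no cross
#'   paths.
#' @export
null_model <- function(roi_labels) usem_model(roi_labels)

#' The saturated (just-identified) comparison model
#'
#' Autoregressive paths, all longitudinal cross paths, and a complete
#' recursive set of contemporaneous paths (one direction per pair, following
#' ROI order). Its degrees of freedom are zero and it reproduces any
#' positive-definite sample covariance exactly (chi-square 0).
#'
#' @param roi_labels Character vector of unique region names.
#' @return A `usem_model`.
#' @export
saturated_model <- function(roi_labels) {
  m <- usem_model(roi_labels)
  R <- length(roi_labels)
  for (a in seq_len(R)) for (b in seq_len(R)) {
    if (a == b) next
    m <- add_path(m, paste0("lag-", roi_labels[a]), roi_labels[b], "longitudinal")
    if (a < b) m <- add_path(m, roi_labels[a], roi_labels[b], "contemporaneous")
  }
  m
}

path_kind <- function(model, src, dst) {
  lag <- startsWith(src, "lag-")
  if (lag && substring(src, 5) == dst) "autoregressive"
  else if (lag) "longitudinal"
  else "contemporaneous"
}

#' Add or remove a single directed path
#'
#' @param model A `usem_model`.
#' @param src,dst Variable names (`dst` must be a current variable; `src`
#'   a current variable for contemporaneous paths or a `lag-` variable).
#' @param kind Optional; inferred from the names when omitted.
#' @param step Search bookkeeping: the addition step, if any.
#' @return The modified model.
#' @export
add_path <- function(model, src, dst, kind = NULL, step = NA_integer_) {
  stopifnot(inherits(model, "usem_model"))
  if (!src %in% model$variables) stop("unknown source variable: ", src)
  if (!dst %in% model$roi_labels)
    stop("path target must be a current variable, got: ", dst)
  if (src == dst) stop("contemporaneous self-loop not allowed: ", src)
  inferred <- path_kind(model, src, dst)
  if (is.null(kind)) kind <- inferred
  else if (kind != inferred)
    stop("path ", src, " -> ", dst, " has kind ", inferred, ", not ", kind)
  if (any(model$paths$src == src & model$paths$dst == dst))
    stop("path already present: ", src, " -> ", dst)
  model$paths <- rbind(model$paths,
                       data.frame(src = src, dst = dst, kind = kind,
                                  step = as.integer(step),
                                  stringsAsFactors = FALSE))
  model
}

#' @rdname add_path
#' @export
remove_path <- function(model, src, dst) {
  stopifnot(inherits(model, "usem_model"))
  hit <- model$paths$src == src & model$paths$dst == dst
  if (!any(hit)) stop("path not in model: ", src, " -> ", dst)
  if (model$paths$kind[hit] == "autoregressive")
    stop("autoregressive paths cannot be removed: ", src, " -> ", dst)
  model$paths <- model$paths[!hit, , drop = FALSE]
  rownames(model$paths) <- NULL
  model
}

#' @rdname add_path
#' @export
has_path <- function(model, src, dst)
  any(model$paths$src == src & model$paths$dst == dst)

#' Add one ROI-pair connection (contemporaneous + longitudinal)
#'
#' The search's unit of growth: the ordered pair `from -> to` contributes
#' both `from -> to` (contemporaneous) and `lag-from -> to` (longitudinal).
#' Paths already present are left untouched.
#'
#' @param model A `usem_model`.
#' @param from,to ROI labels, distinct.
#' @param step Search step index recorded on the added paths.
#' @return The modified model.
#' @export
add_connection <- function(model, from, to, step = NA_integer_) {
  stopifnot(from %in% model$roi_labels, to %in% model$roi_labels, from != to)
  if (!has_path(model, from, to))
    model <- add_path(model, from, to, "contemporaneous", step = step)
  if (!has_path(model, paste0("lag-", from), to))
    model <- add_path(model, paste0("lag-", from), to, "longitudinal", step = step)
  model
}

#' Free parameters and degrees of freedom
#'
#' Free parameters: one coefficient per path, one residual variance per
#' current variable, and the `R(R+1)/2` exogenous (co)variances of the lag
#' block. Degrees of freedom are `p(p+1)/2 - q` with `p = 2R` observed
#' variables.
#'
#' @param model A `usem_model`.
#' @return Integer count.
#' @export
n_free_params <- function(model) {
  R <- length(model$roi_labels)
  nrow(model$paths) + R + R * (R + 1) / 2
}

#' @rdname n_free_params
#' @export
degrees_of_freedom <- function(model) {
  p <- 2L * length(model$roi_labels)
  df <- p * (p + 1) / 2 - n_free_params(model)
  if (df < 0)
    stop("model is over-parameterized (df = ", df, ")")
  as.integer(df)
}

#' @export
print.usem_model <- function(x, ...) {
  k <- table(factor(x$paths$kind,
                    c("autoregressive", "contemporaneous", "longitudinal")))
  cat(sprintf("uSEM path model: %d ROIs (%s)\n", length(x$roi_labels),
              paste(x$roi_labels, collapse = ", ")))
  cat(sprintf("paths: %d autoregressive, %d contemporaneous, %d longitudinal; df = %d\n",
              k[1], k[2], k[3], degrees_of_freedom(x)))
  cross <- x$paths[x$paths$kind != "autoregressive", , drop = FALSE]
  if (nrow(cross))
    cat(paste0("  ", cross$src, " -> ", cross$dst, " (", cross$kind, ")",
               collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize / deserialize a path model as JSON
#'
#' @param model A `usem_model`.
#' @param path File path.
#' @param provenance Optional named list stored under `options`.
#' @return `read_usem_model` returns the model.
#' @export
write_usem_model <- function(model, path, provenance = NULL) {
  stopifnot(inherits(model, "usem_model"))
  obj <- list(variables = model$variables, roi_labels = model$roi_labels,
              paths = model$paths[, c("src", "dst", "kind")],
              options = if (is.null(provenance)) list() else provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_usem_model
#' @export
read_usem_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- usem_model(obj$roi_labels)
  p <- obj$paths
  for (i in seq_len(nrow(p)))
    if (p$kind[i] != "autoregressive")
      m <- add_path(m, p$src[i], p$dst[i], p$kind[i])
  m
}
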