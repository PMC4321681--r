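#' Add the single best ROI-pair connection to a model
#'
#' One step of the exploratory search. Modification indices shortlist the
#' top `shortlist` ordered ROI pairs (summing the contemporaneous and
#' longitudinal index per pair); each shortlisted pair is then actually
#' added (both paths) and refit, and the pair realizing the lowest RMSEA
#' wins. Ties resolve to the lexicographically first `(from, to)` pair, so
#' the step is deterministic. If no candidate improves RMSEA the model is
#' returned unchanged with `stopped = TRUE`.
#'
#' @param model Current `usem_model`.
#' @param dataset A `lagged_dataset`.
#' @param fit Optional pre-computed fit of `model` (avoids a refit).
#' @param shortlist Number of MI-ranked pairs refit exactly (default 5).
#' @return List with `model`, `fit`, `stopped`, and `step` (a one-row
#'   record of the addition: pair, RMSEA before/after, top MI).
#' @export
add_best_connection <- function(model, dataset, fit = NULL, shortlist = 5) {
  if (is.null(fit)) fit <- usem(dataset, model)
  rmsea_old <- fit$rmsea
  mi <- modification_indices(fit)
  if (!nrow(mi))
    return(list(model = model, fit = fit, stopped = TRUE, step = NULL))

  # one score per ordered ROI pair: sum of its absent paths' indices
  from <- sub("^lag-", "", mi$src)
  key <- paste(from, mi$dst, sep = "\r")
  score <- tapply(mi$mi, key, sum)
  pairs <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
  ord <- order(-score, pairs[, 1], pairs[, 2])
  take <- utils::head(ord, shortlist)

  best <- NULL
  for (t in take) {
    cand_model <- add_connection(model, pairs[t, 1], pairs[t, 2])
    cand_fit <- tryCatch(usem(dataset, cand_model, baseline = FALSE),
                         error = function(e) NULL)
    if (is.null(cand_fit)) next      # e.g. addition would exhaust the df
    r <- cand_fit$rmsea
    if (is.na(r)) next
    if (is.null(best) || r < best$rmsea - 1e-12 ||
        (abs(r - best$rmsea) <= 1e-12 &&
         (pairs[t, 1] < best$from ||
          (pairs[t, 1] == best$from && pairs[t, 2] < best$to)))) {
      best <- list(from = pairs[t, 1], to = pairs[t, 2], rmsea = r,
                   model = cand_model, fit = cand_fit,
                   mi = unname(score[paste(pairs[t, 1], pairs[t, 2],
                                           sep = "\r")]))
    }
  }
  if (is.null(best) || !is.na(rmsea_old) && best$rmsea > rmsea_old + 1e-12)
    return(list(model = model, fit = fit, stopped = TRUE, step = NULL))

  step <- data.frame(from = best$from, to = best$to,
                     rmsea_before = rmsea_old, rmsea_after = best$rmsea,
                     mi = best$mi, stringsAsFactors = FALSE)
  best$fit$baseline <- fit$baseline
  best$fit$tli <- tryCatch(
    tli(best$fit$chisq, best$fit$df, fit$baseline$chisq, fit$baseline$df),
    error = function(e) NA_real_)
  list(model = best$model, fit = best$fit, stopped = FALSE, step = step)
}

#' Exploratory stepwise model search
#'
#' Data-driven model generation: starting from the null model
#' (autoregressive paths only), repeatedly add the ROI-pair connection
#' yielding the greatest RMSEA improvement ([add_best_connection()]) until
#' the fit enters the acceptable band (`RMSEA <= rmsea_target`, default
#' 0.08), no candidate improves the fit, or a step cap (3 connections per
#' ROI) is reached. The accepted model is then refined by parsimony pruning
#' ([prune_model()]): paths whose removal leaves RMSEA equal or lower are
#' dropped.
#'
#' @param dataset A `lagged_dataset`.
#' @param rmsea_target Upper edge of the acceptable RMSEA band (default
#'   0.08; the conventional band is 0.05-0.08).
#' @param max_steps Step cap; defaults to `3 * R` connections.
#' @param shortlist Passed to [add_best_connection()].
#' @param prune Apply the pruning pass (default `TRUE`).
#' @return An object of class `usem_search`: list with `model`, `fit`
#'   (final, after pruning), `trace` (`data.frame` of addition steps),
#'   `stop_reason` (`band_reached`, `no_candidate` or `max_steps`), and
#'   `pruned` (`data.frame` of removed paths).
#' @export
#' @examples
#' \donttest{
#' spec <- usem_sim_spec(3, Phi = diag(0.35, 3),
#'                       B = matrix(c(0, 0, 0, 0.5, 0, 0, 0, 0.5, 0),
#'                                  3, 3, byrow = TRUE),
#'                       n_time = 150, n_subjects = 14, seed = 11)
#' ld <- lag_embed(standardize_panel(simulate_usem(spec)))
#' sr <- usem_search(ld)
#' sr$fit
#' }
usem_search <- function(dataset, rmsea_target = 0.08, max_steps = NULL,
                        shortlist = 5, prune = TRUE) {
  stopifnot(inherits(dataset, "lagged_dataset"))
  R <- length(dataset$roi_labels)
  if (is.null(max_steps)) max_steps <- 3L * R
  model <- null_model(dataset$roi_labels)
  fit <- usem(dataset, model)
  trace <- NULL
  stop_reason <- "max_steps"
  if (!is.na(fit$rmsea) && fit$rmsea <= rmsea_target) {
    stop_reason <- "band_reached"
  } else {
    for (k in seq_len(max_steps)) {
      step <- add_best_connection(model, dataset, fit = fit,
                                  shortlist = shortlist)
      if (step$stopped) {
        stop_reason <- "no_candidate"
        break
      }
      model <- step$model
      fit <- step$fit
      trace <- rbind(trace, cbind(step = k, step$step))
      if (!is.na(fit$rmsea) && fit$rmsea <= rmsea_target) {
        stop_reason <- "band_reached"
        break
      }
    }
  }
  pruned <- data.frame(src = character(), dst = character(),
                       kind = character())
  if (prune) {
    pr <- prune_model(model, dataset, fit = fit)
    model <- pr$model
    fit <- pr$fit
    pruned <- pr$removed
  }
  structure(list(model = model, fit = fit,
                 trace = if (is.null(trace)) empty_trace() else trace,
                 stop_reason = stop_reason, pruned = pruned,
                 rmsea_target = rmsea_target),
            class = "usem_search")
}

empty_trace <- function() {
  data.frame(step = integer(), from = character(), to = character(),
             rmsea_before = numeric(), rmsea_after = numeric(),
             mi = numeric())
}

#' @export
print.usem_search <- function(x, ...) {
  cat(sprintf("Exploratory uSEM search: %d addition steps, stop reason: %s\n",
              nrow(x$trace), x$stop_reason))
  if (nrow(x$pruned))
    cat(sprintf("pruned %d path(s): %s\n", nrow(x$pruned),
                paste0(x$pruned$src, "->", x$pruned$dst, collapse = ", ")))
  print(x$fit)
  invisible(x)
}

#' Parsimony pruning of a fitted model
#'
#' Occam's-razor refinement: each non-autoregressive path is removed in
#' turn (reverse order of addition); a removal is kept whenever the refit
#' RMSEA is equal or lower than before. Passes repeat until no removal
#' helps, so the result is a fixed point (`prune(prune(m)) = prune(m)`).
#' Autoregressive paths are never candidates.
#'
#' @param model A `usem_model`.
#' @param dataset A `lagged_dataset`.
#' @param fit Optional pre-computed fit of `model`.
#' @param tol Slack on the RMSEA comparison (removals within `tol` of the
#'   current value count as "did not improve" and are accepted).
#' @return List with `model`, `fit`, and `removed` (a `data.frame` of
#'   removed paths in removal order).
#' @export
prune_model <- function(model, dataset, fit = NULL, tol = 1e-9) {
  if (is.null(fit)) fit <- usem(dataset, model)
  removed <- data.frame(src = character(), dst = character(),
                        kind = character(), stringsAsFactors = FALSE)
  repeat {
    cross <- model$paths[model$paths$kind != "autoregressive", , drop = FALSE]
    if (!nrow(cross)) break
    # reverse order of addition (later steps first); stable on row order
    ord <- order(-ifelse(is.na(cross$step), 0L, cross$step),
                 -seq_len(nrow(cross)))
    changed <- FALSE
    for (i in ord) {
      cand_model <- remove_path(model, cross$src[i], cross$dst[i])
      cand_fit <- usem(dataset, cand_model, baseline = FALSE)
      r_old <- if (is.na(fit$rmsea)) Inf else fit$rmsea
      r_new <- cand_fit$rmsea
      if (!is.na(r_new) && r_new <= r_old + tol) {
        removed <- rbind(removed, cross[i, c("src", "dst", "kind")])
        model <- cand_model
        fit <- cand_fit
        changed <- TRUE
        break  # path set changed; restart the pass
      }
    }
    if (!changed) break
  }
  # restore TLI baseline on the final fit
  fit <- usem(dataset, model)
  rownames(removed) <- NULL
  list(model = model, fit = fit, removed = removed)
}

#' Write a search trace as JSON
#'
#' @param search A `usem_search` result.
#' @param path Output file.
#' @param provenance Optional named list merged into the record.
#' @export
write_search_trace <- function(search, path, provenance = NULL) {
  obj <- c(list(steps = search$trace, stop_reason = search$stop_reason,
                pruned = search$pruned, rmsea_target = search$rmsea_target),
           if (is.null(provenance)) list() else provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
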