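# shared fixtures: small generative specs and their lagged datasets

# 3-ROI chain ROI1 -> ROI2 -> ROI3 (contemporaneous 0.5/0.4, AR 0.35)
chain3_spec <- function(seed = 42, n_time = 150, n_subjects = 14) {
  B <- matrix(0, 3, 3)
  B[2, 1] <- 0.5
  B[3, 2] <- 0.4
  usem_sim_spec(3, Phi = diag(0.35, 3), B = B, n_time = n_time,
                n_subjects = n_subjects, seed = seed)
}

# independent AR(1) ROIs (the null model's own generator)
independent_spec <- function(seed, n_rois = 3, n_time = 150, n_subjects = 14,
                             ar = 0.35) {
  usem_sim_spec(n_rois, Phi = diag(ar, n_rois), n_time = n_time,
                n_subjects = n_subjects, seed = seed)
}

sim_dataset <- function(spec) lag_embed(standardize_panel(simulate_usem(spec)))

# random recursive model + matching generator for the least-squares oracle:
# contemporaneous paths only run from lower to higher ROI index
random_recursive_case <- function(seed, n_rois) {
  set.seed(seed)
  B <- matrix(0, n_rois, n_rois)
  Phi <- diag(runif(n_rois, 0.2, 0.4), n_rois)
  model_paths <- list()
  for (a in seq_len(n_rois)) for (b in seq_len(n_rois)) {
    if (a == b) next
    if (a < b && runif(1) < 0.4) B[b, a] <- runif(1, 0.2, 0.5)
    if (runif(1) < 0.25) Phi[b, a] <- runif(1, 0.15, 0.35)
  }
  spec <- tryCatch(
    usem_sim_spec(n_rois, Phi = Phi, B = B, n_time = 300, n_subjects = 4,
                  seed = seed),
    error = function(e) NULL)
  if (is.null(spec)) return(random_recursive_case(seed + 1000, n_rois))
  labs <- spec$roi_labels
  model <- null_model(labs)
  for (a in seq_len(n_rois)) for (b in seq_len(n_rois)) {
    if (B[b, a] != 0) model <- add_path(model, labs[a], labs[b])
    if (a != b && Phi[b, a] != 0)
      model <- add_path(model, paste0("lag-", labs[a]), labs[b])
  }
  list(spec = spec, model = model)
}

# per-equation least squares on a covariance matrix: the independent oracle
# for ML estimates in recursive all-observed models
ols_oracle <- function(model, S) {
  vars <- model$variables
  out <- numeric(nrow(model$paths))
  for (i in seq_along(out)) {
    dst <- model$paths$dst[i]
    preds <- model$paths$src[model$paths$dst == dst]
    b <- solve(S[preds, preds, drop = FALSE], S[preds, dst])
    out[i] <- b[match(model$paths$src[i], preds)]
  }
  names(out) <- paste0(model$paths$src, "->", model$paths$dst)
  out
}

random_pd_matrix <- function(p, seed) {
  set.seed(seed)
  M <- matrix(rnorm(p * p), p)
  crossprod(M) / p + diag(p)
}
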