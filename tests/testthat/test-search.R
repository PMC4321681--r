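test_that("the single best connection is the true ordered pair", {
  # contemporaneous-only generator: ROI1 -> ROI2 at 0.5
  B <- matrix(0, 2, 2); B[2, 1] <- 0.5
  spec <- usem_sim_spec(2, Phi = diag(0.3, 2), B = B, n_time = 2000,
                        n_subjects = 1, seed = 81)
  ld <- sim_dataset(spec)
  step <- add_best_connection(null_model(ld$roi_labels), ld)
  expect_false(step$stopped)
  expect_equal(step$step$from, "ROI1")
  expect_equal(step$step$to, "ROI2")
  expect_lte(step$step$rmsea_after, step$step$rmsea_before)
  # both members of the pair were added
  expect_true(has_path(step$model, "ROI1", "ROI2"))
  expect_true(has_path(step$model, "lag-ROI1", "ROI2"))
})

test_that("a saturated model stops the step", {
  ld <- sim_dataset(chain3_spec(seed = 82, n_time = 60, n_subjects = 2))
  sat <- saturated_model(ld$roi_labels)
  step <- add_best_connection(sat, ld)
  expect_true(step$stopped)
  expect_identical(step$model$paths, sat$paths)
})

test_that("search recovers a planted network and stops in the band", {
  pn <- planted_network_spec(seed = 83, n_rois = 4, n_conn = 3)
  ld <- sim_dataset(pn$spec)
  sr <- usem_search(ld)
  expect_s3_class(sr, "usem_search")
  expect_lte(sr$fit$rmsea, 0.08)
  recovered <- sum(mapply(function(a, b)
    has_path(sr$model, a, b) || has_path(sr$model, paste0("lag-", a), b),
    pn$from, pn$to))
  expect_gte(recovered, 2)
  # trace invariants: RMSEA non-increasing, 2 df per added connection
  expect_true(all(diff(sr$trace$rmsea_after) <= 1e-12))
  expect_true(all(sr$trace$rmsea_after <= sr$trace$rmsea_before + 1e-12))
})

test_that("search is deterministic", {
  ld <- sim_dataset(chain3_spec(seed = 84, n_time = 100, n_subjects = 6))
  s1 <- usem_search(ld)
  s2 <- usem_search(ld)
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$model$paths, s2$model$paths)
  expect_identical(s1$pruned, s2$pruned)
})

test_that("null-generated data yields at most one false connection", {
  false_conns <- sapply(1:5, function(r) {
    ld <- sim_dataset(independent_spec(850 + r, n_rois = 3))
    sr <- usem_search(ld)
    p <- sr$model$paths
    length(unique(paste(sub("^lag-", "", p$src[p$kind != "autoregressive"]),
                        p$dst[p$kind != "autoregressive"])))
  })
  expect_true(all(false_conns <= 1))
})

test_that("independent ROIs start the search inside the band", {
  ld <- sim_dataset(independent_spec(86, n_rois = 2))
  sr <- usem_search(ld)
  expect_identical(sr$stop_reason, "band_reached")
  expect_equal(nrow(sr$trace), 0)
  expect_true(all(sr$model$paths$kind == "autoregressive"))
})

test_that("pruning removes spurious paths and is idempotent", {
  ld <- sim_dataset(independent_spec(87, n_rois = 3))
  m <- add_path(null_model(ld$roi_labels), "ROI1", "ROI2")
  pr <- prune_model(m, ld)
  expect_true(nrow(pr$removed) >= 1)
  expect_false(has_path(pr$model, "ROI1", "ROI2"))
  pr2 <- prune_model(pr$model, ld)
  expect_equal(nrow(pr2$removed), 0)
  expect_identical(pr2$model$paths, pr$model$paths)
})

test_that("strong true paths survive pruning", {
  B <- matrix(0, 2, 2); B[2, 1] <- 0.6
  Phi <- diag(0.3, 2); Phi[2, 1] <- 0.4
  spec <- usem_sim_spec(2, Phi = Phi, B = B, n_time = 2000, n_subjects = 1,
                        seed = 88)
  ld <- sim_dataset(spec)
  m <- add_connection(null_model(ld$roi_labels), "ROI1", "ROI2")
  pr <- prune_model(m, ld)
  expect_equal(nrow(pr$removed), 0)
  expect_true(has_path(pr$model, "ROI1", "ROI2"))
  expect_true(has_path(pr$model, "lag-ROI1", "ROI2"))
})

test_that("search traces serialize to JSON", {
  ld <- sim_dataset(chain3_spec(seed = 89, n_time = 80, n_subjects = 4))
  sr <- usem_search(ld)
  f <- withr::local_tempfile(fileext = ".json")
  write_search_trace(sr, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(back$stop_reason, sr$stop_reason)
  expect_equal(nrow(back$steps), nrow(sr$trace))
})
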