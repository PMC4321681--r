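# two groups sharing one generator (null difference) unless stated otherwise
make_two_groups <- function(seed, spec_fn = chain3_spec, ...) {
  list(a = sim_dataset(spec_fn(seed, ...)),
       b = sim_dataset(spec_fn(seed + 5000, ...)))
}

chain3_model <- function(labs)
  add_connection(add_connection(null_model(labs), "ROI1", "ROI2"),
                 "ROI2", "ROI3")

test_that("cross-fit re-estimates a fixed structure on the other group", {
  g <- make_two_groups(101)
  m <- chain3_model(g$a$roi_labels)
  own <- usem(g$a, m)
  other <- cross_fit(m, g$b)
  expect_s3_class(other, "usem")
  expect_identical(other$model$paths, m$paths)
  # identical generators at study scale: both fits inside the band
  expect_lte(own$rmsea, 0.08)
  expect_lte(other$rmsea, 0.08)
  # a saturated model cross-fits any group perfectly
  expect_equal(cross_fit(saturated_model(g$a$roi_labels), g$b)$chisq, 0,
               tolerance = 1e-6)
  bad <- sim_dataset(independent_spec(102, n_rois = 2))
  expect_error(cross_fit(m, bad), "labels")
})

test_that("own-group fit beats the cross-fit on average when groups differ", {
  deltas <- sapply(1:4, function(r) {
    B <- matrix(0, 3, 3); B[2, 1] <- 0.5
    spec_a <- usem_sim_spec(3, Phi = diag(0.35, 3), B = B,
                            n_subjects = 14, n_time = 150, seed = 110 + r)
    B2 <- matrix(0, 3, 3); B2[3, 1] <- 0.5   # different true wiring
    spec_b <- usem_sim_spec(3, Phi = diag(0.35, 3), B = B2,
                            n_subjects = 14, n_time = 150, seed = 120 + r)
    da <- sim_dataset(spec_a); db <- sim_dataset(spec_b)
    m <- add_connection(null_model(da$roi_labels), "ROI1", "ROI2")
    cross_fit(m, db)$rmsea - usem(da, m)$rmsea
  })
  expect_gt(mean(deltas), 0)
})

test_that("hybrid models take the union of path sets", {
  labs <- c("A", "B", "C")
  ma <- add_connection(null_model(labs), "A", "B")
  mb <- add_connection(add_connection(null_model(labs), "B", "C"), "A", "B")
  hy <- build_hybrid(ma, mb)
  cross <- hy$paths[hy$paths$kind != "autoregressive", ]
  expect_equal(nrow(cross), 4)
  expect_equal(sum(hy$paths$kind == "autoregressive"), 3)
  # idempotence
  expect_identical(build_hybrid(ma, ma)$paths[, 1:3], ma$paths[, 1:3])
  # disjoint cross sets add up
  mc <- add_path(null_model(labs), "C", "A")
  md <- add_path(add_path(null_model(labs), "B", "A"), "lag-C", "B")
  expect_equal(sum(build_hybrid(mc, md)$paths$kind != "autoregressive"), 3)
  expect_error(build_hybrid(ma, null_model(c("A", "B", "D"))), "ROI sets")
})

test_that("the hybrid fits each group at least as well as its own model", {
  g <- make_two_groups(131)
  ma <- usem_search(g$a)$model
  mb <- usem_search(g$b)$model
  hy <- build_hybrid(ma, mb)
  expect_lte(usem(g$a, hy)$fml, usem(g$a, ma)$fml + 1e-10)
  expect_lte(usem(g$b, hy)$fml, usem(g$b, mb)$fml + 1e-10)
})

test_that("unconstrained joint chi-square is the sum of separate fits", {
  g <- make_two_groups(141)
  m <- chain3_model(g$a$roi_labels)
  jf <- fit_joint(m, g$a, g$b)
  fa <- usem(g$a, m, baseline = FALSE)
  fb <- usem(g$b, m, baseline = FALSE)
  expect_equal(jf$chisq, fa$chisq + fb$chisq, tolerance = 1e-8)
  expect_equal(jf$n, g$a$n_effective + g$b$n_effective)
  p <- 6
  expect_equal(jf$df, 2 * p * (p + 1) / 2 - 2 * n_free_params(m))
  expect_error(fit_joint(m, g$a, g$b, constraints = "ROI3->ROI1"), "absent")
})

test_that("equality constraints cost chi-square but keep good joint fit", {
  g <- make_two_groups(151)
  m <- chain3_model(g$a$roi_labels)
  base <- fit_joint(m, g$a, g$b)
  ids <- paste0(m$paths$src, "->", m$paths$dst)
  all_con <- fit_joint(m, g$a, g$b, constraints = ids)
  expect_gte(all_con$chisq, base$chisq - 1e-8)
  expect_equal(all_con$df, base$df + length(ids))
  # identical generators: fully constrained joint fit stays in the band
  expect_lte(all_con$rmsea, 0.08)
  # constrained coefficients agree across groups
  expect_equal(all_con$estimates_a$coefficient,
               all_con$estimates_b$coefficient, tolerance = 1e-8)
})

test_that("per-path tests flag planted differences and respect alpha", {
  # groups differ in exactly one contemporaneous coefficient (0.5 vs 0.1)
  B_a <- matrix(0, 3, 3); B_a[2, 1] <- 0.5; B_a[3, 2] <- 0.4
  B_b <- B_a; B_b[2, 1] <- 0.1
  spec_a <- usem_sim_spec(3, Phi = diag(0.35, 3), B = B_a, n_time = 150,
                          n_subjects = 14, seed = 161)
  spec_b <- usem_sim_spec(3, Phi = diag(0.35, 3), B = B_b, n_time = 150,
                          n_subjects = 14, seed = 162)
  da <- sim_dataset(spec_a); db <- sim_dataset(spec_b)
  hy <- chain3_model(da$roi_labels)
  cmp <- compare_all_paths(hy, da, db)
  expect_s3_class(cmp, "usem_path_comparison")
  expect_equal(nrow(cmp), 4)   # 2 connections x 2 kinds, AR excluded
  expect_true(all(cmp$delta_chi2 >= 0))
  hit <- cmp$src == "ROI1" & cmp$dst == "ROI2" & cmp$kind == "contemporaneous"
  expect_true(cmp$flagged[hit])
  # alpha = 0 flags nothing
  cmp0 <- compare_all_paths(hy, da, db, alpha = 0)
  expect_false(any(cmp0$flagged))
  # swapping groups leaves the statistics unchanged
  cmp_swap <- compare_all_paths(hy, db, da)
  expect_equal(cmp_swap$delta_chi2, cmp$delta_chi2, tolerance = 1e-5)
  expect_equal(cmp_swap$p, cmp$p, tolerance = 1e-5)
  expect_equal(cmp_swap$coef_a, cmp$coef_b)
  # longitudinal paths are testable like contemporaneous ones
  expect_true(any(cmp$kind == "longitudinal"))
  expect_true(all(is.finite(cmp$p)))
})

test_that("comparisons write TSV and JSON summaries", {
  g <- make_two_groups(171, spec_fn = function(seed)
    chain3_spec(seed, n_time = 100, n_subjects = 4))
  hy <- chain3_model(g$a$roi_labels)
  cmp <- compare_all_paths(hy, g$a, g$b)
  d <- withr::local_tempdir()
  write_comparison(cmp, file.path(d, "paths.tsv"), file.path(d, "sum.json"))
  back <- read.delim(file.path(d, "paths.tsv"))
  expect_equal(nrow(back), nrow(cmp))
  s <- jsonlite::read_json(file.path(d, "sum.json"), simplifyVector = TRUE)
  expect_equal(s$n_paths, nrow(cmp))
})

test_that("row concatenation pools the two groups", {
  g <- make_two_groups(181, spec_fn = function(seed)
    chain3_spec(seed, n_time = 60, n_subjects = 2))
  pooled <- concat_datasets(g$a, g$b)
  expect_equal(pooled$n_effective, g$a$n_effective + g$b$n_effective)
  expect_equal(nrow(pooled$data), pooled$n_effective)
  f <- usem(pooled, chain3_model(pooled$roi_labels))
  expect_s3_class(f, "usem")
})
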