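test_that("implied covariance reproduces hand-traced path rules", {
  # no paths, Psi = I: identity
  m0 <- null_model(c("A", "B"))
  Sig <- implied_covariance(m0, coefficients = c(0, 0),
                            resid_vars = c(1, 1))
  expect_equal(unname(Sig), diag(4), tolerance = 1e-12)

  # single regression X = 0.5 lag-X + e: var(X) = 0.25 + 0.75 = 1,
  # cov(X, lag-X) = 0.5
  m1 <- null_model("X")
  Sig1 <- implied_covariance(m1, coefficients = 0.5, resid_vars = 0.75,
                             lag_cov = matrix(1))
  expect_equal(Sig1["X", "X"], 1)
  expect_equal(Sig1["X", "lag-X"], 0.5)
  expect_equal(Sig1["lag-X", "lag-X"], 1)

  # named coefficients are matched to paths
  m2 <- add_path(null_model(c("A", "B")), "A", "B")
  Sig2 <- implied_covariance(
    m2, coefficients = c("A->B" = 0.3, "lag-A->A" = 0, "lag-B->B" = 0),
    resid_vars = c(1, 1))
  expect_equal(Sig2["A", "B"], 0.3)
  expect_equal(Sig2["B", "B"], 1 + 0.3^2)
  expect_true(isSymmetric(Sig2))
})

test_that("F_ML is a proper discrepancy", {
  S <- random_pd_matrix(4, seed = 21)
  expect_equal(fml_discrepancy(S, S), 0)
  # hand evaluation: S = diag(2, 1) vs I gives 1 - ln 2
  expect_equal(fml_discrepancy(diag(c(2, 1)), diag(2)), 1 - log(2),
               tolerance = 1e-12)
  # strictly positive off the optimum
  for (seed in 1:5) {
    P <- random_pd_matrix(3, seed)
    expect_gt(fml_discrepancy(P, diag(3) * mean(diag(P))), 0)
  }
  expect_error(fml_discrepancy(matrix(c(1, 2, 2, 1), 2), diag(2)),
               "positive-definite")
})

test_that("saturated model fits any dataset perfectly", {
  ld <- sim_dataset(chain3_spec(seed = 23, n_time = 60, n_subjects = 2))
  f <- usem(ld, saturated_model(ld$roi_labels))
  expect_equal(f$chisq, 0, tolerance = 1e-6)
  expect_equal(f$df, 0)
  expect_equal(f$gfi, 1, tolerance = 1e-8)
  expect_equal(f$tli, 1)
  expect_equal(f$Sigma, f$S, tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("ML estimates equal per-equation least squares on recursive models", {
  for (seed in 1:4) {
    case <- random_recursive_case(seed * 7, n_rois = sample(3:6, 1))
    ld <- sim_dataset(case$spec)
    f <- usem(ld, case$model, baseline = FALSE)
    oracle <- ols_oracle(case$model, ld$S)
    expect_true(f$converged)
    expect_lt(max(abs(coef(f) - oracle)), 1e-5)
  }
})

test_that("parameters are recovered within sampling error at large T", {
  B <- matrix(0, 3, 3); B[2, 1] <- 0.5; B[3, 2] <- 0.4
  Phi <- diag(0.35, 3); Phi[3, 1] <- 0.25
  spec <- usem_sim_spec(3, Phi = Phi, B = B, n_time = 2000, n_subjects = 1,
                        seed = 29)
  ld <- sim_dataset(spec)
  labs <- ld$roi_labels
  model <- add_path(add_connection(add_connection(null_model(labs),
                                                  "ROI1", "ROI2"),
                                   "ROI2", "ROI3"),
                    "lag-ROI1", "ROI3")
  f <- usem(ld, model)
  # standardization rescales coefficients by sd ratios of the raw series
  sds <- sqrt(diag(stationary_covariance(spec)))
  truth <- c("ROI1->ROI2" = unname(B[2, 1] * sds[1] / sds[2]),
             "ROI2->ROI3" = unname(B[3, 2] * sds[2] / sds[3]),
             "lag-ROI1->ROI3" = unname(Phi[3, 1] * sds[1] / sds[3]),
             "lag-ROI1->ROI1" = 0.35, "lag-ROI2->ROI2" = 0.35,
             "lag-ROI3->ROI3" = 0.35)
  est <- coef(f)[names(truth)]
  se_bound <- 3 / sqrt(ld$n_effective) * 2  # generous 3-SE envelope
  expect_true(all(abs(est - truth) < se_bound))
})

test_that("adding a free path never increases the optimal discrepancy", {
  ld <- sim_dataset(chain3_spec(seed = 31, n_time = 80, n_subjects = 3))
  m <- null_model(ld$roi_labels)
  f <- usem(ld, m, baseline = FALSE)
  for (step in list(c("ROI1", "ROI2"), c("ROI3", "ROI1"), c("ROI2", "ROI3"))) {
    m <- add_path(m, step[1], step[2])
    f2 <- usem(ld, m, baseline = FALSE)
    expect_lte(f2$fml, f$fml + 1e-10)
    f <- f2
  }
})

test_that("estimated exogenous variances sit near 1 on standardized data", {
  ld <- sim_dataset(chain3_spec(seed = 37))
  f <- usem(ld, add_connection(null_model(ld$roi_labels), "ROI1", "ROI2"))
  expect_true(all(abs(diag(f$psi_lag) - 1) < 0.05))
})

test_that("jittered restarts reach the same optimum", {
  ld <- sim_dataset(chain3_spec(seed = 41, n_time = 100, n_subjects = 4))
  model <- add_connection(add_connection(null_model(ld$roi_labels),
                                         "ROI1", "ROI2"), "ROI2", "ROI3")
  f <- usem(ld, model, baseline = FALSE)
  set.seed(1)
  for (i in 1:3) {
    st <- list(beta = rnorm(nrow(model$paths), sd = 0.2),
               psi = exp(rnorm(3, sd = 0.3)))
    fj <- usem(ld, model, baseline = FALSE, start = st)
    expect_lt(abs(fj$fml - f$fml), 1e-6)
  }
})

test_that("degenerate covariance input is refused", {
  ld <- sim_dataset(chain3_spec(seed = 43, n_time = 50, n_subjects = 1))
  ld$S[, ] <- tcrossprod(ld$S[, 1])  # rank 1
  expect_error(usem(ld), "condition number|positive-definite")
  ld2 <- sim_dataset(independent_spec(44, n_rois = 2, n_time = 30,
                                      n_subjects = 1))
  expect_error(usem(ld2, null_model(c("ROI1", "OTHER"))), "labels")
})

test_that("fit methods expose the standard modelling interface", {
  ld <- sim_dataset(chain3_spec(seed = 47, n_time = 80, n_subjects = 4))
  f <- usem(ld, add_connection(null_model(ld$roi_labels), "ROI1", "ROI2"))
  expect_named(coef(f))
  expect_equal(fitted(f), f$Sigma)
  expect_equal(residuals(f), f$S - f$Sigma)
  expect_equal(dim(residuals(f)), c(6, 6))
  expect_s3_class(fit_indices(f), "data.frame")
  expect_identical(names(fit_indices(f)),
                   c("RMSEA", "Chi_square", "dof", "TLI", "GFI"))
  expect_output(print(summary(f)), "Path coefficients")
  # simulate() round-trips through the generative form deterministically
  p1 <- simulate(f, seed = 5, n_time = 20, n_subjects = 2)
  p2 <- simulate(f, seed = 5, n_time = 20, n_subjects = 2)
  expect_identical(p1$subjects, p2$subjects)
  expect_s3_class(p1, "roi_panel")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
  f2 <- usem(ld)
  expect_s3_class(logLik(f), "logLik")
  expect_gt(as.numeric(logLik(f)), as.numeric(logLik(f2)))
})
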