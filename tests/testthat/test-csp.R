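test_that("normalized covariance has unit trace and matches direct arithmetic", {
  withr::local_seed(1)
  x <- matrix(rnorm(2 * 100), 2)
  C <- normalized_covariance(x)
  expect_equal(sum(diag(C)), 1, tolerance = 1e-12)
  expect_true(isSymmetric(C))

  expect_equal(normalized_covariance(matrix(3.2, 1, 5)), matrix(1, 1, 1))

  # fixed 2x4 integer matrix, hand-computed XX'/trace
  x <- matrix(c(1, 0, 2, 1, 3, 0, 4, 1), 2)
  expect_equal(normalized_covariance(x),
               matrix(c(30, 6, 6, 2), 2) / 32)

  expect_error(normalized_covariance(matrix(0, 2, 4)),
               class = "tfbcsp_degenerate_trial")
})

test_that("identical class covariances give no discriminative direction", {
  C <- random_spd(4)
  model <- csp_from_covariances(C, C, m = 1)
  expect_equal(model$lambda_left, rep(0.5, 4), tolerance = 1e-8)
})

test_that("axis-aligned class covariances recover axis-aligned filters", {
  model <- csp_from_covariances(diag(c(9, 1)) / 10, diag(c(1, 9)) / 10, m = 1)
  expect_equal(model$lambda_left, c(0.9, 0.1), tolerance = 1e-10)
  # extremal rows align with the coordinate axes
  W <- model$W
  expect_lt(abs(W[1, 2]) / abs(W[1, 1]), 1e-8)
  expect_lt(abs(W[2, 1]) / abs(W[2, 2]), 1e-8)
})

test_that("whitening and complementarity identities hold on random problems", {
  withr::local_seed(2)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    C1 <- random_spd(n); C2 <- random_spd(n)
    model <- csp_from_covariances(C1, C2, m = 1)
    P <- model$diagnostics$P
    Cc <- C1 + C2
    expect_equal(P %*% Cc %*% t(P), diag(n), tolerance = 1e-8)
    S <- model$diagnostics$S
    expect_equal(S[[1]] + S[[2]], diag(n), tolerance = 1e-8)
    expect_equal(model$lambda_left + model$lambda_right, rep(1, n),
                 tolerance = 1e-10)
    # W jointly diagonalizes both class covariances
    expect_equal(model$W %*% Cc %*% t(model$W), diag(n), tolerance = 1e-8)
    D1 <- model$W %*% C1 %*% t(model$W)
    expect_equal(D1, diag(model$lambda_left), tolerance = 1e-8)
  }
})

test_that("whitening route agrees with a direct generalized eigensolver", {
  withr::local_seed(3)
  for (i in 1:15) {
    n <- sample(3:6, 1)
    C1 <- random_spd(n); C2 <- random_spd(n)
    model <- csp_from_covariances(C1, C2, m = 1)
    # oracle: eigenpairs of Cc^{-1} C1 solved directly
    ge <- eigen(solve(C1 + C2) %*% C1)
    ord <- order(Re(ge$values), decreasing = TRUE)
    expect_equal(model$lambda_left, Re(ge$values)[ord], tolerance = 1e-8)
    for (r in seq_len(n)) {
      v <- Re(ge$vectors[, ord[r]])
      w <- model$W[r, ]
      cosang <- abs(sum(v * w)) / sqrt(sum(v^2) * sum(w^2))
      expect_equal(cosang, 1, tolerance = 1e-6)
    }
  }
})

test_that("fitting on epochs validates labels and honors m", {
  ep <- tiny_epochs(n_per_class = 8, channels = 3, samples = 300)
  model <- fit_csp(ep, m = 1)
  expect_s3_class(model, "csp_model")
  expect_equal(model$selected_rows, c(1, 3))
  # the class with inflated channel-1 variance loads on an extremal filter
  expect_gt(max(model$lambda_left), 0.6)

  single <- subset_trials(ep, which(ep$labels == "left"))
  expect_error(fit_csp(single, m = 1), class = "tfbcsp_invalid_labels")
  expect_error(fit_csp(ep, m = 5), class = "tfbcsp_invalid_parameter")
})

test_that("22-channel fit with m = 7 yields 14 features per trial", {
  withr::local_seed(4)
  ep <- epoch_set(array(rnorm(12 * 22 * 120), c(12, 22, 120)),
                  rep(c("L", "R"), 6), 250)
  model <- fit_csp(ep, m = 7)
  expect_length(model$selected_rows, 14)
  expect_length(logvar_features(model, trial_matrix_for_test(ep, 1)), 14)
})

test_that("first/last-row duplication is kept when 2m exceeds the channels", {
  withr::local_seed(5)
  ep <- epoch_set(array(rnorm(8 * 3 * 100), c(8, 3, 100)),
                  rep(c("L", "R"), 4), 250)
  m3 <- fit_csp(ep, m = 3)
  expect_equal(m3$selected_rows, c(1, 2, 3, 1, 2, 3))
  dedup <- fit_csp(ep, m = 3, dedupe_components = TRUE)
  expect_equal(dedup$selected_rows, c(1, 2, 3))
})

test_that("log-variance features are normalized, negative, and scale-free", {
  ep <- tiny_epochs(n_per_class = 6, channels = 4, samples = 400)
  model <- fit_csp(ep, m = 2)
  x <- trial_matrix_for_test(ep, 1)
  f <- logvar_features(model, x)
  expect_length(f, 4)
  expect_true(all(f <= 0))
  expect_equal(sum(exp(f)), 1, tolerance = 1e-12)
  expect_equal(logvar_features(model, 17.3 * x), f, tolerance = 1e-10)

  # direct evaluation of the normalized log variance for variances (3, 1):
  # axis-aligned covariances make W the identity, and the trial below has
  # population variances exactly 3 and 1
  axis_model <- csp_from_covariances(diag(c(0.9, 0.1)), diag(c(0.1, 0.9)), m = 1)
  trial31 <- rbind(sqrt(3) * c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(logvar_features(axis_model, trial31),
               c(log(0.75), log(0.25)), tolerance = 1e-12)

  # two selected components with equal variance split the log evenly
  trial11 <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(logvar_features(axis_model, trial11), rep(log(0.5), 2),
               tolerance = 1e-12)

  expect_error(logvar_features(model, matrix(0, 4, 10)),
               class = "tfbcsp_degenerate_trial")
  expect_error(logvar_features(model, matrix(1, 3, 10)),
               class = "tfbcsp_contract_error")
})
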