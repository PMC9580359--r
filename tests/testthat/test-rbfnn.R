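test_that("the Gaussian kernel has its closed-form landmarks", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 3), 1)
  # distance sigma * sqrt(2) gives exp(-1)
  sigma <- 1.7
  x <- c(0, 0); ctr <- c(sigma * sqrt(2), 0)
  expect_equal(rbf_kernel(x, ctr, sigma), exp(-1), tolerance = 1e-12)
  # symmetry and direct arithmetic on a random 5-dim pair
  withr::local_seed(1)
  a <- rnorm(5); b <- rnorm(5)
  expect_equal(rbf_kernel(a, b, 2), rbf_kernel(b, a, 2))
  expect_equal(rbf_kernel(a, b, 2), exp(-sum((a - b)^2) / 8), tolerance = 1e-14)
  expect_error(rbf_kernel(a, b, 0), class = "tfbcsp_invalid_parameter")
  expect_error(rbf_kernel(a, b[1:3], 2), class = "tfbcsp_contract_error")
})

test_that("exact design interpolates its training labels", {
  # defining property of the exact-design network: every training sample is
  # a center and the linear layer solves the interpolation system. Tested in
  # the spread regime where the Gaussian design is numerically
  # well-conditioned (wider kernels flatten the design; see vignette).
  withr::local_seed(2)
  for (i in 1:50) {
    n <- sample(6:40, 1); d <- sample(2:8, 1)
    x <- matrix(rnorm(n * d), n)
    y <- sample(c("L", "R"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- setdiff(c("L", "R"), y[1])
    net <- fit_rbfnn(x, y, spread = runif(1, 0.5, 1.5))
    expect_identical(predict(net, x), y)
  }
})

test_that("four-point exact design solves the documented linear system", {
  x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  y <- c("p", "p", "n", "n")
  net <- fit_rbfnn(x, y, spread = 1)
  expect_identical(predict(net, x), y)
  # direct linear-solve oracle on the 4x5 system in the scaled space;
  # the first sorted class ("n") carries the +1 coding
  Xs <- sweep(sweep(x, 2, net$scaler$center), 2, net$scaler$scale, "/")
  Phi <- exp(-as.matrix(dist(Xs))^2 / 2)
  resid <- cbind(Phi, 1) %*% c(net$weights, net$bias) - c(-1, -1, 1, 1)
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("scores equal the brute-force radial-basis summation", {
  withr::local_seed(3)
  for (sp in c(0.8, 16)) {
    for (mode in c("literal", "matlab")) {
      x <- matrix(rnorm(12 * 4), 12)
      y <- rep(c("a", "b"), 6)
      net <- fit_rbfnn(x, y, spread = sp, sigma_mode = mode)
      q <- rnorm(4)
      expect_equal(predict(net, matrix(q, 1), type = "score"),
                   brute_force_score(net, q), tolerance = 1e-10)
    }
  }
})

test_that("interpolation at a center returns its own label; ties go positive", {
  x <- matrix(c(1, -1, 0, 0), 2, 2)
  net <- fit_rbfnn(x, c("A", "B"), spread = 1)
  expect_identical(predict(net, matrix(c(1, 0), 1)), "A")
  # symmetric centers, equidistant query: score cancels to ~0 -> positive class
  q <- matrix(c(0, 0), 1)
  expect_lt(abs(predict(net, q, type = "score")), 1e-10)
  expect_identical(predict(net, q), "A")
})

test_that("prediction is invariant to training sample order", {
  withr::local_seed(4)
  x <- matrix(rnorm(20 * 3), 20)
  y <- rep(c("L", "R"), 10)
  q <- matrix(rnorm(5 * 3), 5)
  net <- fit_rbfnn(x, y, spread = 1)
  perm <- sample(20)
  net2 <- fit_rbfnn(x[perm, ], y[perm], spread = 1)
  expect_equal(predict(net, q, type = "score"),
               predict(net2, q, type = "score"), tolerance = 1e-6)
})

test_that("spread limits behave as kernel width predicts", {
  withr::local_seed(5)
  x <- rbind(matrix(rnorm(10, -2, 0.3), 5, 2), matrix(rnorm(10, 2, 0.3), 5, 2))
  y <- rep(c("L", "R"), each = 5)
  q <- matrix(c(-1.8, -1.9), 1)
  # narrow kernels approach 1-nearest-neighbor on the centers
  tiny <- fit_rbfnn(x, y, spread = 0.05)
  expect_identical(predict(tiny, q), "L")
  # very wide kernels flatten the hidden-layer responses toward 1, and the
  # interpolation weights blow up as the design degenerates
  wide <- fit_rbfnn(x, y, spread = 0.5)
  wider <- fit_rbfnn(x, y, spread = 500)
  phi_range <- function(net) {
    D2 <- as.matrix(dist(net$centers))^2
    diff(range(exp(-D2 / (2 * net$spread^2))))
  }
  expect_lt(phi_range(wider), 1e-3)
  expect_gt(phi_range(wide), 0.5)
  expect_gt(sqrt(sum(wider$weights^2)) / sqrt(sum(wide$weights^2)), 1e3)
})

test_that("degenerate inputs are handled as documented", {
  x <- matrix(c(1, 1, 2, 2, 1, 1, 2, 2), 4, 2)  # duplicated rows
  expect_warning(fit_rbfnn(x, c("a", "a", "b", "b"), spread = 1),
                 "duplicate")
  expect_error(fit_rbfnn(matrix(rnorm(8), 4), rep("a", 4)),
               class = "tfbcsp_invalid_labels")
  net <- fit_rbfnn(matrix(rnorm(8), 4), c("a", "b", "a", "b"), spread = 1)
  expect_error(predict(net, matrix(1, 1, 5)), class = "tfbcsp_contract_error")
  # constant feature columns get unit scale instead of dividing by zero
  xc <- cbind(rnorm(6), 3)
  net2 <- fit_rbfnn(xc, rep(c("a", "b"), 3), spread = 1)
  expect_true(all(is.finite(predict(net2, xc, type = "score"))))
  expect_identical(net2$scaler$scale[2], 1)
})

test_that("the default spread is 16", {
  withr::local_seed(6)
  net <- fit_rbfnn(matrix(rnorm(12), 6), rep(c("a", "b"), 3))
  expect_equal(net$spread, 16)
})
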