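# Fixtures built in code: tiny epoch sets, random SPD matrices, and a
# brute-force RBF score used as an independent oracle.

# White-noise epochs where the two classes differ in the variance of one
# channel: the simplest CSP-separable construction.
tiny_epochs <- function(n_per_class = 6, channels = 3, samples = 200,
                        fs = 100, seed = 1, gain = 3, varying_channel = 1) {
  withr::local_seed(seed)
  n <- 2 * n_per_class
  dat <- array(rnorm(n * channels * samples), dim = c(n, channels, samples))
  labels <- rep(c("left", "right"), each = n_per_class)
  dat[labels == "right", varying_channel, ] <-
    gain * dat[labels == "right", varying_channel, ]
  epoch_set(dat, labels, fs)
}

# channels x samples matrix of one trial (the container stores 3-d arrays).
trial_matrix_for_test <- function(ep, i) {
  m <- ep$data[i, , , drop = FALSE]
  dim(m) <- dim(ep$data)[2:3]
  m
}

# Random symmetric positive definite matrix with unit trace.
random_spd <- function(n) {
  a <- matrix(rnorm(n * (n + 4)), n)
  s <- tcrossprod(a) / (n + 4) + diag(0.05, n)
  s / sum(diag(s))
}

# Independent oracle for the RBF network score: term-by-term summation of
# the weighted Gaussian responses plus bias, via rbf_kernel on scaled input.
brute_force_score <- function(net, x) {
  xs <- (x - net$scaler$center) / net$scaler$scale
  sigma <- if (net$sigma_mode == "literal") net$spread else
    net$spread / (0.8326 * sqrt(2))
  s <- net$bias
  for (i in seq_len(net$k)) {
    s <- s + net$weights[i] * rbf_kernel(xs, net$centers[i, ], sigma)
  }
  s
}

# Evaluate an expression under a fixed seed without disturbing the suite's
# RNG stream.
with_seed_for_test <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Exhaustive subset enumeration: argmax of `scorer` over all nonempty
# subsets of `cells`.
best_subset_by_enumeration <- function(cells, scorer) {
  best <- -Inf
  best_s <- NULL
  for (k in seq_along(cells)) {
    combs <- utils::combn(cells, k, simplify = FALSE)
    for (s in combs) {
      v <- scorer(s)
      if (v > best) {
        best <- v
        best_s <- s
      }
    }
  }
  list(subset = best_s, score = best)
}
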