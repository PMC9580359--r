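# Exact-design radial basis function network: one Gaussian hidden unit per
# training sample, linear output layer (weights + bias) solved by least
# squares in the +/-1 label coding.

#' Gaussian radial basis kernel
#'
#' `exp(-||x - c||^2 / (2 sigma^2))`: 1 at zero distance, strictly
#' decreasing in the distance, symmetric in its two arguments.
#'
#' @param x,c feature vectors of equal length.
#' @param sigma Gaussian standard deviation (> 0).
#' @return Kernel value in (0, 1].
#' @export
rbf_kernel <- function(x, c, sigma) {
  if (length(x) != length(c)) {
    tfb_stop("x and c must have equal dimension", "tfbcsp_contract_error")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    tfb_stop("sigma must be a positive number", "tfbcsp_invalid_parameter")
  }
  exp(-sum((x - c)^2) / (2 * sigma^2))
}

# Cross kernel matrix between row sets X (n x d) and C (k x d).
# sigma_mode "literal": sigma_i = spread for every unit.
# sigma_mode "matlab": half-response at distance == spread,
#   f = exp(-(0.8326 d / spread)^2), the newrbe convention.
kernel_matrix <- function(X, C, spread, sigma_mode) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  d2[d2 < 0] <- 0
  if (sigma_mode == "literal") {
    exp(-d2 / (2 * spread^2))
  } else {
    exp(-(0.8326^2) * d2 / spread^2)
  }
}

#' Fit an exact-design RBF network classifier
#'
#' Features are z-scored with statistics of the training set; every scaled
#' training sample becomes a Gaussian center (`k = n` hidden units, the
#' exact design); the output weights and bias solve the linear system
#' `[Phi | 1] [w; b] = y` in the +/-1 label coding by minimum-norm least
#' squares. For distinct training points the system is consistent and the
#' network reproduces its training labels. Duplicate rows make the design
#' singular; the least-squares solution is still returned, with a warning.
#'
#' @param x training feature matrix (n x d).
#' @param y training labels, exactly two classes, both present.
#' @param spread width hyperparameter of the Gaussian units (default 16).
#' @param sigma_mode `"literal"` (sigma = spread in the kernel exponent) or
#'   `"matlab"` (half response at distance = spread, the `newrbe`
#'   convention).
#' @return An object of class `rbfnn` with centers, weights, bias, spread,
#'   the feature scaler, and the class-to-sign map (first sorted class is
#'   coded +1).
#' @examples
#' x <- matrix(rnorm(20), 10, 2)
#' y <- rep(c("L", "R"), 5)
#' net <- fit_rbfnn(x, y, spread = 1)
#' all(predict(net, x) == y)
#' @export
fit_rbfnn <- function(x, y, spread = 16,
                      sigma_mode = c("literal", "matlab")) {
  sigma_mode <- match.arg(sigma_mode)
  x <- as.matrix(x)
  if (nrow(x) < 2L) tfb_stop("need at least 2 training samples",
                             "tfbcsp_invalid_data")
  if (length(y) != nrow(x)) tfb_stop("labels length must match rows of x",
                                     "tfbcsp_invalid_data")
  if (!is.numeric(spread) || spread <= 0) {
    tfb_stop("spread must be positive", "tfbcsp_invalid_parameter")
  }
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L) {
    tfb_stop("training labels must contain exactly two classes",
             "tfbcsp_invalid_labels")
  }
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1  # constant features pass through
  Xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  if (anyDuplicated(Xs)) {
    warning("duplicate training rows: design matrix is singular, ",
            "solving in the least-squares sense")
  }
  ysign <- ifelse(y == classes[1], 1, -1)
  Phi <- kernel_matrix(Xs, Xs, spread, sigma_mode)
  coef <- lstsq_minnorm(cbind(Phi, 1), ysign)
  k <- nrow(Xs)
  structure(
    list(centers = Xs, weights = coef[seq_len(k)], bias = coef[k + 1],
         spread = spread, sigma_mode = sigma_mode, k = k,
         scaler = list(center = center, scale = scl),
         classes = classes),
    class = "rbfnn"
  )
}

#' Predict with an exact-design RBF network
#'
#' Scores are `F(x) = sum_i w_i f_i(x, c_i) + b` on the scaled input; the
#' predicted class is the sign of the score, with a score of exactly 0
#' mapped to the positive (first sorted) class.
#'
#' @param object an `rbfnn` from [fit_rbfnn()].
#' @param newdata feature matrix with the fitted dimensionality.
#' @param type `"class"` (default) for labels or `"score"` for raw `F(x)`.
#' @param ... unused.
#' @return Character vector of labels, or numeric scores.
#' @export
predict.rbfnn <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$centers)) {
    tfb_stop("feature dimension does not match the fitted network",
             "tfbcsp_contract_error")
  }
  Xs <- sweep(sweep(newdata, 2, object$scaler$center), 2, object$scaler$scale, "/")
  K <- kernel_matrix(Xs, object$centers, object$spread, object$sigma_mode)
  score <- drop(K %*% object$weights) + object$bias
  if (type == "score") return(score)
  ifelse(score >= 0, object$classes[1], object$classes[2])
}

#' @export
print.rbfnn <- function(x, ...) {
  cat(sprintf("<rbfnn> %d centers, %d features, spread %g (%s), classes %s/%s\n",
              x$k, ncol(x$centers), x$spread, x$sigma_mode,
              x$classes[1], x$classes[2]))
  invisible(x)
}
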