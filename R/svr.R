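#' ANOVA kernel specification
#'
#' The ANOVA kernel is a radial-basis-type similarity: a power `d` of a
#' sum of per-coordinate Gaussian similarities,
#' `K(x, y) = (sum_i exp(-gamma (x_i - y_i)^2))^d`. It is symmetric, takes
#' values in `(0, p^d]` for vectors of length `p`, and is positive
#' semidefinite for `d = 1` (a sum of univariate Gaussian kernels).
#'
#' @param gamma Kernel width parameter, > 0.
#' @param d Integer power, >= 1.
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(gamma, d = 1L) {
  stopifnot(gamma > 0, d >= 1)
  structure(list(gamma = gamma, d = as.integer(d)), class = "kernel_spec")
}

#' Evaluate the ANOVA kernel for one pair of feature vectors
#'
#' @param x,y Numeric vectors of equal length with finite entries.
#' @param spec A [kernel_spec()].
#' @return The scalar kernel value.
#' @export
#' @examples
#' anova_kernel(0, 1, kernel_spec(gamma = 1))  # exp(-1)
anova_kernel <- function(x, y, spec) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  sum(exp(-spec$gamma * (x - y)^2))^spec$d
}

#' ANOVA-kernel Gram matrix
#'
#' @param X Numeric matrix, samples in rows.
#' @param spec A [kernel_spec()].
#' @param Y Optional second matrix with the same columns; when given the
#'   cross-kernel matrix `K[i, j] = K(X[i, ], Y[j, ])` is returned.
#' @return An `nrow(X) x nrow(Y %||% X)` kernel matrix; symmetric with
#'   diagonal `p^d` when `Y` is absent.
#' @export
gram_matrix <- function(X, spec, Y = NULL) {
  X <- as.matrix(X)
  if (is.null(Y)) Y <- X else Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) {
    stop("X and Y must have the same number of features", call. = FALSE)
  }
  K <- matrix(0, nrow(X), nrow(Y))
  for (f in seq_len(ncol(X))) {
    K <- K + exp(-spec$gamma * outer(X[, f], Y[, f], "-")^2)
  }
  K^spec$d
}

#' Support-vector regression configuration
#'
#' The emulated study prints no SVM hyperparameters; these frozen
#' defaults favor reproducibility: `C = 10`, `epsilon = 0.1` (on the LNC
#' mass-percent scale), kernel power `d = 1`, `gamma = 1/p` with `p` the
#' number of features, and per-feature standardization with statistics
#' taken from the training rows only.
#'
#' @param C Regularization constant, > 0.
#' @param epsilon Half-width of the insensitive tube, >= 0.
#' @param gamma Kernel gamma, or `NULL` for the `1/p` default.
#' @param d Kernel power.
#' @param standardize Standardize features using training statistics.
#' @return An `svr_config` list.
#' @export
svr_config <- function(C = 10, epsilon = 0.1, gamma = NULL, d = 1L,
                       standardize = TRUE) {
  stopifnot(C > 0, epsilon >= 0)
  structure(list(C = C, epsilon = epsilon, gamma = gamma, d = as.integer(d),
                 standardize = isTRUE(standardize)),
            class = "svr_config")
}

#' Fit epsilon-SVR with the ANOVA kernel and predict on new rows
#'
#' Solves the epsilon-insensitive support-vector regression dual by
#' sequential minimal optimization on the ANOVA-kernel Gram matrix.
#' Deterministic for fixed inputs and configuration. An all-constant
#' label vector triggers a degenerate-fit warning and constant
#' predictions.
#'
#' @param x_train Numeric matrix of training features (rows = samples);
#'   no missing values (drop sentinel rows upstream).
#' @param y_train Numeric label vector, length `nrow(x_train)` >= 2.
#' @param x_test Numeric matrix of test features, same columns.
#' @param cfg An [svr_config()].
#' @return Numeric vector of predictions for `x_test` rows, with
#'   attributes `n_sv` (support-vector count) and `iterations`.
#' @export
fit_predict_svr <- function(x_train, y_train, x_test, cfg = svr_config()) {
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  if (nrow(x_train) < 2L) stop("need >= 2 training rows", call. = FALSE)
  if (ncol(x_test) != ncol(x_train)) {
    stop("test columns do not match training columns", call. = FALSE)
  }
  if (anyNA(x_train) || anyNA(y_train) || anyNA(x_test)) {
    stop("missing values in SVR inputs; drop sentinel rows upstream",
         call. = FALSE)
  }
  if (stats::sd(y_train) == 0) {
    warning("all training labels identical; degenerate fit returns the constant",
            call. = FALSE)
    out <- rep(y_train[1L], nrow(x_test))
    attr(out, "n_sv") <- 0L
    attr(out, "iterations") <- 0L
    return(out)
  }
  if (cfg$standardize) {
    mu <- colMeans(x_train)
    sdv <- apply(x_train, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    x_train <- sweep(sweep(x_train, 2L, mu), 2L, sdv, "/")
    x_test <- sweep(sweep(x_test, 2L, mu), 2L, sdv, "/")
  }
  gamma <- if (is.null(cfg$gamma)) 1 / ncol(x_train) else cfg$gamma
  spec <- kernel_spec(gamma, cfg$d)
  K <- gram_matrix(x_train, spec)
  fit <- .svr_smo_cpp(K, y_train, cfg$C, cfg$epsilon)
  Kc <- gram_matrix(x_test, spec, x_train)
  out <- as.numeric(Kc %*% fit$beta + fit$b)
  attr(out, "n_sv") <- sum(abs(fit$beta) > 1e-10)
  attr(out, "iterations") <- fit$iterations
  out
}
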