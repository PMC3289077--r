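# Hybrid SVM-KNN classifier.
#
# Training is identical to a soft-margin RBF SVM (solved by the in-package
# SMO routine). At prediction time the functional margin |f(x)| is compared
# with a threshold T: confident samples (|f(x)| > T) take the SVM sign,
# while samples inside the margin band are decided by a class-weighted
# k-nearest-neighbour vote among the support vectors, measured in the
# kernel-induced feature-space distance.

#' RBF kernel
#'
#' `K(x, y) = exp(-gamma * ||x - y||^2)`, in (0, 1], symmetric, and 1 at
#' zero distance.
#'
#' @param x,y numeric vectors of equal length, or `y` a matrix whose rows
#'   are compared against `x`.
#' @param gamma kernel width (> 0).
#' @return scalar (or vector over rows of `y`).
#' @export
rbf_kernel <- function(x, y, gamma) {
  stopifnot(gamma > 0)
  if (is.matrix(y)) {
    if (ncol(y) != length(x)) stop("dimension mismatch: ", length(x), " vs ",
                                   ncol(y))
    return(exp(-gamma * colSums((t(y) - x)^2)))
  }
  if (length(x) != length(y)) stop("dimension mismatch: ", length(x), " vs ",
                                   length(y))
  exp(-gamma * sum((x - y)^2))
}

#' Kernel-induced feature-space distance
#'
#' Distance between the RBF feature-space images of two points:
#' `sqrt(2 - 2 K(x, y))` (using K(x,x) = 1). Zero iff x = y; bounded by
#' sqrt(2); monotone in the input-space distance.
#'
#' @inheritParams rbf_kernel
#' @return non-negative scalar (or vector over rows of `y`).
#' @export
kernel_distance <- function(x, y, gamma) {
  sqrt(pmax(0, 2 - 2 * rbf_kernel(x, y, gamma)))
}

#' SVM decision function
#'
#' `f(x) = sum_i a_i K(x, x_i) + b` over the model's support vectors,
#' where `a_i` are the signed coefficients (`alpha_i * y_i`).
#'
#' @param m an `svmknn_model`.
#' @param x a feature vector, or a matrix of row vectors.
#' @return decision value(s).
#' @export
decision_value <- function(m, x) {
  if (!nrow(m$SV)) {
    if (is.null(m$b)) stop("degenerate model: no support vectors and no bias")
    return(if (is.matrix(x)) rep(m$b, nrow(x)) else m$b)
  }
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(m$SV))
    stop("dimension mismatch: x has ", ncol(x), " features, model expects ",
         ncol(m$SV))
  K <- exp(-m$gamma * .cross_sqdist(x, m$SV))
  drop(K %*% m$coefs + m$b)
}

#' Train the hybrid SVM-KNN model
#'
#' Solves the standard soft-margin RBF-SVM dual (in-package SMO, libsvm
#' conventions) and stores the hybrid routing parameters. The KNN vote
#' weights default to the class-imbalance rule `C1 = 1`,
#' `C2 = N-/N+` of the training set.
#'
#' @param ft a [feature_table()] (or list with `X`, `y`).
#' @param C soft-margin penalty (> 0).
#' @param gamma RBF width (> 0).
#' @param T margin threshold (>= 0) for routing to KNN.
#' @param k number of KNN neighbours (>= 1).
#' @param C1,C2 vote weights for the positive / negative class; `NULL`
#'   picks `C1 = 1`, `C2 = N-/N+`.
#' @param svm_class_weights optional length-2 vector `c(pos, neg)` of
#'   per-class multipliers on `C` (box constraints); default unweighted.
#' @param knn_pool `"support_vectors"` (default) restricts the KNN
#'   candidate pool to the support vectors; `"all"` uses every training
#'   point.
#' @param eps SMO stopping tolerance.
#' @return object of class `svmknn_model`.
#' @export
svmknn_train <- function(ft, C = 1, gamma = 0.0625, T = 1.0, k = 5L,
                         C1 = NULL, C2 = NULL, svm_class_weights = c(1, 1),
                         knn_pool = c("support_vectors", "all"),
                         eps = 1e-3) {
  knn_pool <- match.arg(knn_pool)
  stopifnot(C > 0, gamma > 0, T >= 0, k >= 1)
  X <- as.matrix(ft$X)
  y01 <- as.integer(ft$y)
  if (length(unique(y01)) < 2L)
    stop("degenerate training set: only one class present")
  y <- ifelse(y01 == 1L, 1L, -1L)
  n_pos <- sum(y == 1); n_neg <- sum(y == -1)
  if (is.null(C1)) C1 <- 1
  if (is.null(C2)) C2 <- n_neg / n_pos
  Cvec <- ifelse(y == 1, C * svm_class_weights[1], C * svm_class_weights[2])
  K <- exp(-gamma * .cross_sqdist(X, X))
  sol <- .smo_solve(K, as.integer(y), as.numeric(Cvec), eps = eps)
  sv <- which(sol$alpha > 1e-8)
  model <- structure(list(
    SV = X[sv, , drop = FALSE], sv_y = y[sv],
    alphas = sol$alpha[sv], coefs = sol$alpha[sv] * y[sv], b = sol$b,
    gamma = gamma, C = C, T = T, k = as.integer(k), C1 = C1, C2 = C2,
    knn_pool = knn_pool,
    pool_X = if (knn_pool == "all") X else NULL,
    pool_y = if (knn_pool == "all") y else NULL,
    n_train = length(y), class_ratio = n_neg / n_pos,
    iterations = sol$iterations, converged = sol$converged),
    class = "svmknn_model")
  if (!sol$converged)
    warning("SMO did not converge within the iteration budget")
  model
}

#' @export
print.svmknn_model <- function(x, ...) {
  cat(sprintf(
    paste0("svmknn_model: %d SVs / %d samples, C=%g gamma=%g, ",
           "T=%g k=%d C1=%g C2=%g (pool: %s)\n"),
    nrow(x$SV), x$n_train, x$C, x$gamma, x$T, x$k, x$C1, x$C2, x$knn_pool))
  invisible(x)
}

#' Predict with the hybrid SVM-KNN
#'
#' Samples whose functional margin exceeds the threshold (`|f(x)| > T`)
#' are classified by the SVM sign (routing `"svm"`). The rest take a
#' class-weighted vote among the `k` nearest candidates in the
#' kernel-induced distance: class 1 wins iff
#' `C1 * (#positive neighbours) > C2 * (#negative neighbours)`; ties fall
#' back to the SVM sign (routing `"knn"`).
#'
#' @param object an `svmknn_model`.
#' @param newdata feature matrix (rows = samples) or single vector.
#' @param ... unused.
#' @return data.frame with columns `label` (0/1), `decision` (f(x)),
#'   `routing` ("svm"/"knn").
#' @export
predict.svmknn_model <- function(object, newdata, ...) {
  m <- object
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  f <- decision_value(m, newdata)
  label <- as.integer(f > 0)
  routing <- rep("svm", nrow(newdata))
  uncertain <- which(abs(f) <= m$T)
  if (length(uncertain)) {
    pool_X <- if (m$knn_pool == "all") m$pool_X else m$SV
    pool_y <- if (m$knn_pool == "all") m$pool_y else m$sv_y
    k <- m$k
    if (k > nrow(pool_X)) {
      warning("k = ", k, " exceeds candidate pool size ", nrow(pool_X),
              "; clamped")
      k <- nrow(pool_X)
    }
    d2 <- .cross_sqdist(newdata[uncertain, , drop = FALSE], pool_X)
    kd <- sqrt(pmax(2 - 2 * exp(-m$gamma * d2), 0))
    for (u in seq_along(uncertain)) {
      # k nearest, ties in distance broken by pool order (deterministic)
      nb <- order(kd[u, ])[seq_len(k)]
      vpos <- m$C1 * sum(pool_y[nb] == 1)
      vneg <- m$C2 * sum(pool_y[nb] == -1)
      i <- uncertain[u]
      label[i] <- if (vpos > vneg) 1L else if (vneg > vpos) 0L
                  else as.integer(f[i] > 0)
      routing[i] <- "knn"
    }
  }
  data.frame(label = label, decision = f, routing = routing,
             stringsAsFactors = FALSE)
}

# ---- model serialization --------------------------------------------------

#' Save / load an SVM-KNN model as a self-describing JSON archive
#'
#' @param m an `svmknn_model`.
#' @param path file path (JSON).
#' @return the model (load) or `path` invisibly (save).
#' @export
save_model <- function(m, path) {
  payload <- list(
    format = "spabind-svmknn", version = 1L,
    gamma = m$gamma, C = m$C, T = m$T, k = m$k, C1 = m$C1, C2 = m$C2,
    b = m$b, knn_pool = m$knn_pool, n_train = m$n_train,
    class_ratio = m$class_ratio,
    sv_y = m$sv_y, alphas = m$alphas, SV = m$SV,
    pool_X = m$pool_X, pool_y = m$pool_y)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "spabind-svmknn"))
    stop("not a spabind model archive: ", path)
  SV <- matrix(as.numeric(p$SV), nrow = length(p$sv_y), byrow = FALSE)
  # jsonlite returns a matrix already when rectangular
  if (is.matrix(p$SV)) SV <- p$SV
  structure(list(
    SV = SV, sv_y = as.integer(p$sv_y), alphas = as.numeric(p$alphas),
    coefs = as.numeric(p$alphas) * as.integer(p$sv_y), b = p$b,
    gamma = p$gamma, C = p$C, T = p$T, k = as.integer(p$k),
    C1 = p$C1, C2 = p$C2, knn_pool = p$knn_pool,
    pool_X = if (!is.null(p$pool_X)) p$pool_X else NULL,
    pool_y = if (!is.null(p$pool_y)) as.integer(p$pool_y) else NULL,
    n_train = p$n_train, class_ratio = p$class_ratio,
    iterations = NA_integer_, converged = NA), class = "svmknn_model")
}
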