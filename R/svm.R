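# Gaussian-kernel soft-margin SVM trained by sequential minimal
# optimization (SMO), with Platt-scaled probabilities and an optional
# Gaussian-process Bayesian search over the two kernel hyperparameters.
# Implemented in-package: no SVM library is available in the target
# environment, and the kernel convention must match the printed
# hyperparameters (K(x, y) = exp(-||x - y||^2 / s^2)).

gaussian_kernel_matrix <- function(x, y = x, kernel_scale) {
  x <- as.matrix(x); y <- as.matrix(y)
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  exp(-d2 / kernel_scale^2)
}

#' SVM model configuration
#'
#' Defaults are the optimized hyperparameters of the reference emotion
#' detector: Gaussian kernel with scale 6.385 and box constraint 956.32,
#' no standardization (features are already min-max normalized), one-vs-one
#' coding (vacuous for two classes and kept for fidelity).
#'
#' @param kernel_scale Gaussian kernel scale `s` in
#'   `K(x, y) = exp(-||x - y||^2 / s^2)` (default 6.385).
#' @param box_constraint Soft-margin cost `C` (default 956.32).
#' @param optimize Run Bayesian hyperparameter optimization before the
#'   final fit (default `FALSE`).
#' @param opt_iters Optimization iterations (default 100).
#' @param cv_folds Inner cross-validation folds for optimization
#'   (default 5).
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(kernel_scale = 6.385, box_constraint = 956.32,
                       optimize = FALSE, opt_iters = 100L, cv_folds = 5L) {
  stopifnot(kernel_scale > 0, box_constraint > 0)
  structure(list(kernel = "gaussian", kernel_scale = kernel_scale,
                 box_constraint = box_constraint, multiclass = "one-vs-one",
                 standardize = FALSE, optimize = isTRUE(optimize),
                 opt_iters = as.integer(opt_iters),
                 cv_folds = as.integer(cv_folds)),
            class = "svm_config")
}

# Core SMO solver (simplified Platt variant with deterministic pair
# selection). y in {-1, +1}. Returns alpha and bias b for
# f(x) = sum alpha_i y_i K(x_i, x) + b.
smo_fit <- function(K, y, C, tol = 1e-3, max_passes = 10L,
                    max_iter = 20000L) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  passes <- 0L
  iter <- 0L
  fcache <- function() as.numeric(K %*% (alpha * y)) + b
  while (passes < max_passes && iter < max_iter) {
    changed <- 0L
    f <- fcache()
    E <- f - y
    for (i in seq_len(n)) {
      iter <- iter + 1L
      ri <- E[i] * y[i]
      if ((ri < -tol && alpha[i] < C) || (ri > tol && alpha[i] > 0)) {
        j <- which.max(abs(E - E[i]))
        if (j == i) next
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (E[i] - E[j]) / eta
        aj <- min(H, max(L, aj))
        if (abs(aj - aj_old) < 1e-7 * (aj + aj_old + 1e-7)) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        b1 <- b - E[i] - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - E[j] - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        alpha[i] <- ai; alpha[j] <- aj
        b_old <- b
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else
          (b1 + b2) / 2
        df <- y[i] * (ai - ai_old) * K[, i] +
          y[j] * (aj - aj_old) * K[, j] + (b - b_old)
        f <- f + df
        E <- f - y
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  list(alpha = alpha, b = b)
}

# Platt scaling: fit P(y = +1 | f) = 1 / (1 + exp(A f + B)) by Newton
# iterations on the training decision values with Platt's target priors.
platt_fit <- function(f, y) {
  t_pos <- (sum(y > 0) + 1) / (sum(y > 0) + 2)
  t_neg <- 1 / (sum(y < 0) + 2)
  t <- ifelse(y > 0, t_pos, t_neg)
  A <- 0; B <- log((sum(y < 0) + 1) / (sum(y > 0) + 1))
  for (it in 1:100) {
    z <- A * f + B
    p <- 1 / (1 + exp(z))
    g <- p - t                      # d(-loglik)/dz with this sign setup
    gA <- sum(-g * f); gB <- sum(-g)
    w <- p * (1 - p)
    hAA <- sum(w * f^2) + 1e-12; hBB <- sum(w) + 1e-12; hAB <- sum(w * f)
    det <- hAA * hBB - hAB^2
    if (abs(det) < 1e-12) break
    dA <- (gB * hAB - gA * hBB) / det
    dB <- (gA * hAB - gB * hAA) / det
    A <- A + dA; B <- B + dB
    if (max(abs(c(dA, dB))) < 1e-10) break
  }
  c(A = A, B = B)
}

#' Train the emotion-versus-rest SVM
#'
#' Gaussian-kernel soft-margin SVM solved by SMO. With
#' `cfg$optimize = TRUE` a Bayesian (Gaussian-process expected
#' improvement) search over log-scaled kernel scale and box constraint in
#' `[1e-3, 1e3]^2` is run first, scored by inner `cfg$cv_folds`-fold CV
#' accuracy for `cfg$opt_iters` iterations. Probabilities are calibrated
#' by Platt scaling on the training decision values.
#'
#' @param features Normalized numeric matrix (observations x 8); use
#'   [normalize_features()].
#' @param labels Character/factor vector with the two classes `"emotion"`
#'   and `"rest"` (both must be present).
#' @param cfg An [svm_config()].
#' @param seed RNG seed (used by the optimizer and fold splits).
#' @return An object of class `emophysio_svm` with the support vectors,
#'   dual coefficients, Platt parameters and a fit report
#'   (`$report$train_accuracy`, `$report$n_support`).
#' @export
train_emotion_detector <- function(features, labels, cfg = svm_config(),
                                   seed = 1L) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop("training data must contain exactly two classes", call. = FALSE)
  }
  # positive class = "emotion" when present, else the first class
  pos <- if ("emotion" %in% classes) "emotion" else classes[1L]
  neg <- setdiff(classes, pos)
  y <- ifelse(labels == pos, 1, -1)
  if (cfg$optimize) {
    opt <- bayes_opt_svm(x, y, iters = cfg$opt_iters,
                         folds = cfg$cv_folds, seed = seed)
    cfg$kernel_scale <- opt$kernel_scale
    cfg$box_constraint <- opt$box_constraint
  }
  K <- gaussian_kernel_matrix(x, kernel_scale = cfg$kernel_scale)
  fit <- smo_fit(K, y, C = cfg$box_constraint)
  f <- as.numeric(K %*% (fit$alpha * y)) + fit$b
  sv <- which(fit$alpha > 1e-8)
  platt <- platt_fit(f, y)
  model <- structure(
    list(x = x[sv, , drop = FALSE], coef = (fit$alpha * y)[sv],
         b = fit$b, kernel_scale = cfg$kernel_scale,
         box_constraint = cfg$box_constraint,
         classes = c(positive = pos, negative = neg), platt = platt,
         n_features = ncol(x), seed = seed,
         report = list(train_accuracy = mean((f > 0) == (y > 0)),
                       n_support = length(sv))),
    class = "emophysio_svm")
  model
}

#' @export
print.emophysio_svm <- function(x, ...) {
  cat(sprintf(paste0("<emophysio_svm> %d support vectors, scale %.4g, ",
                     "C %.4g, train acc %.3f\n"),
              x$report$n_support, x$kernel_scale, x$box_constraint,
              x$report$train_accuracy))
  invisible(x)
}

svm_decision <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) {
    stop(sprintf("expected %d features, got %d", model$n_features,
                 ncol(x)), call. = FALSE)
  }
  K <- gaussian_kernel_matrix(x, model$x, model$kernel_scale)
  as.numeric(K %*% model$coef) + model$b
}

#' Predict the emotion/rest state for feature rows
#'
#' @param model An `emophysio_svm` from [train_emotion_detector()].
#' @param feature_row Numeric vector (one observation) or matrix of
#'   normalized feature rows.
#' @return `data.frame` with columns `label` and `probability` (Platt
#'   probability of the predicted label; the two class probabilities sum
#'   to 1).
#' @export
predict_state <- function(model, feature_row) {
  stopifnot(inherits(model, "emophysio_svm"))
  x <- if (is.null(dim(feature_row))) matrix(feature_row, nrow = 1L) else
    as.matrix(feature_row)
  f <- svm_decision(model, x)
  p_pos <- 1 / (1 + exp(model$platt["A"] * f + model$platt["B"]))
  label <- ifelse(p_pos >= 0.5, model$classes["positive"],
                  model$classes["negative"])
  data.frame(label = unname(label),
             probability = unname(pmax(p_pos, 1 - p_pos)),
             p_positive = unname(p_pos),
             stringsAsFactors = FALSE)
}

# ---- Bayesian optimization (GP + expected improvement) -------------------

svm_cv_accuracy <- function(x, y, kernel_scale, box_constraint, folds,
                            seed) {
  n <- length(y)
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  acc <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    if (length(unique(y[tr])) < 2L) { acc[k] <- NA; next }
    K <- gaussian_kernel_matrix(x[tr, , drop = FALSE],
                                kernel_scale = kernel_scale)
    fit <- smo_fit(K, y[tr], C = box_constraint, max_passes = 3L,
                   max_iter = 5000L)
    Kv <- gaussian_kernel_matrix(x[!tr, , drop = FALSE],
                                 x[tr, , drop = FALSE], kernel_scale)
    f <- as.numeric(Kv %*% (fit$alpha[seq_len(sum(tr))] * y[tr])) + fit$b
    acc[k] <- mean((f > 0) == (y[!tr] > 0))
  }
  mean(acc, na.rm = TRUE)
}

bayes_opt_svm <- function(x, y, iters = 100L, folds = 5L, seed = 1L) {
  lo <- -3; hi <- 3   # log10 bounds for both hyperparameters
  seeds <- derive_seeds(seed, iters + 2L)
  n_init <- min(8L, iters)
  pts <- with_seed(seeds[1L],
                   matrix(stats::runif(2L * n_init, lo, hi), ncol = 2L))
  obj <- vapply(seq_len(n_init), function(i) {
    svm_cv_accuracy(x, y, 10^pts[i, 1L], 10^pts[i, 2L], folds, seeds[2L])
  }, numeric(1))
  gp_k <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    exp(-pmax(d2, 0) / (2 * 1.0^2))
  }
  for (it in seq_len(max(0L, iters - n_init))) {
    mu0 <- mean(obj); sd0 <- stats::sd(obj); if (!is.finite(sd0) || sd0 == 0) sd0 <- 1e-3
    z <- (obj - mu0) / sd0
    Kp <- gp_k(pts, pts) + diag(1e-6 + 1e-4, nrow(pts))
    Kin <- solve(Kp)
    cand <- with_seed(seeds[it + 2L],
                      matrix(stats::runif(400, lo, hi), ncol = 2L))
    Kc <- gp_k(cand, pts)
    mu <- as.numeric(Kc %*% Kin %*% z)
    var <- pmax(1 - rowSums((Kc %*% Kin) * Kc), 1e-9)
    s <- sqrt(var)
    best <- max(z)
    imp <- mu - best
    ei <- imp * stats::pnorm(imp / s) + s * stats::dnorm(imp / s)
    nxt <- cand[which.max(ei), , drop = FALSE]
    val <- svm_cv_accuracy(x, y, 10^nxt[1L], 10^nxt[2L], folds, seeds[2L])
    pts <- rbind(pts, nxt)
    obj <- c(obj, val)
  }
  best <- which.max(obj)
  list(kernel_scale = 10^pts[best, 1L], box_constraint = 10^pts[best, 2L],
       cv_accuracy = obj[best], evaluations = cbind(pts, obj))
}
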