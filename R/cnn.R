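# Small convolutional network for arousal-strength classification,
# implemented directly (im2col convolutions, max pooling, SGD with
# momentum, gradient-norm clipping, weighted cross-entropy). No deep
# learning framework is available in the target environment; the
# architecture is a 4-conv-block CPU-friendly stand-in for large
# pretrained backbones, with the final layer sized to the 3 arousal
# classes.

#' CNN training configuration
#'
#' Defaults follow the reference training options: stochastic gradient
#' descent with momentum, 12 epochs, mini-batch 30, learning rate 0.001,
#' gradient-norm threshold 1.0, shuffling every epoch, and a
#' class-weighted cross-entropy loss with weights `N / m_i`.
#'
#' @param backbone `"small_cnn"` (the only backbone available offline;
#'   large pretrained architectures are out of scope).
#' @param epochs Training epochs (default 12).
#' @param mini_batch Mini-batch size (default 30).
#' @param learning_rate SGD learning rate (default 0.001).
#' @param momentum SGD momentum (default 0.9).
#' @param gradient_threshold Per-array L2 gradient clipping norm
#'   (default 1).
#' @param class_weights Optional per-class weights; computed as `N / m_i`
#'   from the training labels when `NULL`.
#' @param seed RNG seed for initialization and shuffling.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(backbone = c("small_cnn", "resnet50"), epochs = 12L,
                       mini_batch = 30L, learning_rate = 0.001,
                       momentum = 0.9, gradient_threshold = 1,
                       class_weights = NULL, seed = 1L) {
  backbone <- match.arg(backbone)
  if (backbone == "resnet50") {
    stop(paste("the resnet50 backbone requires pretrained weights that",
               "cannot be distributed; use backbone = 'small_cnn'"),
         call. = FALSE)
  }
  stopifnot(epochs >= 1L, mini_batch >= 1L, learning_rate > 0)
  if (!is.null(class_weights) && any(class_weights <= 0)) {
    stop("class weights must be positive", call. = FALSE)
  }
  structure(list(backbone = backbone, epochs = as.integer(epochs),
                 mini_batch = as.integer(mini_batch),
                 learning_rate = learning_rate, momentum = momentum,
                 gradient_threshold = gradient_threshold,
                 shuffle = "every-epoch", class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Weighted cross-entropy loss
#'
#' `-(1/N) * sum_n sum_i w_i * T_ni * ln(Y_ni)` for predicted class
#' probabilities `Y`, one-hot targets `T` and per-class weights `w`.
#' Zero predicted probabilities at a true class are clamped at 1e-12.
#'
#' @param pred_probs N x K matrix of predicted probabilities (rows sum
#'   to 1).
#' @param targets N x K one-hot matrix, or a vector of class indices
#'   (1..K).
#' @param weights Length-K positive class weights (see
#'   [class_weights()]).
#' @return The scalar loss.
#' @export
weighted_cross_entropy <- function(pred_probs, targets, weights) {
  p <- as.matrix(pred_probs)
  K <- ncol(p)
  if (!is.matrix(targets)) {
    t_idx <- as.integer(targets)
    targets <- matrix(0, nrow(p), K)
    targets[cbind(seq_len(nrow(p)), t_idx)] <- 1
  }
  stopifnot(all(dim(targets) == dim(p)), length(weights) == K)
  if (max(abs(rowSums(p) - 1)) > 1e-6) {
    stop("rows of pred_probs must sum to 1", call. = FALSE)
  }
  p <- pmax(p, 1e-12)
  -sum(sweep(targets * log(p), 2L, weights, "*")) / nrow(p)
}

# ---- layers --------------------------------------------------------------

im2col3 <- function(xpad, H, W, C, k = 3L) {
  out <- matrix(0, k * k * C, H * W)
  r <- 0L
  for (c in seq_len(C)) for (j in seq_len(k)) for (i in seq_len(k)) {
    r <- r + 1L
    out[r, ] <- as.vector(xpad[i:(i + H - 1L), j:(j + W - 1L), c])
  }
  out
}

col2im3 <- function(dcols, H, W, C, k = 3L) {
  p <- (k - 1L) %/% 2L
  dxp <- array(0, c(H + 2L * p, W + 2L * p, C))
  r <- 0L
  for (c in seq_len(C)) for (j in seq_len(k)) for (i in seq_len(k)) {
    r <- r + 1L
    dxp[i:(i + H - 1L), j:(j + W - 1L), c] <-
      dxp[i:(i + H - 1L), j:(j + W - 1L), c] + matrix(dcols[r, ], H, W)
  }
  dxp[(p + 1L):(p + H), (p + 1L):(p + W), , drop = FALSE]
}

pad_same <- function(x, p = 1L) {
  d <- dim(x)
  xp <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L]))
  xp[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]), ] <- x
  xp
}

conv_forward <- function(x, W, b) {
  d <- dim(x)
  cols <- im2col3(pad_same(x), d[1L], d[2L], d[3L])
  out <- W %*% cols + b
  list(out = array(t(out), c(d[1L], d[2L], nrow(W))), cols = cols)
}

conv_backward <- function(dout, cache_cols, x_dim, W) {
  dmat <- t(matrix(dout, prod(x_dim[1:2]), dim(dout)[3L]))
  dW <- dmat %*% t(cache_cols)
  db <- rowSums(dmat)
  dcols <- t(W) %*% dmat
  dx <- col2im3(dcols, x_dim[1L], x_dim[2L], x_dim[3L])
  list(dx = dx, dW = dW, db = db)
}

maxpool_forward <- function(x) {
  d <- dim(x)
  Ho <- d[1L] %/% 2L; Wo <- d[2L] %/% 2L
  out <- array(-Inf, c(Ho, Wo, d[3L]))
  arg <- array(0L, c(Ho, Wo, d[3L]))
  for (code in 1:4) {
    di <- (code - 1L) %% 2L; dj <- (code - 1L) %/% 2L
    sub <- x[seq(1L + di, 2L * Ho, 2L), seq(1L + dj, 2L * Wo, 2L), ,
             drop = FALSE]
    upd <- sub > out
    out[upd] <- sub[upd]
    arg[upd] <- code
  }
  list(out = out, arg = arg, in_dim = d)
}

maxpool_backward <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  Ho <- dim(dout)[1L]; Wo <- dim(dout)[2L]
  for (code in 1:4) {
    di <- (code - 1L) %% 2L; dj <- (code - 1L) %/% 2L
    tmp <- array(0, dim(dout))
    mask <- cache$arg == code
    tmp[mask] <- dout[mask]
    ii <- seq(1L + di, 2L * Ho, 2L); jj <- seq(1L + dj, 2L * Wo, 2L)
    dx[ii, jj, ] <- dx[ii, jj, ] + tmp
  }
  dx
}

# ---- network -------------------------------------------------------------

cnn_init <- function(in_dim, n_classes, seed) {
  # 4 conv blocks (8, 16, 32, 32 filters; pools after blocks 1-3), FC head
  filt <- c(8L, 16L, 32L, 32L)
  chans <- c(in_dim[3L], filt)
  with_seed(seed, {
    params <- list()
    for (l in 1:4) {
      fan_in <- 9L * chans[l]
      params[[paste0("W", l)]] <-
        matrix(stats::rnorm(filt[l] * fan_in, 0, sqrt(2 / fan_in)),
               nrow = filt[l])
      params[[paste0("b", l)]] <- numeric(filt[l])
    }
    hw <- c(in_dim[1L] %/% 8L, in_dim[2L] %/% 8L)  # after 3 pools
    d_flat <- prod(hw) * filt[4L]
    params$Wfc <- matrix(stats::rnorm(n_classes * d_flat, 0,
                                      sqrt(2 / d_flat)),
                         nrow = n_classes)
    params$bfc <- numeric(n_classes)
    list(params = params, in_dim = in_dim, n_classes = n_classes,
         d_flat = d_flat)
  })
}

cnn_forward <- function(net, x, keep_cache = FALSE) {
  p <- net$params
  cache <- list(x = x)
  a <- x
  for (l in 1:4) {
    cv <- conv_forward(a, p[[paste0("W", l)]], p[[paste0("b", l)]])
    r <- pmax(cv$out, 0)
    cache[[paste0("cols", l)]] <- cv$cols
    cache[[paste0("pre", l)]] <- cv$out
    cache[[paste0("in_dim", l)]] <- dim(a)
    if (l <= 3L) {
      mp <- maxpool_forward(r)
      cache[[paste0("pool", l)]] <- mp
      a <- mp$out
    } else {
      a <- r
    }
  }
  flat <- as.numeric(a)
  scores <- as.numeric(p$Wfc %*% flat + p$bfc)
  cache$flat <- flat
  cache$last_dim <- dim(a)
  if (keep_cache) list(scores = scores, cache = cache) else
    list(scores = scores)
}

cnn_backward <- function(net, cache, dscores) {
  p <- net$params
  grads <- list()
  grads$Wfc <- outer(dscores, cache$flat)
  grads$bfc <- dscores
  da <- array(as.numeric(t(p$Wfc) %*% dscores), cache$last_dim)
  for (l in 4:1) {
    if (l <= 3L) da <- maxpool_backward(da, cache[[paste0("pool", l)]])
    da <- da * (cache[[paste0("pre", l)]] > 0)
    bk <- conv_backward(da, cache[[paste0("cols", l)]],
                        cache[[paste0("in_dim", l)]], p[[paste0("W", l)]])
    grads[[paste0("W", l)]] <- bk$dW
    grads[[paste0("b", l)]] <- bk$db
    da <- bk$dx
  }
  grads
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

clip_array <- function(g, threshold) {
  nrm <- sqrt(sum(g^2))
  if (is.finite(nrm) && nrm > threshold) g * (threshold / nrm) else g
}

#' Train the arousal-strength CNN
#'
#' Trains the small convolutional network on scalogram images with SGD
#' plus momentum, per-array gradient-norm clipping, epoch-wise shuffling
#' and the class-weighted cross-entropy loss
#' ([weighted_cross_entropy()], weights `N / m_i` unless supplied).
#'
#' @param images List of numeric arrays `H x W x C` (all the same shape;
#'   grayscale matrices are promoted to `H x W x 1`). `H` and `W` must be
#'   divisible by 8.
#' @param labels Vector with classes `"low"`, `"mid"`, `"high"` (factor
#'   or character); every class must be present.
#' @param cfg A [cnn_config()].
#' @return An object of class `emophysio_cnn` with the fitted parameters
#'   and `$history` (per-epoch mean loss and training accuracy).
#' @export
train_arousal_classifier <- function(images, labels, cfg = cnn_config()) {
  stopifnot(inherits(cfg, "cnn_config"), length(images) == length(labels))
  images <- lapply(images, function(im) {
    if (is.matrix(im)) im <- array(im, c(dim(im), 1L))
    im
  })
  in_dim <- dim(images[[1L]])
  if (any(in_dim[1:2] %% 8L != 0L)) {
    stop("image height and width must be divisible by 8", call. = FALSE)
  }
  classes <- c("low", "mid", "high")
  labels <- as.character(labels)
  if (!all(labels %in% classes)) {
    classes <- sort(unique(labels))   # generic label sets allowed in tests
  }
  counts <- table(factor(labels, levels = classes))
  if (any(counts == 0L)) {
    stop("every class must have at least one example (class weights ",
         "N/m_i are undefined otherwise)", call. = FALSE)
  }
  w <- cfg$class_weights %||% as.numeric(length(labels) / counts)
  y <- match(labels, classes)
  net <- cnn_init(in_dim, length(classes), cfg$seed)
  vel <- lapply(net$params, function(p) p * 0)
  n <- length(images)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  ep_seeds <- derive_seeds(cfg$seed + 1L, cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(ep_seeds[ep], sample.int(n))
    ep_loss <- 0; ep_correct <- 0L
    for (start in seq(1L, n, by = cfg$mini_batch)) {
      idx <- ord[start:min(start + cfg$mini_batch - 1L, n)]
      bgrads <- NULL
      for (i in idx) {
        fw <- cnn_forward(net, images[[i]], keep_cache = TRUE)
        pr <- softmax(fw$scores)
        ep_loss <- ep_loss - w[y[i]] * log(max(pr[y[i]], 1e-12))
        ep_correct <- ep_correct + as.integer(which.max(pr) == y[i])
        dsc <- w[y[i]] * pr
        dsc[y[i]] <- dsc[y[i]] - w[y[i]]
        dsc <- dsc / length(idx)
        g <- cnn_backward(net, fw$cache, dsc)
        bgrads <- if (is.null(bgrads)) g else
          Map(function(a, b) a + b, bgrads, g)
      }
      for (nm in names(net$params)) {
        gc_ <- clip_array(bgrads[[nm]], cfg$gradient_threshold)
        vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$learning_rate * gc_
        net$params[[nm]] <- net$params[[nm]] + vel[[nm]]
      }
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss / n,
                                accuracy = ep_correct / n))
  }
  structure(list(net = net, classes = classes, weights = w, cfg = cfg,
                 history = history),
            class = "emophysio_cnn")
}

#' @export
print.emophysio_cnn <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<emophysio_cnn> %d epochs, final loss %.4f, train acc %.3f\n",
              nrow(x$history), last$loss, last$accuracy))
  invisible(x)
}

#' Predict arousal strength for a scalogram image
#'
#' @param model An `emophysio_cnn` from [train_arousal_classifier()].
#' @param image Numeric array `H x W x C` matching the training shape
#'   (grayscale matrices are promoted).
#' @return `data.frame` with `label` and one probability column per class
#'   (summing to 1).
#' @export
predict_arousal <- function(model, image) {
  stopifnot(inherits(model, "emophysio_cnn"))
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (!all(dim(image) == model$net$in_dim)) {
    stop(sprintf("image shape %s does not match training shape %s",
                 paste(dim(image), collapse = "x"),
                 paste(model$net$in_dim, collapse = "x")), call. = FALSE)
  }
  pr <- softmax(cnn_forward(model$net, image)$scores)
  out <- data.frame(label = model$classes[which.max(pr)],
                    stringsAsFactors = FALSE)
  for (k in seq_along(model$classes)) out[[model$classes[k]]] <- pr[k]
  out
}
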