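#' CNN architecture and training hyperparameters
#'
#' The classifier follows a compact AlexNet-style layout: two 5x5
#' convolutional layers of 32 filters each (stride 1, zero padding preserving
#' size), each followed by ReLU and 2x2 max-pooling, then two fully-connected
#' layers (a ReLU hidden layer and the 2-class softmax output). Dropout is
#' applied to the inputs of both fully-connected layers. The loss is softmax
#' cross-entropy, optimized with Adam.
#'
#' The architectural constants (filter count, kernel, pooling, layer count)
#' are fixed by the study design; the remaining hyperparameters default to
#' common small-network choices and can be overridden.
#'
#' @param conv_filters filters per convolutional layer (default 32).
#' @param conv_kernel convolution kernel size (default 5, odd).
#' @param fc_hidden width of the fully-connected hidden layer (default 256).
#' @param dropout_rate dropout probability in [0, 1) (default 0.5).
#' @param learning_rate Adam step size (default 1e-4).
#' @param epochs training epochs (default 100).
#' @param batch_size minibatch size (default 16).
#' @return an object of class `arch_config`.
#' @export
arch_config <- function(conv_filters = 32L, conv_kernel = 5L, fc_hidden = 256L,
                        dropout_rate = 0.5, learning_rate = 1e-4,
                        epochs = 100L, batch_size = 16L) {
  if (conv_filters < 1L || fc_hidden < 1L || epochs < 1L || batch_size < 1L)
    stop("widths, epochs and batch size must be positive")
  if (conv_kernel < 1L || conv_kernel %% 2L == 0L) stop("conv_kernel must be odd")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 fc_hidden = as.integer(fc_hidden),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size)),
            class = "arch_config")
}

# He-initialized network for input_size x input_size single-channel crops.
# Uses the current RNG state.
cnn_init <- function(arch, input_size = 64L, in_channels = 1L, n_classes = 2L) {
  if (input_size %% 4L != 0L) stop("input_size must be divisible by 4")
  K <- arch$conv_kernel; Fn <- arch$conv_filters
  s_out <- input_size %/% 4L
  flat_dim <- s_out * s_out * Fn
  he <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  params <- list(W1 = he(K * K * in_channels, Fn, K * K * in_channels),
                 b1 = numeric(Fn),
                 W2 = he(K * K * Fn, Fn, K * K * Fn),
                 b2 = numeric(Fn),
                 Wf1 = he(flat_dim, arch$fc_hidden, flat_dim),
                 bf1 = numeric(arch$fc_hidden),
                 Wf2 = he(arch$fc_hidden, n_classes, arch$fc_hidden),
                 bf2 = numeric(n_classes))
  structure(list(params = params, arch = arch, input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels), n_classes = as.integer(n_classes),
                 flat_dim = flat_dim),
            class = "cnn_net")
}

# 2x2 max-pooling (stride 2) over an (H, W, M) array; records which of the
# four window positions won (first-wins tie-break, fixed order).
maxpool_fwd <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  subs <- list(x[ro, co, , drop = FALSE], x[re, co, , drop = FALSE],
               x[ro, ce, , drop = FALSE], x[re, ce, , drop = FALSE])
  best <- subs[[1]]
  amax <- array(1L, dim(best))
  for (p in 2:4) {
    upd <- subs[[p]] > best
    amax[upd] <- p
    best[upd] <- subs[[p]][upd]
  }
  list(out = best, amax = amax, in_dim = d)
}

maxpool_bwd <- function(dout, pool) {
  d <- pool$in_dim
  dx <- array(0, d)
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  rows <- list(ro, re, ro, re); cols <- list(co, co, ce, ce)
  for (p in 1:4) {
    sub <- array(0, dim(dout))
    sel <- pool$amax == p
    sub[sel] <- dout[sel]
    dx[rows[[p]], cols[[p]], ] <- sub
  }
  dx
}

# slice indices of images `sel` inside an (H, W, C*N) stacked cube
stack_slices <- function(sel, C) {
  if (C == 1L) return(sel)
  as.vector(vapply(sel, function(n) (n - 1L) * C + seq_len(C), integer(C)))
}

# Full forward pass. x: (H, W, Cin*N) array. With dropout = TRUE the inverted
# dropout masks are drawn from the current RNG state and kept in the cache.
cnn_forward <- function(net, x, N, dropout = FALSE) {
  pr <- net$params; a <- net$arch
  K <- a$conv_kernel; Fn <- a$conv_filters
  z1 <- .conv_fwd_batch(x, N, net$in_channels, pr$W1, pr$b1, K)
  a1 <- pmax(z1, 0)
  p1 <- maxpool_fwd(a1)
  z2 <- .conv_fwd_batch(p1$out, N, Fn, pr$W2, pr$b2, K)
  a2 <- pmax(z2, 0)
  p2 <- maxpool_fwd(a2)
  flat <- t(matrix(p2$out, net$flat_dim, N))
  keep <- 1 - a$dropout_rate
  d0 <- if (dropout && a$dropout_rate > 0)
    matrix((runif(length(flat)) >= a$dropout_rate) / keep, N) else NULL
  flatd <- if (is.null(d0)) flat else flat * d0
  hpre <- flatd %*% pr$Wf1 + matrix(pr$bf1, N, a$fc_hidden, byrow = TRUE)
  h <- pmax(hpre, 0)
  d1 <- if (dropout && a$dropout_rate > 0)
    matrix((runif(length(h)) >= a$dropout_rate) / keep, N) else NULL
  hd <- if (is.null(d1)) h else h * d1
  scores <- hd %*% pr$Wf2 + matrix(pr$bf2, N, net$n_classes, byrow = TRUE)
  e <- exp(scores - apply(scores, 1L, max))
  probs <- e / rowSums(e)
  list(probs = probs, x = x, z1 = z1, p1 = p1, z2 = z2, p2 = p2,
       flat = flat, flatd = flatd, d0 = d0, h = h, hd = hd, d1 = d1)
}

# Gradients of the mean softmax cross-entropy w.r.t. every parameter.
# y: integer class labels (0/1), length N.
cnn_backward <- function(net, cache, y, N) {
  pr <- net$params; a <- net$arch
  K <- a$conv_kernel; Fn <- a$conv_filters
  Y <- matrix(0, N, net$n_classes)
  Y[cbind(seq_len(N), y + 1L)] <- 1
  dsc <- (cache$probs - Y) / N
  dWf2 <- crossprod(cache$hd, dsc)
  dbf2 <- colSums(dsc)
  dh <- dsc %*% t(pr$Wf2)
  if (!is.null(cache$d1)) dh <- dh * cache$d1
  dh <- dh * (cache$h > 0)
  dWf1 <- crossprod(cache$flatd, dh)
  dbf1 <- colSums(dh)
  dflat <- dh %*% t(pr$Wf1)
  if (!is.null(cache$d0)) dflat <- dflat * cache$d0
  dp2 <- array(t(dflat), dim(cache$p2$out))
  da2 <- maxpool_bwd(dp2, cache$p2)
  dz2 <- da2 * (cache$z2 > 0)
  g2 <- .conv_bwd_batch(cache$p1$out, dz2, N, Fn, pr$W2, K, TRUE)
  da1 <- maxpool_bwd(g2$dx, cache$p1)
  dz1 <- da1 * (cache$z1 > 0)
  g1 <- .conv_bwd_batch(cache$x, dz1, N, net$in_channels, pr$W1, K, FALSE)
  list(W1 = g1$dW, b1 = as.numeric(g1$db), W2 = g2$dW, b2 = as.numeric(g2$db),
       Wf1 = dWf1, bf1 = dbf1, Wf2 = dWf2, bf2 = dbf2)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# Stack a list of crops into an (64, 64, N) array plus 0/1 labels
crops_to_tensor <- function(crops) {
  N <- length(crops)
  x <- array(0, c(64L, 64L, N))
  for (i in seq_len(N)) x[, , i] <- crops[[i]]$pixels
  list(x = x, y = as.integer(crop_labels(crops)), n = N)
}

#' Train the CNN on a set of lesion crops
#'
#' Minibatch training with Adam on softmax cross-entropy. All randomness
#' (weight initialization, epoch shuffling, dropout masks) comes from a stream
#' derived from `seed`, so identical inputs and seed give an identical model.
#'
#' @param crops list of [lesion_crop()]s (both classes should be present).
#' @param arch an [arch_config()].
#' @param seed integer seed.
#' @return a trained `cnn_net`.
#' @export
train_cnn <- function(crops, arch = arch_config(), seed = 1L) {
  if (length(crops) < 2L) stop("need at least two crops to train")
  dat <- crops_to_tensor(crops)
  with_seed(derive_seed(seed, 0L, 4L), {
    net <- cnn_init(arch)
    opt <- adam_init(net$params)
    for (ep in seq_len(arch$epochs)) {
      perm <- sample(dat$n)
      starts <- seq(1L, dat$n, by = arch$batch_size)
      for (s in starts) {
        sel <- perm[s:min(s + arch$batch_size - 1L, dat$n)]
        nb <- length(sel)
        xb <- dat$x[, , stack_slices(sel, net$in_channels), drop = FALSE]
        cache <- cnn_forward(net, xb, nb, dropout = TRUE)
        grads <- cnn_backward(net, cache, dat$y[sel], nb)
        upd <- adam_step(net$params, grads, opt, arch$learning_rate)
        net$params <- upd$params
        opt <- upd$opt
      }
    }
    net
  })
}

#' Responder probabilities from a trained CNN
#'
#' @param net a trained `cnn_net`.
#' @param crops list of [lesion_crop()]s.
#' @return numeric vector of softmax responder probabilities.
#' @export
predict_cnn <- function(net, crops) {
  dat <- crops_to_tensor(crops)
  out <- numeric(dat$n)
  step <- 64L
  for (s in seq(1L, dat$n, by = step)) {
    sel <- s:min(s + step - 1L, dat$n)
    xb <- dat$x[, , stack_slices(sel, net$in_channels), drop = FALSE]
    out[sel] <- cnn_forward(net, xb, length(sel), dropout = FALSE)$probs[, 2L]
  }
  out
}

# sensitivity/specificity/accuracy (percent) at a probability threshold plus
# the (orientation-corrected) AUC of the continuous probabilities
metrics_from_probs <- function(probs, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  pred <- probs >= threshold
  c(sensitivity = 100 * sum(pred & labels) / sum(labels),
    specificity = 100 * sum(!pred & !labels) / sum(!labels),
    accuracy = 100 * mean(pred == labels),
    auc = roc_analysis(probs, labels)$auc)
}

#' k-fold cross-validated CNN training
#'
#' Splits the training crops into `k` patient-level, class-stratified folds,
#' trains one model per fold on the other `k - 1` folds, and evaluates it on
#' the held-out fold. Reported validation metrics are the per-fold values
#' together with their mean and median.
#'
#' @param crops training crops.
#' @param arch an [arch_config()].
#' @param k number of folds (default 3).
#' @param seed integer seed (fold assignment and per-fold training streams).
#' @param threshold probability threshold for sensitivity/specificity/accuracy.
#' @return an object of class `cnn_ensemble`: `models` (list of `cnn_net`),
#'   `folds` (fold id per crop), and `validation` with `fold_values`
#'   (data.frame), `mean` and `median` (named vectors, percent / AUC).
#' @export
train_crossval <- function(crops, arch = arch_config(), k = 3L, seed = 1L,
                           threshold = 0.5) {
  folds <- assign_folds(crops, k, seed)
  models <- vector("list", k)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- crops[folds != f]
    va <- crops[folds == f]
    models[[f]] <- train_cnn(tr, arch, seed = derive_seed(seed, f, 5L))
    m <- metrics_from_probs(predict_cnn(models[[f]], va), crop_labels(va), threshold)
    rows[[f]] <- data.frame(fold = f, n_validation = length(va), t(m))
  }
  fold_values <- do.call(rbind, rows)
  met <- c("sensitivity", "specificity", "accuracy", "auc")
  structure(list(models = models, folds = folds,
                 validation = list(fold_values = fold_values,
                                   mean = colMeans(fold_values[met]),
                                   median = apply(fold_values[met], 2L, median))),
            class = "cnn_ensemble")
}

#' Evaluate a fold ensemble on a held-out test set
#'
#' The responder probability of each test crop is the mean softmax responder
#' output over the fold models; sensitivity, specificity and accuracy are
#' computed at `threshold`, and the AUC comes from [roc_analysis()] on the
#' continuous probabilities.
#'
#' @param ensemble a `cnn_ensemble` from [train_crossval()] (or a list of
#'   `cnn_net`s).
#' @param test_crops held-out crops containing both classes.
#' @param threshold probability threshold (default 0.5).
#' @return list: `sensitivity`, `specificity`, `accuracy` (percent), `auc`,
#'   `n_test`, `probabilities`.
#' @export
evaluate_ensemble <- function(ensemble, test_crops, threshold = 0.5) {
  models <- if (inherits(ensemble, "cnn_ensemble")) ensemble$models else ensemble
  labels <- crop_labels(test_crops)
  if (length(unique(labels)) < 2L)
    stop("test set must contain both classes")
  probs <- rowMeans(vapply(models, function(m) predict_cnn(m, test_crops),
                           numeric(length(test_crops))))
  m <- metrics_from_probs(probs, labels, threshold)
  list(sensitivity = unname(m["sensitivity"]), specificity = unname(m["specificity"]),
       accuracy = unname(m["accuracy"]), auc = unname(m["auc"]),
       n_test = length(test_crops), probabilities = probs)
}
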