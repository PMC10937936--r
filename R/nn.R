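# Small neural regressors used as step-1 models of the stacked estimator:
# a two-hidden-layer perceptron and a 1-D convolutional network that treats
# the 106-feature vector as an ordered sequence. Both are trained full-batch
# with Adam, MSE loss, and early stopping on a 10% inner validation split.
# Inputs are expected standardized; targets are standardized internally.

.adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

.adam_step <- function(state, params, grads, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  for (k in seq_along(params)) {
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * grads[[k]]
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - b1^state$t)
    vhat <- state$v[[k]] / (1 - b2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

.val_split <- function(n, frac = 0.1) {
  nv <- max(1L, round(frac * n))
  vi <- sample.int(n, nv)
  list(train = setdiff(seq_len(n), vi), val = vi)
}

#' Fit a two-hidden-layer neural-network regressor
#'
#' Dense 64-32-1 architecture with rectified activations, He
#' initialization, full-batch Adam and early stopping (patience in epochs)
#' on a 10% inner validation split. Uses the current R random-number state.
#'
#' @param x Numeric matrix (observations x features), standardized.
#' @param y Numeric targets.
#' @param hidden Hidden layer sizes (default `c(64, 32)`).
#' @param epochs Maximum epochs (default 500).
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience, epochs.
#' @return Object of class `mlp_model`.
#' @export
fit_mlp <- function(x, y, hidden = c(64, 32), epochs = 500, lr = 0.005,
                    patience = 40) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  y_mu <- mean(y); y_sd <- max(sd(y), 1e-12)
  ys <- (y - y_mu) / y_sd
  sizes <- c(ncol(x), hidden, 1L)
  params <- list()
  for (l in seq_len(length(sizes) - 1)) {
    params[[paste0("W", l)]] <- matrix(
      rnorm(sizes[l] * sizes[l + 1]) * sqrt(2 / sizes[l]), sizes[l], sizes[l + 1])
    params[[paste0("b", l)]] <- numeric(sizes[l + 1])
  }
  nl <- length(sizes) - 1
  fwd <- function(params, X) {
    acts <- list(X)
    for (l in seq_len(nl)) {
      Z <- sweep(acts[[l]] %*% params[[paste0("W", l)]], 2,
                 params[[paste0("b", l)]], "+")
      acts[[l + 1]] <- if (l < nl) pmax(Z, 0) else Z
    }
    acts
  }
  sp <- .val_split(nrow(x))
  Xt <- x[sp$train, , drop = FALSE]; yt <- ys[sp$train]
  Xv <- x[sp$val, , drop = FALSE]; yv <- ys[sp$val]
  opt <- .adam_new(params)
  best <- list(loss = Inf, params = params, epoch = 0)
  for (ep in seq_len(epochs)) {
    acts <- fwd(params, Xt)
    delta <- 2 * (acts[[nl + 1]] - yt) / length(yt)
    grads <- params
    for (l in rev(seq_len(nl))) {
      grads[[paste0("W", l)]] <- crossprod(acts[[l]], delta)
      grads[[paste0("b", l)]] <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(params[[paste0("W", l)]])) * (acts[[l]] > 0)
    }
    st <- .adam_step(opt, params, grads, lr)
    opt <- st$state; params <- st$params
    vl <- mean((fwd(params, Xv)[[nl + 1]] - yv)^2)
    if (vl < best$loss - 1e-9) best <- list(loss = vl, params = params, epoch = ep)
    if (ep - best$epoch >= patience) break
  }
  structure(list(params = best$params, n_layers = nl, y_mu = y_mu, y_sd = y_sd,
                 hidden = hidden, epochs_run = ep, val_mse = best$loss),
            class = "mlp_model")
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  A <- as.matrix(newdata)
  for (l in seq_len(object$n_layers)) {
    Z <- sweep(A %*% object$params[[paste0("W", l)]], 2,
               object$params[[paste0("b", l)]], "+")
    A <- if (l < object$n_layers) pmax(Z, 0) else Z
  }
  as.numeric(A) * object$y_sd + object$y_mu
}

# ---- 1-D convolutional regressor ------------------------------------------

# valid convolution along the sequence axis of an N x T x C array
.conv1d_fwd <- function(X, W, b) {
  K <- dim(W)[1]; Cin <- dim(W)[2]; Cout <- dim(W)[3]
  N <- dim(X)[1]; Tin <- dim(X)[2]
  Tout <- Tin - K + 1
  out <- matrix(0, N * Tout, Cout)
  for (k in seq_len(K)) {
    Xs <- matrix(X[, k:(k + Tout - 1), , drop = FALSE], N * Tout, Cin)
    out <- out + Xs %*% matrix(W[k, , ], Cin, Cout)
  }
  array(sweep(out, 2, b, "+"), c(N, Tout, Cout))
}

.conv1d_bwd <- function(X, W, dOut) {
  K <- dim(W)[1]; Cin <- dim(W)[2]; Cout <- dim(W)[3]
  N <- dim(X)[1]; Tin <- dim(X)[2]; Tout <- dim(dOut)[2]
  dOm <- matrix(dOut, N * Tout, Cout)
  dW <- W * 0
  dX <- X * 0
  for (k in seq_len(K)) {
    Xs <- matrix(X[, k:(k + Tout - 1), , drop = FALSE], N * Tout, Cin)
    dW[k, , ] <- crossprod(Xs, dOm)
    dXs <- array(dOm %*% t(matrix(W[k, , ], Cin, Cout)), c(N, Tout, Cin))
    dX[, k:(k + Tout - 1), ] <- dX[, k:(k + Tout - 1), , drop = FALSE] + dXs
  }
  list(dW = dW, db = colSums(dOm), dX = dX)
}

.pool2_fwd <- function(X) {
  Tout <- dim(X)[2] %/% 2
  A <- X[, seq(1, 2 * Tout, 2), , drop = FALSE]
  B <- X[, seq(2, 2 * Tout, 2), , drop = FALSE]
  list(out = pmax(A, B), take_first = A >= B, t_out = Tout)
}

.pool2_bwd <- function(pool, dOut, dim_in) {
  dX <- array(0, dim_in)
  Tout <- pool$t_out
  dX[, seq(1, 2 * Tout, 2), ] <- dOut * pool$take_first
  dX[, seq(2, 2 * Tout, 2), ] <- dOut * !pool$take_first
  dX
}

#' Fit a 1-D convolutional neural-network regressor
#'
#' Treats the ordered feature vector as a one-dimensional sequence: two
#' convolution blocks (16 then 32 channels, kernel 5, max-pooling 2,
#' rectified activations) followed by a 32-unit dense head. Trained
#' full-batch with Adam and early stopping on a 10% inner split. Uses the
#' current R random-number state.
#'
#' @param x Numeric matrix (observations x sequence positions),
#'   standardized.
#' @param y Numeric targets.
#' @param channels Channel counts of the two blocks (default `c(16, 32)`).
#' @param kernel Kernel length (default 5).
#' @param dense Dense head width (default 32).
#' @param epochs Maximum epochs (default 500).
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience, epochs.
#' @return Object of class `cnn_model`.
#' @export
fit_cnn <- function(x, y, channels = c(16, 32), kernel = 5, dense = 32,
                    epochs = 500, lr = 0.002, patience = 60) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  y_mu <- mean(y); y_sd <- max(sd(y), 1e-12)
  ys <- (y - y_mu) / y_sd
  L <- ncol(x)
  t1 <- L - kernel + 1; p1 <- t1 %/% 2
  t2 <- p1 - kernel + 1; p2 <- t2 %/% 2
  if (p2 < 1)
    stop("fit_cnn: input sequence too short (", L,
         " positions) for two kernel-", kernel, " convolution blocks")
  flat <- p2 * channels[2]
  he <- function(fan, d) array(rnorm(prod(d)) * sqrt(2 / fan), d)
  params <- list(
    W1 = he(kernel, c(kernel, 1, channels[1])), b1 = numeric(channels[1]),
    W2 = he(kernel * channels[1], c(kernel, channels[1], channels[2])),
    b2 = numeric(channels[2]),
    W3 = matrix(rnorm(flat * dense) * sqrt(2 / flat), flat, dense),
    b3 = numeric(dense),
    W4 = matrix(rnorm(dense) * sqrt(2 / dense), dense, 1), b4 = 0)
  fwd <- function(params, X, keep = FALSE) {
    N <- nrow(X)
    A0 <- array(X, c(N, L, 1))
    Z1 <- .conv1d_fwd(A0, params$W1, params$b1); A1 <- pmax(Z1, 0)
    P1 <- .pool2_fwd(A1)
    Z2 <- .conv1d_fwd(P1$out, params$W2, params$b2); A2 <- pmax(Z2, 0)
    P2 <- .pool2_fwd(A2)
    Fl <- matrix(P2$out[, seq_len(p2), , drop = FALSE], N, flat)
    Z3 <- sweep(Fl %*% params$W3, 2, params$b3, "+"); A3 <- pmax(Z3, 0)
    yhat <- as.numeric(A3 %*% params$W4 + params$b4)
    if (!keep) return(yhat)
    list(yhat = yhat, A0 = A0, Z1 = Z1, A1 = A1, P1 = P1, Z2 = Z2, A2 = A2,
         P2 = P2, Fl = Fl, A3 = A3)
  }
  sp <- .val_split(nrow(x))
  Xt <- x[sp$train, , drop = FALSE]; yt <- ys[sp$train]
  Xv <- x[sp$val, , drop = FALSE]; yv <- ys[sp$val]
  opt <- .adam_new(params)
  best <- list(loss = Inf, params = params, epoch = 0)
  for (ep in seq_len(epochs)) {
    fw <- fwd(params, Xt, keep = TRUE)
    N <- nrow(Xt)
    d <- matrix(2 * (fw$yhat - yt) / N, N, 1)
    g <- params
    g$W4 <- crossprod(fw$A3, d); g$b4 <- sum(d)
    d3 <- (d %*% t(params$W4)) * (fw$A3 > 0)
    g$W3 <- crossprod(fw$Fl, d3); g$b3 <- colSums(d3)
    dFl <- d3 %*% t(params$W3)
    dP2 <- array(dFl, c(N, p2, channels[2]))
    dA2 <- .pool2_bwd(fw$P2, dP2, dim(fw$A2))
    dZ2 <- dA2 * (fw$Z2 > 0)
    bw2 <- .conv1d_bwd(fw$P1$out, params$W2, dZ2)
    g$W2 <- bw2$dW; g$b2 <- bw2$db
    dA1 <- .pool2_bwd(fw$P1, bw2$dX, dim(fw$A1))
    dZ1 <- dA1 * (fw$Z1 > 0)
    bw1 <- .conv1d_bwd(fw$A0, params$W1, dZ1)
    g$W1 <- bw1$dW; g$b1 <- bw1$db
    st <- .adam_step(opt, params, g, lr)
    opt <- st$state; params <- st$params
    vl <- mean((fwd(params, Xv) - yv)^2)
    if (vl < best$loss - 1e-9) best <- list(loss = vl, params = params, epoch = ep)
    if (ep - best$epoch >= patience) break
  }
  structure(list(params = best$params, L = L, kernel = kernel,
                 channels = channels, dense = dense, p2 = p2, flat = flat,
                 y_mu = y_mu, y_sd = y_sd, epochs_run = ep,
                 val_mse = best$loss),
            class = "cnn_model")
}

#' @export
predict.cnn_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  stopifnot(ncol(X) == object$L)
  p <- object$params
  N <- nrow(X)
  A <- array(X, c(N, object$L, 1))
  A <- .pool2_fwd(pmax(.conv1d_fwd(A, p$W1, p$b1), 0))$out
  A <- .pool2_fwd(pmax(.conv1d_fwd(A, p$W2, p$b2), 0))$out
  Fl <- matrix(A[, seq_len(object$p2), , drop = FALSE], N, object$flat)
  A3 <- pmax(sweep(Fl %*% p$W3, 2, p$b3, "+"), 0)
  as.numeric(A3 %*% p$W4 + p$b4) * object$y_sd + object$y_mu
}
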