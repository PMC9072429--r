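# Hand-rolled multilayer perceptron with SMAPE loss, written in base R
# matrix code. Architecture: five hidden layers in an encoder-decoder
# (autoencoder-perceptron) width profile, mish activations, batch
# normalization, dropout with a max-norm constraint on incoming weights,
# additive Gaussian input noise, a sigmoid output layer, AdamW (decoupled
# weight decay) wrapped in lookahead averaging, plateau learning-rate
# decay, and early stopping with best-weight restoration.

.mish <- function(x) {
  sp <- ifelse(x > 20, x, log1p(exp(pmin(x, 20))))
  x * tanh(sp)
}

.mish_grad <- function(x) {
  sp <- ifelse(x > 20, x, log1p(exp(pmin(x, 20))))
  tsp <- tanh(sp)
  sig <- 1 / (1 + exp(-pmin(pmax(x, -30), 30)))
  tsp + x * (1 - tsp^2) * sig
}

.sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

.mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  L <- length(sizes) - 1L
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    W <- matrix(stats::rnorm(fan_in * sizes[l + 1], 0, sqrt(2 / fan_in)),
                fan_in, sizes[l + 1])
    layers[[l]] <- list(
      W = W,
      b = rep(0, sizes[l + 1]),
      # batch-norm parameters (hidden layers only)
      gamma = rep(1, sizes[l + 1]),
      beta = rep(0, sizes[l + 1]),
      run_mean = rep(0, sizes[l + 1]),
      run_var = rep(1, sizes[l + 1])
    )
  }
  list(layers = layers, L = L)
}

# Forward pass. In training mode uses batch statistics and dropout masks;
# in inference mode uses running statistics and no dropout.
.mlp_forward <- function(net, X, train = FALSE, dropout = 0, eps = 1e-5) {
  L <- net$L
  H <- X
  cache <- vector("list", L)
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    Z <- H %*% ly$W
    if (l < L) {
      if (train) {
        mu <- colMeans(Z)
        va <- colMeans(sweep(Z, 2, mu)^2)
      } else {
        mu <- ly$run_mean
        va <- ly$run_var
      }
      inv_sd <- 1 / sqrt(va + eps)
      Zhat <- sweep(sweep(Z, 2, mu), 2, inv_sd, "*")
      Yl <- sweep(sweep(Zhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
      A <- .mish(Yl)
      mask <- NULL
      if (train && dropout > 0) {
        mask <- matrix(stats::rbinom(length(A), 1, 1 - dropout) / (1 - dropout),
                       nrow(A), ncol(A))
        A <- A * mask
      }
      cache[[l]] <- list(H = H, Z = Z, mu = mu, va = va, inv_sd = inv_sd,
                         Zhat = Zhat, Yl = Yl, mask = mask)
      H <- A
    } else {
      Zo <- sweep(Z, 2, ly$b, "+")
      P <- .sigmoid(Zo)
      cache[[l]] <- list(H = H, Zo = Zo, P = P)
      H <- P
    }
  }
  list(out = H, cache = cache)
}

# SMAPE loss over the (scaled, non-negative) outputs plus its gradient.
.smape_loss_grad <- function(P, T) {
  n <- length(P)
  den <- abs(P) + abs(T)
  ok <- den > 0
  loss <- 200 * sum(abs(P - T)[ok] / den[ok]) / n
  G <- matrix(0, nrow(P), ncol(P))
  # d/dp |p-t|/(p+t) for p,t >= 0: (sign(p-t)(p+t) - |p-t|) / (p+t)^2
  G[ok] <- 200 / n * (sign(P - T)[ok] * den[ok] - abs(P - T)[ok]) / den[ok]^2
  list(loss = loss, grad = G)
}

.mlp_backward <- function(net, cache, dOut, eps = 1e-5) {
  L <- net$L
  grads <- vector("list", L)
  up <- dOut
  for (l in rev(seq_len(L))) {
    ly <- net$layers[[l]]
    cc <- cache[[l]]
    if (l == L) {
      dZ <- up * cc$P * (1 - cc$P)
      grads[[l]] <- list(W = crossprod(cc$H, dZ), b = colSums(dZ))
      up <- dZ %*% t(ly$W)
    } else {
      if (!is.null(cc$mask)) up <- up * cc$mask
      dY <- up * .mish_grad(cc$Yl)
      dgamma <- colSums(dY * cc$Zhat)
      dbeta <- colSums(dY)
      dZhat <- sweep(dY, 2, ly$gamma, "*")
      N <- nrow(dZhat)
      s1 <- colSums(dZhat)
      s2 <- colSums(dZhat * cc$Zhat)
      dZ <- sweep(
        N * dZhat - matrix(s1, N, length(s1), byrow = TRUE) -
          cc$Zhat * matrix(s2, N, length(s2), byrow = TRUE),
        2, cc$inv_sd / N, "*")
      grads[[l]] <- list(W = crossprod(cc$H, dZ), gamma = dgamma, beta = dbeta)
      up <- dZ %*% t(ly$W)
    }
  }
  grads
}

# One AdamW step with decoupled weight decay, followed by a per-unit
# max-norm clip of incoming weight columns.
.adamw_step <- function(net, grads, state, lr, wd, max_norm, t_step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_len(net$L)) {
    for (p in names(grads[[l]])) {
      g <- grads[[l]][[p]]
      key <- paste0(l, ".", p)
      if (is.null(state[[key]])) state[[key]] <- list(m = g * 0, v = g * 0)
      st <- state[[key]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      state[[key]] <- st
      mhat <- st$m / (1 - beta1^t_step)
      vhat <- st$v / (1 - beta2^t_step)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      if (p == "W") upd <- upd + lr * wd * net$layers[[l]][[p]]
      net$layers[[l]][[p]] <- net$layers[[l]][[p]] - upd
    }
    if (max_norm > 0) {
      W <- net$layers[[l]]$W
      nrm <- sqrt(colSums(W^2))
      over <- nrm > max_norm
      if (any(over)) {
        W[, over] <- sweep(W[, over, drop = FALSE], 2,
                           max_norm / nrm[over], "*")
        net$layers[[l]]$W <- W
      }
    }
  }
  list(net = net, state = state)
}

#' Train the SMAPE-loss deep regressor
#'
#' Fits the five-hidden-layer encoder-decoder perceptron on scaled
#' features and min-max-scaled targets. Training is full-batch (the
#' printed batch size equals the dataset size) with the SMAPE objective,
#' AdamW (learning rate 0.015, weight decay 0.001) wrapped in lookahead
#' averaging, batch normalization, dropout plus a max-norm constraint,
#' additive Gaussian input noise, learning-rate reduction on plateau
#' (patience 100 epochs, factor 0.9), and early stopping that restores
#' the best weights. Deterministic for a fixed seed.
#'
#' @param X Scaled feature matrix.
#' @param Y Scaled target matrix in \[0, 1\].
#' @param hidden Hidden-layer widths; default `c(256, 128, 64, 128, 256)`.
#' @param epochs Maximum training epochs.
#' @param lr Learning rate (default 0.015).
#' @param wd Decoupled weight decay (default 0.001).
#' @param dropout Dropout probability on hidden activations.
#' @param max_norm Max-norm bound on incoming weight columns (0 disables).
#' @param noise_sd SD of additive Gaussian input noise on scaled features.
#' @param lr_patience,lr_factor Plateau schedule (epochs, multiplier).
#' @param stop_patience Early-stopping patience in epochs.
#' @param lookahead_k,lookahead_alpha Lookahead synchronisation period and
#'   interpolation factor.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param verbose Print progress every 200 epochs.
#' @return A list of class `syn_mlp` (layers, loss history, best loss).
#' @export
mlp_train <- function(X, Y, hidden = c(256, 128, 64, 128, 256),
                      epochs = 2000, lr = 0.015, wd = 0.001,
                      dropout = 0.05, max_norm = 3, noise_sd = 0.01,
                      lr_patience = 100, lr_factor = 0.9,
                      stop_patience = 400, lookahead_k = 5,
                      lookahead_alpha = 0.5, seed = 1L, verbose = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  set.seed(seed)
  net <- .mlp_init(ncol(X), hidden, ncol(Y))
  state <- list()
  slow <- net$layers
  best <- list(loss = Inf, layers = net$layers)
  history <- numeric(0)
  since_best <- 0L
  since_lr <- 0L
  cur_lr <- lr
  for (ep in seq_len(epochs)) {
    Xn <- if (noise_sd > 0) X + stats::rnorm(length(X), 0, noise_sd) else X
    fw <- .mlp_forward(net, Xn, train = TRUE, dropout = dropout)
    lg <- .smape_loss_grad(fw$out, Y)
    if (!is.finite(lg$loss)) {
      stop("non-finite training loss at epoch ", ep, call. = FALSE)
    }
    # update running batch-norm statistics
    for (l in seq_len(net$L - 1L)) {
      cc <- fw$cache[[l]]
      net$layers[[l]]$run_mean <- 0.9 * net$layers[[l]]$run_mean + 0.1 * cc$mu
      net$layers[[l]]$run_var <- 0.9 * net$layers[[l]]$run_var + 0.1 * cc$va
    }
    grads <- .mlp_backward(net, fw$cache, lg$grad)
    stp <- .adamw_step(net, grads, state, cur_lr, wd, max_norm, ep)
    net <- stp$net; state <- stp$state
    if (ep %% lookahead_k == 0) {
      for (l in seq_len(net$L)) {
        for (p in c("W", "b", "gamma", "beta")) {
          if (!is.null(slow[[l]][[p]]) && !is.null(net$layers[[l]][[p]])) {
            slow[[l]][[p]] <- slow[[l]][[p]] +
              lookahead_alpha * (net$layers[[l]][[p]] - slow[[l]][[p]])
            net$layers[[l]][[p]] <- slow[[l]][[p]]
          }
        }
      }
    }
    history[ep] <- lg$loss
    if (lg$loss < best$loss - 1e-9) {
      best$loss <- lg$loss
      best$layers <- net$layers
      since_best <- 0L
      since_lr <- 0L
    } else {
      since_best <- since_best + 1L
      since_lr <- since_lr + 1L
    }
    if (since_lr >= lr_patience) {
      cur_lr <- cur_lr * lr_factor
      since_lr <- 0L
    }
    if (since_best >= stop_patience) break
    if (verbose && ep %% 200 == 0) {
      message("epoch ", ep, " SMAPE ", format(lg$loss, digits = 5))
    }
  }
  net$layers <- best$layers  # early stopping: restore best weights
  structure(list(layers = net$layers, L = net$L, hidden = hidden,
                 loss = best$loss, history = history, seed = seed),
            class = "syn_mlp")
}

#' Predict with a trained MLP (scaled space)
#'
#' @param object A `syn_mlp`.
#' @param newdata Scaled feature matrix.
#' @param ... Unused.
#' @return Matrix of sigmoid outputs in \[0, 1\].
#' @export
predict.syn_mlp <- function(object, newdata, ...) {
  net <- list(layers = object$layers, L = object$L)
  .mlp_forward(net, as.matrix(newdata), train = FALSE)$out
}
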