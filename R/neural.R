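# Minimal reference implementations of the two sequence regressors used in
# the suite: a one-block 1-D convolutional network and a single-layer LSTM,
# both reading the feature vector as a length-J sequence with one channel
# and trained full-batch with stochastic gradient descent with momentum
# (SGDM). Inputs and target are z-scored internally; predictions are
# returned on the original scale. Backward passes are hand-derived and
# verified against numerical gradients in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- 1-D CNN ---------------------------------------------------------------

cnn1d_init <- function(J, kernel, filters) {
  L <- J - kernel + 1L
  list(
    W = matrix(stats::rnorm(kernel * filters, 0, 0.1), kernel, filters),
    b = rep(0, filters),
    V = matrix(stats::rnorm(L * filters, 0, 0.1), L, filters),
    c = 0,
    kernel = kernel, filters = filters, L = L, J = J
  )
}

# forward + loss + gradients; drop_mask (n x L x F array or NULL) applies
# inverted dropout on the ReLU activations
cnn1d_loss_grad <- function(par, X, y, drop_mask = NULL, drop_rate = 0) {
  n <- nrow(X); L <- par$L; Fk <- par$filters; k <- par$kernel
  Z <- array(0, c(n, L, Fk))
  for (l in seq_len(L)) {
    Z[, l, ] <- X[, l:(l + k - 1), drop = FALSE] %*% par$W +
      matrix(par$b, n, Fk, byrow = TRUE)
  }
  A <- pmax(Z, 0)
  if (!is.null(drop_mask)) A <- A * drop_mask / (1 - drop_rate)
  yhat <- par$c + vapply(seq_len(n), function(i) sum(A[i, , ] * par$V), numeric(1))
  resid <- yhat - y
  loss <- mean(resid^2)
  dyhat <- 2 * resid / n
  gV <- matrix(0, L, Fk); gW <- matrix(0, k, Fk); gb <- rep(0, Fk)
  dA <- array(0, c(n, L, Fk))
  for (i in seq_len(n)) {
    gV <- gV + dyhat[i] * A[i, , ]
    dA[i, , ] <- dyhat[i] * par$V
  }
  if (!is.null(drop_mask)) dA <- dA * drop_mask / (1 - drop_rate)
  dZ <- dA * (Z > 0)
  for (l in seq_len(L)) {
    gW <- gW + t(X[, l:(l + k - 1), drop = FALSE]) %*% dZ[, l, ]
    gb <- gb + colSums(matrix(dZ[, l, ], ncol = Fk))
  }
  list(loss = loss, yhat = yhat,
       grads = list(W = gW, b = gb, V = gV, c = sum(dyhat)))
}

cnn1d_predict_raw <- function(par, X) {
  cnn1d_loss_grad(par, X, rep(0, nrow(X)))$yhat
}

# ---- LSTM ------------------------------------------------------------------

lstm_init <- function(H) {
  gate <- function() list(
    w = stats::rnorm(H, 0, 0.1),          # input weight (scalar input)
    U = matrix(stats::rnorm(H * H, 0, 0.1), H, H),
    b = rep(0, H)
  )
  g <- list(i = gate(), f = gate(), o = gate(), g = gate())
  g$f$b <- rep(1, H)  # forget-gate bias init at 1 (standard practice)
  list(gates = g, v = stats::rnorm(H, 0, 0.1), c0 = 0, H = H)
}

lstm_loss_grad <- function(par, X, y, drop_mask = NULL, drop_rate = 0) {
  n <- nrow(X); J <- ncol(X); H <- par$H
  gs <- par$gates
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  cache <- vector("list", J)
  for (t in seq_len(J)) {
    xt <- X[, t]
    pre <- function(gt) outer(xt, gt$w) + h %*% gt$U +
      matrix(gt$b, n, H, byrow = TRUE)
    i_t <- sigmoid(pre(gs$i)); f_t <- sigmoid(pre(gs$f))
    o_t <- sigmoid(pre(gs$o)); g_t <- tanh(pre(gs$g))
    c_new <- f_t * cc + i_t * g_t
    h_new <- o_t * tanh(c_new)
    cache[[t]] <- list(i = i_t, f = f_t, o = o_t, g = g_t,
                       c_prev = cc, h_prev = h, c = c_new)
    h <- h_new; cc <- c_new
  }
  h_out <- h
  if (!is.null(drop_mask)) h_out <- h_out * drop_mask / (1 - drop_rate)
  yhat <- as.vector(h_out %*% par$v) + par$c0
  resid <- yhat - y
  loss <- mean(resid^2)
  dyhat <- 2 * resid / n

  zero_gate <- function() list(w = rep(0, H), U = matrix(0, H, H), b = rep(0, H))
  gr <- list(i = zero_gate(), f = zero_gate(), o = zero_gate(), g = zero_gate())
  gv <- colSums(dyhat * h_out); gc0 <- sum(dyhat)
  dh <- dyhat %o% par$v
  if (!is.null(drop_mask)) dh <- dh * drop_mask / (1 - drop_rate)
  dc <- matrix(0, n, H)
  for (t in rev(seq_len(J))) {
    ch <- cache[[t]]
    tc <- tanh(ch$c)
    do_ <- dh * tc
    dc <- dc + dh * ch$o * (1 - tc^2)
    df <- dc * ch$c_prev
    di <- dc * ch$g
    dg <- dc * ch$i
    dzi <- di * ch$i * (1 - ch$i)
    dzf <- df * ch$f * (1 - ch$f)
    dzo <- do_ * ch$o * (1 - ch$o)
    dzg <- dg * (1 - ch$g^2)
    xt <- X[, t]
    acc <- function(slot, dz) {
      gr[[slot]]$w <<- gr[[slot]]$w + colSums(dz * xt)
      gr[[slot]]$U <<- gr[[slot]]$U + t(ch$h_prev) %*% dz
      gr[[slot]]$b <<- gr[[slot]]$b + colSums(dz)
    }
    acc("i", dzi); acc("f", dzf); acc("o", dzo); acc("g", dzg)
    dh <- dzi %*% t(gs$i$U) + dzf %*% t(gs$f$U) +
      dzo %*% t(gs$o$U) + dzg %*% t(gs$g$U)
    dc <- dc * ch$f
  }
  list(loss = loss, yhat = yhat, grads = list(gates = gr, v = gv, c0 = gc0))
}

lstm_predict_raw <- function(par, X) {
  lstm_loss_grad(par, X, rep(0, nrow(X)))$yhat
}

# ---- SGDM trainer over flattened parameter lists ---------------------------

flatten_params <- function(p) {
  if (is.numeric(p)) return(as.vector(p))
  unlist(lapply(p, flatten_params), use.names = FALSE)
}

unflatten_params <- function(template, theta) {
  pos <- 0
  rebuild <- function(p) {
    if (is.numeric(p)) {
      k <- length(p)
      out <- theta[(pos + 1):(pos + k)]
      pos <<- pos + k
      if (is.matrix(p)) dim(out) <- dim(p)
      return(out)
    }
    lapply(p, rebuild)
  }
  rebuild(template)
}

# param slots subject to training (scalars kernel/filters/L/J/H excluded)
trainable <- function(par, arch) {
  if (arch == "cnn") par[c("W", "b", "V", "c")]
  else list(gates = par$gates, v = par$v, c0 = par$c0)
}

sgdm_train <- function(par, arch, X, y, epochs, lr, momentum, dropout, seed) {
  tr <- trainable(par, arch)
  theta <- flatten_params(tr)
  vel <- numeric(length(theta))
  n <- nrow(X)
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      cur <- unflatten_params(tr, theta)
      p <- par
      if (arch == "cnn") { p[names(cur)] <- cur } else {
        p$gates <- cur$gates; p$v <- cur$v; p$c0 <- cur$c0
      }
      mask <- NULL
      if (dropout > 0) {
        mask <- if (arch == "cnn") {
          array(stats::rbinom(n * p$L * p$filters, 1, 1 - dropout),
                c(n, p$L, p$filters))
        } else {
          matrix(stats::rbinom(n * p$H, 1, 1 - dropout), n, p$H)
        }
      }
      res <- if (arch == "cnn") cnn1d_loss_grad(p, X, y, mask, dropout)
             else lstm_loss_grad(p, X, y, mask, dropout)
      g <- flatten_params(if (arch == "cnn") res$grads
                          else res$grads[c("gates", "v", "c0")])
      vel <- momentum * vel - lr * g
      theta <- theta + vel
    }
  })
  cur <- unflatten_params(tr, theta)
  if (arch == "cnn") { par[names(cur)] <- cur } else {
    par$gates <- cur$gates; par$v <- cur$v; par$c0 <- cur$c0
  }
  par
}
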