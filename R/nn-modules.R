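# Minimal 1-D neural-network engine.
#
# Feature maps are numeric arrays of shape (channels C, length L, batch B).
# Each primitive module is an environment exposing:
#   params / grads : named lists of numeric arrays (same shapes)
#   forward(x, train = TRUE) -> y   (caches what backward needs)
#   backward(dy) -> dx              (accumulates into grads)
# Convolutions are computed as one GEMM per kernel offset on the flattened
# (C, L*B) matrix, which is where essentially all of the FLOPs go.

flat3 <- function(x) { d <- dim(x); dim(x) <- c(d[1L], d[2L] * d[3L]); x }
unflat3 <- function(m, C, L, B) { dim(m) <- c(C, L, B); m }

new_module <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list(); e$grads <- list()
  e
}

zero_grads_module <- function(m) {
  for (nm in names(m$params)) m$grads[[nm]] <- m$params[[nm]] * 0
  invisible(m)
}

# ---- convolution, stride 1, 'same' zero padding -----------------------------

nn_conv1d <- function(cin, cout, k = 3L) {
  stopifnot(k %% 2L == 1L || k == 1L)
  m <- new_module()
  m$cin <- cin; m$cout <- cout; m$k <- as.integer(k)
  m$params$W <- array(stats::rnorm(cout * cin * k, sd = sqrt(2 / (cin * k))),
                      dim = c(cout, cin, k))
  m$params$b <- numeric(cout)
  zero_grads_module(m)
  m$idx_key <- ""
  m$forward <- function(x, train = TRUE) {
    d <- dim(x); C <- d[1L]; L <- d[2L]; B <- d[3L]
    if (m$k == 1L) {                    # pointwise: plain GEMM, no padding
      Xm <- flat3(x)
      W1 <- matrix(m$params$W[, , 1L], m$cout, m$cin)
      m$cache <- list(Xm = Xm, L = L, B = B)
      return(unflat3(W1 %*% Xm + m$params$b, m$cout, L, B))
    }
    p <- (m$k - 1L) %/% 2L
    Lp <- L + 2L * p
    xp <- array(0, c(C, Lp, B))
    xp[, (p + 1L):(p + L), ] <- x
    Xm <- flat3(xp)
    key <- paste(L, B)
    if (!identical(m$idx_key, key)) {
      m$idx <- lapply(seq_len(m$k), function(j)
        as.vector(outer(seq_len(L) + (j - 1L), (0:(B - 1L)) * Lp, "+")))
      m$idx_key <- key
    }
    Xj <- lapply(m$idx, function(ix) Xm[, ix, drop = FALSE])
    Y <- matrix(m$params$b, m$cout, L * B)
    for (j in seq_len(m$k)) {
      Wj <- matrix(m$params$W[, , j], m$cout, m$cin)
      Y <- Y + Wj %*% Xj[[j]]
    }
    m$cache <- list(Xj = Xj, L = L, B = B, p = p, Lp = Lp)
    unflat3(Y, m$cout, L, B)
  }
  m$backward <- function(dy) {
    cc <- m$cache
    dYm <- flat3(dy)
    m$grads$b <- m$grads$b + rowSums(dYm)
    if (m$k == 1L) {
      W1 <- matrix(m$params$W[, , 1L], m$cout, m$cin)
      m$grads$W[, , 1L] <- m$grads$W[, , 1L] + tcrossprod(dYm, cc$Xm)
      return(unflat3(crossprod(W1, dYm), m$cin, cc$L, cc$B))
    }
    dXp <- matrix(0, m$cin, cc$Lp * cc$B)
    for (j in seq_len(m$k)) {
      Wj <- matrix(m$params$W[, , j], m$cout, m$cin)
      m$grads$W[, , j] <- m$grads$W[, , j] + tcrossprod(dYm, cc$Xj[[j]])
      dXp[, m$idx[[j]]] <- dXp[, m$idx[[j]]] + crossprod(Wj, dYm)
    }
    dxp <- unflat3(dXp, m$cin, cc$Lp, cc$B)
    dxp[, (cc$p + 1L):(cc$p + cc$L), , drop = FALSE]
  }
  m
}

# ---- batch normalization (per channel over length x batch) ------------------

nn_batchnorm <- function(C, momentum = 0.1, eps = 1e-5) {
  m <- new_module()
  m$C <- C; m$momentum <- momentum; m$eps <- eps
  m$params$gamma <- rep(1, C)
  m$params$beta <- numeric(C)
  m$running_mean <- numeric(C)
  m$running_var <- rep(1, C)
  zero_grads_module(m)
  m$forward <- function(x, train = TRUE) {
    d <- dim(x); L <- d[2L]; B <- d[3L]
    Xm <- flat3(x)
    if (train) {
      mu <- rowMeans(Xm)
      xc <- Xm - mu
      v <- rowMeans(xc * xc)
      m$running_mean <- (1 - m$momentum) * m$running_mean + m$momentum * mu
      m$running_var <- (1 - m$momentum) * m$running_var + m$momentum * v
    } else {
      mu <- m$running_mean
      xc <- Xm - mu
      v <- m$running_var
    }
    ivs <- 1 / sqrt(v + m$eps)
    xhat <- xc * ivs
    m$cache <- list(xhat = xhat, ivs = ivs, L = L, B = B, train = train)
    unflat3(xhat * m$params$gamma + m$params$beta, m$C, L, B)
  }
  m$backward <- function(dy) {
    cc <- m$cache
    dYm <- flat3(dy)
    m$grads$gamma <- m$grads$gamma + rowSums(dYm * cc$xhat)
    m$grads$beta <- m$grads$beta + rowSums(dYm)
    dxhat <- dYm * m$params$gamma
    if (cc$train) {
      dXm <- cc$ivs * (dxhat - rowMeans(dxhat) - cc$xhat * rowMeans(dxhat * cc$xhat))
    } else {
      dXm <- cc$ivs * dxhat
    }
    unflat3(dXm, m$C, cc$L, cc$B)
  }
  m
}

# ---- activations and pooling ------------------------------------------------

nn_relu <- function() {
  m <- new_module()
  m$forward <- function(x, train = TRUE) {
    m$mask <- x > 0
    x * m$mask
  }
  m$backward <- function(dy) dy * m$mask
  m
}

nn_maxpool2 <- function() {
  m <- new_module()
  m$forward <- function(x, train = TRUE) {
    d <- dim(x); C <- d[1L]; L <- d[2L]; B <- d[3L]
    a <- x[, seq(1L, L, 2L), , drop = FALSE]
    b <- x[, seq(2L, L, 2L), , drop = FALSE]
    m$mask <- a >= b                     # ties break to the left element
    m$dims <- d
    a * m$mask + b * !m$mask
  }
  m$backward <- function(dy) {
    d <- m$dims
    dx <- array(0, d)
    dx[, seq(1L, d[2L], 2L), ] <- dy * m$mask
    dx[, seq(2L, d[2L], 2L), ] <- dy * !m$mask
    dx
  }
  m
}

nn_identity <- function() {
  m <- new_module()
  m$forward <- function(x, train = TRUE) x
  m$backward <- function(dy) dy
  m
}

# ---- transposed convolution, kernel 2, stride 2 (x2 upsampling) -------------

nn_upconv2 <- function(cin, cout) {
  m <- new_module()
  m$cin <- cin; m$cout <- cout
  m$params$W <- array(stats::rnorm(cout * cin * 2L, sd = sqrt(2 / cin)),
                      dim = c(cout, cin, 2L))
  m$params$b <- numeric(cout)
  zero_grads_module(m)
  m$forward <- function(x, train = TRUE) {
    d <- dim(x); L <- d[2L]; B <- d[3L]
    Xm <- flat3(x)
    Y1 <- matrix(m$params$W[, , 1L], m$cout, m$cin) %*% Xm
    Y2 <- matrix(m$params$W[, , 2L], m$cout, m$cin) %*% Xm
    y <- array(0, c(m$cout, 2L * L, B))
    y[, seq(1L, 2L * L, 2L), ] <- Y1
    y[, seq(2L, 2L * L, 2L), ] <- Y2
    m$cache <- list(Xm = Xm, L = L, B = B)
    y + m$params$b
  }
  m$backward <- function(dy) {
    cc <- m$cache
    D1 <- flat3(dy[, seq(1L, 2L * cc$L, 2L), , drop = FALSE])
    D2 <- flat3(dy[, seq(2L, 2L * cc$L, 2L), , drop = FALSE])
    m$grads$W[, , 1L] <- m$grads$W[, , 1L] + tcrossprod(D1, cc$Xm)
    m$grads$W[, , 2L] <- m$grads$W[, , 2L] + tcrossprod(D2, cc$Xm)
    m$grads$b <- m$grads$b + rowSums(D1) + rowSums(D2)
    dXm <- crossprod(matrix(m$params$W[, , 1L], m$cout, m$cin), D1) +
           crossprod(matrix(m$params$W[, , 2L], m$cout, m$cin), D2)
    unflat3(dXm, m$cin, cc$L, cc$B)
  }
  m
}

# ---- fixed (parameter-free) linear x2 upsampling, used by auxiliary heads ---

upsample2_linear <- function(x) {
  d <- dim(x); C <- d[1L]; L <- d[2L]; B <- d[3L]
  xn <- x[, c(2:L, L), , drop = FALSE]   # next sample, edge replicated
  y <- array(0, c(C, 2L * L, B))
  y[, seq(1L, 2L * L, 2L), ] <- x
  y[, seq(2L, 2L * L, 2L), ] <- (x + xn) / 2
  y
}

upsample2_linear_bw <- function(dy) {
  d <- dim(dy); C <- d[1L]; L2 <- d[2L]; B <- d[3L]
  L <- L2 %/% 2L
  dodd <- dy[, seq(1L, L2, 2L), , drop = FALSE]
  deven <- dy[, seq(2L, L2, 2L), , drop = FALSE]
  dx <- dodd + deven / 2
  if (L > 1L) {
    dx[, 2:L, ] <- dx[, 2:L, , drop = FALSE] + deven[, 1:(L - 1L), , drop = FALSE] / 2
  }
  dx[, L, ] <- dx[, L, ] + deven[, L, ] / 2    # edge replication
  dx
}
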