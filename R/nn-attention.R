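# Channel attention for skip connections: classic squeeze-and-excitation with
# a bottlenecked fully connected excitation, and the recurrent variant that
# replaces the fully connected pair with a GRU scanned across the channel
# descriptors.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Global average pooling of a feature map to channel descriptors
#'
#' Each channel is reduced to the mean of its samples (the "squeeze" step of
#' squeeze-and-excitation, specialized to 1-D feature maps).
#'
#' @param x A `C x L` matrix (channels by length) or a `C x L x B` array.
#' @return A length-`C` vector (matrix input) or a `C x B` matrix.
#' @export
#' @examples
#' squeeze_channels(rbind(c(1, 3), c(-2, 2)))  # c(2, 0)
squeeze_channels <- function(x) {
  if (is.matrix(x)) return(rowMeans(x))
  d <- dim(x)
  stopifnot(length(d) == 3L)
  colSums(aperm(x, c(2L, 1L, 3L))) / d[2L]
}

#' One step of a gated recurrent unit (GRU)
#'
#' Implements the gate formulation
#' \deqn{r_t = \sigma(W_r [h_{t-1}, x_t] + b_r)}
#' \deqn{z_t = \sigma(W_z [h_{t-1}, x_t] + b_z)}
#' \deqn{\tilde h_t = \tanh(W [r_t \odot h_{t-1}, x_t] + b)}
#' \deqn{h_t = (1 - z_t) \odot h_{t-1} + z_t \odot \tilde h_t}
#' where the update gate weighs the candidate state (so zero parameters give
#' \eqn{h_t = 0.5\, h_{t-1}}).
#'
#' @param x_t Input at this step: length-`n` vector or `n x B` matrix.
#' @param h_prev Previous hidden state: length-`H` vector or `H x B` matrix.
#' @param params List with `W_r`, `W_z`, `W` (each `H x (H + n)`) and
#'   `b_r`, `b_z`, `b` (length `H`).
#' @return The new hidden state, same shape as `h_prev`.
#' @export
gru_step <- function(x_t, h_prev, params) {
  gru_cell(x_t, h_prev, params)$h
}

# internal: full cell returning intermediates for backpropagation
gru_cell <- function(x_t, h_prev, params) {
  vec_in <- !is.matrix(h_prev)
  if (vec_in) {
    h_prev <- matrix(h_prev, ncol = 1L)
    x_t <- matrix(x_t, ncol = 1L)
  } else if (!is.matrix(x_t)) {
    x_t <- matrix(x_t, nrow = 1L)
  }
  H <- nrow(h_prev)
  if (ncol(params$W_r) != H + nrow(x_t)) {
    stop("GRU parameter shapes inconsistent with [h, x] size ",
         H + nrow(x_t), call. = FALSE)
  }
  U <- rbind(h_prev, x_t)
  r <- sigmoid(params$W_r %*% U + params$b_r)
  z <- sigmoid(params$W_z %*% U + params$b_z)
  U2 <- rbind(r * h_prev, x_t)
  htil <- tanh(params$W %*% U2 + params$b)
  h <- (1 - z) * h_prev + z * htil
  if (vec_in) h <- drop(h)
  list(h = h, r = r, z = z, htil = htil, U = U, U2 = U2, h_prev = h_prev)
}

# internal: random GRU + projection parameters for C channels, hidden size H
se_gru_params <- function(C, H, n_in = 1L) {
  lim <- 1 / sqrt(H)
  ru <- function(n) stats::runif(n, -lim, lim)
  list(
    W_r = matrix(ru(H * (H + n_in)), H), b_r = ru(H),
    W_z = matrix(ru(H * (H + n_in)), H), b_z = ru(H),
    W = matrix(ru(H * (H + n_in)), H), b = ru(H),
    w_p = matrix(ru(H), 1L), b_p = ru(1L)
  )
}

#' Channel excitation weights from a GRU scanned over channel descriptors
#'
#' Squeezes the feature map to per-channel descriptors, scans them as a
#' length-`C` sequence of scalar inputs through a GRU (hidden size `C/r`),
#' and projects each hidden state to one scalar passed through a sigmoid,
#' yielding one weight in (0, 1) per channel. The recurrence makes the
#' weights order-sensitive, unlike the fully connected excitation.
#'
#' @param x A `C x L` matrix or `C x L x B` array.
#' @param params Parameter list as produced inside the model: GRU matrices
#'   `W_r`, `W_z`, `W`, biases `b_r`, `b_z`, `b`, and the projection `w_p`
#'   (`1 x H`), `b_p` (scalar).
#' @return Length-`C` weight vector in (0, 1) (or `C x B` matrix).
#' @export
se_gru_weights <- function(x, params) {
  z <- squeeze_channels(x)
  single <- !is.matrix(z)
  zm <- if (single) matrix(z, ncol = 1L) else z
  C <- nrow(zm); B <- ncol(zm)
  H <- nrow(params$W_r)
  h <- matrix(0, H, B)
  s <- matrix(0, C, B)
  for (t in seq_len(C)) {
    h <- gru_cell(matrix(zm[t, ], 1L, B), h, params)$h
    s[t, ] <- sigmoid(params$w_p %*% h + params$b_p)
  }
  if (single) drop(s) else s
}

#' Apply per-channel excitation weights to a feature map
#'
#' Scales channel `c` of the input by weight `s[c]`; with all-ones weights
#' this is the identity.
#'
#' @param x A `C x L` matrix or `C x L x B` array.
#' @param s Length-`C` weights (or `C x B` matrix for batched input).
#' @return Feature map of the same shape.
#' @export
se_apply <- function(x, s) {
  if (is.matrix(x)) {
    stopifnot(length(s) == nrow(x))
    return(x * as.vector(s))
  }
  d <- dim(x)
  if (!is.matrix(s)) s <- matrix(s, d[1L], d[3L])
  stopifnot(nrow(s) == d[1L], ncol(s) == d[3L])
  Xm <- flat3(x)
  Sm <- s[, rep(seq_len(d[3L]), each = d[2L]), drop = FALSE]
  unflat3(Xm * Sm, d[1L], d[2L], d[3L])
}

# ---- SE module with fully connected excitation (batched layer) --------------

nn_se_fc <- function(C, r = 8L) {
  if (C %% r != 0L) {
    stop("SE reduction r = ", r, " must divide the channel count C = ", C,
         call. = FALSE)
  }
  H <- C %/% r
  m <- new_module()
  m$C <- C; m$H <- H
  lim1 <- sqrt(2 / C); lim2 <- sqrt(2 / H)
  m$params$W1 <- matrix(stats::rnorm(H * C, sd = lim1), H, C)
  m$params$b1 <- numeric(H)
  m$params$W2 <- matrix(stats::rnorm(C * H, sd = lim2), C, H)
  m$params$b2 <- numeric(C)
  zero_grads_module(m)
  m$forward <- function(x, train = TRUE) {
    d <- dim(x); L <- d[2L]; B <- d[3L]
    z <- squeeze_channels(x)
    pre1 <- m$params$W1 %*% z + m$params$b1
    hh <- pre1 * (pre1 > 0)
    s <- sigmoid(m$params$W2 %*% hh + m$params$b2)
    Xm <- flat3(x)
    Sm <- s[, rep(seq_len(B), each = L), drop = FALSE]
    m$cache <- list(Xm = Xm, Sm = Sm, s = s, hh = hh, pre1 = pre1, z = z,
                    L = L, B = B)
    unflat3(Xm * Sm, m$C, L, B)
  }
  m$backward <- function(dy) {
    cc <- m$cache
    dYm <- flat3(dy)
    dXm <- dYm * cc$Sm
    tmp <- unflat3(dYm * cc$Xm, m$C, cc$L, cc$B)
    ds <- colSums(aperm(tmp, c(2L, 1L, 3L)))         # C x B
    dpre2 <- ds * cc$s * (1 - cc$s)
    m$grads$W2 <- m$grads$W2 + tcrossprod(dpre2, cc$hh)
    m$grads$b2 <- m$grads$b2 + rowSums(dpre2)
    dh <- crossprod(m$params$W2, dpre2)
    dpre1 <- dh * (cc$pre1 > 0)
    m$grads$W1 <- m$grads$W1 + tcrossprod(dpre1, cc$z)
    m$grads$b1 <- m$grads$b1 + rowSums(dpre1)
    dz <- crossprod(m$params$W1, dpre1)              # C x B
    dXm <- dXm + dz[, rep(seq_len(cc$B), each = cc$L), drop = FALSE] / cc$L
    unflat3(dXm, m$C, cc$L, cc$B)
  }
  m
}

# ---- SE module with GRU excitation (batched layer) --------------------------

nn_se_gru <- function(C, r = 8L) {
  if (C %% r != 0L) {
    stop("SE reduction r = ", r, " must divide the channel count C = ", C,
         call. = FALSE)
  }
  H <- C %/% r
  m <- new_module()
  m$C <- C; m$H <- H
  m$params <- se_gru_params(C, H)
  zero_grads_module(m)
  m$forward <- function(x, train = TRUE) {
    d <- dim(x); L <- d[2L]; B <- d[3L]
    z <- squeeze_channels(x)
    zm <- if (is.matrix(z)) z else matrix(z, ncol = 1L)
    h <- matrix(0, H, B)
    s <- matrix(0, C, B)
    steps <- vector("list", C)
    for (t in seq_len(C)) {
      st <- gru_cell(matrix(zm[t, ], 1L, B), h, m$params)
      h <- st$h
      st$pre_p <- m$params$w_p %*% h + m$params$b_p
      s[t, ] <- sigmoid(st$pre_p)
      steps[[t]] <- st
    }
    Xm <- flat3(x)
    Sm <- s[, rep(seq_len(B), each = L), drop = FALSE]
    m$cache <- list(Xm = Xm, Sm = Sm, s = s, steps = steps, L = L, B = B)
    unflat3(Xm * Sm, C, L, B)
  }
  m$backward <- function(dy) {
    cc <- m$cache
    L <- cc$L; B <- cc$B
    dYm <- flat3(dy)
    dXm <- dYm * cc$Sm
    tmp <- unflat3(dYm * cc$Xm, C, L, B)
    ds <- colSums(aperm(tmp, c(2L, 1L, 3L)))         # C x B
    p <- m$params
    dh <- matrix(0, H, B)
    dz_desc <- matrix(0, C, B)                       # grad wrt descriptors
    for (t in rev(seq_len(C))) {
      st <- cc$steps[[t]]
      s_t <- cc$s[t, ]
      dpre_p <- matrix(ds[t, ] * s_t * (1 - s_t), 1L, B)
      m$grads$w_p <- m$grads$w_p + tcrossprod(dpre_p, st$h)
      m$grads$b_p <- m$grads$b_p + sum(dpre_p)
      dh <- dh + crossprod(p$w_p, dpre_p)
      # through h = (1-z) h_prev + z htil
      dzt <- dh * (st$htil - st$h_prev)
      dhtil <- dh * st$z
      dhprev <- dh * (1 - st$z)
      dpre_c <- dhtil * (1 - st$htil^2)
      m$grads$W <- m$grads$W + tcrossprod(dpre_c, st$U2)
      m$grads$b <- m$grads$b + rowSums(dpre_c)
      dU2 <- crossprod(p$W, dpre_c)
      drh <- dU2[seq_len(H), , drop = FALSE]
      dxt <- dU2[H + 1L, ]
      dr <- drh * st$h_prev
      dhprev <- dhprev + drh * st$r
      dpre_r <- dr * st$r * (1 - st$r)
      m$grads$W_r <- m$grads$W_r + tcrossprod(dpre_r, st$U)
      m$grads$b_r <- m$grads$b_r + rowSums(dpre_r)
      dU <- crossprod(p$W_r, dpre_r)
      dpre_z <- dzt * st$z * (1 - st$z)
      m$grads$W_z <- m$grads$W_z + tcrossprod(dpre_z, st$U)
      m$grads$b_z <- m$grads$b_z + rowSums(dpre_z)
      dU <- dU + crossprod(p$W_z, dpre_z)
      dhprev <- dhprev + dU[seq_len(H), , drop = FALSE]
      dxt <- dxt + dU[H + 1L, ]
      dz_desc[t, ] <- dxt
      dh <- dhprev
    }
    dXm <- dXm + dz_desc[, rep(seq_len(B), each = L), drop = FALSE] / L
    unflat3(dXm, C, L, B)
  }
  m
}
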