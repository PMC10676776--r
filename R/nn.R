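# Neural-network primitives: scaled dot-product attention, ELU, BCE, 1D
# convolution, average pooling and nearest-neighbour up-sampling, each with a
# hand-derived backward pass. Token tensors are 3D arrays (n, L, C):
# sample x token x channel.

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K^T / sqrt(d_k)) V` with the softmax applied row-wise,
#' so every output row is a convex combination of the value rows.
#'
#' @param q Query matrix (n x d_k).
#' @param k Key matrix (m x d_k).
#' @param v Value matrix (m x d_v).
#' @return An n x d_v matrix.
#' @examples
#' scaled_dot_attention(diag(2), diag(2), diag(2))
#' @export
scaled_dot_attention <- function(q, k, v) {
  q <- as.matrix(q); k <- as.matrix(k); v <- as.matrix(v)
  if (ncol(q) != ncol(k)) {
    stop("`q` and `k` must have the same number of columns (d_k)",
         call. = FALSE)
  }
  if (nrow(k) != nrow(v)) {
    stop("`k` and `v` must have the same number of rows", call. = FALSE)
  }
  a <- row_softmax(q %*% t(k) / sqrt(ncol(q)))
  a %*% v
}

# numerically stable row-wise softmax (max.col is C-level; ties.method
# "first" keeps it deterministic)
row_softmax <- function(s) {
  mx <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - mx)
  e / rowSums(e)
}

#' Exponential linear unit
#'
#' `elu(x) = x` for `x > 0` and `alpha * (exp(x) - 1)` otherwise: continuous
#' at 0, monotone, lower-bounded by `-alpha`. Negative outputs keep the mean
#' activation near zero, which speeds up learning.
#'
#' @param x Numeric vector/array.
#' @param alpha Positive scale of the negative saturation (default 1).
#' @return Object shaped like `x`.
#' @export
elu <- function(x, alpha = 1) {
  stopifnot(alpha > 0)
  neg <- x <= 0
  x[neg] <- alpha * (exp(x[neg]) - 1)
  x
}

# derivative given input x and output y = elu(x): 1 for x > 0, y + alpha else
elu_grad <- function(x, y, alpha = 1) {
  g <- array(1, dim = dim(x) %||% length(x))
  neg <- x <= 0
  g[neg] <- y[neg] + alpha
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binary cross-entropy loss
#'
#' `-[y log(yhat) + (1 - y) log(1 - yhat)]`, averaged over samples.
#' Predictions are clamped to `[eps, 1 - eps]` before the logarithms.
#'
#' @param y Binary labels (0/1 vector).
#' @param y_hat Predicted probabilities in `[0, 1]`.
#' @param eps Clamping constant (default 1e-7).
#' @return Mean loss (non-negative scalar).
#' @export
bce_loss <- function(y, y_hat, eps = 1e-7) {
  stopifnot(length(y) == length(y_hat), all(y %in% c(0, 1)))
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- tensor helpers ---------------------------------------------------------

# n x D feature matrix -> (n, L, 3) token array: one token per x/y/z triple
tokens_from_features <- function(x) {
  n <- nrow(x); d <- ncol(x)
  stopifnot(d %% 3L == 0L)
  aperm(array(x, dim = c(n, 3L, d %/% 3L)), c(1L, 3L, 2L))
}

tensor_to_mat <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1L] * d[2L], d[3L])
  a
}

mat_to_tensor <- function(m, n, l) {
  array(m, dim = c(n, l, ncol(m)))
}

# shift a token tensor by `o` positions (token l of output = token l + o of
# input), zero-filled at the boundary
shift_tokens <- function(a, o) {
  if (o == 0L) return(a)
  d <- dim(a)
  out <- array(0, dim = d)
  l <- d[2L]
  if (o > 0L && o < l) {
    out[, seq_len(l - o), ] <- a[, (o + 1L):l, , drop = FALSE]
  } else if (o < 0L && -o < l) {
    out[, (1L - o):l, ] <- a[, seq_len(l + o), , drop = FALSE]
  }
  out
}

# ---- attention layer --------------------------------------------------------

# internally token-major (L, d, n): per-sample slices are contiguous
attn_forward <- function(x, wq, wk, wv) {
  d <- dim(x); n <- d[1L]; l <- d[2L]
  xm <- tensor_to_mat(x)
  dk <- ncol(wq); dv <- ncol(wv)
  qp <- aperm(mat_to_tensor(xm %*% wq, n, l), c(2L, 3L, 1L))
  kp <- aperm(mat_to_tensor(xm %*% wk, n, l), c(2L, 3L, 1L))
  vp <- aperm(mat_to_tensor(xm %*% wv, n, l), c(2L, 3L, 1L))
  scale <- 1 / sqrt(dk)
  # all n score matrices stacked row-wise for one batched softmax
  s <- matrix(0, n * l, l)
  for (i in seq_len(n)) {
    s[((i - 1L) * l + 1L):(i * l), ] <- tcrossprod(qp[, , i], kp[, , i])
  }
  a <- row_softmax(s * scale)
  yp <- array(0, dim = c(l, dv, n))
  for (i in seq_len(n)) {
    yp[, , i] <- a[((i - 1L) * l + 1L):(i * l), ] %*% vp[, , i]
  }
  list(y = aperm(yp, c(3L, 1L, 2L)),
       cache = list(x = x, qp = qp, kp = kp, vp = vp, a = a,
                    wq = wq, wk = wk, wv = wv))
}

attn_backward <- function(dy, cache) {
  x <- cache$x; d <- dim(x); n <- d[1L]; l <- d[2L]
  dk <- ncol(cache$wq)
  scale <- 1 / sqrt(dk)
  dyp <- aperm(dy, c(2L, 3L, 1L))
  dqp <- array(0, dim = dim(cache$qp))
  dkp <- array(0, dim = dim(cache$kp))
  dvp <- array(0, dim = dim(cache$vp))
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * l + 1L):(i * l)
    a <- cache$a[rows, , drop = FALSE]
    dyi <- dyp[, , i]
    da <- tcrossprod(dyi, cache$vp[, , i])
    dvp[, , i] <- crossprod(a, dyi)
    ds <- a * (da - rowSums(a * da)) * scale
    dqp[, , i] <- ds %*% cache$kp[, , i]
    dkp[, , i] <- crossprod(ds, cache$qp[, , i])
  }
  xm <- tensor_to_mat(x)
  dqm <- tensor_to_mat(aperm(dqp, c(3L, 1L, 2L)))
  dkm <- tensor_to_mat(aperm(dkp, c(3L, 1L, 2L)))
  dvm <- tensor_to_mat(aperm(dvp, c(3L, 1L, 2L)))
  dxm <- tcrossprod(dqm, cache$wq) + tcrossprod(dkm, cache$wk) +
    tcrossprod(dvm, cache$wv)
  list(dx = mat_to_tensor(dxm, n, l),
       dwq = crossprod(xm, dqm),
       dwk = crossprod(xm, dkm),
       dwv = crossprod(xm, dvm))
}

# ---- 1D convolution (same zero padding) -------------------------------------

conv_offsets <- function(kernel) {
  stopifnot(kernel %% 2L == 1L)
  seq.int(-(kernel - 1L) %/% 2L, (kernel - 1L) %/% 2L)
}

conv_forward <- function(x, w, b) {
  d <- dim(x); n <- d[1L]; l <- d[2L]
  offsets <- conv_offsets(length(w))
  cout <- ncol(w[[1L]])
  ym <- matrix(rep(b, each = n * l), n * l, cout)
  for (j in seq_along(offsets)) {
    ym <- ym + tensor_to_mat(shift_tokens(x, offsets[j])) %*% w[[j]]
  }
  list(y = mat_to_tensor(ym, n, l), cache = list(x = x, w = w))
}

conv_backward <- function(dy, cache) {
  x <- cache$x; w <- cache$w
  d <- dim(x); n <- d[1L]; l <- d[2L]
  offsets <- conv_offsets(length(w))
  dym <- tensor_to_mat(dy)
  dw <- vector("list", length(w))
  dx <- array(0, dim = d)
  for (j in seq_along(offsets)) {
    dw[[j]] <- crossprod(tensor_to_mat(shift_tokens(x, offsets[j])), dym)
    dx <- dx + shift_tokens(mat_to_tensor(tcrossprod(dym, w[[j]]), n, l),
                            -offsets[j])
  }
  list(dx = dx, dw = dw, db = colSums(dym))
}

# ---- average pooling and nearest-neighbour up-sampling ----------------------

pool_forward <- function(x, p) {
  d <- dim(x); n <- d[1L]; l <- d[2L]; cc <- d[3L]
  stopifnot(l %% p == 0L)
  l2 <- l %/% p
  xp <- array(x, dim = c(n, p, l2, cc))
  y <- array(0, dim = c(n, l2, cc))
  for (r in seq_len(p)) {
    y <- y + array(xp[, r, , , drop = FALSE], dim = c(n, l2, cc))
  }
  y / p
}

pool_backward <- function(dy, p) {
  d <- dim(dy); n <- d[1L]; l2 <- d[2L]; cc <- d[3L]
  idx <- rep(seq_len(l2), each = p)
  array(dy[, idx, , drop = FALSE], dim = c(n, l2 * p, cc)) / p
}

upsample_forward <- function(x, f) {
  d <- dim(x)
  idx <- rep(seq_len(d[2L]), each = f)
  array(x[, idx, , drop = FALSE], dim = c(d[1L], d[2L] * f, d[3L]))
}

upsample_backward <- function(dy, f) {
  d <- dim(dy); n <- d[1L]; l2 <- d[2L] %/% f; cc <- d[3L]
  dyp <- array(dy, dim = c(n, f, l2, cc))
  out <- array(0, dim = c(n, l2, cc))
  for (r in seq_len(f)) {
    out <- out + array(dyp[, r, , , drop = FALSE], dim = c(n, l2, cc))
  }
  out
}
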