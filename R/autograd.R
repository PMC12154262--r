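## A compact reverse-mode automatic-differentiation core for the
## segmentation network. Values are numeric arrays (H x W x C feature maps);
## a tape records op nodes in creation order and backward() replays it in
## reverse. Convolutions use im2col + BLAS matrix multiplication.
##
## Conventions: 3x3 convolutions are cross-correlations with 'same' zero
## padding; a kernel array [k, k, c_in, c_out] flattens column-major into the
## (k*k*c_in) x c_out weight matrix used throughout (see conv_kernel_matrix).

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 64L)
  t$k <- 0L
  t
}

ag_node <- function(tape, val, bw = NULL, need = TRUE) {
  n <- new.env(parent = emptyenv())
  n$val <- val; n$grad <- NULL; n$bw <- bw; n$need <- need
  if (!is.null(tape) && !is.null(bw)) {
    tape$k <- tape$k + 1L
    if (tape$k > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$k]] <- n
  }
  n
}

ag_const <- function(val) ag_node(NULL, val, need = FALSE)

ag_param <- function(val) {
  n <- ag_node(NULL, val, need = TRUE)
  n$is_param <- TRUE
  n
}

ag_acc <- function(n, g) {
  if (isTRUE(n$need))
    n$grad <- if (is.null(n$grad)) g else n$grad + g
  invisible(NULL)
}

## seed the output node's gradient and sweep the tape in reverse
ag_backward <- function(tape, out, seed) {
  out$grad <- seed
  for (i in rev(seq_len(tape$k))) {
    n <- tape$nodes[[i]]
    if (!is.null(n$grad)) n$bw(n)
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## --- im2col / col2im -------------------------------------------------------

im2col <- function(xv, k, stride, pad) {
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  if (pad > 0) {
    xp <- array(0, c(Hp, Wp, C))
    xp[pad + seq_len(H), pad + seq_len(W), ] <- xv
  } else xp <- xv
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  ri <- seq(1L, by = stride, length.out = Ho)
  cj <- seq(1L, by = stride, length.out = Wo)
  col <- matrix(0, Ho * Wo, k * k * C)
  idx <- 1L
  for (c in seq_len(C)) for (kj in seq_len(k)) for (ki in seq_len(k)) {
    col[, idx] <- xp[ri + ki - 1L, cj + kj - 1L, c]
    idx <- idx + 1L
  }
  list(col = col, Ho = Ho, Wo = Wo)
}

col2im <- function(dcol, d, k, stride, pad, Ho, Wo) {
  H <- d[1]; W <- d[2]; C <- d[3]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  dxp <- array(0, c(Hp, Wp, C))
  ri <- seq(1L, by = stride, length.out = Ho)
  cj <- seq(1L, by = stride, length.out = Wo)
  idx <- 1L
  for (c in seq_len(C)) for (kj in seq_len(k)) for (ki in seq_len(k)) {
    rr <- ri + ki - 1L; cc <- cj + kj - 1L
    dxp[rr, cc, c] <- dxp[rr, cc, c] + matrix(dcol[, idx], Ho, Wo)
    idx <- idx + 1L
  }
  if (pad > 0) dxp[pad + seq_len(H), pad + seq_len(W), , drop = FALSE] else dxp
}

#' Flatten a 4D kernel array into the internal convolution weight matrix
#'
#' @param kernels array `[k, k, c_in, c_out]`; entry `[ki, kj, c, o]` is the
#'   weight connecting input channel `c` at kernel offset `(ki, kj)` (row,
#'   col; centre at `((k+1)/2, (k+1)/2)`) to output channel `o`.
#' @return `(k*k*c_in) x c_out` matrix.
#' @export
conv_kernel_matrix <- function(kernels) {
  d <- dim(kernels)
  matrix(kernels, d[1] * d[2] * d[3], d[4])
}

## --- ops -------------------------------------------------------------------

ag_conv2d <- function(tape, x, W, b, stride = 1L, pad = 1L, k = 3L) {
  cc <- im2col(x$val, k, stride, pad)
  cout <- ncol(W$val)
  ymat <- cc$col %*% W$val
  ymat <- ymat + rep(b$val, each = nrow(ymat))
  y <- array(ymat, c(cc$Ho, cc$Wo, cout))
  d_in <- dim(x$val)
  ag_node(tape, y, bw = function(n) {
    dY <- matrix(n$grad, cc$Ho * cc$Wo, cout)
    ag_acc(W, crossprod(cc$col, dY))
    ag_acc(b, colSums(dY))
    if (isTRUE(x$need))
      ag_acc(x, col2im(dY %*% t(W$val), d_in, k, stride, pad, cc$Ho, cc$Wo))
  })
}

ag_conv1x1 <- function(tape, x, W, b) {
  d <- dim(x$val)
  xm <- matrix(x$val, d[1] * d[2], d[3])
  cout <- ncol(W$val)
  ymat <- xm %*% W$val + rep(b$val, each = d[1] * d[2])
  ag_node(tape, array(ymat, c(d[1], d[2], cout)), bw = function(n) {
    dY <- matrix(n$grad, d[1] * d[2], cout)
    ag_acc(W, crossprod(xm, dY))
    ag_acc(b, colSums(dY))
    if (isTRUE(x$need)) ag_acc(x, array(dY %*% t(W$val), d))
  })
}

ag_relu <- function(tape, x) {
  pos <- x$val > 0
  ag_node(tape, x$val * pos, bw = function(n) {
    if (isTRUE(x$need)) ag_acc(x, n$grad * pos)
  })
}

ag_add <- function(tape, a, b) {
  ag_node(tape, a$val + b$val, bw = function(n) {
    ag_acc(a, n$grad); ag_acc(b, n$grad)
  })
}

ag_mul <- function(tape, a, b) {
  ag_node(tape, a$val * b$val, bw = function(n) {
    ag_acc(a, n$grad * b$val); ag_acc(b, n$grad * a$val)
  })
}

ag_concat_c <- function(tape, xs) {
  chans <- vapply(xs, function(x) dim(x$val)[3], 1)
  off <- cumsum(c(0, chans))
  d <- dim(xs[[1]]$val)
  y <- array(0, c(d[1], d[2], sum(chans)))
  for (i in seq_along(xs)) y[, , off[i] + seq_len(chans[i])] <- xs[[i]]$val
  ag_node(tape, y, bw = function(n) {
    for (i in seq_along(xs))
      ag_acc(xs[[i]], n$grad[, , off[i] + seq_len(chans[i]), drop = FALSE])
  })
}

ag_slice_c <- function(tape, x, idx) {
  d <- dim(x$val)
  ag_node(tape, x$val[, , idx, drop = FALSE], bw = function(n) {
    if (isTRUE(x$need)) {
      g <- array(0, d)
      g[, , idx] <- n$grad
      ag_acc(x, g)
    }
  })
}

## separable interpolation: y[,,c] = A %*% x[,,c] %*% t(B)
ag_upsample <- function(tape, x, A, B) {
  d <- dim(x$val)
  C <- d[3]
  y <- array(0, c(nrow(A), nrow(B), C))
  for (c in seq_len(C)) y[, , c] <- A %*% x$val[, , c] %*% t(B)
  ag_node(tape, y, bw = function(n) {
    if (isTRUE(x$need)) {
      g <- array(0, d)
      for (c in seq_len(C)) g[, , c] <- crossprod(A, n$grad[, , c]) %*% B
      ag_acc(x, g)
    }
  })
}

## interpolation matrix (n_out x n_in), half-pixel-centre alignment
interp_matrix <- function(n_in, n_out, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  M <- matrix(0, n_out, n_in)
  if (method == "nearest") {
    j <- pmin(pmax(floor(src + 0.5), 0), n_in - 1)
    M[cbind(seq_len(n_out), j + 1)] <- 1
  } else {
    j0 <- floor(src)
    w <- src - j0
    j0c <- pmin(pmax(j0, 0), n_in - 1)
    j1c <- pmin(pmax(j0 + 1, 0), n_in - 1)
    for (i in seq_len(n_out)) {
      M[i, j0c[i] + 1] <- M[i, j0c[i] + 1] + (1 - w[i])
      M[i, j1c[i] + 1] <- M[i, j1c[i] + 1] + w[i]
    }
  }
  M
}

## per-sample (instance) normalization over spatial positions, per channel,
## with learned affine parameters: the same statistics are used in training
## and inference, so the two paths coincide exactly
ag_bn <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- dim(x$val)
  m <- d[1] * d[2]; C <- d[3]
  xm <- matrix(x$val, m, C)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = m)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = m)
  ymat <- xhat * rep(gamma$val, each = m) + rep(beta$val, each = m)
  ag_node(tape, array(ymat, d), bw = function(n) {
    dY <- matrix(n$grad, m, C)
    ag_acc(gamma, colSums(dY * xhat))
    ag_acc(beta, colSums(dY))
    if (isTRUE(x$need)) {
      ## backward through the per-sample statistics
      dxhat <- dY * rep(gamma$val, each = m)
      dvar <- colSums(dxhat * xc) * (-0.5) * istd^3
      dmu <- colSums(-dxhat * rep(istd, each = m))
      dx <- dxhat * rep(istd, each = m) +
        xc * rep(2 * dvar / m, each = m) +
        rep(dmu / m, each = m)
      ag_acc(x, array(dx, d))
    }
  })
}

## --- Adam ------------------------------------------------------------------

adam_state <- function() {
  s <- new.env(parent = emptyenv())
  s$t <- 0L
  s
}

adam_step <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    if (is.null(p$m)) { p$m <- p$grad * 0; p$v <- p$grad * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    p$val <- p$val - lr * (p$m / bc1) / (sqrt(p$v / bc2) + eps)
  }
  invisible(NULL)
}
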