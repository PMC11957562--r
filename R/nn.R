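## Minimal 1-D convolutional network engine (forward + exact backprop) used
## by the sequence-to-profile model. Channels-first matrices: x is
## [channels x length]. Convolutions are implemented as a single matrix
## multiply against an im2col view; the backward pass scatters gradients
## tap by tap. Everything is deterministic given the initialization seed.

.conv_pad <- function(k, dilation) (k - 1L) %/% 2L * dilation

## forward: returns list(out, xp) where xp is the (padded) input retained
## for the backward pass.
conv1d_forward <- function(x, W, b, dilation = 1L, pad = c("same", "valid")) {
  pad <- match.arg(pad)
  k <- dim(W)[3]
  c_in <- dim(W)[2]
  c_out <- dim(W)[1]
  L <- ncol(x)
  if (nrow(x) != c_in) stop("channel mismatch in conv1d")
  if (pad == "same") {
    pw <- .conv_pad(k, dilation)
    xp <- cbind(matrix(0, c_in, pw), x, matrix(0, c_in, pw))
    Lout <- L
  } else {
    xp <- x
    Lout <- L - (k - 1L) * dilation
    if (Lout < 1L) stop("valid convolution output would be empty")
  }
  Xc <- matrix(0, c_in * k, Lout)
  for (j in seq_len(k)) {
    Xc[((j - 1L) * c_in + 1L):(j * c_in), ] <-
      xp[, seq_len(Lout) + (j - 1L) * dilation, drop = FALSE]
  }
  Wm <- matrix(W, c_out, c_in * k)  # dim order (c_out, c_in, k) flattens right
  out <- Wm %*% Xc + b
  list(out = out, Xc = Xc, Lin = L)
}

conv1d_backward <- function(dOut, x_cache, W, dilation = 1L,
                            pad = c("same", "valid")) {
  pad <- match.arg(pad)
  k <- dim(W)[3]
  c_in <- dim(W)[2]
  c_out <- dim(W)[1]
  Xc <- x_cache$Xc
  Lout <- ncol(dOut)
  db <- rowSums(dOut)
  dWm <- dOut %*% t(Xc)
  dW <- array(dWm, dim = dim(W))
  Wm <- matrix(W, c_out, c_in * k)
  dXc <- crossprod(Wm, dOut)  # (c_in*k) x Lout
  Lp <- if (pad == "same") x_cache$Lin + 2L * .conv_pad(k, dilation) else
    x_cache$Lin
  dxp <- matrix(0, c_in, Lp)
  for (j in seq_len(k)) {
    cols <- seq_len(Lout) + (j - 1L) * dilation
    dxp[, cols] <- dxp[, cols] + dXc[((j - 1L) * c_in + 1L):(j * c_in), ,
                                     drop = FALSE]
  }
  dx <- if (pad == "same") {
    pw <- .conv_pad(k, dilation)
    dxp[, (pw + 1L):(pw + x_cache$Lin), drop = FALSE]
  } else dxp
  list(dW = dW, db = db, dx = dx)
}

## He-style initialization, deterministic given seed.
.init_conv <- function(c_out, c_in, k) {
  sd <- sqrt(2 / (c_in * k))
  list(W = array(stats::rnorm(c_out * c_in * k, 0, sd), c(c_out, c_in, k)),
       b = numeric(c_out))
}

## Build the parameter list for a profile model configuration.
nn_init_params <- function(config, seed = 1) {
  with_seed(seed, {
    F <- config$n_filters
    layers <- vector("list", config$n_conv_layers)
    layers[[1]] <- .init_conv(F, 4L, config$first_kernel)
    for (l in 2:config$n_conv_layers) {
      layers[[l]] <- .init_conv(F, F, config$dilated_kernel)
    }
    list(
      trunk = layers,
      head_profile = .init_conv(2L, F, config$profile_kernel),
      head_1x1 = .init_conv(2L, 4L, 1L),
      dense1 = list(W = matrix(stats::rnorm(F, 0, sqrt(1 / F)), 1, F),
                    b = 0),
      dense2 = list(W = matrix(stats::rnorm(2, 0, sqrt(1 / 2)), 1, 2),
                    b = 0)
    )
  })
}

## Forward pass. x: 4 x input_length one-hot; ctrl_profile: 2 x
## output_length; ctrl_logtot: scalar. Returns logits (2 x output_length),
## log_total (scalar) and the cache needed for backprop.
nn_forward <- function(params, config, x, ctrl_profile = NULL,
                       ctrl_logtot = 0) {
  n <- config$n_conv_layers
  out_len <- config$output_length
  if (is.null(ctrl_profile) || !config$use_control) {
    ctrl_profile <- matrix(0, 2, out_len)
    if (!config$use_control) ctrl_logtot <- 0
  }
  caches <- vector("list", n)
  hs <- vector("list", n)
  pres <- vector("list", n)
  h <- x
  for (l in seq_len(n)) {
    d <- if (l == 1L) 1L else 2L^(l - 1L)
    cf <- conv1d_forward(h, params$trunk[[l]]$W, params$trunk[[l]]$b,
                         dilation = d, pad = "same")
    pre <- cf$out
    act <- pmax(pre, 0)
    h_new <- if (l == 1L) act else act + h  # residual skip from layer 2 on
    caches[[l]] <- cf
    pres[[l]] <- pre
    hs[[l]] <- h_new
    h <- h_new
  }
  ## profile head: wide valid conv, center crop, stack control, 1x1 conv
  pf <- conv1d_forward(h, params$head_profile$W, params$head_profile$b,
                       dilation = 1L, pad = "valid")
  PL <- ncol(pf$out)
  crop <- (PL - out_len) %/% 2L
  if (crop < 0 || (PL - out_len) %% 2L != 0L) {
    stop("profile head output cannot be center-cropped to output_length")
  }
  P <- pf$out[, (crop + 1L):(crop + out_len), drop = FALSE]
  Z <- rbind(P, ctrl_profile)
  zf <- conv1d_forward(Z, params$head_1x1$W, params$head_1x1$b,
                       dilation = 1L, pad = "valid")
  logits <- zf$out
  ## counts head: GAP -> dense -> concat control log-total -> dense
  g <- rowMeans(h)
  s1 <- as.numeric(params$dense1$W %*% g + params$dense1$b)
  cc <- c(s1, ctrl_logtot)
  log_total <- as.numeric(params$dense2$W %*% cc + params$dense2$b)
  list(logits = logits, log_total = log_total,
       cache = list(caches = caches, pres = pres, hs = hs, x = x, pf = pf,
                    crop = crop, PL = PL, zf = zf, Z = Z, g = g, s1 = s1,
                    ctrl_logtot = ctrl_logtot, h_last = h))
}

## Backward pass: dlogits (2 x output_length), dlog_total (scalar).
## Returns gradient structure parallel to params.
nn_backward <- function(params, config, cache, dlogits, dlog_total) {
  n <- config$n_conv_layers
  out_len <- config$output_length
  grads <- list(trunk = vector("list", n))
  ## counts head
  cc <- c(cache$s1, cache$ctrl_logtot)
  grads$dense2 <- list(W = matrix(dlog_total * cc, 1, 2), b = dlog_total)
  ds1 <- dlog_total * params$dense2$W[1, 1]
  grads$dense1 <- list(W = matrix(ds1 * cache$g, 1,
                                  length(cache$g)),
                       b = ds1)
  dg <- ds1 * as.numeric(params$dense1$W)
  Lh <- ncol(cache$h_last)
  dh <- matrix(dg / Lh, nrow = length(dg), ncol = Lh)
  ## profile head
  zb <- conv1d_backward(dlogits, cache$zf, params$head_1x1$W, 1L, "valid")
  grads$head_1x1 <- list(W = zb$dW, b = zb$db)
  dP <- zb$dx[1:2, , drop = FALSE]  # control rows get no gradient
  dPfull <- matrix(0, 2, cache$PL)
  dPfull[, (cache$crop + 1L):(cache$crop + out_len)] <- dP
  pb <- conv1d_backward(dPfull, cache$pf, params$head_profile$W, 1L, "valid")
  grads$head_profile <- list(W = pb$dW, b = pb$db)
  dh <- dh + pb$dx
  ## trunk, back through residual chain
  for (l in rev(seq_len(n))) {
    d <- if (l == 1L) 1L else 2L^(l - 1L)
    dpre <- dh * (cache$pres[[l]] > 0)
    cb <- conv1d_backward(dpre, cache$caches[[l]], params$trunk[[l]]$W,
                          d, "same")
    grads$trunk[[l]] <- list(W = cb$dW, b = cb$db)
    dh <- if (l == 1L) cb$dx else cb$dx + dh  # residual passes dh through
  }
  grads
}

## -- flat parameter utilities (for Adam and for numeric gradient checks) --

nn_flatten <- function(p) {
  unlist(list(
    trunk = lapply(p$trunk, function(l) c(as.numeric(l$W), l$b)),
    hp = c(as.numeric(p$head_profile$W), p$head_profile$b),
    h1 = c(as.numeric(p$head_1x1$W), p$head_1x1$b),
    d1 = c(as.numeric(p$dense1$W), p$dense1$b),
    d2 = c(as.numeric(p$dense2$W), p$dense2$b)), use.names = FALSE)
}

nn_unflatten <- function(v, template) {
  pos <- 0L
  take <- function(n) {
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  p <- template
  for (l in seq_along(p$trunk)) {
    W <- p$trunk[[l]]$W
    p$trunk[[l]]$W <- array(take(length(W)), dim(W))
    p$trunk[[l]]$b <- take(length(p$trunk[[l]]$b))
  }
  for (nm in c("head_profile", "head_1x1")) {
    W <- p[[nm]]$W
    p[[nm]]$W <- array(take(length(W)), dim(W))
    p[[nm]]$b <- take(length(p[[nm]]$b))
  }
  for (nm in c("dense1", "dense2")) {
    W <- p[[nm]]$W
    p[[nm]]$W <- matrix(take(length(W)), nrow(W), ncol(W))
    p[[nm]]$b <- take(length(p[[nm]]$b))
  }
  p
}

## Adam optimizer state and update over the flat parameter vector.
adam_init <- function(n_par) {
  list(m = numeric(n_par), v = numeric(n_par), t = 0L)
}

adam_step <- function(theta, grad, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(theta = theta, state = state)
}
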