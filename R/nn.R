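## Minimal CNN engine on BLAS GEMM.
##
## Activations are 4-D arrays with dims (H, W, N, C) — channels last, so a
## (H*W*N) x C matrix view is a plain `dim<-` and channel concatenation is
## contiguous. Each module is a list(type, cfg, params, state); nn_forward()
## returns list(y, cache) and nn_backward() returns list(dx, grads) with
## `grads` shaped exactly like `params`.

as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

## ---- constructors -----------------------------------------------------

nn_conv <- function(cin, cout, k = 3, stride = 1, pad = (k - 1) %/% 2,
                    dilation = 1, groups = 1, bias = FALSE) {
  stopifnot(cin %% groups == 0, cout %% groups == 0)
  cin_g <- cin %/% groups
  params <- list(W = he_init(c(k, k, cin_g, cout), k * k * cin_g))
  if (bias) params$b <- numeric(cout)
  list(type = "conv", params = params,
       cfg = list(cin = cin, cout = cout, k = k, stride = stride, pad = pad,
                  dilation = dilation, groups = groups, bias = bias))
}

nn_bn <- function(C, eps = 1e-5, momentum = 0.1) {
  list(type = "bn",
       params = list(gamma = rep(1, C), beta = rep(0, C)),
       state = new.env(parent = emptyenv()),
       cfg = list(C = C, eps = eps, momentum = momentum))
}

nn_bn1d <- function(C, eps = 1e-5, momentum = 0.1) {
  m <- nn_bn(C, eps, momentum)
  m$type <- "bn1d"
  m
}

nn_linear <- function(fin, fout, bias = TRUE) {
  params <- list(W = he_init(c(fin, fout), fin))
  if (bias) params$b <- numeric(fout)
  list(type = "linear", params = params,
       cfg = list(fin = fin, fout = fout, bias = bias))
}

nn_relu <- function() list(type = "relu", params = list(), cfg = list())
nn_avgpool <- function() list(type = "avgpool", params = list(), cfg = list())
nn_maxpool <- function() list(type = "maxpool", params = list(),
                              cfg = list(k = 3, stride = 2, pad = 1))
nn_gap <- function() list(type = "gap", params = list(), cfg = list())

## ---- conv -------------------------------------------------------------

conv_out_dim <- function(H, k, stride, pad, dilation) {
  (H + 2 * pad - ((k - 1) * dilation + 1)) %/% stride + 1
}

conv_forward <- function(mod, x) {
  cf <- mod$cfg
  d <- dim(x)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  H2 <- conv_out_dim(H, cf$k, cf$stride, cf$pad, cf$dilation)
  W2 <- conv_out_dim(W, cf$k, cf$stride, cf$pad, cf$dilation)
  xp <- if (cf$pad > 0) {
    tmp <- array(0, c(H + 2 * cf$pad, W + 2 * cf$pad, N, C))
    tmp[cf$pad + seq_len(H), cf$pad + seq_len(W), , ] <- x
    tmp
  } else x
  Y <- matrix(0, H2 * W2 * N, cf$cout)
  g_in <- split(seq_len(C), rep(seq_len(cf$groups), each = C %/% cf$groups))
  g_out <- split(seq_len(cf$cout),
                 rep(seq_len(cf$groups), each = cf$cout %/% cf$groups))
  for (i in seq_len(cf$k)) {
    rows <- seq(1 + (i - 1) * cf$dilation, by = cf$stride, length.out = H2)
    for (j in seq_len(cf$k)) {
      cols <- seq(1 + (j - 1) * cf$dilation, by = cf$stride, length.out = W2)
      slab <- as_mat(xp[rows, cols, , , drop = FALSE])
      Wk <- mod$params$W[i, j, , , drop = TRUE]
      if (is.null(dim(Wk))) Wk <- matrix(Wk, dim(mod$params$W)[3],
                                         dim(mod$params$W)[4])
      if (cf$groups == 1) {
        Y <- Y + slab %*% Wk
      } else {
        for (g in seq_len(cf$groups)) {
          Y[, g_out[[g]]] <- Y[, g_out[[g]]] +
            slab[, g_in[[g]], drop = FALSE] %*% Wk[, g_out[[g]], drop = FALSE]
        }
      }
    }
  }
  if (cf$bias) Y <- Y + rep(mod$params$b, each = nrow(Y))
  list(y = array(Y, c(H2, W2, N, cf$cout)),
       cache = list(xp = xp, dims = d, H2 = H2, W2 = W2,
                    g_in = g_in, g_out = g_out))
}

conv_backward <- function(mod, cache, dy) {
  cf <- mod$cfg
  d <- cache$dims
  H2 <- cache$H2; W2 <- cache$W2
  dY <- as_mat(dy)
  xp <- cache$xp
  dxp <- array(0, dim(xp))
  dW <- array(0, dim(mod$params$W))
  g_in <- cache$g_in; g_out <- cache$g_out
  for (i in seq_len(cf$k)) {
    rows <- seq(1 + (i - 1) * cf$dilation, by = cf$stride, length.out = H2)
    for (j in seq_len(cf$k)) {
      cols <- seq(1 + (j - 1) * cf$dilation, by = cf$stride, length.out = W2)
      slab <- as_mat(xp[rows, cols, , , drop = FALSE])
      Wk <- mod$params$W[i, j, , , drop = TRUE]
      if (is.null(dim(Wk))) Wk <- matrix(Wk, dim(mod$params$W)[3],
                                         dim(mod$params$W)[4])
      if (cf$groups == 1) {
        dW[i, j, , ] <- crossprod(slab, dY)
        dslab <- tcrossprod(dY, Wk)
      } else {
        dslab <- matrix(0, nrow(slab), ncol(slab))
        for (g in seq_len(cf$groups)) {
          dW[i, j, , g_out[[g]]] <-
            crossprod(slab[, g_in[[g]], drop = FALSE],
                      dY[, g_out[[g]], drop = FALSE])
          dslab[, g_in[[g]]] <- dslab[, g_in[[g]]] +
            tcrossprod(dY[, g_out[[g]], drop = FALSE],
                       Wk[g_in[[g]] - (g - 1) * length(g_in[[g]]),
                          g_out[[g]], drop = FALSE])
        }
      }
      dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] +
        array(dslab, c(H2, W2, d[3], d[4]))
    }
  }
  dx <- if (cf$pad > 0) {
    dxp[cf$pad + seq_len(d[1]), cf$pad + seq_len(d[2]), , , drop = FALSE]
  } else dxp
  grads <- list(W = dW)
  if (cf$bias) grads$b <- colSums(dY)
  list(dx = dx, grads = grads)
}

## ---- batchnorm --------------------------------------------------------

bn_forward <- function(mod, x, train) {
  is4d <- mod$type == "bn"
  xm <- if (is4d) as_mat(x) else x
  M <- nrow(xm)
  st <- mod$state
  if (train || is.null(st$rm)) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    mom <- mod$cfg$momentum
    st$rm <- if (is.null(st$rm)) mu else (1 - mom) * st$rm + mom * mu
    st$rv <- if (is.null(st$rv)) v else (1 - mom) * st$rv + mom * v
  } else {
    mu <- st$rm
    v <- st$rv
  }
  ivar <- 1 / sqrt(v + mod$cfg$eps)
  xhat <- (xm - rep(mu, each = M)) * rep(ivar, each = M)
  y <- xhat * rep(mod$params$gamma, each = M) +
    rep(mod$params$beta, each = M)
  if (is4d) dim(y) <- dim(x)
  list(y = y, cache = list(xhat = xhat, ivar = ivar, M = M,
                           dims = if (is4d) dim(x) else NULL,
                           train = train))
}

bn_backward <- function(mod, cache, dy) {
  dym <- if (!is.null(cache$dims)) as_mat(dy) else dy
  M <- cache$M
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  g_iv <- mod$params$gamma * cache$ivar
  if (cache$train) {
    dx <- rep(g_iv / M, each = M) *
      (M * dym - rep(dbeta, each = M) - xhat * rep(dgamma, each = M))
  } else {
    dx <- dym * rep(g_iv, each = M)
  }
  if (!is.null(cache$dims)) dim(dx) <- cache$dims
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

## ---- simple layers ----------------------------------------------------

relu_forward <- function(x) list(y = pmax(x, 0), cache = x > 0)

avgpool_forward <- function(x) {
  d <- dim(x)
  H2 <- d[1] %/% 2; W2 <- d[2] %/% 2
  ri <- seq_len(2 * H2); ci <- seq_len(2 * W2)
  xo <- x[ri, ci, , , drop = FALSE]
  y <- (xo[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2), , , drop = FALSE] +
        xo[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2), , , drop = FALSE] +
        xo[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2), , , drop = FALSE] +
        xo[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2), , , drop = FALSE]) / 4
  list(y = y, cache = d)
}

avgpool_backward <- function(cache, dy) {
  d <- cache
  H2 <- d[1] %/% 2; W2 <- d[2] %/% 2
  dx <- array(0, d)
  q <- dy / 4
  dx[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2), , ] <- q
  dx[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2), , ] <- q
  dx[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2), , ] <- q
  dx[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2), , ] <- q
  dx
}

maxpool_forward <- function(mod, x) {
  cf <- mod$cfg
  d <- dim(x)
  H2 <- conv_out_dim(d[1], cf$k, cf$stride, cf$pad, 1)
  W2 <- conv_out_dim(d[2], cf$k, cf$stride, cf$pad, 1)
  xp <- array(-Inf, c(d[1] + 2 * cf$pad, d[2] + 2 * cf$pad, d[3], d[4]))
  xp[cf$pad + seq_len(d[1]), cf$pad + seq_len(d[2]), , ] <- x
  best <- array(-Inf, c(H2, W2, d[3], d[4]))
  win <- array(0L, c(H2, W2, d[3], d[4]))
  idx <- 0L
  for (i in seq_len(cf$k)) {
    rows <- seq(i, by = cf$stride, length.out = H2)
    for (j in seq_len(cf$k)) {
      idx <- idx + 1L
      cols <- seq(j, by = cf$stride, length.out = W2)
      slab <- xp[rows, cols, , , drop = FALSE]
      upd <- slab > best
      best[upd] <- slab[upd]
      win[upd] <- idx
    }
  }
  list(y = best, cache = list(win = win, dims = d, H2 = H2, W2 = W2))
}

maxpool_backward <- function(mod, cache, dy) {
  cf <- mod$cfg
  d <- cache$dims
  H2 <- cache$H2; W2 <- cache$W2
  dxp <- array(0, c(d[1] + 2 * cf$pad, d[2] + 2 * cf$pad, d[3], d[4]))
  idx <- 0L
  for (i in seq_len(cf$k)) {
    rows <- seq(i, by = cf$stride, length.out = H2)
    for (j in seq_len(cf$k)) {
      idx <- idx + 1L
      cols <- seq(j, by = cf$stride, length.out = W2)
      sel <- cache$win == idx
      add <- array(0, c(H2, W2, d[3], d[4]))
      add[sel] <- dy[sel]
      dxp[rows, cols, , ] <- dxp[rows, cols, , ] + add
    }
  }
  dxp[cf$pad + seq_len(d[1]), cf$pad + seq_len(d[2]), , , drop = FALSE]
}

gap_forward <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  list(y = matrix(colMeans(xm), d[3], d[4]), cache = d)
}

gap_backward <- function(cache, dy) {
  d <- cache
  dx <- array(rep(as.vector(dy), each = d[1] * d[2]) / (d[1] * d[2]), d)
  dx
}

linear_forward <- function(mod, x) {
  y <- x %*% mod$params$W
  if (mod$cfg$bias) y <- y + rep(mod$params$b, each = nrow(x))
  list(y = y, cache = x)
}

linear_backward <- function(mod, cache, dy) {
  grads <- list(W = crossprod(cache, dy))
  if (mod$cfg$bias) grads$b <- colSums(dy)
  list(dx = tcrossprod(dy, mod$params$W), grads = grads)
}

## ---- generic dispatch -------------------------------------------------

nn_forward <- function(mod, x, train = TRUE) {
  switch(mod$type,
    conv = conv_forward(mod, x),
    bn = ,
    bn1d = bn_forward(mod, x, train),
    relu = relu_forward(x),
    avgpool = avgpool_forward(x),
    maxpool = maxpool_forward(mod, x),
    gap = gap_forward(x),
    linear = linear_forward(mod, x),
    sk = sk_forward(mod, x, train),
    stop("unknown module type ", mod$type)
  )
}

nn_backward <- function(mod, cache, dy) {
  switch(mod$type,
    conv = conv_backward(mod, cache, dy),
    bn = ,
    bn1d = bn_backward(mod, cache, dy),
    relu = list(dx = dy * cache, grads = list()),
    avgpool = list(dx = avgpool_backward(cache, dy), grads = list()),
    maxpool = list(dx = maxpool_backward(mod, cache, dy), grads = list()),
    gap = list(dx = gap_backward(cache, dy), grads = list()),
    linear = linear_backward(mod, cache, dy),
    sk = sk_backward(mod, cache, dy),
    stop("unknown module type ", mod$type)
  )
}

## ---- parameter bookkeeping --------------------------------------------

# walk a (possibly nested) params structure, returning a flat named list;
# unnamed list elements (e.g. blocks, layers) are addressed by index
flatten_params <- function(p, prefix = "") {
  out <- list()
  nms <- names(p)
  for (i in seq_along(p)) {
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
    full <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(p[[i]])) out <- c(out, flatten_params(p[[i]], full))
    else out[[full]] <- p[[i]]
  }
  out
}

assign_flat <- function(p, flat, prefix = "") {
  nms <- names(p)
  for (i in seq_along(p)) {
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
    full <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(p[[i]])) p[[i]] <- assign_flat(p[[i]], flat, full)
    else p[[i]] <- flat[[full]]
  }
  p
}

n_params <- function(p) sum(vapply(flatten_params(p), length, numeric(1)))
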